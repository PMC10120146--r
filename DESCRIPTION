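Package: ventergy
Title: Partitioning Tidal Inflation Energy into Safe and Hazardous Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculator and simulator for assessing the risk of
    ventilator-induced lung injury from the energetics of passive mechanical
    ventilation. Partitions the elastic energy of each inflation cycle into
    safe and hazardous fractions at a threshold elastic airway pressure,
    solves inversely for driving-pressure, plateau-pressure and tidal-volume
    targets that achieve a requested hazard (or safety) ratio, extends the
    threshold regionally along the gravitational pleural-pressure gradient,
    expresses damaging power as frequency times supra-threshold energy, and
    simulates the intracycle pressure-volume-energy trajectory of a single
    inflation under constant, decelerating or custom flow profiles. Includes
    an independent numeric pressure-volume area oracle, batch scenario I/O
    (JSON/CSV in, TSV/JSON out), a seeded fixture generator and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
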