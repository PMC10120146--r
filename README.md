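# ventergy

Energetics of passive mechanical ventilation for assessing the risk of
ventilator-induced lung injury (VILI), built for respiratory physiologists,
intensivists and modellers who reason about lung protection in terms of
pressures, volumes, energy and power rather than any single guideline
number.

During each passive inflation the ventilator stores elastic energy in the
respiratory system — the area under the pressure–volume line that climbs
from PEEP to the plateau pressure `Ps` while the tidal volume `VT` is
delivered. Only the part of that energy delivered while the elastic
pressure exceeds a *threshold pressure* `Pt` is considered potentially
damaging. With `DP = Ps − PEEP` (the driving pressure) the per-cycle
energies are

```
W_elastic = ½ (Ps + PEEP) · VT        (all conserved energy, PEEP block included)
W_drive   = ½ DP · VT = VT²/(2C)      (tidal component only)
```

and the supra-threshold ("hazard") fractions follow from the P–V area
geometry:

```
HR_drive   = (2·DP + Pt − Ps)(Ps − Pt) / DP²  =  1 − ((Pt − PEEP)/DP)²
HR_elastic = (Ps² − Pt²) / (Ps² − PEEP²)
SR = 1 − HR                                      (safety ratio)
```

Damaging power is frequency × supra-threshold energy per cycle,
`f · HR · W`. The package also:

* inverse-solves the hazard formulas for **targets** — the driving
  pressure, plateau pressure and tidal volume that achieve a requested
  hazard (or safety) ratio;
* extends the threshold **regionally** along the gravitational
  pleural-pressure gradient (non-dependent lung: lower local `Pt`, more
  vulnerable; prone position: narrower gradient, narrower spread of
  vulnerability);
* **simulates** the time-resolved single-compartment inflation under
  constant, decelerating or custom flow profiles — same total elastic
  energy for every waveform, but different intracycle power and time spent
  above `Pt`;
* verifies every closed form against an independent **numeric P–V area
  oracle**, and runs **batches** (JSON/CSV in, TSV/JSON out) with per-row
  error collection.

## Worked example

A breath at plateau 25 cmH2O on PEEP 5 (so DP = 20), 0.5 L at 20/min, with
the damage threshold set at 20 cmH2O:

```r
library(ventergy)

sc <- ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20)
sc |> partition_energy() |> tidy()
#> # A tibble: 16 × 4
#>    name       quantity                   value unit
#>    <chr>      <chr>                      <dbl> <chr>
#>  1 scenario_1 w_elastic                  7.5   cmH2O.L
#>  2 scenario_1 w_drive                    5     cmH2O.L
#>  3 scenario_1 hr_drive                   0.438 ratio
#>  4 scenario_1 hr_elastic                 0.375 ratio
#>  5 scenario_1 sr_drive                   0.562 ratio
#>  6 scenario_1 sr_elastic                 0.625 ratio
#>  7 scenario_1 hazardous_energy_drive     2.19  cmH2O.L
#>  8 scenario_1 hazardous_energy_elastic   2.81  cmH2O.L
#>  9 scenario_1 driving_power            100     cmH2O.L/min
#> 10 scenario_1 elastic_power            150     cmH2O.L/min
#> 11 scenario_1 damaging_power_drive      43.8   cmH2O.L/min
#> 12 scenario_1 damaging_power_elastic    56.2   cmH2O.L/min
#> 13 scenario_1 driving_power_J            9.81  J/min
#> 14 scenario_1 elastic_power_J           14.7   J/min
#> 15 scenario_1 damaging_power_drive_J     4.29  J/min
#> 16 scenario_1 damaging_power_elastic_J   5.52  J/min
```

Reading: each breath stores 7.5 cmH2O·L of elastic energy, 5 of which is
tidal (drive) energy; 43.75% of the drive energy (2.19 cmH2O·L per breath)
is delivered above the 20 cmH2O threshold, which at 20 breaths/min amounts
to a damaging drive power of 43.8 cmH2O·L/min (4.29 J/min) out of a total
elastic power of 150 cmH2O·L/min.

To bring the hazardous fraction of drive energy down to 20%:

```r
sc |> prescribe_targets(0.2, variant = "drive", mode = "hazard") |> tidy()
#> # A tibble: 1 × 10
#>   name  variant mode  requested_ratio hr_requested target_dp target_ps target_vt
#>   <chr> <chr>   <chr>           <dbl>        <dbl>     <dbl>     <dbl>     <dbl>
#> 1 scen… drive   haza…             0.2          0.2      2.64        25    0.0660
#> # ℹ 2 more variables: achieved_ratio <dbl>, held_fixed <chr>
```

`glance()` on the prescription reports a maximum round-trip error of
~9e-16: re-inserting the solved target into the hazard formula recovers the
requested ratio. Regional profiles (`regional_hazard()`), single-breath
simulations (`simulate_cycle()`, `time_above_threshold()`) and figures
(`autoplot()`, `plot_pv_partition()`) follow the same data-frame-in,
tibble-out pattern; `inst/cli/ventergy.R` exposes the whole toolkit as a
command line (`compute`, `batch`, `target`, `regional`, `simulate`,
`fixtures`).

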