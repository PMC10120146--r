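# Shared fixtures, built in code.

# Reference scenario used throughout: Ps 25, PEEP 5, VT 0.5 L, f 20, Pt 20.
# Closed-form values: w_elastic 7.5, w_drive 5, hr_drive 0.4375,
# hr_elastic 0.375 (oracle-verified in test-oracle.R).
ref_scenario <- function(f = 20, pt = 20) {
  ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = f, pt = pt)
}

# Randomised valid (ps, peep, pt) pressure triples for property tests.
random_triples <- function(n, seed = 42) {
  withr::with_seed(seed, {
    peep <- runif(n, 0, 15)
    dp <- runif(n, 5, 25)
    ps <- peep + dp
    pt <- peep + runif(n) * dp
    tibble::tibble(ps = ps, peep = peep, pt = pt, dp = dp)
  })
}
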