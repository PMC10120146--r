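test_that("every flow waveform delivers the same elastic energy", {
  sc <- ref_scenario()
  w_ref <- w_elastic(25, 5, 0.5)
  e_const <- max(simulate_cycle(sc, kind = "constant", ti = 1)$cum_energy)
  e_decel <- max(simulate_cycle(sc, kind = "decelerating", ti = 1)$cum_energy)
  expect_equal(e_const, w_ref, tolerance = 1e-6)
  expect_equal(e_decel, w_ref, tolerance = 1e-6)
  expect_equal(e_const, e_decel, tolerance = 1e-6)

  # randomised sampled profiles, renormalised to the tidal volume
  withr::with_seed(99, {
    for (k in 1:5) {
      tt <- seq(0, 1, length.out = 40)
      prof <- flow_profile("custom", ti = 1, vt = 0.5, time = tt,
                           flow = runif(40, 0.05, 1))
      e <- max(simulate_cycle(sc, profile = prof)$cum_energy)
      expect_equal(e, w_ref, tolerance = 1e-6)
    }
  })
})

test_that("trace invariants: monotone volume, plateau at end-inspiration", {
  sc <- ref_scenario()
  for (kind in c("constant", "decelerating")) {
    tr <- simulate_cycle(sc, kind = kind, ti = 0.8)
    expect_true(all(diff(tr$volume) >= 0))
    expect_equal(tr$p_elastic[nrow(tr)], 25, tolerance = 1e-6)
    expect_equal(tr$volume[nrow(tr)], 0.5, tolerance = 1e-12)
    expect_equal(tr$flow[1] * 0 + pracma::trapz(tr$t, tr$flow), 0.5,
                 tolerance = 1e-6)
  }
})

test_that("time above threshold matches the analytic crossing times", {
  sc <- ref_scenario()
  # constant flow: elastic pressure linear in time, crosses Pt at
  # (Pt - PEEP)/DP * Ti = 0.75 s, leaving 0.25 s above threshold
  tr <- simulate_cycle(sc, kind = "constant", ti = 1)
  expect_equal(attr(tr, "time_above_pt"), 0.25, tolerance = 1e-9)
  expect_equal(time_above_threshold(tr, 20), 0.25, tolerance = 1e-9)
  # threshold at the plateau: never exceeded
  expect_equal(time_above_threshold(tr, 25), 0)
  # threshold at/below PEEP: the whole inspiration is supra-threshold
  expect_equal(time_above_threshold(tr, 5), 1)
  expect_equal(time_above_threshold(tr, 3), 1)

  # decelerating ramp: V(tau)/VT = 2 tau - tau^2, so the crossing solves
  # 2 tau - tau^2 = (Pt - PEEP)/DP, i.e. tau = 1 - sqrt(1 - 0.75) = 0.5
  trd <- simulate_cycle(sc, kind = "decelerating", ti = 1)
  expect_equal(attr(trd, "time_above_pt"), 0.5, tolerance = 1e-6)
  # the decelerating profile front-loads volume, so it spends longer above
  # threshold than constant flow for the same breath
  expect_gt(attr(trd, "time_above_pt"), attr(tr, "time_above_pt"))
})

test_that("crossing-time error shrinks about quadratically with the grid", {
  # threshold 18: the decelerating crossing solves 2 tau - tau^2 = 0.65,
  # tau = 1 - sqrt(0.35), an irrational instant that never lands on a node
  sc <- ref_scenario(pt = 18)
  truth <- sqrt(0.35) # time above threshold, s
  errs <- vapply(c(100, 400, 1600), function(n) {
    tr <- simulate_cycle(sc, kind = "decelerating", ti = 1, n_steps = n)
    abs(attr(tr, "time_above_pt") - truth)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # roughly 16x smaller per 4x refinement; allow slack for where the
  # crossing sits inside its grid cell
  expect_lt(errs[2], errs[1] / 4)
  expect_lt(errs[3], errs[1] / 50)
  # energy stays at the closed-form value at every resolution
  for (n in c(100, 400, 1600)) {
    tr <- simulate_cycle(sc, kind = "decelerating", ti = 1, n_steps = n)
    expect_equal(max(tr$cum_energy), 7.5, tolerance = 1e-9)
  }
})

test_that("resistance shifts airway pressure but never the elastic energy", {
  sc <- ref_scenario()
  tr5 <- simulate_cycle(sc, kind = "constant", ti = 1, r = 5)
  tr20 <- simulate_cycle(sc, kind = "constant", ti = 1, r = 20)
  expect_equal(max(tr5$cum_energy), max(tr20$cum_energy), tolerance = 1e-12)
  expect_gt(max(tr20$p_airway), max(tr5$p_airway))
  expect_equal(tr5$p_elastic, tr20$p_elastic)
  expect_equal(tr5$p_elastic[nrow(tr5)], 25, tolerance = 1e-9)
})

test_that("profile validation and volume matching are enforced", {
  sc <- ref_scenario()
  expect_error(simulate_cycle(sc, profile = flow_profile("constant", 1, 0.4)),
               "tidal volume")
  expect_error(flow_profile("constant", ti = 0, vt = 0.5), "ti")
  expect_error(flow_profile("custom", ti = 1, vt = 0.5,
                            time = c(0, 0.5, 1), flow = c(1, -0.1, 1)),
               "non-negative")
  expect_error(flow_profile("custom", ti = 1, vt = 0.5,
                            time = c(0, 0.6), flow = c(1, 1)),
               "span")
  expect_error(simulate_cycle(sc, kind = "constant", n_steps = 50), "n_steps")
  expect_error(simulate_cycle(ventilation_scenarios(
    ps = c(25, 30), peep = 5, vt = 0.5, f = 20, pt = 20)), "single scenario")
})

test_that("trace CSV export is tidy and round-trips", {
  sc <- ref_scenario()
  tr <- simulate_cycle(sc, kind = "constant", ti = 1, n_steps = 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("t", "flow", "volume", "p_elastic", "p_airway",
                       "cum_energy"))
  expect_equal(back$cum_energy, tr$cum_energy, tolerance = 1e-12)
})
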