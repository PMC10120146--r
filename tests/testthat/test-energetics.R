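test_that("per-cycle energies match the P-V area geometry", {
  expect_equal(w_elastic(25, 5, 0.5), 7.5)   # 1/2 (Ps + PEEP) VT
  expect_equal(w_drive(25, 5, 0.5), 5)       # 1/2 DP VT
  # both printed algebraic forms of w_elastic agree when C is supplied
  vt <- 0.5; c <- 0.025; peep <- 5; ps <- vt / c + peep
  expect_equal(w_elastic(ps, peep, vt), vt^2 / (2 * c) + vt * peep,
               tolerance = 1e-12)
  expect_equal(w_drive(ps, peep, vt), vt^2 / (2 * c), tolerance = 1e-12)
  # zero PEEP: the PEEP block vanishes and the two accountings coincide
  expect_identical(w_elastic(20, 0, 0.4), w_drive(20, 0, 0.4))
  expect_equal(w_drive(20, 0, 0.4), 4)
  expect_error(w_elastic(5, 5, 0.5), "degenerate")
})

test_that("hazard ratios match their closed forms and boundary values", {
  expect_equal(hr_drive(25, 5, 20), 0.4375)
  expect_equal(hr_elastic(25, 5, 20), 0.375)
  # boundaries are exact
  expect_identical(hr_drive(25, 5, 25), 0)
  expect_identical(hr_drive(25, 5, 5), 1)
  expect_identical(hr_elastic(25, 5, 25), 0)
  expect_identical(hr_elastic(25, 5, 5), 1)
})

test_that("implemented hr_drive equals the printed product form everywhere", {
  g <- random_triples(500)
  printed <- (2 * g$dp + g$pt - g$ps) * (g$ps - g$pt) / g$dp^2
  expect_equal(hr_drive(g$ps, g$peep, g$pt), printed, tolerance = 1e-12)
  # and the quadratic identity 1 - ((pt - peep)/dp)^2
  expect_equal(hr_drive(g$ps, g$peep, g$pt),
               1 - ((g$pt - g$peep) / g$dp)^2, tolerance = 1e-12)
})

test_that("hazard ratio structure: complement, ordering, monotonicity, zero-PEEP collapse", {
  g <- random_triples(500, seed = 7)
  hd <- hr_drive(g$ps, g$peep, g$pt)
  he <- hr_elastic(g$ps, g$peep, g$pt)
  sr <- safety_ratios(g$ps, g$peep, g$pt)
  expect_true(all(hd >= 0 & hd <= 1 & he >= 0 & he <= 1))
  expect_equal(sr$sr_drive + hd, rep(1, nrow(g)), tolerance = 1e-15)
  expect_equal(sr$sr_elastic + he, rep(1, nrow(g)), tolerance = 1e-15)
  # with a PEEP block and interior threshold, the elastic hazard fraction
  # is diluted relative to the drive fraction
  interior <- g$peep > 0 & g$pt > g$peep & g$pt < g$ps
  expect_true(all(he[interior] <= hd[interior]))

  # strictly decreasing in pt on (peep, ps)
  pts <- seq(5 + 1e-6, 25 - 1e-6, length.out = 50)
  expect_true(all(diff(hr_drive(25, 5, pts)) < 0))
  expect_true(all(diff(hr_elastic(25, 5, pts)) < 0))
  # hr_elastic strictly increasing in ps for fixed peep, pt
  pss <- seq(21, 40, length.out = 40)
  expect_true(all(diff(hr_elastic(pss, 5, 20)) > 0))

  # PEEP = 0 collapses the two accountings exactly
  g0 <- random_triples(200, seed = 11)
  expect_identical(hr_drive(g0$ps, 0, pmin(g0$pt, g0$ps)),
                   hr_elastic(g0$ps, 0, pmin(g0$pt, g0$ps)))
})

test_that("threshold policy clamps by default and errors in strict mode", {
  expect_equal(hr_drive(25, 5, 30), 0)  # pt above ps: nothing supra-threshold
  expect_equal(hr_drive(25, 5, 2), 1)   # pt below peep: everything hazardous
  expect_equal(hr_elastic(25, 5, 30), 0)
  expect_error(hr_drive(25, 5, 30, policy = "strict"), "pt outside")
  expect_error(hr_elastic(25, 5, 2, policy = "strict"), "pt outside")
})

test_that("partition_energy() populates energies, splits and powers coherently", {
  p <- partition_energy(ref_scenario())
  expect_s3_class(p, "energy_partition")
  expect_equal(p$w_elastic, 7.5)
  expect_equal(p$w_drive, 5)
  expect_equal(p$hazardous_energy_drive, 2.1875)       # 0.4375 x 5
  expect_equal(p$hazardous_energy_elastic, 0.375 * 7.5)
  expect_equal(p$damaging_power_drive, 43.75)          # x f = 20
  expect_equal(p$elastic_power, 150)
  expect_equal(p$driving_power_J, 100 * 0.0980665)
  expect_equal(p$damaging_power_drive_J, 43.75 * 0.0980665)

  # doubling frequency doubles every power exactly, energies unchanged
  p2 <- partition_energy(ref_scenario(f = 40))
  pow <- c("driving_power", "elastic_power", "damaging_power_drive",
           "damaging_power_elastic")
  for (col in pow) expect_identical(p2[[col]], 2 * p[[col]])
  expect_identical(p2$w_elastic, p$w_elastic)
  expect_identical(p2$w_drive, p$w_drive)

  # pt at the plateau: innocuous power - elastic power positive, damaging zero
  pinn <- partition_energy(ref_scenario(pt = 25))
  expect_identical(pinn$damaging_power_drive, 0)
  expect_identical(pinn$damaging_power_elastic, 0)
  expect_gt(pinn$elastic_power, 0)
})

test_that("tidy() and glance() summarise partitions", {
  p <- partition_energy(ref_scenario())
  td <- tidy(p)
  expect_named(td, c("name", "quantity", "value", "unit"))
  expect_equal(td$value[td$quantity == "w_elastic"], 7.5)
  expect_equal(td$unit[td$quantity == "damaging_power_drive_J"], "J/min")
  gl <- glance(p)
  expect_equal(gl$n_scenarios, 1)
  expect_equal(gl$mean_hr_drive, 0.4375)
})
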