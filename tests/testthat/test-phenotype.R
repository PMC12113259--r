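test_that("gamma is zero for symmetric activities and bounded in [-1, 1]", {
  tt <- 0:150
  r <- trace(tt, 1 + 0.3 * sin(tt / 20), "r")
  s <- compute_gamma(r, trace(tt, r$value, "c"), w = 1)
  expect_equal(s$gamma, 0)
  expect_identical(s$label, "mixed")
  # null stimulus scores exactly zero (0/0 convention)
  flat <- trace(tt, rep(1, length(tt)), "r")
  expect_equal(compute_gamma(flat, trace(tt, flat$value, "c"), w = 2)$gamma, 0)

  w <- calibrate_weight(default_params())
  for (seed in 1:6) {
    pr <- random_protocol(seed, t_end = 150)
    rho <- with_seed(seed + 20, runif(1, 0, 3))
    kp <- kinetic_params(rho = rho)
    g <- simulate_recruitment(pr, recruitment_params())
    gam <- gamma_for_stimulus(g, kp, w)
    expect_gte(gam, -1)
    expect_lte(gam, 1)
  }
  expect_error(compute_gamma(trace(0:50, rep(1, 51), "r"),
                             trace(0:50, rep(1, 51), "c"), w = 1),
               "window")
})

test_that("weight calibration zeroes gamma at the transition and is idempotent", {
  kp <- default_params()
  w <- calibrate_weight(kp)
  expect_gt(w, 1)
  g <- step_stimulus(2, t_end = 120)
  expect_lt(abs(gamma_for_stimulus(g, kinetic_params(rho = 0.5), w)), 1e-4)
  # monotonicity around the calibrated root
  expect_gt(gamma_for_stimulus(g, kinetic_params(rho = 0.25), w), 0)
  expect_lt(gamma_for_stimulus(g, kinetic_params(rho = 1.0), w), 0)
  # doubling the step amplitude preserves the signs
  g3 <- step_stimulus(3, t_end = 120)
  expect_gt(gamma_for_stimulus(g3, kinetic_params(rho = 0.25), w), 0)
  expect_lt(gamma_for_stimulus(g3, kinetic_params(rho = 1.0), w), 0)
  # recalibration reproduces the weight
  expect_equal(calibrate_weight(kp), w, tolerance = 1e-6)
})

test_that("gamma decreases monotonically with Geq/Kb", {
  w <- calibrate_weight(default_params())
  g <- simulate_recruitment(std_train(t_end = 120), recruitment_params())
  gam <- vapply(seq(0, 2, length.out = 50), function(rho) {
    gamma_for_stimulus(g, kinetic_params(rho = rho), w)
  }, 0)
  expect_gt(gam[1], 0)          # retraction at vanishing expression
  expect_true(all(diff(gam) <= 1e-9))
})

test_that("the phenotype map has a frequency-switchable band near Geq/Kb 0.5", {
  kp <- default_params()
  w <- calibrate_weight(kp)
  map <- build_phenotype_map(seq(0, 1.5, 0.05), seq(10, 120, 5), kp, w)
  # zero expression retracts at every period
  expect_true(all(map$label[1, ] == "retraction"))
  band <- switchable_band(map, periods = seq(15, 60, 5))
  expect_gt(length(band$rho), 0)
  expect_gte(band$center, 0.35)
  expect_lte(band$center, 0.65)
  # at the band center, high frequency protrudes and low frequency retracts
  i <- which.min(abs(map$rho_grid - band$center))
  expect_identical(map$label[i, map$period_grid == 15], "protrusion")
  expect_identical(map$label[i, map$period_grid == 60], "retraction")
  # along the period axis each row flips at most once: protrusion at short
  # periods, retraction at long, never protrusion beyond a retraction
  # (mixed may dither near the boundary where the pulse count inside the
  # scoring window changes discretely with the period)
  for (i in seq_len(nrow(map$label))) {
    row <- map$label[i, ]
    if (any(row == "protrusion") && any(row == "retraction")) {
      expect_lt(max(which(row == "protrusion")),
                min(which(row == "retraction")))
    }
  }
  expect_error(build_phenotype_map(numeric(0), c(10), kp, w), "nonempty")
})

test_that("pulse intensity alone never switches the phenotype", {
  kp <- default_params()
  w <- calibrate_weight(kp)
  low <- intensity_sweep(0.2, 30, kp, w)
  expect_true(all(low$label == "retraction"))
  expect_false(attr(low, "switched"))
  high <- intensity_sweep(1.5, 30, kp, w)
  expect_true(all(high$label == "protrusion"))
  expect_false(attr(high, "switched"))
  null <- intensity_sweep(0.5, 30, kp, w, folds = 1)
  expect_equal(null$gamma, 0)
  expect_identical(null$label, "mixed")
})
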