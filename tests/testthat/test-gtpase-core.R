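test_that("rho = 0 reduces to first-order activation with the closed form", {
  g <- step_stimulus(2, t_end = 120)
  r <- simulate_rhoa(g, default_params(rho = 0))
  # dr/dt = k2 (2 - r), r(0) = 1  =>  r(t) = 2 - exp(-k2 t)
  expect_equal(r$value[r$time_s == 60], 2 - exp(-0.014 * 60), tolerance = 1e-6)
  cc <- simulate_cdc42(g, default_params())
  expect_equal(cc$value, r$value, tolerance = 1e-6)
})

test_that("sequestration jump follows the conservation of the active pool", {
  g <- step_stimulus(2, t_end = 120)
  r <- simulate_rhoa(g, default_params(rho = 1))
  expect_equal(r$value[r$time_s == 0], 2 / 3, tolerance = 1e-9)
  # independent check: resolve the jump as a fast finite ramp, integrated
  # on sampled data with no analytic jump handling
  pr <- pulse_protocol(0.5, amplitude_fold = 2, t_end = 2)
  gr <- simulate_recruitment(pr, recruitment_params(),
                             grid = seq(0, 2, by = 0.002), rise_s = 0.01)
  expect_null(attr(gr, "gmodel"))
  rr <- simulate_rhoa(gr, kinetic_params(rho = 1))
  r_after <- rr$value[which.min(abs(rr$time_s - 0.52))]
  expect_equal(r_after, 2 / 3, tolerance = 1e-3)
})

test_that("jump formula holds across random pulse trains", {
  for (seed in 1:4) {
    pr <- random_protocol(seed)
    rho <- with_seed(seed + 100, runif(1, 0.2, 3))
    # grid carries a point just before each pulse so the left limit of r
    # is available directly
    grid <- sort(unique(c(seq(0, pr$t_end, 1), pr$pulse_times - 1e-7)))
    g <- simulate_recruitment(pr, recruitment_params(), grid = grid)
    r <- simulate_rhoa(g, kinetic_params(rho = rho))
    for (tk in pr$pulse_times[pr$pulse_times > 0]) {
      i <- which(abs(g$time_s - tk) < 1e-9)
      j <- which(abs(g$time_s - (tk - 1e-7)) < 1e-9)
      g_minus <- g$value[j]
      g_plus <- g_minus + pr$delta
      expected <- r$value[j] * (1 + rho * g_minus) / (1 + rho * g_plus)
      expect_equal(r$value[i], expected, tolerance = 1e-6)
    }
  }
})

test_that("all activities stay positive and converge to the fixed point", {
  for (seed in 1:5) {
    pr <- random_protocol(seed)
    rho <- with_seed(seed + 50, runif(1, 0, 3))
    kp <- kinetic_params(rho = rho)
    g <- simulate_recruitment(pr, recruitment_params())
    r <- simulate_rhoa(g, kp)
    cc <- simulate_cdc42(g, kp)
    b <- simulate_biosensor(r, kp)
    expect_true(all(r$value > 0))
    expect_true(all(cc$value > 0))
    expect_true(all(b$value > 0))
  }
  # constant g = ghat: r, c, b -> ghat, r at rate k2 / (1 + rho ghat)
  ghat <- 2
  g <- step_stimulus(ghat, t_end = 4000)
  for (rho in c(0, 0.5, 2)) {
    kp <- kinetic_params(rho = rho)
    r <- simulate_rhoa(g, kp)
    cc <- simulate_cdc42(g, kp)
    b <- simulate_biosensor(r, kp)
    expect_equal(r$value[length(r$value)], ghat, tolerance = 1e-3)
    expect_equal(cc$value[length(cc$value)], ghat, tolerance = 1e-3)
    expect_equal(b$value[length(b$value)], ghat, tolerance = 1e-3)
    # relaxation rate bound: log-distance to the fixed point shrinks at
    # least as fast as exp(-k2 t / (1 + rho ghat)) predicts ... up to the
    # initial sequestration dip, so check from t = 500 on
    rate <- 0.014 / (1 + rho * ghat)
    d500 <- abs(r$value[r$time_s == 500] - ghat)
    d1500 <- abs(r$value[r$time_s == 1500] - ghat)
    expect_lt(d1500, d500 * exp(-rate * 1000) * 1.05)
  }
})

test_that("Cdc42 is continuous at pulses while RhoA jumps down", {
  pr <- std_train(t_end = 300)
  g <- simulate_recruitment(pr, recruitment_params())
  kp <- kinetic_params(rho = 1.5)
  r <- simulate_rhoa(g, kp)
  cc <- simulate_cdc42(g, kp)
  # at interior pulse times r drops by more than the inter-sample scale,
  # c never does
  for (tk in pr$pulse_times[-1]) {
    i <- which(g$time_s == tk)
    expect_lt(r$value[i] - r$value[i - 1], -0.02)
    expect_gt(cc$value[i] - cc$value[i - 1], -1e-6)
  }
})

test_that("biosensor lags and attenuates the sequestration dip", {
  g <- step_stimulus(2, t_end = 300)
  kp <- kinetic_params(rho = 1)
  r <- simulate_rhoa(g, kp)
  b <- simulate_biosensor(r, kp)
  expect_gt(min(b$value), min(r$value))
  expect_gt(b$time_s[which.min(b$value)], r$time_s[which.min(r$value)])
  # closed-form first-order response to a step of r
  rstep <- trace(seq(0, 60, 0.5), rep(2, 121), channel = "r")
  bs <- simulate_biosensor(rstep, kinetic_params(koff_sensor = 0.08))
  expect_equal(bs$value[bs$time_s == 12.5], 2 - exp(-1), tolerance = 1e-9)
})

test_that("biosensor shows the dip-then-rise shape at high Geq/Kb", {
  pr <- pulse_train(30, 2, t_end = 600)
  g <- simulate_recruitment(pr, recruitment_params())
  for (rho in c(1, 1.5, 2)) {
    kp <- kinetic_params(rho = rho)
    b <- simulate_biosensor(simulate_rhoa(g, kp), kp)
    expect_lt(min(b$value[b$time_s <= 60]), 1)
    expect_gt(b$value[b$time_s == 600], 1)
  }
})

test_that("quasi-steady-state solution agrees with the mass-action oracle", {
  pr <- std_train(t_end = 600)
  g <- simulate_recruitment(pr, recruitment_params())
  d <- qssa_oracle_distance(g, kinetic_params(rho = 0.5), ratio = 100)
  expect_lt(d$sup, 0.02)
  # tighter binding, tighter agreement
  d5 <- qssa_oracle_distance(g, kinetic_params(rho = 0.5), ratio = 500)
  expect_lt(d5$sup, d$sup)
  # slow binding deviates visibly (regime check, not asserted small)
  d1 <- qssa_oracle_distance(g, kinetic_params(rho = 0.5), ratio = 1)
  expect_gt(d1$sup, d$sup)

  # vanishing Geq/Kb: full model reproduces the rho = 0 closed form
  gstep <- step_stimulus(2, t_end = 300)
  fp <- full_model_params(Geq = 1e-4, Kb = 1, koff_bind = 1.4)
  fs <- simulate_full(gstep, fp, k2 = 0.014)
  expect_equal(fs$r$value, 2 - exp(-0.014 * fs$r$time_s), tolerance = 1e-3)
})

test_that("simulation results serialize with their parameters", {
  sim <- simulate_model(std_train(t_end = 120), default_params(rho = 0.8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_result(sim, path)
  back <- read_sim_result(path)
  expect_equal(back$r$value, sim$r$value, tolerance = 1e-6)
  expect_equal(back$params$rho, 0.8)
  expect_equal(back$protocol$pulse_times, sim$protocol$pulse_times)
})
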