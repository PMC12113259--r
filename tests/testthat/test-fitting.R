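test_that("rho is recovered from noisy synthetic cells", {
  # cells at Geq/Kb = 1 with 5% multiplicative noise, 20-min traces
  ests <- vapply(1:12, function(seed) {
    cell <- gen_cell_traces(1.0, pulse_train(30, 1.5, 1200), default_params(),
                            noise_model(0.05), seed = seed)
    fit_rho(cell$g, cell$b)$estimates[["rho"]]
  }, 0)
  expect_true(all(ests >= 0.8 & ests <= 1.2))
  expect_lt(abs(mean(ests) - 1), 0.1)
})

test_that("noise-free fits are self-consistent and estimator error shrinks with noise", {
  cell0 <- gen_cell_traces(0, pulse_train(30, 1.5, 1200), default_params(),
                           noise_model(0))
  f0 <- fit_rho(cell0$g, cell0$b)
  expect_lt(f0$estimates[["rho"]], 0.02)
  expect_lt(f0$rss, 1e-4)
  expect_identical(f0$convergence, "converged")

  ests <- lapply(c(0.10, 0.05, 0.01), function(sig) {
    vapply(1:8, function(seed) {
      cell <- gen_cell_traces(1.0, pulse_train(30, 1.5, 900), default_params(),
                              noise_model(sig), seed = seed)
      fit_rho(cell$g, cell$b)$estimates[["rho"]]
    }, 0)
  })
  sds <- vapply(ests, stats::sd, 0)
  bias <- vapply(ests, function(e) abs(mean(e) - 1), 0)
  expect_lt(sds[3], sds[1])
  expect_lt(bias[3], 0.05)
})

test_that("a flat biosensor trace is flagged non-identifiable", {
  g <- simulate_recruitment(pulse_train(30, 1.5, 600), recruitment_params(),
                            grid = seq(-30, 600, 1))
  b <- trace(g$time_s, rep(1, nrow(g)), channel = "b")
  fit <- fit_rho(g, b)
  expect_identical(fit$convergence, "nonidentifiable")
  expect_match(fit$flags, "uninformative", all = FALSE)
})

test_that("fit is invariant to a uniform time shift of both traces", {
  cell <- gen_cell_traces(0.8, pulse_train(30, 1.5, 900), default_params(),
                          noise_model(0.05), seed = 11)
  f1 <- fit_rho(cell$g, cell$b)
  shift <- function(tr, dt) trace(tr$time_s + dt, tr$value,
                                  channel = attr(tr, "channel"))
  f2 <- fit_rho(shift(cell$g, 137), shift(cell$b, 137))
  expect_equal(f1$estimates[["rho"]], f2$estimates[["rho"]], tolerance = 1e-6)
})

test_that("accepted objective values decrease monotonically", {
  cell <- gen_cell_traces(0.5, pulse_train(30, 1.5, 600), default_params(),
                          noise_model(0.05), seed = 3)
  f1 <- fit_rho(cell$g, cell$b)
  expect_true(all(diff(f1$trajectory) <= 1e-12))
  cells <- lapply(1:3, function(s) {
    gen_cell_traces(0, pulse_train(30, 1.5, 600), default_params(),
                    noise_model(0.05), seed = s)
  })
  f2 <- fit_k2_koff(cells)
  expect_true(all(diff(f2$trajectory) <= 1e-12))
})

test_that("pooled joint fit recovers k2 and the sensor rate", {
  cells <- lapply(1:6, function(s) {
    gen_cell_traces(0, pulse_train(30, 1.5, 1200), default_params(),
                    noise_model(0.05), seed = s)
  })
  fit <- fit_k2_koff(cells)
  expect_identical(fit$convergence, "converged")
  expect_lt(abs(fit$estimates[["k2"]] - 0.014), 0.003)
  expect_lt(abs(fit$estimates[["koff_sensor"]] - 0.08), 0.04)
  expect_false(any(grepl("lack of fit", fit$flags)))

  # noise-free single cell: recovery to the stimulus-reconstruction accuracy
  cell <- gen_cell_traces(0, pulse_train(30, 1.5, 1200), default_params(),
                          noise_model(0))
  f1 <- fit_k2_koff(list(cell), min_cells = 1)
  expect_equal(f1$estimates[["k2"]], 0.014, tolerance = 1e-2)
  expect_equal(f1$estimates[["koff_sensor"]], 0.08, tolerance = 1e-2)
  expect_lt(f1$rss / f1$n_points, 1e-8)
})

test_that("cohort size and alignment contracts are enforced", {
  cell <- gen_cell_traces(0, pulse_train(30, 1.5, 300), default_params(),
                          noise_model(0.05), seed = 1)
  expect_error(fit_k2_koff(list(cell, cell)), "at least 3")
  g <- trace(0:100, rep(1, 101), "g")
  b <- trace(200:300, rep(1, 101), "b")
  expect_error(fit_rho(g, b), "overlap")
  expect_error(fit_rho(g, trace(0:100, rep(1, 101), "b"), fixed = list(k2 = 0.014)),
               "koff_sensor")
})

test_that("sequestering cells forced through the rho = 0 model are flagged", {
  cells <- lapply(1:5, function(s) {
    gen_cell_traces(0.8, pulse_train(30, 1.5, 1200), default_params(),
                    noise_model(0.05), seed = s)
  })
  fit <- suppressWarnings(fit_k2_koff(cells))
  expect_true(any(grepl("lack of fit", fit$flags)))
  # deactivation rate estimate is biased by the unmodeled sequestration,
  # well beyond the sampling error of a correctly specified fit
  expect_gt(abs(fit$estimates[["k2"]] - 0.014), 0.0015)
})
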