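# shared fixtures: printed point estimates and standard stimuli
default_params <- function(rho = 0) kinetic_params(k2 = 0.014, rho = rho,
                                                   koff_sensor = 0.08)

std_train <- function(period = 30, fold = 1.5, t_end = 300) {
  pulse_train(period, fold, t_end)
}

# random protocol on a 1-s grid, deterministic given seed
random_protocol <- function(seed, t_end = 300, max_pulses = 8) {
  with_seed(seed, {
    n <- sample(1:max_pulses, 1)
    times <- sort(sample(0:(t_end - 20), n))
    while (any(diff(times) < 5)) times <- sort(sample(0:(t_end - 20), n))
    pulse_protocol(times, amplitude_fold = runif(1, 1.1, 3), t_end = t_end)
  })
}

expect_trace_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$time_s, b$time_s, tolerance = tol)
  expect_equal(a$value, b$value, tolerance = tol)
}
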