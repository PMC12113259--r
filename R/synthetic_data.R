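#' Measurement-noise model for synthetic traces
#'
#' Synthetic fluorescence traces carry independent multiplicative Gaussian
#' noise per frame: `x_noisy = x (1 + N(0, sigma))`. The default 5% matches
#' the frame-to-frame scatter of normalized TIRF traces; no temporal
#' autocorrelation is modeled.
#'
#' @param sigma Noise fraction, `>= 0`; default 0.05.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.05) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma), class = "noise_model")
}

apply_noise <- function(values, noise) {
  if (noise$sigma == 0) return(values)
  values * (1 + stats::rnorm(length(values), 0, noise$sigma))
}

#' Generate noisy per-cell recruitment and biosensor traces
#'
#' Stand-in for per-cell microscopy: simulates the clean model (recruitment,
#' RhoA with sequestration at the given `rho`, biosensor) on a grid that
#' includes `pre_s` seconds of pre-activation baseline, then applies
#' independent multiplicative noise to the `g` and `b` channels.
#' Deterministic given `seed`.
#'
#' @param rho Geq/Kb of the synthetic cell.
#' @param protocol A [pulse_protocol()].
#' @param params A [kinetic_params()] supplying `k2` and `koff_sensor`
#'   (its `rho` is ignored in favor of the `rho` argument).
#' @param noise A [noise_model()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param recruit A [recruitment_params()].
#' @param pre_s Pre-activation baseline length in seconds, default 30.
#' @param dt Grid spacing (s), default 1.
#' @return List with noisy traces `g`, `b` and the clean `sim_result`-like
#'   list `clean` (traces `g`, `r`, `b`).
#' @export
gen_cell_traces <- function(rho, protocol, params = kinetic_params(),
                            noise = noise_model(), seed = NULL,
                            recruit = recruitment_params(), pre_s = 30,
                            dt = 1) {
  stopifnot(inherits(protocol, "pulse_protocol"),
            inherits(params, "kinetic_params"),
            inherits(noise, "noise_model"))
  grid <- seq(-pre_s, protocol$t_end, by = dt)
  g <- simulate_recruitment(protocol, recruit, grid = grid)
  kp <- kinetic_params(params$k2, rho, params$koff_sensor)
  r <- simulate_rhoa(g, kp)
  b <- simulate_biosensor(r, kp)
  with_seed(seed, {
    g_noisy <- trace(g$time_s, pmax(apply_noise(g$value, noise), 1e-6), "g")
    b_noisy <- trace(b$time_s, pmax(apply_noise(b$value, noise), 1e-6), "b")
    list(g = g_noisy, b = b_noisy, clean = list(g = g, r = r, b = b),
         rho = rho, seed = seed)
  })
}

# smooth ramp from 0 to 1 over [0, t_ramp]; the area response develops over
# the first minutes after activation onset
area_ramp <- function(t, t_ramp = 150) {
  x <- pmin(pmax(t / t_ramp, 0), 1)
  x * x * (3 - 2 * x)
}

#' Generate a synthetic cell cohort with an expression-phenotype structure
#'
#' Emulates a transient-transfection experiment: per-cell expression `I`
#' (arbitrary fluorescence units) is drawn from a log-normal distribution
#' straddling the phenotype threshold `I_thresh` (~40 a.u.), mapped linearly
#' onto the model's free parameter by `rho = I / (2 I_thresh)` so that the
#' threshold corresponds to `rho = 0.5`, the model's transition point. Each
#' cell is simulated under the shared protocol, scored with
#' [compute_gamma()], and given (i) a true label from the score and (ii) an
#' observed label from a synthetic normalized-area trace read out at 5 min,
#' `area(t) = 1 - beta * gamma * ramp(t)` with multiplicative noise — a
#' deliberate affine stand-in for membrane mechanics, not a mechanical
#' model.
#'
#' @param n Number of cells (`>= 0`).
#' @param protocol A [pulse_protocol()]; default 30 s-period train at fold
#'   1.5 over 5 min.
#' @param params A [kinetic_params()].
#' @param w Phenotype weight; calibrated via [calibrate_weight()] when
#'   missing.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of the expression
#'   distribution; the defaults (`meanlog = log(I_thresh)`, `sdlog = 1`)
#'   center the cohort on the threshold with the decade-plus spread typical
#'   of transient transfection.
#' @param I_thresh Phenotype threshold in a.u., default 40 (arbitrary-unit
#'   convention only).
#' @param beta Gain of the affine area readout, default 0.6.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the cohort is bit-reproducible given the seed.
#' @param T Scoring window (s), default 120.
#' @param epsilon Gray zone on gamma, default 0.05.
#' @param area_delta Gray zone of the area classifier, default 0.05.
#' @param t_eval Area read-out time (s), default 300.
#' @return An object of class `cell_cohort`: list of `cell_record`s with a
#'   `as.data.frame` method producing the cohort manifest.
#' @export
gen_cohort <- function(n, protocol = pulse_train(30, 1.5, 300),
                       params = kinetic_params(), w = NULL,
                       expr_meanlog = log(40), expr_sdlog = 1,
                       I_thresh = 40, beta = 0.6, noise = noise_model(),
                       seed = NULL, T = 120, epsilon = 0.05,
                       area_delta = 0.05, t_eval = 300) {
  stopifnot(n >= 0)
  if (!is.finite(expr_sdlog) || expr_sdlog < 0 || !is.finite(expr_meanlog)) {
    stop("invalid expression distribution parameters", call. = FALSE)
  }
  if (is.null(w)) w <- calibrate_weight(params)
  cells <- with_seed(seed, {
    I <- stats::rlnorm(n, expr_meanlog, expr_sdlog)
    cell_seeds <- if (is.null(seed)) rep(list(NULL), n)
                  else as.list(seed + seq_len(n))
    lapply(seq_len(n), function(i) {
      rho <- I[i] / (2 * I_thresh)
      tr <- gen_cell_traces(rho, protocol, params, noise,
                            seed = cell_seeds[[i]])
      kp <- kinetic_params(params$k2, rho, params$koff_sensor)
      cc <- simulate_cdc42(tr$clean$g, kp)
      gam <- compute_gamma(tr$clean$r, cc, w = w, T = T,
                           epsilon = epsilon)$gamma
      tt <- tr$clean$g$time_s
      area_clean <- 1 - beta * gam * area_ramp(tt)
      area_noisy <- with_seed(
        if (is.null(seed)) NULL else seed + n + i,
        pmax(apply_noise(area_clean, noise), 1e-6)
      )
      area <- trace(tt, area_noisy, channel = "area")
      structure(list(
        cell_id = sprintf("cell%03d", i),
        expression_au = I[i], rho = rho, gamma = gam,
        g = tr$g, b = tr$b, area = area,
        true_label = label_from_gamma(gam, epsilon),
        observed_label = classify_from_area(area, t_eval = t_eval,
                                            delta = area_delta)
      ), class = "cell_record")
    })
  })
  structure(list(cells = cells,
                 config = list(n = n, w = w, I_thresh = I_thresh,
                               beta = beta, sigma = noise$sigma, seed = seed,
                               expr_meanlog = expr_meanlog,
                               expr_sdlog = expr_sdlog, T = T,
                               epsilon = epsilon, area_delta = area_delta,
                               t_eval = t_eval)),
            class = "cell_cohort")
}

#' @export
print.cell_cohort <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<cell_cohort> %d cells; labels: %s\n", nrow(df),
              paste(names(table(df$observed_label)),
                    table(df$observed_label), sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.cell_cohort <- function(x, ...) {
  do.call(rbind, lapply(x$cells, function(cell) {
    data.frame(cell_id = cell$cell_id, I_au = cell$expression_au,
               rho = cell$rho, gamma = cell$gamma,
               true_label = cell$true_label,
               observed_label = cell$observed_label,
               area_5min = cell$area$value[
                 which.min(abs(cell$area$time_s - x$config$t_eval))],
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to a directory
#'
#' Emits the manifest CSV (`cohort.csv`), per-cell trace CSVs
#' (`<cell_id>_g.csv`, `<cell_id>_b.csv`, `<cell_id>_area.csv`) and the
#' generation config with its seed (`config.yaml`).
#'
#' @param cohort A `cell_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cell_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  for (cell in cohort$cells) {
    write_trace(cell$g, file.path(dir, paste0(cell$cell_id, "_g.csv")))
    write_trace(cell$b, file.path(dir, paste0(cell$cell_id, "_b.csv")))
    write_trace(cell$area, file.path(dir, paste0(cell$cell_id, "_area.csv")))
  }
  yaml::write_yaml(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
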