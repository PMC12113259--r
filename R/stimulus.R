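#' Illumination protocols
#'
#' An optogenetic stimulation protocol is a set of brief blue-light pulses.
#' Each pulse recruits a fixed increment of GEF to the membrane: the
#' normalized recruitment curve `g` jumps by `delta = amplitude_fold - 1`
#' at each pulse time (measurable per-pulse fold changes span roughly
#' 1.1 to 3) and relaxes back toward baseline in the dark.
#'
#' @param pulse_times Pulse onset times in seconds, strictly increasing,
#'   within `[0, t_end]`.
#' @param amplitude_fold Per-pulse fold increase of `g`; the increment is
#'   `amplitude_fold - 1 > 0`.
#' @param t_end End of the observation window (seconds).
#' @return An object of class `pulse_protocol`.
#' @seealso [pulse_train()] for regular trains, [simulate_recruitment()].
#' @export
pulse_protocol <- function(pulse_times, amplitude_fold, t_end) {
  pulse_times <- as.numeric(pulse_times)
  if (length(pulse_times) > 0) {
    if (anyNA(pulse_times) || is.unsorted(pulse_times, strictly = TRUE)) {
      stop("pulse times must be strictly increasing", call. = FALSE)
    }
    if (min(pulse_times) < 0 || max(pulse_times) > t_end) {
      stop("pulse times must lie within [0, t_end]", call. = FALSE)
    }
  }
  delta <- amplitude_fold - 1
  if (!is.finite(delta) || delta <= 0) {
    stop("amplitude_fold must exceed 1 (delta > 0)", call. = FALSE)
  }
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive", call. = FALSE)
  structure(
    list(pulse_times = pulse_times, amplitude_fold = amplitude_fold,
         delta = delta, t_end = t_end),
    class = "pulse_protocol"
  )
}

#' @param period Inter-pulse interval in seconds (> 0).
#' @param t_start Time of the first pulse (seconds), default 0.
#' @param n_pulses Optional pulse count; defaults to as many pulses as fit
#'   in `[t_start, t_end]`.
#' @rdname pulse_protocol
#' @export
pulse_train <- function(period, amplitude_fold, t_end, t_start = 0,
                        n_pulses = NULL) {
  if (!is.finite(period) || period <= 0) {
    stop("period must be positive", call. = FALSE)
  }
  if (is.null(n_pulses)) n_pulses <- floor((t_end - t_start) / period) + 1
  times <- t_start + period * seq_len(n_pulses) - period
  pulse_protocol(times[times <= t_end], amplitude_fold, t_end)
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<pulse_protocol> %d pulses, fold %.3g (delta %.3g), t_end %g s\n",
              length(x$pulse_times), x$amplitude_fold, x$delta, x$t_end))
  invisible(x)
}

#' Membrane recruitment kinetics
#'
#' Parameters of the iLID/SspB recruitment step: the optogenetic dimer
#' dissociates in the dark with a time constant of about 20 s, so between
#' pulses the recruited GEF decays exponentially back to its pre-activation
#' level. Under the normalization `g = Gtot / Geq` the baseline is 1.
#'
#' @param tau_off Dark-state dissociation time constant (seconds), default 20.
#' @param baseline Pre-activation level of `g`, 1 under the standard
#'   normalization.
#' @return An object of class `recruitment_params`.
#' @export
recruitment_params <- function(tau_off = 20, baseline = 1) {
  if (!is.finite(tau_off) || tau_off <= 0) {
    stop("tau_off must be positive", call. = FALSE)
  }
  structure(list(tau_off = tau_off, baseline = baseline),
            class = "recruitment_params")
}

#' Simulate the membrane-recruited GEF curve g(t)
#'
#' Pulses are modeled as instantaneous increments of `g` by
#' `amplitude_fold - 1` (recruitment is fast relative to the ~20 s dark-state
#' dissociation); between pulses `g` relaxes exponentially toward baseline:
#' \deqn{g(t) = 1 + \sum_{k:\, t_k \le t} \Delta\, e^{-(t - t_k)/\tau_{off}}.}
#' The returned trace is right-continuous at pulse times and carries the
#' analytic description of the curve, which downstream ODE solvers use to
#' handle the jumps exactly.
#'
#' @param protocol A [pulse_protocol()].
#' @param params A [recruitment_params()].
#' @param grid Output time grid (seconds) covering `[0, t_end]`; default 1 s
#'   spacing from 0. Pulse times are snapped to the nearest grid point (with
#'   a warning when off by more than 1e-6 s).
#' @param rise_s Optional finite rise time: instead of an instantaneous jump
#'   each pulse ramps up linearly over `rise_s` seconds. Used for numerical
#'   cross-checks of the jump handling; the returned trace then has no
#'   analytic description and is integrated like measured data.
#' @return A [trace()] with channel `"g"`.
#' @examples
#' pr <- pulse_train(period = 30, amplitude_fold = 1.5, t_end = 300)
#' g <- simulate_recruitment(pr, recruitment_params())
#' max(g$value)
#' @export
simulate_recruitment <- function(protocol, params = recruitment_params(),
                                 grid = NULL, rise_s = 0) {
  stopifnot(inherits(protocol, "pulse_protocol"),
            inherits(params, "recruitment_params"))
  if (is.null(grid)) grid <- seq(0, protocol$t_end, by = 1)
  grid <- sort(unique(as.numeric(grid)))
  if (grid[1] > 0 || grid[length(grid)] < protocol$t_end - 1e-9) {
    stop("grid must cover [0, t_end]", call. = FALSE)
  }
  tau <- params$tau_off
  pt <- protocol$pulse_times
  if (length(pt) > 0) {
    snapped <- vapply(pt, function(t0) grid[which.min(abs(grid - t0))], 0)
    if (any(abs(snapped - pt) > 1e-6)) {
      warning("pulse times snapped to the output grid (off-grid by > 1e-6 s)")
    }
    pt <- snapped
  }
  delta <- protocol$delta
  g <- rep(params$baseline, length(grid))
  if (rise_s > 0) {
    for (t0 in pt) {
      dt <- grid - t0
      up <- dt >= 0 & dt < rise_s
      post <- dt >= rise_s
      g[up] <- g[up] + delta * dt[up] / rise_s
      g[post] <- g[post] + delta * exp(-(dt[post] - rise_s) / tau)
    }
    return(trace(grid, g, channel = "g"))
  }
  for (t0 in pt) {
    idx <- grid >= t0
    g[idx] <- g[idx] + delta * exp(-(grid[idx] - t0) / tau)
  }
  out <- trace(grid, g, channel = "g")
  attr(out, "gmodel") <- list(
    type = "pulse_train", tau = tau,
    jump_times = pt, jump_delta = rep(delta, length(pt)),
    baseline = params$baseline
  )
  out
}

#' Sustained-step stimulus
#'
#' Generates a `g` trace that jumps from 1 to `fold` at `t_on` and is then
#' held constant — the reference stimulus used to calibrate the phenotype
#' weight, where the pulsed map must remain a genuine model prediction.
#'
#' @param fold Held level of `g` (> 1).
#' @param t_end End of the window (seconds).
#' @param t_on Step time (seconds), default 0.
#' @param dt Grid spacing (seconds), default 1.
#' @return A [trace()] with channel `"g"` carrying an analytic description.
#' @export
step_stimulus <- function(fold, t_end, t_on = 0, dt = 1) {
  stopifnot(fold > 1, t_end > t_on)
  grid <- sort(unique(c(seq(min(0, t_on), t_end, by = dt), t_on, t_end)))
  g <- ifelse(grid >= t_on, fold, 1)
  out <- trace(grid, g, channel = "g")
  attr(out, "gmodel") <- list(
    type = "step", tau = Inf,
    jump_times = t_on, jump_delta = fold - 1,
    baseline = 1
  )
  out
}

#' Read / write a protocol as YAML
#'
#' Protocols serialize to a YAML mapping with either explicit `pulse_times`
#' or `period` (+ optional `n_pulses`), plus `amplitude_fold` and `t_end`.
#'
#' @param path File path.
#' @param protocol A [pulse_protocol()] (for `write_protocol`).
#' @return `read_protocol` returns a `pulse_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$amplitude_fold) || is.null(y$t_end)) {
    stop("protocol YAML needs amplitude_fold and t_end", call. = FALSE)
  }
  if (!is.null(y$pulse_times)) {
    pulse_protocol(unlist(y$pulse_times), y$amplitude_fold, y$t_end)
  } else if (!is.null(y$period)) {
    pulse_train(y$period, y$amplitude_fold, y$t_end,
                t_start = if (is.null(y$t_start)) 0 else y$t_start,
                n_pulses = y$n_pulses)
  } else {
    stop("protocol YAML needs pulse_times or period", call. = FALSE)
  }
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  yaml::write_yaml(list(
    pulse_times = protocol$pulse_times,
    amplitude_fold = protocol$amplitude_fold,
    t_end = protocol$t_end
  ), path)
  invisible(path)
}
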