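#' Per-cell time series container
#'
#' A `trace` is the package's basic unit of data: one channel of a single
#' cell's time course (GEF recruitment `g`, free active RhoA `r`, active
#' Cdc42 `c`, biosensor `b`, or normalized area), sampled on a grid of times
#' in seconds. Values are dimensionless intensities normalized so that the
#' pre-activation equilibrium is 1.
#'
#' @param times Numeric vector of times in seconds, strictly increasing.
#' @param values Numeric vector of the same length, finite.
#' @param channel Channel tag, one of `"g"`, `"r"`, `"c"`, `"b"`, `"area"`.
#' @param normalized Logical; whether values are normalized to a
#'   pre-activation mean of 1.
#' @return An object of class `trace`: a data frame with columns `time_s`
#'   and `value` plus `channel`/`normalized` attributes.
#' @examples
#' tr <- trace(0:10, rep(1, 11), channel = "g")
#' print(tr)
#' @export
trace <- function(times, values, channel = c("g", "r", "c", "b", "area"),
                  normalized = TRUE) {
  channel <- match.arg(channel)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) == 0L) {
    stop("a trace needs at least one timepoint", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(values))) {
    stop("trace times and values must be finite", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(time_s = times, value = values),
    channel = channel,
    normalized = normalized,
    class = c("trace", "data.frame")
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf(
    "<trace> channel '%s', %d points, t = [%g, %g] s, value range [%.4g, %.4g]\n",
    attr(x, "channel"), nrow(x), min(x$time_s), max(x$time_s),
    min(x$value), max(x$value)
  ))
  invisible(x)
}

#' @export
plot.trace <- function(x, ...) {
  plot(x$time_s, x$value, type = "l", xlab = "time (s)",
       ylab = attr(x, "channel"), ...)
  invisible(x)
}

is_trace <- function(x) inherits(x, "trace")

trace_channel <- function(x) attr(x, "channel")

#' Resample a trace onto a new time grid
#'
#' Linear interpolation; times outside the original range are an error so
#' that fits never silently extrapolate.
#'
#' @param x A [trace()].
#' @param times New time grid (seconds) within the range of `x`.
#' @return A `trace` on the new grid, same channel tag.
#' @export
resample_trace <- function(x, times) {
  stopifnot(is_trace(x))
  if (min(times) < min(x$time_s) - 1e-9 || max(times) > max(x$time_s) + 1e-9) {
    stop("requested grid extends beyond the trace; refusing to extrapolate",
         call. = FALSE)
  }
  v <- stats::approx(x$time_s, x$value, xout = times, rule = 2)$y
  trace(times, v, channel = trace_channel(x), normalized = attr(x, "normalized"))
}

#' Read / write a trace as delimited text
#'
#' Traces are stored as plain CSV with a `time_s,value` header and
#' '#'-prefixed comment lines carrying the channel tag and normalization
#' status. Round-trips are exact to numeric text precision.
#'
#' @param path File path.
#' @param x A [trace()] (for `write_trace`).
#' @return `read_trace` returns a `trace`; `write_trace` returns `path`
#'   invisibly.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty trace file: ", path, call. = FALSE)
  comments <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  if (length(body) < 2L) stop("trace file has no data rows: ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("trace file must have columns time_s,value: ", path, call. = FALSE)
  }
  channel <- "g"
  normalized <- TRUE
  m <- regmatches(comments, regexec("^#\\s*channel:\\s*(\\S+)", comments))
  hit <- vapply(m, length, 1L) == 2L
  if (any(hit)) channel <- m[[which(hit)[1]]][2]
  m <- regmatches(comments, regexec("^#\\s*normalized:\\s*(\\S+)", comments))
  hit <- vapply(m, length, 1L) == 2L
  if (any(hit)) normalized <- as.logical(m[[which(hit)[1]]][2])
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("non-monotone time column in ", path, call. = FALSE)
  }
  trace(df$time_s, df$value, channel = channel, normalized = normalized)
}

#' @rdname read_trace
#' @export
write_trace <- function(x, path) {
  stopifnot(is_trace(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# channel: %s", trace_channel(x)),
    sprintf("# normalized: %s", isTRUE(attr(x, "normalized")))
  ), con)
  utils::write.csv(as.data.frame(x)[, c("time_s", "value")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# trapezoidal integral of a sampled function, optionally restricted to [t0, t1]
trapz_trace <- function(times, values, t0 = NULL, t1 = NULL) {
  if (!is.null(t0) || !is.null(t1)) {
    t0 <- if (is.null(t0)) times[1] else t0
    t1 <- if (is.null(t1)) times[length(times)] else t1
    keep <- times >= t0 - 1e-9 & times <= t1 + 1e-9
    times <- times[keep]
    values <- values[keep]
  }
  n <- length(times)
  if (n < 2L) return(0)
  sum(diff(times) * (values[-1] + values[-n]) / 2)
}

# Exact solution of dx/dt = k (u(t) - x) for u piecewise linear on the grid.
# Used for the Cdc42 branch, the biosensor layer, and the rho = 0 RhoA limit,
# where the governing equation is exactly this first-order relaxation.
# `jumps`/`u_pre` mark samples that sit just after a step of u: over the
# preceding interval u is taken to ramp to u_pre (the extrapolated pre-step
# value) and to jump at the sample time, instead of ramping all the way to
# the post-step sample.
lin_relax <- function(times, u, k, x0 = u[1], jumps = integer(0),
                      u_pre = numeric(0)) {
  n <- length(times)
  if (n == 1L) return(x0)
  h <- diff(times)
  u_end <- u[-1]
  if (length(jumps)) u_end[jumps - 1L] <- u_pre
  s <- (u_end - u[-n]) / h
  E <- exp(-k * h)
  # x_{i+1} = E_i x_i + d_i
  d <- u_end - s / k - (u[-n] - s / k) * E
  if (all(abs(h - h[1]) < 1e-12)) {
    x <- stats::filter(d, E[1], method = "recursive", init = x0)
    c(x0, as.numeric(x))
  } else {
    x <- numeric(n)
    x[1] <- x0
    for (i in seq_len(n - 1L)) x[i + 1L] <- E[i] * x[i] + d[i]
    x
  }
}

# Detect step-like rises in a sampled pulsed-recruitment trace: increments
# exceeding both `min_jump` and `k_mad` robust scales of the typical
# increment. Returns indices of the post-step samples.
detect_trace_jumps <- function(times, values, min_jump = 0.25, k_mad = 4) {
  inc <- diff(values)
  if (!length(inc)) return(integer(0))
  thr <- max(min_jump, k_mad * stats::mad(inc))
  which(inc > thr) + 1L
}

# Pre-step value at a detected jump: first-order continuation of the
# dark-state decay, estimated by a least-squares line through up to the
# five preceding samples (averaging down per-sample noise).
prejump_value <- function(times, values, i) {
  lo <- max(1L, i - 5L)
  idx <- lo:(i - 1L)
  v <- if (length(idx) >= 2L) {
    tt <- times[idx] - times[i]
    vv <- values[idx]
    fit <- stats::lm.fit(cbind(1, tt), vv)
    fit$coefficients[[1]]
  } else {
    values[i - 1L]
  }
  min(max(v, 1e-6), values[i])
}

# Post-step value at a detected jump: least-squares line through up to the
# five following samples, evaluated at the step time.
postjump_value <- function(times, values, i) {
  hi <- min(length(values), i + 4L)
  idx <- i:hi
  v <- if (length(idx) >= 2L) {
    tt <- times[idx] - times[i]
    fit <- stats::lm.fit(cbind(1, tt), values[idx])
    fit$coefficients[[1]]
  } else {
    values[i]
  }
  max(v, 1e-6)
}

# run expr with a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
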