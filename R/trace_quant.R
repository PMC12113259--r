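#' Mask/intensity stack for an activated-region experiment
#'
#' Bundles the per-frame segmentation of one cell, the static optogenetic
#' activation region, and the per-frame intensity image. Masks are binary
#' grids with unit-square pixels; areas are pixel counts, matching
#' thresholded-segmentation practice.
#'
#' @param intensity Numeric array `height x width x frames`.
#' @param cell_mask Logical (or 0/1) array of the same shape: per-frame cell
#'   segmentation.
#' @param region_mask Logical matrix `height x width`: the activation
#'   region, static over time and nonempty.
#' @param frame_times Frame acquisition times in seconds, one per frame.
#' @param activation_start Index of the first frame at or after optogenetic
#'   activation (frames before it are the pre-activation baseline; at least
#'   one is required).
#' @return An object of class `region_stack`.
#' @export
region_stack <- function(intensity, cell_mask, region_mask, frame_times,
                         activation_start) {
  intensity <- as.array(intensity)
  cell_mask <- as.array(cell_mask) > 0
  region_mask <- as.matrix(region_mask) > 0
  if (length(dim(intensity)) != 3L) {
    stop("intensity must be a height x width x frames array", call. = FALSE)
  }
  if (!identical(dim(cell_mask), dim(intensity))) {
    stop("cell_mask shape must match intensity", call. = FALSE)
  }
  if (!identical(dim(region_mask), dim(intensity)[1:2])) {
    stop("region_mask shape must match a frame", call. = FALSE)
  }
  if (!any(region_mask)) stop("activation region is empty", call. = FALSE)
  n <- dim(intensity)[3]
  if (length(frame_times) != n || is.unsorted(frame_times, strictly = TRUE)) {
    stop("frame_times must be strictly increasing, one per frame",
         call. = FALSE)
  }
  activation_start <- as.integer(activation_start)
  if (activation_start < 2L || activation_start > n) {
    stop("need at least one pre-activation frame", call. = FALSE)
  }
  structure(list(intensity = intensity, cell_mask = cell_mask,
                 region_mask = region_mask, frame_times = frame_times,
                 activation_start = activation_start),
            class = "region_stack")
}

#' @export
print.region_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<region_stack> %dx%d px, %d frames (%d pre-activation), region %d px\n",
    d[1], d[2], d[3], x$activation_start - 1L, sum(x$region_mask)))
  invisible(x)
}

#' Four-step biosensor normalization
#'
#' Reproduces the standard normalization of relocation-biosensor movies:
#' (1) subtract the background, (2) average the intensity over the
#' intersection of the cell segmentation with the activation region,
#' (3) divide by the mean intensity in the non-activated part of the cell
#' (correcting global expression and bleaching), and (4) divide by the
#' pre-activation mean so the baseline is 1. Invariant under global
#' multiplicative rescaling of the stack (with equally rescaled
#' background).
#'
#' @param stack A [region_stack()].
#' @param background Scalar background intensity, below the cell signal.
#' @return A [trace()] (channel `"b"`), times relative to activation onset.
#' @export
normalize_biosensor <- function(stack, background) {
  stopifnot(inherits(stack, "region_stack"))
  n <- dim(stack$intensity)[3]
  ratio <- numeric(n)
  for (f in seq_len(n)) {
    img <- stack$intensity[, , f] - background
    cm <- stack$cell_mask[, , f]
    inter <- cm & stack$region_mask
    outer <- cm & !stack$region_mask
    if (!any(inter)) {
      stop("empty cell/region intersection at frame ", f, call. = FALSE)
    }
    if (!any(outer)) {
      stop("empty non-activated cell region at frame ", f, call. = FALSE)
    }
    denom <- mean(img[outer])
    if (denom <= 0) {
      stop("non-positive non-activated mean after background subtraction; ",
           "background too high", call. = FALSE)
    }
    ratio[f] <- mean(img[inter]) / denom
  }
  pre <- ratio[seq_len(stack$activation_start - 1L)]
  baseline <- mean(pre)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("non-positive pre-activation baseline", call. = FALSE)
  }
  t0 <- stack$frame_times[stack$activation_start]
  trace(stack$frame_times - t0, ratio / baseline, channel = "b")
}

#' Surface displacement in the activated region
#'
#' The area of the intersection between the activation region and the cell
#' segmentation, per frame, normalized by its mean over the pre-activation
#' frames. Values above 1 indicate membrane extension into the region,
#' below 1 retraction out of it.
#'
#' @param stack A [region_stack()].
#' @return A [trace()] (channel `"area"`), times relative to activation
#'   onset.
#' @export
surface_displacement <- function(stack) {
  stopifnot(inherits(stack, "region_stack"))
  n <- dim(stack$intensity)[3]
  area <- vapply(seq_len(n), function(f) {
    sum(stack$cell_mask[, , f] & stack$region_mask)
  }, 0)
  pre <- area[seq_len(stack$activation_start - 1L)]
  if (mean(pre) <= 0) {
    stop("zero pre-activation intersection area", call. = FALSE)
  }
  t0 <- stack$frame_times[stack$activation_start]
  trace(stack$frame_times - t0, area / mean(pre), channel = "area")
}

#' Phenotype call from a normalized area trace
#'
#' `protrusion` if the normalized area at `t_eval` exceeds `1 + delta`,
#' `retraction` if below `1 - delta`, `mixed` inside the gray zone. The
#' default read-out time is 5 minutes after activation.
#'
#' @param area A [trace()] of normalized area covering `t_eval`.
#' @param t_eval Evaluation time (s), default 300.
#' @param delta Gray-zone half-width, default 0.05.
#' @return One of `"protrusion"`, `"retraction"`, `"mixed"`.
#' @export
classify_from_area <- function(area, t_eval = 300, delta = 0.05) {
  stopifnot(is_trace(area))
  if (max(area$time_s) < t_eval - 1e-9) {
    stop("area trace does not cover the evaluation time", call. = FALSE)
  }
  a <- stats::approx(area$time_s, area$value, xout = t_eval, rule = 2)$y
  if (a > 1 + delta) "protrusion" else if (a < 1 - delta) "retraction" else "mixed"
}

#' Migration persistence of a trajectory
#'
#' Ratio of the net displacement from the initial position to the total
#' path length; 1 for straight-line motion, 0 for a closed path.
#'
#' @param path Numeric matrix of positions (rows = timepoints, columns =
#'   coordinates), at least two rows.
#' @return A number in `[0, 1]`, or `NA` (with attribute
#'   `"degenerate" = TRUE`) when the cell never moves.
#' @export
persistence <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("need at least two positions", call. = FALSE)
  steps <- diff(path)
  total <- sum(sqrt(rowSums(steps^2)))
  if (total == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  net <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  net / total
}

#' Read / write a region stack as multi-page TIFF
#'
#' The intensity stack and per-frame cell masks are multi-page TIFFs; the
#' static activation region is a single-page TIFF. Frame times and the
#' activation start index travel in a YAML sidecar next to the intensity
#' file (`<path>.yaml`).
#'
#' @param intensity_path,cellmask_path,region_path TIFF paths.
#' @param stack A [region_stack()] (for writing).
#' @param scale Intensity scale used to map to TIFF's unit range; writing
#'   records it in the sidecar and reading undoes it.
#' @return `read_region_stack` returns a `region_stack`;
#'   `write_region_stack` returns `intensity_path` invisibly.
#' @export
read_region_stack <- function(intensity_path, cellmask_path, region_path) {
  side <- yaml::read_yaml(paste0(intensity_path, ".yaml"))
  as_stack <- function(pages) {
    if (is.list(pages)) array(unlist(pages), dim = c(dim(pages[[1]]),
                                                     length(pages)))
    else array(pages, dim = c(dim(pages), 1L))
  }
  intensity <- as_stack(tiff::readTIFF(intensity_path, all = TRUE)) *
    side$scale
  cell <- as_stack(tiff::readTIFF(cellmask_path, all = TRUE)) > 0.5
  region <- tiff::readTIFF(region_path) > 0.5
  region_stack(intensity, cell, region,
               frame_times = unlist(side$frame_times),
               activation_start = side$activation_start)
}

#' @rdname read_region_stack
#' @export
write_region_stack <- function(stack, intensity_path, cellmask_path,
                               region_path, scale = NULL) {
  stopifnot(inherits(stack, "region_stack"))
  if (is.null(scale)) scale <- max(stack$intensity) * 1.001
  n <- dim(stack$intensity)[3]
  pages <- lapply(seq_len(n), function(f) stack$intensity[, , f] / scale)
  tiff::writeTIFF(pages, intensity_path, bits.per.sample = 16)
  masks <- lapply(seq_len(n), function(f) stack$cell_mask[, , f] * 1)
  tiff::writeTIFF(masks, cellmask_path, bits.per.sample = 8)
  tiff::writeTIFF(stack$region_mask * 1, region_path, bits.per.sample = 8)
  yaml::write_yaml(list(frame_times = stack$frame_times,
                        activation_start = stack$activation_start,
                        scale = scale),
                   paste0(intensity_path, ".yaml"))
  invisible(intensity_path)
}

#' Synthetic region-stack fixture
#'
#' Builds a small synthetic movie of a disk-shaped cell in a rectangular
#' activation region: the cell translates at constant velocity after
#' activation, and the intensity inside the activated part of the cell is
#' multiplied by `signal_fold` post-activation. Used to exercise
#' [normalize_biosensor()] and [surface_displacement()] against analytic
#' expectations; labeled synthetic, it stands in for microscopy data.
#'
#' @param size Image side in pixels, default 40.
#' @param radius Cell radius in pixels, default 12.
#' @param n_frames Total frames, default 12.
#' @param n_pre Pre-activation frames, default 3.
#' @param dt Frame interval (s), default 10.
#' @param velocity Per-frame displacement (pixels/frame) applied after
#'   activation, default `c(0, 0)`.
#' @param signal_fold Intensity fold in the activated cell part after
#'   activation, default 1.
#' @param base_intensity Cell intensity before background, default 100.
#' @param background Added background level, default 10.
#' @return A [region_stack()].
#' @export
synthetic_region_stack <- function(size = 40, radius = 12, n_frames = 12,
                                   n_pre = 3, dt = 10, velocity = c(0, 0),
                                   signal_fold = 1, base_intensity = 100,
                                   background = 10) {
  ctr0 <- c(size / 2, size / 2)
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  region <- xs <= size / 2   # left half-plane activation region
  intensity <- array(background, dim = c(size, size, n_frames))
  cell <- array(FALSE, dim = c(size, size, n_frames))
  for (f in seq_len(n_frames)) {
    shift <- if (f >= n_pre + 1) (f - n_pre) * velocity else c(0, 0)
    ctr <- ctr0 + shift
    disk <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= radius^2
    cell[, , f] <- disk
    img <- matrix(background, size, size)
    img[disk] <- background + base_intensity
    if (f >= n_pre + 1 && signal_fold != 1) {
      act <- disk & region
      img[act] <- background + base_intensity * signal_fold
    }
    intensity[, , f] <- img
  }
  region_stack(intensity, cell, region,
               frame_times = dt * (seq_len(n_frames) - 1),
               activation_start = n_pre + 1L)
}
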