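test_that("biosensor normalization cancels constant stacks and scales", {
  st <- synthetic_region_stack(signal_fold = 1)
  tr <- normalize_biosensor(st, background = 10)
  expect_equal(tr$value, rep(1, length(tr$value)), tolerance = 1e-12)
  expect_equal(tr$time_s[st$activation_start], 0)

  st2 <- synthetic_region_stack(signal_fold = 2)
  tr2 <- normalize_biosensor(st2, background = 10)
  pre <- tr2$value[tr2$time_s < 0]
  post <- tr2$value[tr2$time_s >= 0]
  expect_equal(pre, rep(1, length(pre)), tolerance = 1e-12)
  expect_equal(post, rep(2, length(post)), tolerance = 1e-12)

  # invariance under global multiplicative rescaling
  st3 <- st2
  st3$intensity <- st2$intensity * 7.3
  tr3 <- normalize_biosensor(st3, background = 73)
  expect_equal(tr3$value, tr2$value, tolerance = 1e-12)

  # background at the cell intensity level destroys the normalization
  expect_error(normalize_biosensor(st2, background = 110), "background")
})

test_that("surface displacement tracks the cell/region intersection", {
  st <- synthetic_region_stack(velocity = c(0, 0))
  a <- surface_displacement(st)
  expect_equal(a$value, rep(1, length(a$value)), tolerance = 1e-12)

  # disk translating out of the region: area falls and eventually vanishes
  st2 <- synthetic_region_stack(size = 60, radius = 8, n_frames = 15,
                                velocity = c(4, 0))
  a2 <- surface_displacement(st2)
  expect_equal(a2$value[1], 1)
  expect_true(all(diff(a2$value[st2$activation_start:15]) <= 0))
  expect_equal(a2$value[15], 0)

  # joint rigid translation of both masks leaves the trace unchanged
  st3 <- st2
  shift_rows <- function(m, k) rbind(m[(k + 1):nrow(m), , drop = FALSE],
                                     m[1:k, , drop = FALSE])
  st3$region_mask <- shift_rows(st2$region_mask, 5)
  for (f in seq_len(dim(st3$cell_mask)[3])) {
    st3$cell_mask[, , f] <- shift_rows(st2$cell_mask[, , f], 5)
  }
  a3 <- surface_displacement(st3)
  expect_equal(a3$value, a2$value, tolerance = 1e-12)
})

test_that("halving the intersection by analytic geometry gives area 0.5", {
  # disk centered on the region boundary: the intersection is half the disk;
  # move the disk fully inside pre/post comparison via a vertical translation
  size <- 61
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  region <- xs <= 30
  disk_at <- function(cx) (xs - cx)^2 + (ys - 31)^2 <= 10^2
  n_frames <- 4
  cell <- array(FALSE, c(size, size, n_frames))
  cell[, , 1] <- disk_at(20)   # fully inside the region
  cell[, , 2] <- disk_at(20)
  cell[, , 3] <- disk_at(30.5) # centered on the boundary
  cell[, , 4] <- disk_at(30.5)
  intensity <- array(100, c(size, size, n_frames))
  st <- region_stack(intensity, cell, region, frame_times = c(0, 10, 20, 30),
                     activation_start = 3)
  a <- surface_displacement(st)
  expect_equal(a$value[4], 0.5, tolerance = 0.05)
})

test_that("area classification applies the gray-zone rule", {
  mk <- function(v) trace(c(0, 150, 300), c(1, (1 + v) / 2, v), "area")
  expect_identical(classify_from_area(mk(1.3)), "protrusion")
  expect_identical(classify_from_area(mk(0.7)), "retraction")
  expect_identical(classify_from_area(mk(1.0)), "mixed")
  expect_identical(classify_from_area(mk(1.04)), "mixed")
  expect_error(classify_from_area(trace(0:10, rep(1, 11), "area")), "cover")
  # agreement with sign(area - 1) outside the gray zone on random values
  vals <- with_seed(2, runif(40, 0.5, 1.5))
  for (v in vals[abs(vals - 1) > 0.05]) {
    expect_identical(classify_from_area(mk(v)),
                     if (v > 1) "protrusion" else "retraction")
  }
})

test_that("persistence is the net-over-total displacement ratio", {
  expect_equal(persistence(cbind(0:5, 0)), 1)
  expect_equal(persistence(rbind(c(0, 0), c(2, 0), c(0, 0))), 0)
  expect_equal(persistence(rbind(c(0, 0), c(3, 0), c(3, 4))), 5 / 7)
  still <- persistence(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_true(is.na(still))
  expect_true(attr(still, "degenerate"))
  expect_error(persistence(matrix(0, 1, 2)), "two positions")
})

test_that("region stacks round-trip through TIFF", {
  st <- synthetic_region_stack(size = 24, radius = 7, n_frames = 5, n_pre = 2,
                               signal_fold = 2)
  dir <- withr::local_tempdir()
  ip <- file.path(dir, "intensity.tif")
  cp <- file.path(dir, "cell.tif")
  rp <- file.path(dir, "region.tif")
  write_region_stack(st, ip, cp, rp)
  back <- read_region_stack(ip, cp, rp)
  expect_equal(dim(back$intensity), dim(st$intensity))
  expect_identical(back$cell_mask, st$cell_mask)
  expect_identical(back$region_mask, st$region_mask)
  expect_equal(back$frame_times, st$frame_times)
  # 16-bit quantization keeps the normalized trace close to the original
  t1 <- normalize_biosensor(st, background = 10)
  t2 <- normalize_biosensor(back, background = 10)
  expect_equal(t2$value, t1$value, tolerance = 1e-2)
})

test_that("stack validation enforces geometry preconditions", {
  st <- synthetic_region_stack()
  expect_error(region_stack(st$intensity, st$cell_mask,
                            matrix(FALSE, 40, 40), st$frame_times,
                            st$activation_start), "empty")
  expect_error(region_stack(st$intensity, st$cell_mask[, , 1:3],
                            st$region_mask, st$frame_times,
                            st$activation_start), "shape")
  expect_error(region_stack(st$intensity, st$cell_mask, st$region_mask,
                            st$frame_times, 1), "pre-activation")
  # cell entirely outside the region: degenerate intersection
  st2 <- synthetic_region_stack()
  st2$region_mask[] <- FALSE
  st2$region_mask[1, 1] <- TRUE
  expect_error(normalize_biosensor(st2, background = 10), "intersection")
})
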