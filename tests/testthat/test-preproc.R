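make_stack <- function(a, rate = 2, pitch = 0.1, stage = "raw") {
  frame_stack(a, c(454, 523, 595, 640), rate, pitch, stage = stage)
}

test_that("binning block-averages and conserves the frame mean", {
  a <- array(0, c(3, 4, 64, 64))
  a[] <- 7
  s <- bin_frames(make_stack(a), c(16, 16))
  expect_equal(dim(s$data), c(3, 4, 16, 16))
  expect_true(all(s$data == 7))
  expect_equal(s$pixel_pitch, 0.4)

  b <- array(0, c(1, 4, 2, 2))
  b[1, 1, , ] <- matrix(c(1, 5, 3, 7), 2, 2)   # column-major [1,3;5,7]
  s2 <- bin_frames(make_stack(b), c(1, 1))
  expect_equal(s2$data[1, 1, 1, 1], 4)

  set.seed(1)
  r <- array(rnorm(2 * 4 * 8 * 8), c(2, 4, 8, 8))
  s3 <- bin_frames(make_stack(r), c(4, 4))
  expect_equal(mean(s3$data[1, 2, , ]), mean(r[1, 2, , ]))

  expect_error(bin_frames(make_stack(r), c(3, 3)), "multiple")
})

test_that("detrending removes ramps and offsets and is idempotent", {
  nt <- 40
  ramp <- array(rep(seq_len(nt), 4 * 4 * 4), c(nt, 4, 4, 4)) + 100
  out <- detrend_and_center(make_stack(ramp))
  expect_lt(max(abs(out$data)), 1e-9)

  offs <- array(rep(1:64 * 2, each = nt), c(nt, 4, 4, 4)) + 50
  out2 <- detrend_and_center(make_stack(offs))
  expect_lt(max(abs(out2$data)), 1e-9)

  # ramp + pixel-specific sinusoid amplitudes: each pixel keeps its
  # deviation from the mean amplitude, detrended (explicit regression oracle)
  tt <- seq_len(nt)
  sine <- sin(2 * pi * tt / 8)
  amps <- array(seq(0.5, 2, length.out = 16), c(4, 2, 2))
  a <- array(0, c(nt, 4, 2, 2))
  for (c in 1:4) for (i in 1:2) for (j in 1:2)
    a[, c, i, j] <- 100 + 0.5 * tt + amps[c, i, j] * sine
  out3 <- detrend_and_center(make_stack(a))
  sine_res <- unname(residuals(lm(sine ~ tt)))
  for (c in 1:4) {
    mean_amp <- mean(amps[c, , ])
    expect_equal(as.vector(out3$data[, c, 1, 2]),
                 (amps[c, 1, 2] - mean_amp) * sine_res, tolerance = 1e-9)
  }

  out4 <- detrend_and_center(out)
  expect_equal(out4$data, out$data, tolerance = 1e-9)
  expect_error(detrend_and_center(make_stack(ramp[1:2, , , , drop = FALSE])),
               "3 frames")
  zero <- array(0, c(nt, 4, 2, 2))
  expect_error(detrend_and_center(make_stack(zero)), "zero mean")
})

test_that("resampling to 1 Hz preserves slow content and frame counts", {
  nt <- 120
  const <- array(5, c(nt, 4, 2, 2))
  s <- resample_to_1hz(make_stack(const, rate = 4, stage = "detrended"))
  expect_equal(s$frame_rate, 1)
  expect_lt(max(abs(s$data - 5)), 1e-6)

  # 16.81 Hz input of N seconds -> ~N output frames
  nsec <- 20
  n1681 <- floor(nsec * 16.81)
  a <- array(rnorm(n1681 * 4 * 1 * 1), c(n1681, 4, 1, 1))
  s2 <- resample_to_1hz(make_stack(a, rate = 16.81, stage = "detrended"))
  expect_true(abs(dim(s2$data)[1] - nsec) <= 1)

  # 0.1 Hz sinusoid amplitude preserved within 1%
  rate <- 5; dur <- 120
  tt <- (seq_len(dur * rate) - 1) / rate
  sig <- sin(2 * pi * 0.1 * tt)
  a3 <- array(rep(sig, 4), c(length(tt), 4, 1, 1))
  s3 <- resample_to_1hz(make_stack(a3, rate = rate, stage = "detrended"))
  t_out <- seq_len(dim(s3$data)[1]) - 1
  y <- s3$data[, 1, 1, 1]
  basis <- cbind(sin(2 * pi * 0.1 * t_out), cos(2 * pi * 0.1 * t_out))
  amp <- sqrt(sum(coef(lm(y ~ basis - 1))^2))
  expect_equal(amp, 1, tolerance = 0.01)

  expect_error(resample_to_1hz(make_stack(const, rate = 0.5,
                                          stage = "detrended")), "below 1 Hz")
})

test_that("affine estimation recovers known maps", {
  px <- cbind(ix = c(0, 10, 0, 10), iy = c(0, 0, 10, 10))
  id <- estimate_affine(px, px)
  expect_equal(id$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-12)

  shift <- px; shift[, 1] <- shift[, 1] + 3; shift[, 2] <- shift[, 2] - 2
  tr <- estimate_affine(px, shift)
  expect_equal(tr$matrix[, 3], c(3, -2), tolerance = 1e-12)
  expect_equal(tr$residual, 0, tolerance = 1e-12)

  set.seed(7)
  A <- matrix(c(0.09, 0.02, -1.2, -0.01, -0.11, 0.8), 2, 3, byrow = TRUE)
  pts <- cbind(runif(6, 0, 100), runif(6, 0, 100))
  atlas <- t(A %*% rbind(t(pts), 1))
  fit <- estimate_affine(pts, atlas)
  expect_lt(max(abs(fit$matrix - A)), 1e-9)

  col <- cbind(0:3, 0:3)
  expect_error(estimate_affine(col, col), "collinear")
})

test_that("mask and transform behave as an exact gather for identity maps", {
  nt <- 5
  set.seed(2)
  a <- array(rnorm(nt * 4 * 8 * 8), c(nt, 4, 8, 8))
  st <- make_stack(a, rate = 1, stage = "detrended")
  st <- resample_to_1hz(st)
  full <- apply_mask_and_transform(st, matrix(TRUE, 8, 8))
  expect_equal(full$data, a, tolerance = 1e-12)

  half <- matrix(TRUE, 8, 8); half[, 1:4] <- FALSE
  hm <- apply_mask_and_transform(st, half)
  expect_true(all(is.na(hm$data[, , , 1:4])))
  expect_true(all(is.finite(hm$data[, , , 5:8])))
  expect_error(apply_mask_and_transform(st, matrix(FALSE, 8, 8)), "empty")
})

test_that("transform then inverse-transform is identity within tolerance", {
  ny <- 24; nx <- 24
  g <- outer(sin(seq(0, pi, length.out = ny)),
             cos(seq(0, pi, length.out = nx)))
  arr <- array(0, c(3, 4, ny, nx))
  for (t in 1:3) for (c in 1:4) arr[t, c, , ] <- g
  st <- make_stack(arr, rate = 1, pitch = 0.1, stage = "detrended")
  st <- resample_to_1hz(st)
  th <- 8 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) * 0.1
  fwd <- structure(list(matrix = cbind(R, c(-1, 1)), residual = 0),
                   class = "affine_map")
  out <- apply_mask_and_transform(st, matrix(TRUE, ny, nx), fwd)
  # compose: out-grid indices -> atlas mm -> original pixel indices
  cx <- out$coords$x_mm; cy <- out$coords$y_mm
  A2 <- matrix(c(cx[2] - cx[1], 0, cx[1],
                 0, cy[2] - cy[1], cy[1]), 2, 3, byrow = TRUE)
  Ri <- solve(R)
  Mi <- cbind(Ri, -Ri %*% c(-1, 1))      # mm -> original (ix, iy)
  M2 <- cbind(Mi[, 1:2] %*% A2[, 1:2], Mi[, 1:2] %*% A2[, 3] + Mi[, 3])
  back_map <- structure(list(matrix = M2, residual = 0),
                        class = "affine_map")
  st2 <- out; st2$stage <- "resampled"; st2$baseline <- NULL
  mask2 <- is.finite(out$data[1, 1, , ])
  back <- apply_mask_and_transform(st2, mask2, back_map)
  # expected: bilinear sample of g at the back-grid's original-pixel coords
  bx <- back$coords$x_mm; by <- back$coords$y_mm   # original ix / iy units
  bilin <- function(iy, ix) {
    if (ix < 0 || ix > nx - 1 || iy < 0 || iy > ny - 1) return(NA_real_)
    i0 <- floor(iy); j0 <- floor(ix)
    i1 <- min(i0 + 1, ny - 1); j1 <- min(j0 + 1, nx - 1)
    fy <- iy - i0; fx <- ix - j0
    (1 - fy) * ((1 - fx) * g[i0 + 1, j0 + 1] + fx * g[i0 + 1, j1 + 1]) +
      fy * ((1 - fx) * g[i1 + 1, j0 + 1] + fx * g[i1 + 1, j1 + 1])
  }
  err <- c()
  for (r in seq(4, ny - 3)) for (cc in seq(4, nx - 3)) {
    v <- back$data[1, 1, r, cc]
    e <- bilin(by[r], bx[cc])
    if (is.finite(v) && is.finite(e)) err <- c(err, abs(v - e))
  }
  expect_gt(length(err), 100)
  expect_lt(stats::quantile(err, 0.95), 0.05)
})

test_that("mean normalization is an exact invertible fractional change", {
  nt <- 10
  base <- array(rep(seq(50, 113, length.out = 64), each = nt),
                c(nt, 4, 4, 4))
  wig <- array(rnorm(length(base), 0, 1), dim(base))
  raw <- base + wig
  st <- detrend_and_center(make_stack(raw))
  st <- resample_to_1hz(st)
  st <- apply_mask_and_transform(st, matrix(TRUE, 4, 4))
  nm <- mean_normalize(st)
  expect_equal(nm$stage, "normalized")
  # de-normalization reproduces the atlas-stage data exactly
  nt2 <- dim(nm$data)[1]
  for (c in 1:4) {
    b <- nm$baseline[c, , ]
    rec <- nm$data[, c, , ] * array(rep(as.vector(b), each = nt2),
                                    c(nt2, 4, 4))
    expect_equal(rec, st$data[, c, , ], tolerance = 1e-12)
  }

  cst <- array(3, c(nt, 4, 4, 4))
  stc <- detrend_and_center(make_stack(cst))
  stc <- apply_mask_and_transform(resample_to_1hz(stc), matrix(TRUE, 4, 4))
  nmc <- mean_normalize(stc)
  expect_lt(max(abs(nmc$data)), 1e-12)
})

test_that("a pixel doubling its baseline reads 1.0 fractional change", {
  # isolate mean_normalize: an atlas-stage stack whose detrended value at
  # one frame equals the stored baseline (i.e. the raw signal doubled)
  nt <- 5
  base <- array(seq(80, 120, length.out = 4 * 3 * 3), c(4, 3, 3))
  a <- array(0, c(nt, 4, 3, 3))
  a[3, 1, 2, 2] <- base[1, 2, 2]
  st <- frame_stack(a, c(454, 523, 595, 640), 1, 0.1, stage = "atlas",
                    baseline = base, mask = matrix(TRUE, 3, 3),
                    coords = default_coords(3, 3, 0.1))
  nm <- mean_normalize(st)
  expect_equal(nm$data[3, 1, 2, 2], 1.0)
  expect_equal(nm$data[1, 1, 2, 2], 0)

  bad <- base; bad[2, 1, 1] <- 0
  st2 <- st; st2$baseline <- bad
  expect_error(mean_normalize(st2), "zero-baseline")
})
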