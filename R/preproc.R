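#' Block-mean spatial binning
#'
#' Downsamples each frame by averaging non-overlapping pixel blocks (e.g.
#' camera-native frames down to the 128 x 128 analysis grid). The pixel pitch
#' is scaled by the block factor.
#'
#' @param stack a raw [frame_stack()].
#' @param target `c(ny, nx)` output grid; source dimensions must be integer
#'   multiples.
#' @return A binned [frame_stack()].
#' @export
bin_frames <- function(stack, target) {
  check_stage(stack, "raw")
  d <- stack_dims(stack)
  ny <- as.integer(target[1]); nx <- as.integer(target[2])
  if (d$y %% ny != 0L || d$x %% nx != 0L)
    stopf("source grid %dx%d is not an integer multiple of target %dx%d",
          d$y, d$x, ny, nx)
  fy <- d$y %/% ny; fx <- d$x %/% nx
  # average blocks: reshape (t*c, fy, ny, fx, nx) and mean over fy, fx
  a <- stack$data
  dim(a) <- c(d$t * d$c, d$y, d$x)
  out <- array(0, c(d$t * d$c, ny, nx))
  for (iy in seq_len(fy)) for (ix in seq_len(fx)) {
    out <- out + a[, seq(iy, d$y, by = fy), seq(ix, d$x, by = fx),
                   drop = FALSE]
  }
  out <- out / (fy * fx)
  dim(out) <- c(d$t, d$c, ny, nx)
  frame_stack(out, stack$wavelengths, stack$frame_rate,
              stack$pixel_pitch * sqrt(fy * fx), stage = "binned",
              coords = NULL)
}

#' Temporal detrending and ambient-light subtraction
#'
#' Removes, per pixel and channel, the least-squares linear temporal trend
#' (including the mean), then subtracts the spatial-mean trace of each channel
#' to remove shared ambient/illumination fluctuations. The per-pixel raw
#' temporal means are stored on the stack so [mean_normalize()] can express
#' later stages as fractional change about baseline.
#'
#' @param stack a `raw` or `binned` [frame_stack()].
#' @return A detrended [frame_stack()] (per-pixel temporal mean ~ 0).
#' @export
detrend_and_center <- function(stack) {
  # re-applying to an already-detrended stack is a (near-)identity: the
  # original raw baselines are kept for later mean normalization
  check_stage(stack, c("raw", "binned", "detrended"))
  d <- stack_dims(stack)
  if (d$t < 3L) stopf("need at least 3 frames to detrend")
  m <- stack_matrix(stack)                       # time x (c*y*x)
  baseline <- colMeans(m)
  already <- stack$stage == "detrended"
  if (!already && any(abs(baseline) < .Machine$double.eps * 100)) {
    # an all-zero channel has no light level to normalize against
    ch_means <- apply(array(baseline, c(d$c, d$y, d$x)), 1, mean)
    if (any(abs(ch_means) < .Machine$double.eps * 100))
      stopf("channel with zero mean intensity cannot be detrended")
  }
  tt <- seq_len(d$t) - (d$t + 1) / 2             # centered time regressor
  slope <- as.vector(crossprod(tt, m)) / sum(tt^2)
  m <- m - rep(baseline, each = d$t)
  m <- m - tcrossprod(tt, slope)
  # subtract per-channel spatial mean trace
  a <- array(m, c(d$t, d$c, d$y, d$x))
  for (c in seq_len(d$c)) {
    tr <- rowMeans(matrix(a[, c, , ], d$t))
    a[, c, , ] <- a[, c, , ] - tr
  }
  frame_stack(a, stack$wavelengths, stack$frame_rate, stack$pixel_pitch,
              stage = "detrended",
              baseline = if (already) stack$baseline
              else array(baseline, c(d$c, d$y, d$x)),
              coords = stack$coords)
}

# windowed-sinc low-pass kernel (Hamming), cutoff in cycles/sample
sinc_kernel <- function(cutoff, half_width_samples) {
  n <- -half_width_samples:half_width_samples
  h <- 2 * cutoff * sinc_fn(2 * cutoff * n)
  w <- 0.54 + 0.46 * cos(pi * n / half_width_samples)
  h <- h * w
  h / sum(h)
}
sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Resample a stack to 1 Hz
#'
#' Anti-aliased decimation: a Hamming-windowed sinc low-pass at half the
#' target rate (0.5 Hz) is applied along time, then the filtered series is
#' sampled at integer seconds (linear interpolation between native frames, so
#' non-integer native rates such as 16.81 Hz are handled exactly).
#'
#' @param stack a detrended [frame_stack()] with `frame_rate >= 1`.
#' @param filter_half_width_s half-width of the sinc kernel, s.
#' @return A [frame_stack()] at 1 Hz.
#' @export
resample_to_1hz <- function(stack, filter_half_width_s = 4) {
  check_stage(stack, "detrended")
  if (stack$frame_rate < 1) stopf("frame rate %.3g Hz is below 1 Hz",
                                  stack$frame_rate)
  d <- stack_dims(stack)
  if (abs(stack$frame_rate - 1) < 1e-12) {
    out <- stack
    out$stage <- "resampled"
    return(out)
  }
  rate <- stack$frame_rate
  hw <- max(1L, as.integer(ceiling(filter_half_width_s * rate)))
  kern <- sinc_kernel(0.5 / rate, hw)
  m <- stack_matrix(stack)
  t_in <- (seq_len(d$t) - 1) / rate
  t_out <- seq(0, t_in[d$t], by = 1)
  idx <- findInterval(t_out, t_in, rightmost.closed = TRUE)
  idx <- pmin(idx, d$t - 1L)
  w <- (t_out - t_in[idx]) / (t_in[idx + 1L] - t_in[idx])
  exact <- abs(w) < 1e-9
  # filtered values are needed only at the input rows bracketing each output
  # sample; evaluate the convolution just there (replicate-padded edges)
  rows_needed <- sort(unique(c(idx, idx[!exact] + 1L)))
  # banded convolution as one BLAS product: K[j, ] holds the kernel taps of
  # output row j (edge-replicated)
  K <- matrix(0, length(rows_needed), d$t)
  for (k in -hw:hw) {
    src <- pmin(pmax(rows_needed + k, 1L), d$t)
    K[cbind(seq_along(rows_needed), src)] <-
      K[cbind(seq_along(rows_needed), src)] + kern[k + hw + 1L]
  }
  mf <- K %*% m
  pos <- match(idx, rows_needed)
  out <- mf[pos, , drop = FALSE]
  if (any(!exact)) {
    pos2 <- match(idx + 1L, rows_needed)
    ne <- which(!exact)
    out[ne, ] <- out[ne, ] * (1 - w[ne]) +
      mf[pos2[ne], , drop = FALSE] * w[ne]
  }
  frame_stack(array(out, c(length(t_out), d$c, d$y, d$x)),
              stack$wavelengths, frame_rate = 1, stack$pixel_pitch,
              stage = "resampled", baseline = stack$baseline,
              coords = stack$coords)
}

#' Landmark-based affine registration to atlas space
#'
#' Least-squares 2x3 affine mapping 0-based pixel coordinates `(ix, iy)`
#' (column, row) to atlas mm coordinates `(x, y)` (bregma origin, +x right,
#' +y anterior), estimated from matched landmark pairs (e.g. bregma, lambda,
#' midline points).
#'
#' @param landmarks_pixel matrix/data frame with columns `ix`, `iy` (>= 3
#'   non-collinear points).
#' @param landmarks_atlas matched matrix with columns `x_mm`, `y_mm`.
#' @return An `affine_map`: list with 2x3 `matrix` and `residual` (RMS mm).
#' @export
estimate_affine <- function(landmarks_pixel, landmarks_atlas) {
  P <- as.matrix(landmarks_pixel); A <- as.matrix(landmarks_atlas)
  if (nrow(P) < 3 || nrow(P) != nrow(A))
    stopf("need >= 3 matched landmark pairs")
  X <- cbind(P[, 1], P[, 2], 1)
  if (qr(X)$rank < 3) stopf("landmarks are collinear")
  B <- qr.solve(X, A)                 # 3 x 2
  fitted <- X %*% B
  res <- sqrt(mean((fitted - A)^2))
  structure(list(matrix = unname(t(B)), residual = res),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat("<affine_map> pixel (ix, iy) -> atlas mm, residual",
      format(x$residual, digits = 3), "mm\n")
  print(x$matrix)
  invisible(x)
}

#' Write / read an affine map as JSON
#' @param map an `affine_map`.
#' @param path JSON path.
#' @return `read_affine_json()` returns an `affine_map`.
#' @export
write_affine_json <- function(map, path) {
  jsonlite::write_json(list(matrix = map$matrix, residual = map$residual),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(matrix = matrix(unlist(x$matrix), 2, 3),
                 residual = x$residual),
            class = "affine_map")
}

# affine map for a stack whose pixel grid is already bregma-centred:
# identity up to the pitch scaling (the default for generated scenes)
#' Default pixel-to-atlas affine for a bregma-centred grid
#' @param stack a [frame_stack()].
#' @return An `affine_map`.
#' @export
default_affine <- function(stack) {
  d <- stack_dims(stack)
  p <- stack$pixel_pitch
  m <- matrix(c(p, 0, -(d$x - 1) / 2 * p,
                0, -p, (d$y - 1) / 2 * p), 2, 3, byrow = TRUE)
  structure(list(matrix = m, residual = 0), class = "affine_map")
}

invert_affine <- function(map) {
  L <- map$matrix[, 1:2]
  if (abs(det(L)) < 1e-12) stopf("affine linear part is singular")
  Li <- solve(L)
  cbind(Li, -Li %*% map$matrix[, 3])
}

#' Apply the brain mask and transform to atlas space
#'
#' Resamples every frame onto a regular atlas-mm grid via inverse-mapped
#' bilinear interpolation; pixels outside the brain mask (or mapping outside
#' the source grid) become `NA`. The per-pixel baselines recorded during
#' detrending are transformed alongside the data. The atlas grid defaults to
#' the image of the source grid (same number of pixels, pitch from the affine
#' scale); when the affine is an axis-aligned pixel-to-mm scaling the
#' resampling is exact (no interpolation blur).
#'
#' @param stack a resampled [frame_stack()].
#' @param mask logical `y x x` brain mask on the source grid.
#' @param map an `affine_map` from [estimate_affine()] or [default_affine()].
#' @return A [frame_stack()] in atlas space with `mask` and `coords` set.
#' @export
apply_mask_and_transform <- function(stack, mask, map = default_affine(stack)) {
  check_stage(stack, "resampled")
  d <- stack_dims(stack)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == c(d$y, d$x)))
    stopf("mask grid %dx%d does not match stack %dx%d",
          nrow(mask), ncol(mask), d$y, d$x)
  mask <- mask > 0
  if (!any(mask)) stopf("brain mask is empty")

  M <- map$matrix
  # atlas grid: map the source pixel index axes through the affine
  ix <- 0:(d$x - 1); iy <- 0:(d$y - 1)
  sx <- sqrt(M[1, 1]^2 + M[2, 1]^2)      # mm per source column step
  sy <- sqrt(M[1, 2]^2 + M[2, 2]^2)
  corners <- M %*% rbind(c(0, d$x - 1, 0, d$x - 1),
                         c(0, 0, d$y - 1, d$y - 1),
                         1)
  x_mm <- seq(min(corners[1, ]), max(corners[1, ]), length.out = d$x)
  y_mm <- seq(max(corners[2, ]), min(corners[2, ]), length.out = d$y)

  Mi <- invert_affine(map)
  tgt <- rbind(rep(x_mm, each = d$y), rep(y_mm, times = d$x), 1)
  src <- Mi %*% tgt                      # (ix, iy) 0-based fractional
  cx <- matrix(src[1, ], d$y, d$x)       # y-fastest layout
  cy <- matrix(src[2, ], d$y, d$x)

  i0 <- floor(cx); j0 <- floor(cy)
  fx <- cx - i0; fy <- cy - j0
  # snap near-integer coordinates so identity-scale maps resample exactly
  snap <- 1e-9
  fx[fx < snap] <- 0; fx[fx > 1 - snap] <- 1
  fy[fy < snap] <- 0; fy[fy > 1 - snap] <- 1

  inb <- function(i, j) i >= 0 & i <= d$x - 1 & j >= 0 & j <= d$y - 1
  mget <- function(i, j) {               # mask validity at source (i=ix,j=iy)
    ok <- inb(i, j)
    v <- rep(FALSE, length(i))
    v[ok] <- mask[cbind(j[ok] + 1L, i[ok] + 1L)]
    v
  }
  corners_ij <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  wts <- list((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)

  npx <- d$y * d$x
  valid <- vector("list", 4L)
  lin <- vector("list", 4L)
  for (k in 1:4) {
    i <- as.vector(i0) + corners_ij[[k]][1]
    j <- as.vector(j0) + corners_ij[[k]][2]
    ok <- mget(i, j) & as.vector(wts[[k]]) > 0
    valid[[k]] <- ok
    l <- rep(1L, npx)
    l[ok] <- j[ok] * 1L + 1L + i[ok] * d$y  # index into y-fastest frame vec
    lin[[k]] <- l
  }
  wsum <- Reduce(`+`, lapply(1:4, function(k)
    ifelse(valid[[k]], as.vector(wts[[k]]), 0)))
  out_mask <- wsum > 0.5                  # target valid if mostly in-mask

  # pure-gather fast path: every target sits exactly on one source pixel
  # (the case for an axis-aligned pixel-to-mm scaling)
  pure <- all(abs(as.vector(fx) - round(as.vector(fx))) == 0) &&
    all(abs(as.vector(fy) - round(as.vector(fy))) == 0)
  gather <- NULL
  if (pure) {
    gather <- rep(NA_integer_, npx)
    for (k in 1:4) {
      on <- valid[[k]] & as.vector(wts[[k]]) == 1
      gather[on] <- lin[[k]][on]
    }
    gather[!out_mask] <- NA_integer_
  }

  resample_frame <- function(fv) {        # fv: y-fastest vector of one frame
    num <- rep(0, npx)
    for (k in 1:4) {
      ok <- valid[[k]]
      num[ok] <- num[ok] + as.vector(wts[[k]])[ok] * fv[lin[[k]][ok]]
    }
    r <- num / wsum
    r[!out_mask] <- NA_real_
    r
  }

  a <- array(NA_real_, dim(stack$data))
  for (c in seq_len(d$c)) {
    sl <- matrix(stack$data[, c, , ], d$t)   # time x pixel (y-fastest)
    if (pure) {
      a[, c, , ] <- sl[, gather]             # NA index -> NA column
    } else {
      res <- apply(sl, 1, resample_frame)    # pixel x time
      a[, c, , ] <- t(res)
    }
  }
  baseline <- stack$baseline
  if (!is.null(baseline)) {
    for (c in seq_len(d$c))
      baseline[c, , ] <- resample_frame(as.vector(baseline[c, , ]))
  }
  frame_stack(a, stack$wavelengths, stack$frame_rate, (sx + sy) / 2,
              stage = "atlas", baseline = baseline,
              mask = matrix(out_mask, d$y, d$x),
              coords = list(x_mm = x_mm, y_mm = y_mm))
}

#' Express each pixel as fractional change about its baseline
#'
#' Divides the detrended, atlas-space data by the per-pixel raw temporal
#' means recorded by [detrend_and_center()], yielding dimensionless
#' fractional change (dI/I) suitable for the spectroscopic inversion.
#'
#' @param stack an `atlas`-stage [frame_stack()] carrying baselines.
#' @return A `normalized` [frame_stack()].
#' @export
mean_normalize <- function(stack) {
  check_stage(stack, "atlas")
  if (is.null(stack$baseline))
    stopf("stack carries no baseline means; run detrend_and_center() first")
  d <- stack_dims(stack)
  a <- stack$data
  for (c in seq_len(d$c)) {
    b <- stack$baseline[c, , ]
    bad <- is.finite(b) & abs(b) < .Machine$double.eps * 100
    if (!is.null(stack$mask) && any(bad & stack$mask))
      stopf("zero-baseline pixel inside the brain mask")
    bv <- array(rep(as.vector(b), each = d$t), c(d$t, d$y, d$x))
    a[, c, , ] <- a[, c, , ] / bv
  }
  frame_stack(a, stack$wavelengths, stack$frame_rate, stack$pixel_pitch,
              stage = "normalized", baseline = stack$baseline,
              mask = stack$mask, coords = stack$coords)
}

#' Full image-conditioning chain
#'
#' Convenience wrapper: detrend + ambient-light subtraction, resample to
#' 1 Hz, mask + atlas transform, mean normalization. Binning is applied
#' first when a `bin_to` grid is given.
#'
#' @param stack raw [frame_stack()].
#' @param mask logical brain mask (defaults to all-true).
#' @param map affine map (defaults to the bregma-centred identity scaling).
#' @param bin_to optional `c(ny, nx)` binning target.
#' @return A `normalized` [frame_stack()].
#' @export
preprocess_stack <- function(stack, mask = NULL, map = NULL, bin_to = NULL) {
  if (!is.null(bin_to)) stack <- bin_frames(stack, bin_to)
  d <- stack_dims(stack)
  if (is.null(mask)) mask <- matrix(TRUE, d$y, d$x)
  stack <- detrend_and_center(stack)
  stack <- resample_to_1hz(stack)
  stack <- apply_mask_and_transform(stack, mask,
                                    map %||% default_affine(stack))
  mean_normalize(stack)
}
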