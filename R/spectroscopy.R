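#' Spectral model for the modified Beer-Lambert inversion
#'
#' Holds hemoglobin extinction coefficients and wavelength-dependent mean
#' pathlength factors for the three reflectance channels. The differential
#' modified Beer-Lambert model is
#' `dA(lambda) = -ln(1 + dR/R) = D(lambda) * (eps_HbO(lambda) * dHbO +
#' eps_HbR(lambda) * dHbR)`, solved per pixel and time point by least squares
#' for the two chromophores.
#'
#' Default extinction coefficients are rounded from the standard compiled
#' hemoglobin spectra (Prahl compilation, cm^-1 M^-1); default pathlength
#' factors are representative Monte-Carlo-derived values for mouse dorsal
#' cortex (cm), longer at red wavelengths where tissue absorption is weak.
#' Both are configuration, not measurements, and can be replaced.
#'
#' @param wavelengths reflectance wavelengths, nm.
#' @param eps_hbo,eps_hbr molar extinction coefficients, cm^-1 M^-1.
#' @param pathlength mean pathlength factors D(lambda), cm.
#' @return A `spectral_model`.
#' @export
spectral_model <- function(wavelengths = c(523, 595, 640),
                           eps_hbo = c(24600, 4900, 440),
                           eps_hbr = c(23900, 15600, 4930),
                           pathlength = c(0.046, 0.070, 0.250)) {
  E <- cbind(hbo = eps_hbo, hbr = eps_hbr) * pathlength
  if (qr(E)$rank < 2)
    stopf("extinction/pathlength matrix is rank deficient")
  if (any(pathlength <= 0)) stopf("pathlength factors must be > 0")
  structure(list(wavelengths = wavelengths, eps_hbo = eps_hbo,
                 eps_hbr = eps_hbr, pathlength = pathlength,
                 design = E,
                 pinv = solve(crossprod(E), t(E))),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat("<spectral_model>\n")
  print(tibble::tibble(wavelength_nm = x$wavelengths, eps_hbo = x$eps_hbo,
                       eps_hbr = x$eps_hbr, pathlength_cm = x$pathlength))
  invisible(x)
}

#' Write / read a spectral model as JSON
#' @param model a [spectral_model()].
#' @param path JSON path.
#' @export
write_spectral_model <- function(model, path) {
  jsonlite::write_json(model[c("wavelengths", "eps_hbo", "eps_hbr",
                               "pathlength")], path, digits = NA)
  invisible(path)
}

#' @rdname write_spectral_model
#' @export
read_spectral_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spectral_model(x$wavelengths, x$eps_hbo, x$eps_hbr, x$pathlength)
}

#' Forward modified Beer-Lambert model
#'
#' Synthesizes differential absorbances `dA(lambda)` from known chromophore
#' concentration changes; the exact forward counterpart of
#' [beer_lambert_invert()] (used as its round-trip oracle).
#'
#' @param d_hbo,d_hbr concentration changes, micromolar (same shape).
#' @param model a [spectral_model()].
#' @return List of `dA` arrays, one per model wavelength.
#' @export
beer_lambert_forward <- function(d_hbo, d_hbr, model = spectral_model()) {
  lapply(seq_along(model$wavelengths), function(i)
    model$design[i, "hbo"] * d_hbo * 1e-6 +
      model$design[i, "hbr"] * d_hbr * 1e-6)
}

#' Invert reflectance changes to hemoglobin concentration changes
#'
#' Converts mean-normalized fractional reflectance changes at 523, 595 and
#' 640 nm into oxy-, deoxy- and total hemoglobin changes via the modified
#' Beer-Lambert law: `dA = -ln(1 + dR/R)` per wavelength, then a per-sample
#' least-squares solve of the 3x2 system. `dHbT = dHbO + dHbR` holds exactly
#' by construction.
#'
#' @param r523,r595,r640 arrays of fractional reflectance change (any common
#'   shape, e.g. `time x y x x`).
#' @param model a [spectral_model()].
#' @return List of arrays `hbo`, `hbr`, `hbt` in micromolar.
#' @export
beer_lambert_invert <- function(r523, r595, r640, model = spectral_model()) {
  shp <- dim(r523) %||% length(r523)
  if (any(r523 <= -1 | r595 <= -1 | r640 <= -1, na.rm = TRUE))
    stopf("fractional reflectance change <= -1 is nonphysical")
  dA <- rbind(-log1p(as.vector(r523)),
              -log1p(as.vector(r595)),
              -log1p(as.vector(r640)))
  conc <- model$pinv %*% dA * 1e6            # micromolar
  shape <- function(v) if (is.null(dim(r523))) v else array(v, dim(r523))
  hbo <- shape(conc[1, ]); hbr <- shape(conc[2, ])
  list(hbo = hbo, hbr = hbr, hbt = hbo + hbr)
}

#' Ratiometric hemodynamic correction of GCaMP fluorescence
#'
#' Divides the fluorescence ratio by the co-processed 523 nm reflectance
#' ratio: `corrected = (1 + dF/F) / (1 + dR523/R) - 1`. This exactly inverts
#' multiplicative absorption crosstalk of the form
#' `(1 + dF/F_obs) = (1 + dF/F_true)(1 + dR523/R)`.
#'
#' @param fluorescence fractional fluorescence change array.
#' @param r523 fractional 523 nm reflectance change array, same shape.
#' @return Corrected fractional calcium signal, same shape.
#' @export
ratiometric_correct <- function(fluorescence, r523) {
  if (!identical(dim(fluorescence), dim(r523)))
    stopf("fluorescence and 523 nm reflectance must share a grid/timebase")
  if (any(r523 <= -1, na.rm = TRUE))
    stopf("fractional 523 nm reflectance change <= -1 is nonphysical")
  (1 + fluorescence) / (1 + r523) - 1
}

# separable two-pass implementation for fully-valid frames; identical to the
# normalized 2-D convolution because the truncated kernel is separable and
# the valid region is the full rectangle (edge renormalization per axis)
gaussian_smooth_separable <- function(x, size, sigma) {
  d <- dim(x)
  h <- (size - 1L) %/% 2L
  g <- exp(-(-h:h)^2 / (2 * sigma^2))
  g <- g / sum(g)
  pass <- function(a, margin) {
    n <- d[margin + 1L]
    num <- array(0, dim(a))
    den <- numeric(n)
    for (dd in -h:h) {
      w <- g[dd + h + 1L]
      tgt <- max(1L, 1L - dd):min(n, n - dd)
      src <- tgt + dd
      if (margin == 1L) {
        num[, tgt, ] <- num[, tgt, , drop = FALSE] +
          w * a[, src, , drop = FALSE]
      } else {
        num[, , tgt] <- num[, , tgt, drop = FALSE] +
          w * a[, , src, drop = FALSE]
      }
      den[tgt] <- den[tgt] + w
    }
    if (margin == 1L) num / rep(rep(den, each = d[1]), times = d[3])
    else num / rep(den, each = d[1] * d[2])
  }
  pass(pass(x, 1L), 2L)
}

# truncated 2-D Gaussian kernel
gaussian_kernel <- function(size = 5L, sigma = 1.2) {
  h <- (size - 1L) %/% 2L
  g1 <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Mask-aware spatial Gaussian smoothing
#'
#' Smooths each frame with a truncated Gaussian kernel (5 x 5 pixels,
#' sigma 1.2 px by default) using normalized convolution: invalid (`NA`)
#' pixels are excluded from the kernel mass so smoothing never bleeds across
#' the brain-mask boundary, and edge kernels are renormalized.
#'
#' @param x 3-D array `time x y x x` (NA marks invalid pixels).
#' @param size odd kernel size in pixels.
#' @param sigma Gaussian sigma in pixels.
#' @return Smoothed array, same shape; `NA` pixels stay `NA`.
#' @export
gaussian_smooth <- function(x, size = 5L, sigma = 1.2) {
  d <- dim(x)
  if (length(d) != 3L) stopf("expected a time x y x x array")
  if (size > d[2] || size > d[3])
    stopf("kernel (%d px) larger than the image (%d x %d)", size, d[2], d[3])
  k <- gaussian_kernel(size, sigma)
  h <- (size - 1L) %/% 2L
  valid <- is.finite(x)
  if (all(valid)) return(gaussian_smooth_separable(x, size, sigma))
  xv <- x; xv[!valid] <- 0
  # validity is normally a static brain mask: compute the kernel-mass
  # normalizer once per pixel instead of per frame when it is
  v1 <- matrix(valid[1, , ], d[2], d[3])
  static_valid <- all(valid == rep(as.vector(v1), each = d[1]))
  num <- array(0, d)
  den2 <- if (static_valid) matrix(0, d[2], d[3]) else NULL
  den3 <- if (!static_valid) array(0, d) else NULL
  v1n <- v1 * 1
  for (dy in -h:h) for (dx in -h:h) {
    w <- k[dy + h + 1L, dx + h + 1L]
    ty <- max(1L, 1L - dy):min(d[2], d[2] - dy)
    tx <- max(1L, 1L - dx):min(d[3], d[3] - dx)
    sy <- ty + dy; sx <- tx + dx
    num[, ty, tx] <- num[, ty, tx, drop = FALSE] +
      w * xv[, sy, sx, drop = FALSE]
    if (static_valid) {
      den2[ty, tx] <- den2[ty, tx, drop = FALSE] + w * v1n[sy, sx]
    } else {
      den3[, ty, tx] <- den3[, ty, tx, drop = FALSE] +
        w * valid[, sy, sx, drop = FALSE]
    }
  }
  out <- if (static_valid)
    num / rep(as.vector(den2), each = d[1]) else num / den3
  dim(out) <- d
  out[!valid] <- NA_real_
  out
}

#' Global signal regression
#'
#' Computes the global signal as the average trace over all valid (in-mask)
#' pixels and removes, per pixel, the least-squares projection of the pixel
#' trace onto it. After regression every pixel trace has zero regression
#' coefficient on the original global signal.
#'
#' @param x 3-D array `time x y x x`.
#' @return Array of residuals, same shape.
#' @export
global_signal_regress <- function(x) {
  d <- dim(x)
  if (length(d) != 3L || d[1] < 3L) stopf("need a time x y x x array, >= 3 frames")
  m <- matrix(x, nrow = d[1])
  vpix <- colSums(is.finite(m)) == d[1]
  if (!any(vpix)) stopf("no valid pixels")
  g <- rowMeans(m[, vpix, drop = FALSE])
  gc <- g - mean(g)
  ss <- sum(gc^2)
  if (ss < .Machine$double.eps * 100)
    stopf("global signal is constant; regression is degenerate")
  mc <- m[, vpix, drop = FALSE]
  mc <- sweep(mc, 2, colMeans(mc))     # remove intercepts ...
  beta <- as.vector(crossprod(gc, mc)) / ss
  res <- mc - outer(gc, beta)          # ... and the g-component
  m[, vpix] <- res
  array(m, d)
}

#' Hemoglobin / calcium map set
#'
#' Runs the spectroscopy stage on a normalized atlas-space stack: modified
#' Beer-Lambert inversion of the three reflectance channels to dHbO / dHbR /
#' dHbT, ratiometric hemodynamic correction of the 454 nm fluorescence
#' channel, optional 5 x 5 Gaussian smoothing and global signal regression
#' (applied to all four map types, smoothing first).
#'
#' @param stack a `normalized` [frame_stack()].
#' @param model a [spectral_model()].
#' @param smooth apply [gaussian_smooth()].
#' @param gsr apply [global_signal_regress()].
#' @return A `hemo_maps` object: arrays `hbo`, `hbr`, `hbt` (micromolar) and
#'   `calcium` (fractional), plus `mask`, `coords`, `pixel_pitch`,
#'   `time_step`.
#' @export
compute_hemo_maps <- function(stack, model = spectral_model(),
                              smooth = TRUE, gsr = TRUE) {
  check_stage(stack, "normalized")
  r523 <- stack_channel(stack, 523)
  r595 <- stack_channel(stack, 595)
  r640 <- stack_channel(stack, 640)
  fluo <- stack_channel(stack, 454)
  hb <- beer_lambert_invert(r523, r595, r640, model)
  ca <- ratiometric_correct(fluo, r523)
  maps <- list(hbo = hb$hbo, hbr = hb$hbr, hbt = hb$hbt, calcium = ca)
  if (smooth) maps <- lapply(maps, gaussian_smooth)
  if (gsr) maps <- lapply(maps, global_signal_regress)
  structure(c(maps, list(mask = stack$mask, coords = stack$coords,
                         pixel_pitch = stack$pixel_pitch,
                         time_step = 1 / stack$frame_rate)),
            class = "hemo_maps")
}

#' @export
print.hemo_maps <- function(x, ...) {
  d <- dim(x$hbt)
  cat(sprintf("<hemo_maps> %d frames x %d x %d px (dHbO/dHbR/dHbT uM, calcium dF/F)\n",
              d[1], d[2], d[3]))
  invisible(x)
}
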