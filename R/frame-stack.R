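#' Multispectral widefield frame stack
#'
#' A `frame_stack` holds an interleaved multispectral widefield recording as a
#' 4-D array `time x channel x y x x` together with its acquisition metadata.
#' The four channels are the sequential LED illumination wavelengths used for
#' combined intrinsic optical signal (iOS) and calcium imaging: 454 nm
#' (GCaMP excitation readout) and 523, 595, 640 nm reflectance.
#'
#' The `stage` field tracks the conditioning chain; operations check that they
#' are applied in order `raw -> binned -> detrended -> resampled -> atlas ->
#' normalized` (binning may be skipped when data are generated at the target
#' grid).
#'
#' @param data numeric 4-D array, `time x channel x y x x`.
#' @param wavelengths numeric vector of channel wavelengths in nm.
#' @param frame_rate frames per second *per channel*.
#' @param pixel_pitch pixel size in mm.
#' @param stage processing stage label.
#' @param baseline optional `channel x y x x` array of per-pixel raw temporal
#'   means (recorded by [detrend_and_center()], consumed by [mean_normalize()]).
#' @param mask optional logical `y x x` brain mask.
#' @param coords optional list with atlas-space mm coordinates `x_mm`, `y_mm`
#'   of pixel centers (bregma origin, +x right, +y anterior).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, wavelengths, frame_rate, pixel_pitch,
                        stage = "raw", baseline = NULL, mask = NULL,
                        coords = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("`data` must be a 4-D array (time x channel x y x x)")
  if (length(wavelengths) != dim(data)[2L])
    stopf("length(wavelengths) must equal the channel dimension")
  if (!is_scalar_num(frame_rate) || frame_rate <= 0)
    stopf("`frame_rate` must be a positive number")
  if (!is_scalar_num(pixel_pitch) || pixel_pitch <= 0)
    stopf("`pixel_pitch` must be a positive number")
  structure(
    list(data = data, wavelengths = as.numeric(wavelengths),
         frame_rate = frame_rate, pixel_pitch = pixel_pitch,
         stage = stage, baseline = baseline, mask = mask, coords = coords),
    class = "frame_stack")
}

stack_dims <- function(stack) {
  d <- dim(stack$data)
  list(t = d[1L], c = d[2L], y = d[3L], x = d[4L])
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- stack_dims(x)
  cat(sprintf(
    "<frame_stack> %d frames x %d channels x %d x %d px  [%s]\n",
    d$t, d$c, d$y, d$x, x$stage))
  cat(sprintf("  channels: %s nm | %.4g Hz/channel | %.4g mm/px\n",
              paste(x$wavelengths, collapse = "/"), x$frame_rate,
              x$pixel_pitch))
  if (!is.null(x$mask))
    cat(sprintf("  mask: %d/%d pixels in brain\n", sum(x$mask), d$y * d$x))
  invisible(x)
}

# stage ordering used by the preprocessing chain
.stages <- c(raw = 1, binned = 2, detrended = 3, resampled = 4,
             atlas = 5, normalized = 6)

check_stage <- function(stack, allowed) {
  if (!stack$stage %in% allowed)
    stopf("operation expects stage %s, got '%s'",
          paste(sQuote(allowed), collapse = " or "), stack$stage)
  invisible(TRUE)
}

# time x pixel matrix view (pixels ordered channel-major as stored)
stack_matrix <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, nrow = d[1L])
}

matrix_to_stack_data <- function(m, dims) {
  array(m, dim = dims)
}

#' Channel slice of a frame stack
#'
#' Returns the `time x y x x` array for one wavelength channel.
#'
#' @param stack a [frame_stack()].
#' @param wavelength channel wavelength in nm.
#' @return 3-D numeric array.
#' @export
stack_channel <- function(stack, wavelength) {
  i <- match(wavelength, stack$wavelengths)
  if (is.na(i)) stopf("no %s nm channel in stack", wavelength)
  d <- stack_dims(stack)
  array(stack$data[, i, , , drop = FALSE], dim = c(d$t, d$y, d$x))
}

#' Write / read a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-interleaved in acquisition order (454, 523, 595, 640 nm
#' within each time point). Pixel values are affinely mapped to `[0, 1]` for
#' 32-bit float TIFF storage; the offset/scale and all acquisition metadata
#' are stored in `<path>.json` so the round trip is lossless to float32
#' precision.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF file path.
#' @return `write_frame_stack()` returns `path` invisibly; `read_frame_stack()`
#'   returns a [frame_stack()].
#' @export
write_frame_stack <- function(stack, path) {
  d <- stack_dims(stack)
  rng <- range(stack$data, finite = TRUE)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- vector("list", d$t * d$c)
  k <- 1L
  for (t in seq_len(d$t)) for (c in seq_len(d$c)) {
    pg <- (matrix(stack$data[t, c, , ], d$y, d$x) - rng[1]) / scale
    pg[!is.finite(pg)] <- 0
    pages[[k]] <- pg
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    wavelengths = stack$wavelengths, frame_rate = stack$frame_rate,
    pixel_pitch = stack$pixel_pitch, stage = stack$stage,
    n_time = d$t, n_channel = d$c, offset = rng[1], scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  a <- array(NA_real_, c(meta$n_time, meta$n_channel, ny, nx))
  k <- 1L
  for (t in seq_len(meta$n_time)) for (c in seq_len(meta$n_channel)) {
    a[t, c, , ] <- pages[[k]] * meta$scale + meta$offset
    k <- k + 1L
  }
  frame_stack(a, meta$wavelengths, meta$frame_rate, meta$pixel_pitch,
              stage = meta$stage)
}

# atlas mm coordinates of pixel centers for a grid centered on bregma:
# column ix (0-based) -> x = (ix - (nx-1)/2) * pitch   (+x right)
# row iy (0-based)    -> y = ((ny-1)/2 - iy) * pitch   (+y anterior, row 0 top)
default_coords <- function(ny, nx, pitch) {
  list(x_mm = (seq_len(nx) - 1 - (nx - 1) / 2) * pitch,
       y_mm = ((ny - 1) / 2 - (seq_len(ny) - 1)) * pitch)
}
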