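#' Scene configuration for the synthetic widefield generator
#'
#' Describes the acquisition geometry and noise model of a simulated
#' multispectral widefield recording. Defaults mirror the acquisition used for
#' CSD imaging in this pipeline's target preparation: four sequentially
#' illuminated LED channels (454 nm GCaMP excitation; 523, 595, 640 nm
#' reflectance) at 16.81 Hz per channel, with the speed calibration of
#' 11 pixels/mm (pixel pitch 1/11 mm).
#'
#' @param nx,ny grid size in pixels.
#' @param pixel_pitch pixel size, mm.
#' @param frame_rate acquisition rate per channel, Hz.
#' @param duration recording length, s.
#' @param channels channel wavelengths, nm; must be exactly 454/523/595/640.
#' @param baseline_counts mean detector counts per channel at rest.
#' @param noise_sigma per-channel Gaussian noise s.d. as a fraction of the
#'   baseline counts.
#' @param drift_amplitude fractional amplitude of a slow shared illumination
#'   drift (linear + slow sinusoid), removed by detrending downstream.
#' @param hemodynamic_coupling scalar mapping the simulated 523 nm fractional
#'   reflectance change into multiplicative fluorescence contamination;
#'   1 reproduces the absorption crosstalk that the ratiometric correction
#'   inverts exactly.
#' @param seed integer seed; identical seed + config reproduce the scene
#'   bit for bit.
#' @return A `scene_config` list.
#' @export
scene_config <- function(nx = 128, ny = 128, pixel_pitch = 1 / 11,
                         frame_rate = 16.81, duration = 120,
                         channels = c(454, 523, 595, 640),
                         baseline_counts = c(`454` = 200, `523` = 100,
                                             `595` = 80, `640` = 120),
                         noise_sigma = c(`454` = 0.005, `523` = 0.005,
                                         `595` = 0.005, `640` = 0.005),
                         drift_amplitude = 0.01,
                         hemodynamic_coupling = 1,
                         seed = 1L) {
  if (!identical(sort(as.numeric(channels)), c(454, 523, 595, 640)))
    stopf("channels must be exactly {454, 523, 595, 640} nm")
  if (!is_scalar_num(pixel_pitch) || pixel_pitch <= 0)
    stopf("pixel_pitch must be > 0")
  if (!is_scalar_num(frame_rate) || frame_rate <= 0)
    stopf("frame_rate must be > 0")
  if (!is_scalar_num(duration) || duration <= 0)
    stopf("duration must be > 0")
  noise_sigma <- rep_len(as.numeric(noise_sigma), 4L)
  baseline_counts <- rep_len(as.numeric(baseline_counts), 4L)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_pitch = pixel_pitch, frame_rate = frame_rate,
                 duration = duration, channels = as.numeric(channels),
                 baseline_counts = baseline_counts, noise_sigma = noise_sigma,
                 drift_amplitude = drift_amplitude,
                 hemodynamic_coupling = hemodynamic_coupling,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Specification of one simulated spreading-depolarization wave
#'
#' The wavefront is a Gaussian bump travelling at constant speed: a pixel at
#' distance `d` mm from the origin along the spread direction sees a Gaussian
#' transient in time centred at `onset + d / speed`. The canonical CSD range
#' in cortex is 3-5 mm/min.
#'
#' @param speed propagation speed, mm/min (> 0).
#' @param origin `c(x_mm, y_mm)` start of the wave in atlas coordinates.
#' @param direction unit vector `c(dx, dy)` of planar spread, or `"radial"`.
#' @param hemisphere which hemisphere carries the wave: `"left"` (x < 0),
#'   `"right"` (x > 0) or `"bilateral"`.
#' @param onset wave start time, s (>= 0).
#' @param half_width spatial FWHM of the hemodynamic wavefront profile, mm.
#' @param amplitude named fractional signal change per optical channel at the
#'   wave peak; reflectance channels typically decrease (increased absorption)
#'   while the intrinsic fluorescence transient is positive.
#' @param calcium_lead_s how much the neuronal calcium transient precedes the
#'   hemodynamic response at each pixel, s (depolarization drives the
#'   vascular response, so calcium leads).
#' @param calcium_half_width spatial FWHM of the calcium transient, mm;
#'   defaults to 0.75 of the hemodynamic width (the depolarization front is
#'   sharper than the vascular response).
#' @return A `wave_spec` list.
#' @export
wave_spec <- function(speed, origin = c(0, -4.5), direction = c(0, 1),
                      hemisphere = c("bilateral", "left", "right"),
                      onset = 10, half_width = 1.5,
                      amplitude = c(`454` = 0.01, `523` = -0.02,
                                    `595` = -0.015, `640` = -0.01),
                      calcium_lead_s = 5, calcium_half_width = NULL) {
  hemisphere <- match.arg(hemisphere)
  if (!is_scalar_num(speed) || speed <= 0) stopf("speed must be > 0 mm/min")
  if (!is_scalar_num(half_width) || half_width <= 0)
    stopf("half_width must be > 0 mm")
  if (!is_scalar_num(onset) || onset < 0) stopf("onset must be >= 0 s")
  if (!all(is.finite(amplitude))) stopf("amplitudes must be finite")
  radial <- identical(direction, "radial")
  if (!radial) {
    direction <- as.numeric(direction)
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stopf("direction must be non-zero or \"radial\"")
    direction <- direction / nrm
  }
  structure(list(speed = speed, origin = as.numeric(origin),
                 direction = if (radial) "radial" else direction,
                 hemisphere = hemisphere, onset = onset,
                 half_width = half_width,
                 amplitude = rep_len(as.numeric(amplitude), 4L),
                 calcium_lead_s = calcium_lead_s,
                 calcium_half_width = calcium_half_width %||%
                   0.75 * half_width),
            class = "wave_spec")
}

# fractional signal field of one wave: pixels x time matrix of the unit
# (amplitude-free) Gaussian transient; lead_s shifts the transient earlier
# (calcium precedes the hemodynamic response), width_mm overrides the FWHM
wave_profile_matrix <- function(wave, x_mm, y_mm, times, lead_s = 0,
                                width_mm = NULL) {
  grid <- expand.grid(y = y_mm, x = x_mm)   # y fastest: matches array layout
  if (identical(wave$direction, "radial")) {
    d <- sqrt((grid$x - wave$origin[1])^2 + (grid$y - wave$origin[2])^2)
  } else {
    d <- (grid$x - wave$origin[1]) * wave$direction[1] +
      (grid$y - wave$origin[2]) * wave$direction[2]
  }
  hemi <- switch(wave$hemisphere,
                 bilateral = rep(TRUE, nrow(grid)),
                 left = grid$x < 0,
                 right = grid$x > 0)
  sigma <- (width_mm %||% wave$half_width) / (2 * sqrt(2 * log(2)))
  v <- wave$speed / 60                       # mm/s
  tt <- times + lead_s
  front <- v * (tt - wave$onset)             # front distance from origin, mm
  front[tt < wave$onset] <- -Inf             # wave has not started
  # pixels x time: exp(-(d - front)^2 / 2 sigma^2)
  z <- outer(d, front, `-`)
  prof <- exp(-z^2 / (2 * sigma^2))
  prof[!hemi, ] <- 0
  prof
}

#' Generate a synthetic multispectral wave recording
#'
#' Builds a raw 4-channel frame stack containing the specified travelling
#' depolarization waves, hemodynamic crosstalk into the fluorescence channel,
#' shared illumination drift, and per-channel Gaussian noise, together with a
#' ground-truth record of the true wavefront positions.
#'
#' The forward model per pixel is
#' `counts = B_c * (1 + s_c) * (1 + drift(t)) + noise`, where `s_c` is the
#' channel's fractional wave signal. The fluorescence channel observes
#' `(1 + dF/F_true) * (1 + k * dR523/R) - 1`, i.e. multiplicative attenuation
#' by the 523 nm reflectance ratio (coupling `k`), which the ratiometric
#' correction inverts exactly when `k = 1`.
#'
#' @param scene a [scene_config()].
#' @param waves list of [wave_spec()] objects (possibly empty).
#' @return A list with elements `stack` (a raw [frame_stack()]) and `truth`
#'   (list: `waves` tibble, `front` tibble of true front positions per frame,
#'   `seed`).
#' @export
generate_wave_stack <- function(scene, waves = list()) {
  if (inherits(waves, "wave_spec")) waves <- list(waves)
  d <- list(t = max(1L, floor(scene$duration * scene$frame_rate)),
            c = 4L, y = scene$ny, x = scene$nx)
  coords <- default_coords(scene$ny, scene$nx, scene$pixel_pitch)
  half_x <- (scene$nx - 1) / 2 * scene$pixel_pitch + scene$pixel_pitch / 2
  half_y <- (scene$ny - 1) / 2 * scene$pixel_pitch + scene$pixel_pitch / 2
  for (w in waves) {
    if (!inherits(w, "wave_spec")) stopf("waves must be wave_spec objects")
    if (abs(w$origin[1]) > half_x || abs(w$origin[2]) > half_y)
      stopf("wave origin (%.2f, %.2f) lies outside the imaged grid",
            w$origin[1], w$origin[2])
    if (w$onset > scene$duration)
      stopf("wave onset %.1f s is beyond scene duration %.1f s", w$onset,
            scene$duration)
  }
  times <- (seq_len(d$t) - 1) / scene$frame_rate
  npix <- d$y * d$x

  # accumulate fractional signal per channel (pixels x time)
  frac <- lapply(1:4, function(i) matrix(0, npix, d$t))
  for (w in waves) {
    prof <- wave_profile_matrix(w, coords$x_mm, coords$y_mm, times)
    for (c in 2:4) frac[[c]] <- frac[[c]] + w$amplitude[c] * prof
    # channel 1 carries the true calcium transient (leads the hemodynamics,
    # narrower front) before hemodynamic contamination is applied
    prof_ca <- wave_profile_matrix(w, coords$x_mm, coords$y_mm, times,
                                   lead_s = w$calcium_lead_s,
                                   width_mm = w$calcium_half_width)
    frac[[1]] <- frac[[1]] + w$amplitude[1] * prof_ca
  }
  # hemodynamic contamination of the fluorescence channel by 523 nm
  k <- scene$hemodynamic_coupling
  frac[[1]] <- (1 + frac[[1]]) * (1 + k * frac[[2]]) - 1

  drift <- scene$drift_amplitude *
    (0.5 * sin(2 * pi * times / max(scene$duration, 1)) +
       (times / max(scene$duration, 1) - 0.5))

  a <- array(NA_real_, c(d$t, d$c, d$y, d$x))
  with_seed(scene$seed, {
    for (c in 1:4) {
      B <- scene$baseline_counts[c]
      sig <- t(frac[[c]])                    # time x pixels
      sig <- B * (1 + sig) * (1 + drift)
      if (scene$noise_sigma[c] > 0)
        sig <- sig + matrix(rnorm(length(sig), 0, scene$noise_sigma[c] * B),
                            nrow = d$t)
      a[, c, , ] <- sig
    }
  })

  front <- purrr::imap_dfr(waves, function(w, i) {
    tv <- times[times >= w$onset]
    tibble::tibble(wave = i, time = tv,
                   front_mm = (w$speed / 60) * (tv - w$onset))
  })
  truth <- list(
    waves = purrr::imap_dfr(waves, function(w, i)
      tibble::tibble(wave = i, speed_mm_min = w$speed,
                     origin_x = w$origin[1], origin_y = w$origin[2],
                     hemisphere = w$hemisphere, onset = w$onset,
                     half_width = w$half_width)),
    front = front,
    calcium_true = NULL,
    seed = scene$seed)

  stack <- frame_stack(a, scene$channels, scene$frame_rate,
                       scene$pixel_pitch, stage = "raw", coords = coords)
  list(stack = stack, truth = truth)
}

#' True calcium transient of a synthetic scene
#'
#' Recomputes the contamination-free fractional fluorescence signal of a set
#' of waves on an arbitrary time base; used as the oracle for the ratiometric
#' hemodynamic correction.
#'
#' @param scene a [scene_config()].
#' @param waves list of [wave_spec()].
#' @param times evaluation times, s.
#' @return array `time x y x x` of fractional fluorescence change.
#' @export
true_calcium_field <- function(scene, waves, times) {
  if (inherits(waves, "wave_spec")) waves <- list(waves)
  coords <- default_coords(scene$ny, scene$nx, scene$pixel_pitch)
  acc <- matrix(0, scene$ny * scene$nx, length(times))
  for (w in waves)
    acc <- acc + w$amplitude[1] *
      wave_profile_matrix(w, coords$x_mm, coords$y_mm, times,
                          lead_s = w$calcium_lead_s,
                          width_mm = w$calcium_half_width)
  array(t(acc), dim = c(length(times), scene$ny, scene$nx))
}
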