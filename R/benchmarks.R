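# Validation benchmarks: parameter-recovery experiments run on the synthetic
# generator through the full analysis chain. Used by the test suite and the
# acceptance script; problem sizes are chosen to exercise the study grid
# (128 x 128 px at 11 px/mm) while staying tractable on one CPU.

#' Simulate one planar-wave scene and recover its speed
#'
#' Generates a noiseless or noisy planar wave travelling anterior (+y) across
#' a bregma-centred grid, runs the full conditioning + spectroscopy chain,
#' and fits the wavefront speed from the right-hemisphere position-time plot
#' for both total hemoglobin and corrected calcium.
#'
#' The scene is simulated at `native_rate` Hz (resampled to 1 Hz by the
#' chain). `snr` is the per-pixel, per-frame ratio of each channel's wave
#' amplitude to its Gaussian noise sigma; `Inf` gives a noiseless scene.
#'
#' @param speed_mm_min true wave speed.
#' @param snr per-pixel amplitude-to-noise ratio (`Inf` = noiseless).
#' @param seed scene seed.
#' @param ny,nx,pixel_pitch grid geometry (defaults: 128 x 128 at 1/11 mm).
#' @param native_rate simulated acquisition rate, Hz.
#' @param duration scene length, s. The default (`NULL`) scales the
#'   observation window with the transit time — slow waves are observed
#'   longer, as in a real recording session — so the full crossing plus
#'   baseline margins is always captured.
#' @param gsr apply global signal regression in the chain.
#' @return List: `fits` (named `hbt`/`calcium` [fit_speed()] objects or
#'   `NULL`), `truth` (generator ground truth), `maps`.
#' @export
simulate_speed_run <- function(speed_mm_min, snr = Inf, seed = 1L,
                               ny = 128, nx = 128, pixel_pitch = 1 / 11,
                               native_rate = 2, duration = NULL,
                               gsr = FALSE) {
  half_y <- (ny - 1) / 2 * pixel_pitch
  wave <- wave_spec(speed = speed_mm_min, origin = c(0, -0.8 * half_y),
                    direction = c(0, 1), hemisphere = "bilateral",
                    onset = 10)
  if (is.null(duration)) {
    transit_s <- 1.8 * half_y * 60 / speed_mm_min
    duration <- 10 + ceiling(transit_s) + 30
  }
  sig <- if (is.finite(snr)) abs(wave$amplitude) / snr else rep(0, 4)
  scene <- scene_config(nx = nx, ny = ny, pixel_pitch = pixel_pitch,
                        frame_rate = native_rate, duration = duration,
                        noise_sigma = sig, seed = seed)
  sim <- generate_wave_stack(scene, list(wave))
  pre <- preprocess_stack(sim$stack)
  maps <- compute_hemo_maps(pre, gsr = gsr)
  ppm <- 1 / maps$pixel_pitch
  fits <- list(
    hbt = fit_window(maps, "hbt", "y", "right", NULL, ppm),
    calcium = fit_window(maps, "calcium", "y", "right", NULL, ppm))
  list(fits = fits, truth = sim$truth, maps = maps)
}

#' Speed parameter-recovery benchmark
#'
#' Runs [simulate_speed_run()] over a grid of true speeds (and optionally
#' several noise replicates) and tabulates the relative recovery error per
#' modality.
#'
#' @param speeds true speeds, mm/min.
#' @param snr per-pixel amplitude-to-noise ratio.
#' @param replicates seeded replicates per speed.
#' @param seed base seed; replicate r of speed s uses
#'   `seed + 1000 * index(s) + r`.
#' @param ... passed to [simulate_speed_run()].
#' @return Tibble: one row per (speed, replicate) with estimated speeds and
#'   relative errors.
#' @export
speed_recovery_benchmark <- function(speeds = c(2, 3, 4, 5, 6, 8, 10),
                                     snr = Inf, replicates = 1, seed = 1L,
                                     ...) {
  grid <- tidyr::expand_grid(speed = speeds, rep = seq_len(replicates))
  purrr::pmap_dfr(grid, function(speed, rep) {
    run_seed <- seed + 1000L * match(speed, speeds) + rep
    run <- simulate_speed_run(speed, snr = snr, seed = run_seed, ...)
    est_hbt <- if (!is.null(run$fits$hbt)) run$fits$hbt$speed_mm_min
    else NA_real_
    est_ca <- if (!is.null(run$fits$calcium))
      run$fits$calcium$speed_mm_min else NA_real_
    tibble::tibble(
      speed_true = speed, rep = rep, seed = run_seed,
      speed_hbt = est_hbt, speed_calcium = est_ca,
      rel_error_hbt = abs(est_hbt - speed) / speed,
      rel_error_calcium = abs(est_ca - speed) / speed)
  })
}

#' Imaging vs EEG speed concordance benchmark
#'
#' Joint simulation of one wave with a two-electrode EEG whose suppression
#' lag matches the wave's transit time over the electrode separation. Returns
#' the three speed estimates (total hemoglobin, calcium, EEG).
#'
#' @param seed base seed.
#' @param speed_mm_min true speed.
#' @param separation_mm electrode separation.
#' @param ... passed to [simulate_speed_run()].
#' @return One-row tibble with `speed_true`, `speed_hbt`, `speed_calcium`,
#'   `speed_eeg`.
#' @export
concordance_benchmark <- function(seed = 1L, speed_mm_min = 4,
                                  separation_mm = 3, ...) {
  run <- simulate_speed_run(speed_mm_min, seed = seed, ...)
  lag_s <- separation_mm / speed_mm_min * 60
  spec <- eeg_spec(
    duration = 150, fs = 250, channels = c("left", "right"),
    electrode_separation_mm = separation_mm,
    events = tibble::tibble(onset = 30, duration = lag_s + 30,
                            reduction = 0.8, laterality = "bilateral",
                            lag_s = lag_s, transition_s = 5,
                            recovery_s = 5),
    seed = seed + 7L)
  eeg <- generate_eeg(spec)
  es <- eeg_speed(eeg$record$traces$right, eeg$record$traces$left,
                  fs = 250, separation_mm = separation_mm)
  tibble::tibble(
    speed_true = speed_mm_min,
    speed_hbt = run$fits$hbt$speed_mm_min,
    speed_calcium = run$fits$calcium$speed_mm_min,
    speed_eeg = es$speed_mm_min)
}

#' Beer-Lambert forward/inverse round-trip error
#'
#' Draws random (dHbO, dHbR) pairs, synthesizes differential absorbances with
#' the forward model, converts them to fractional reflectance changes,
#' inverts, and reports the maximum recovery error relative to the signal
#' magnitude.
#'
#' @param n number of random samples.
#' @param seed seed.
#' @param sd_um s.d. of the drawn concentration changes, micromolar.
#' @param model [spectral_model()].
#' @return Max relative recovery error (scalar).
#' @export
beer_lambert_roundtrip <- function(n = 1e4, seed = 1L, sd_um = 10,
                                   model = spectral_model()) {
  with_seed(seed, {
    hbo <- rnorm(n, 0, sd_um)
    hbr <- rnorm(n, 0, sd_um)
    dA <- beer_lambert_forward(hbo, hbr, model)
    refl <- lapply(dA, function(a) expm1(-a))
    out <- beer_lambert_invert(refl[[1]], refl[[2]], refl[[3]], model)
    max(abs(out$hbo - hbo), abs(out$hbr - hbr)) /
      max(abs(hbo), abs(hbr))
  })
}

#' Exactness of the ratiometric correction on a noiseless scene
#'
#' On a noiseless contaminated scene the ratiometric correction must return
#' the contamination-free calcium transient exactly (the correction divides
#' out both the hemodynamic crosstalk and any shared multiplicative drift).
#' Fractional changes are formed against the generator's known baseline
#' counts so the comparison isolates the correction itself.
#'
#' @param seed seed.
#' @param ny,nx grid size.
#' @return Max absolute deviation from the true calcium field.
#' @export
ratiometric_exactness <- function(seed = 1L, ny = 32, nx = 32) {
  scene <- scene_config(nx = nx, ny = ny, frame_rate = 2, duration = 90,
                        noise_sigma = rep(0, 4), seed = seed)
  wave <- wave_spec(speed = 4, origin = c(0, -1), hemisphere = "bilateral")
  sim <- generate_wave_stack(scene, list(wave))
  times <- (seq_len(dim(sim$stack$data)[1]) - 1) / scene$frame_rate
  drift_free <- function(ch, B) {
    # counts = B (1 + s)(1 + drift): the ratio of two channels cancels drift
    stack_channel(sim$stack, ch) / B - 1
  }
  f <- drift_free(454, scene$baseline_counts[1])
  r <- drift_free(523, scene$baseline_counts[2])
  corrected <- ratiometric_correct(f, r)
  truth <- true_calcium_field(scene, list(wave), times)
  max(abs(corrected - truth))
}

#' Does the ratiometric correction decorrelate calcium from hemodynamics?
#'
#' On contaminated noisy scenes, compares |corr| between total hemoglobin and
#' the fluorescence signal before vs after ratiometric correction. The
#' simulated calcium transient leads and is narrower than the hemodynamic
#' response, so residual crosstalk inflates the correlation and the
#' correction must reduce it.
#'
#' @param replicates number of seeded replicates.
#' @param seed base seed.
#' @return Tibble per replicate: `cor_uncorrected`, `cor_corrected`.
#' @export
ratiometric_contamination_benchmark <- function(replicates = 5, seed = 1L) {
  purrr::map_dfr(seq_len(replicates), function(r) {
    scene <- scene_config(nx = 48, ny = 48, frame_rate = 2, duration = 120,
                          seed = seed + r)
    wave <- wave_spec(speed = 4, origin = c(0, -2), hemisphere = "bilateral")
    sim <- generate_wave_stack(scene, list(wave))
    pre <- preprocess_stack(sim$stack)
    maps <- compute_hemo_maps(pre, smooth = TRUE, gsr = FALSE)
    uncorrected <- gaussian_smooth(stack_channel(pre, 454))
    cc <- function(a, b) {
      ok <- is.finite(a) & is.finite(b)
      stats::cor(a[ok], b[ok])
    }
    tibble::tibble(rep = r,
                   cor_uncorrected = cc(uncorrected, maps$hbt),
                   cor_corrected = cc(maps$calcium, maps$hbt))
  })
}

#' LVA detector boundary grid
#'
#' Synthesizes one suppression event per combination of power reduction,
#' onset-transition time, and duration on a grid straddling the LVA criterion
#' (0.75 reduction, 15 s onset, 600 s duration) and records whether the
#' detector found it. Detection must occur exactly when
#' `reduction > 0.75 & transition <= 15 & duration < 600`.
#'
#' @param seed base seed.
#' @param reductions,transitions,durations grid values.
#' @return Tibble with the grid, `expected`, and `detected`.
#' @export
lva_boundary_grid <- function(seed = 1L,
                              reductions = c(0.70, 0.74, 0.76, 0.90),
                              transitions = c(5, 14, 16, 30),
                              durations = c(30, 300, 590, 700)) {
  grid <- tidyr::expand_grid(reduction = reductions,
                             transition = transitions,
                             duration = durations)
  purrr::pmap_dfr(grid, function(reduction, transition, duration) {
    duration <- max(duration, transition)
    spec <- eeg_spec(
      duration = 90 + duration + 60, channels = "right",
      events = tibble::tibble(onset = 90, duration = duration,
                              reduction = reduction,
                              laterality = "unilateral-right",
                              transition_s = transition, recovery_s = 5),
      seed = seed + round(1000 * reduction) + 10L * transition)
    eeg <- generate_eeg(spec)
    ev <- detect_lva_record(eeg$record)
    tibble::tibble(reduction = reduction, transition = transition,
                   duration = duration,
                   expected = reduction > 0.75 & transition <= 15 &
                     duration < 600,
                   detected = nrow(ev) > 0)
  })
}

#' False positives on event-free synthetic EEG
#'
#' @param hours record length, h.
#' @param seed seed.
#' @return Number of LVA events detected (should be 0).
#' @export
lva_false_positive_hours <- function(hours = 10, seed = 1L) {
  spec <- eeg_spec(duration = hours * 3600, channels = "right", seed = seed)
  eeg <- generate_eeg(spec)
  nrow(detect_lva_record(eeg$record))
}

#' Statistics oracle benchmark
#'
#' Compares [chi_squared()] and [compare_event_rates()] against independent
#' closed-form textbook computations on random small tables and samples.
#'
#' @param n_tables,n_tests numbers of random cases.
#' @param seed seed.
#' @return One-row tibble with the maximum absolute deviations.
#' @export
stats_oracle_benchmark <- function(n_tables = 100, n_tests = 100, seed = 1L) {
  with_seed(seed, {
    chi_err <- max(vapply(seq_len(n_tables), function(i) {
      tab <- matrix(sample(1:50, 4, replace = TRUE), 2, 2)
      got <- chi_squared(tab)
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- sum((tab - e)^2 / e)
      p <- stats::pchisq(stat, 1, lower.tail = FALSE)
      max(abs(got$statistic - stat), abs(got$p_value - p))
    }, numeric(1)))
    t_err <- max(vapply(seq_len(n_tests), function(i) {
      a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.5)
      got <- compare_event_rates(a, b)
      na <- length(a); nb <- length(b)
      sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
        (na + nb - 2)
      tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
      p <- 2 * stats::pt(-abs(tt), na + nb - 2)
      max(abs(got$t - tt), abs(got$p_value - p))
    }, numeric(1)))
    tibble::tibble(chi_squared_max_abs_err = chi_err,
                   t_test_max_abs_err = t_err)
  })
}
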