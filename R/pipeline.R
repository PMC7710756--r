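#' Read a pipeline configuration file
#'
#' YAML configuration with all analysis thresholds surfaced; unspecified
#' fields fall back to the standard defaults (LVA reduction 0.75, onset
#' window 15 s, maximum duration 600 s, 60 s righting criterion,
#' 11 pixels/mm).
#'
#' @param path YAML file.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_pipeline_config(), user)
  for (f in c("pixels_per_mm", "lva_threshold", "lva_onset_window_s",
              "lva_max_duration_s", "righting_s"))
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] <= 0)
      stopf("config field '%s' must be a positive number", f)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @export
default_pipeline_config <- function() {
  list(pixels_per_mm = 11, lva_threshold = 0.75, lva_onset_window_s = 15,
       lva_max_duration_s = 600, righting_s = 60, hemisphere = "right",
       axis = "y", seed = 1L)
}

#' Machine-readable provenance record for a run
#'
#' @param config configuration list.
#' @param seeds named seeds used by the run.
#' @return List: md5 hash of the serialized config, seeds, package and R
#'   versions.
#' @export
provenance_record <- function(config, seeds = list()) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  list(config_hash = unname(tools::md5sum(tf)),
       seeds = seeds,
       package_version = as.character(utils::packageVersion("csdwave")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

# speed fits for one time window of a map set; returns NULL on "no transient"
fit_window <- function(maps, signal, axis, hemisphere, window,
                       pixels_per_mm, min_prominence = NULL) {
  tryCatch({
    pt <- build_position_time_plot(maps, signal = signal, axis = axis,
                                   hemisphere = hemisphere, window = window)
    ridge <- extract_ridge(pt, min_prominence = min_prominence)
    fit_speed(ridge, pixels_per_mm)
  }, error = function(e) {
    if (grepl("no transient", conditionMessage(e))) NULL else stop(e)
  })
}

#' Induced-CSD session analysis
#'
#' Runs the full conditioning + spectroscopy chain once, then fits a
#' wavefront speed (total hemoglobin and corrected calcium) inside each
#' pinprick trial window. Trials in which no propagating transient follows
#' the pinprick are flagged `excluded` and drop out of the summary, mirroring
#' the discard rule for trials without an immediate CSD.
#'
#' @param stack raw [frame_stack()] covering the whole session.
#' @param trials tibble with `trial`, `t0`, `t1` (s, post-resampling
#'   timebase).
#' @param mask,map optional brain mask / affine (defaults: full mask,
#'   bregma-centred scaling).
#' @param hemisphere,axis spread annotation used for the position-time plots.
#' @param model [spectral_model()].
#' @param pixels_per_mm spatial calibration (defaults to the stack pitch).
#' @param gsr apply global signal regression.
#' @return List: `events` (one row per non-excluded trial), `excluded`
#'   (flagged trials), `maps`, `provenance`.
#' @export
run_icsd <- function(stack, trials, mask = NULL, map = NULL,
                     hemisphere = "right", axis = "y",
                     model = spectral_model(), pixels_per_mm = NULL,
                     gsr = FALSE) {
  pre <- preprocess_stack(stack, mask = mask, map = map)
  maps <- compute_hemo_maps(pre, model = model, gsr = gsr)
  ppm <- pixels_per_mm %||% (1 / maps$pixel_pitch)
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(trials))) {
    win <- c(trials$t0[i], trials$t1[i])
    fits <- list(hbt = fit_window(maps, "hbt", axis, hemisphere, win, ppm),
                 calcium = fit_window(maps, "calcium", axis, hemisphere,
                                      win, ppm))
    if (is.null(fits$hbt) && is.null(fits$calcium)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        trial = trials$trial[i], reason = "no CSD followed the pinprick")
      next
    }
    rows[[length(rows) + 1L]] <-
      summarize_event(fits, hemisphere = hemisphere, axes = axis,
                      event_id = trials$trial[i], onset = win[1])
  }
  list(events = dplyr::bind_rows(rows), excluded = dplyr::bind_rows(excl),
       maps = maps,
       provenance = provenance_record(
         list(hemisphere = hemisphere, axis = axis,
              pixels_per_mm = ppm, gsr = gsr, trials = trials)))
}

#' Spontaneous-CSD session: joint imaging + EEG analysis
#'
#' Fits CSD speeds on the imaging record, detects LVA events on the EEG
#' record (classifying laterality when both channels are present), and
#' annotates temporal co-occurrence between the imaging transit window and
#' each LVA event. Imaging and EEG must share one timebase: their durations
#' must agree within `sync_tol_s`.
#'
#' @param stack raw [frame_stack()].
#' @param record [eeg_record()] synchronized with the stack.
#' @param window optional imaging analysis window `c(t0, t1)`, s.
#' @param sync_tol_s maximum allowed duration mismatch, s.
#' @inheritParams run_icsd
#' @return List: `csd` (event tibble), `lva` (event tibble with laterality),
#'   `association` (per-LVA co-occurrence), `provenance`.
#' @export
run_scsd_session <- function(stack, record, window = NULL, mask = NULL,
                             map = NULL, hemisphere = "right", axis = "y",
                             model = spectral_model(), pixels_per_mm = NULL,
                             gsr = FALSE, sync_tol_s = 2) {
  d <- stack_dims(stack)
  dur_img <- d$t / stack$frame_rate
  dur_eeg <- length(record$traces[[1]]) / record$fs
  if (abs(dur_img - dur_eeg) > sync_tol_s)
    stopf("imaging (%.1f s) and EEG (%.1f s) timebases are not synchronized",
          dur_img, dur_eeg)
  pre <- preprocess_stack(stack, mask = mask, map = map)
  maps <- compute_hemo_maps(pre, model = model, gsr = gsr)
  ppm <- pixels_per_mm %||% (1 / maps$pixel_pitch)
  fits <- list(hbt = fit_window(maps, "hbt", axis, hemisphere, window, ppm),
               calcium = fit_window(maps, "calcium", axis, hemisphere,
                                    window, ppm))
  csd <- if (is.null(fits$hbt) && is.null(fits$calcium)) {
    tibble::tibble()
  } else {
    f <- fits[!vapply(fits, is.null, logical(1))][[1]]
    summarize_event(fits, hemisphere = hemisphere, axes = axis,
                    onset = min(f$points$time))
  }
  per_channel <- detect_lva_record(record)
  lva <- if (all(c("left", "right") %in% per_channel$channel)) {
    classify_laterality(per_channel[per_channel$channel == "left", ],
                        per_channel[per_channel$channel == "right", ])
  } else if (nrow(per_channel)) {
    dplyr::mutate(per_channel,
                  laterality = paste0("unilateral-", .data$channel))
  } else per_channel
  association <- if (nrow(lva) && nrow(csd)) {
    f <- fits[!vapply(fits, is.null, logical(1))][[1]]
    span <- range(f$points$time)
    dplyr::mutate(lva, csd_overlap_s = interval_overlap(
      .data$onset, .data$offset, span[1], span[2]),
      co_occurring = .data$csd_overlap_s > 0)
  } else if (nrow(lva)) {
    dplyr::mutate(lva, csd_overlap_s = 0, co_occurring = FALSE)
  } else lva
  list(csd = csd, lva = lva, association = association,
       provenance = provenance_record(
         list(hemisphere = hemisphere, axis = axis, pixels_per_mm = ppm,
              gsr = gsr, window = window)))
}

#' Render a position-time plot with its ridge fit to PNG
#'
#' Heatmap of the position-time matrix with the fitted regression line and a
#' speed annotation overlaid.
#'
#' @param plot a [build_position_time_plot()] result.
#' @param fit optional [fit_speed()] result to overlay.
#' @param path output PNG path.
#' @param width,height,dpi device geometry.
#' @return `path`, invisibly.
#' @export
render_position_time_png <- function(plot, fit = NULL, path,
                                     width = 6, height = 4, dpi = 120) {
  p <- autoplot(plot, fit = fit)
  grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi)
  print(p)
  grDevices::dev.off()
  invisible(path)
}
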