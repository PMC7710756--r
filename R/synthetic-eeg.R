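#' EEG record container
#'
#' Holds one or two cortical EEG traces (microvolts) with their sampling rate
#' and the band-pass applied at acquisition (0.5-100 Hz by default, digitized
#' at 250 Hz in the emulated setup).
#'
#' @param traces named list of numeric vectors (`left`, `right`), microvolts.
#' @param fs sampling rate, Hz.
#' @param filters acquisition band `c(high_pass, low_pass)`, Hz.
#' @return An `eeg_record`.
#' @export
eeg_record <- function(traces, fs, filters = c(0.5, 100)) {
  if (!is.list(traces) || is.null(names(traces)))
    stopf("`traces` must be a named list of numeric vectors")
  if (!all(names(traces) %in% c("left", "right")))
    stopf("channel names must be 'left' and/or 'right'")
  n <- lengths(traces)
  if (length(unique(n)) != 1L) stopf("all channels must have equal length")
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be > 0")
  if (fs <= 2 * filters[2])
    stopf("sampling rate must exceed twice the low-pass corner")
  structure(list(traces = traces, fs = fs, filters = filters),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  n <- length(x$traces[[1]])
  cat(sprintf("<eeg_record> %s | %g Hz | %.1f s | band %g-%g Hz\n",
              paste(names(x$traces), collapse = "+"), x$fs, n / x$fs,
              x$filters[1], x$filters[2]))
  invisible(x)
}

#' @export
as_tibble.eeg_record <- function(x, ...) {
  n <- length(x$traces[[1]])
  t <- (seq_len(n) - 1) / x$fs
  purrr::imap_dfr(x$traces, function(v, ch)
    tibble::tibble(time = t, channel = ch, uv = v))
}

#' Specification of a synthetic EEG recording
#'
#' Background is band-limited (0.5-100 Hz) Gaussian noise plus a ~3 Hz
#' breathing artifact. Suppression events scale the instantaneous signal
#' *power* down by `reduction`, ramping linearly in power over
#' `transition_s`, holding until `onset + duration`, then recovering linearly
#' over `recovery_s`. When two channels are requested the left channel is a
#' copy of the right delayed by the events' inter-electrode lag.
#'
#' @param duration record length, s.
#' @param fs sampling rate, Hz.
#' @param channels `"right"` or `c("left", "right")`.
#' @param electrode_separation_mm distance between the two electrodes.
#' @param background_sd s.d. of the broadband background, microvolts.
#' @param breathing_hz,breathing_amp frequency (Hz) and amplitude (microvolts)
#'   of the breathing artifact.
#' @param events tibble with columns `onset`, `duration`, `reduction`
#'   (fraction of total power lost, in `[0, 1]`), `laterality`
#'   (`"bilateral"`, `"unilateral-left"`, `"unilateral-right"`), and
#'   optionally `lag_s`, `transition_s`, `recovery_s`.
#' @param seed integer seed.
#' @return An `eeg_spec` list.
#' @export
eeg_spec <- function(duration, fs = 250, channels = c("left", "right"),
                     electrode_separation_mm = 3,
                     background_sd = 5, breathing_hz = 3, breathing_amp = 50,
                     events = NULL, seed = 1L) {
  if (!is_scalar_num(duration) || duration <= 0) stopf("duration must be > 0")
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be > 0")
  if (is.null(events))
    events <- tibble::tibble(onset = numeric(), duration = numeric(),
                             reduction = numeric(), laterality = character())
  events <- tibble::as_tibble(events)
  if (nrow(events)) {
    if (!"lag_s" %in% names(events)) events$lag_s <- 0
    if (!"transition_s" %in% names(events)) events$transition_s <- 5
    if (!"recovery_s" %in% names(events)) events$recovery_s <- 5
    if (any(events$reduction < 0 | events$reduction > 1))
      stopf("power reduction must lie in [0, 1]")
    if (any(events$lag_s >= events$duration))
      stopf("inter-electrode lag must be smaller than the event duration")
    ev <- events[order(events$onset), ]
    if (nrow(ev) > 1) {
      ends <- ev$onset + ev$duration + ev$recovery_s
      if (any(ev$onset[-1] < ends[-nrow(ev)]))
        stopf("suppression events must not overlap")
    }
  }
  structure(list(duration = duration, fs = fs, channels = channels,
                 electrode_separation_mm = electrode_separation_mm,
                 background_sd = background_sd, breathing_hz = breathing_hz,
                 breathing_amp = breathing_amp, events = events,
                 seed = as.integer(seed)),
            class = "eeg_spec")
}

# band-limited Gaussian noise via FFT masking
band_noise <- function(n, fs, band, sd) {
  if (sd <= 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency
  keep <- f >= band[1] & f <= band[2]
  W[!keep] <- 0i
  x <- Re(fft(W, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# piecewise-linear power envelope of one suppression event, evaluated at t
event_power_envelope <- function(t, onset, duration, reduction,
                                 transition, recovery) {
  p <- rep(1, length(t))
  floor_p <- 1 - reduction
  ramp <- t >= onset & t < onset + transition
  p[ramp] <- 1 - reduction * (t[ramp] - onset) / transition
  hold <- t >= onset + transition & t < onset + duration
  p[hold] <- floor_p
  rec <- t >= onset + duration & t < onset + duration + recovery
  p[rec] <- floor_p + reduction * (t[rec] - onset - duration) / recovery
  p
}

#' Generate a synthetic EEG record with known suppression events
#'
#' @param spec an [eeg_spec()].
#' @return A list with `record` (an [eeg_record()]) and `truth` (the event
#'   tibble with the seed attached).
#' @export
generate_eeg <- function(spec) {
  n <- round(spec$duration * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  ev <- spec$events
  lags <- if (nrow(ev)) unique(ev$lag_s) else numeric()
  if (length(lags) > 1)
    stopf("all events in one record must share a single inter-electrode lag")
  lag <- if (length(lags)) lags else 0

  base <- with_seed(spec$seed, {
    band_noise(n, spec$fs, c(0.5, 100), spec$background_sd) +
      spec$breathing_amp * sin(2 * pi * spec$breathing_hz * t)
  })

  envelope_for <- function(channel, tt) {
    p <- rep(1, length(tt))
    if (!nrow(ev)) return(p)
    for (i in seq_len(nrow(ev))) {
      lat <- ev$laterality[i]
      applies <- lat == "bilateral" ||
        (lat == "unilateral-left" && channel == "left") ||
        (lat == "unilateral-right" && channel == "right")
      if (!applies) next
      p <- p * event_power_envelope(tt, ev$onset[i], ev$duration[i],
                                    ev$reduction[i], ev$transition_s[i],
                                    ev$recovery_s[i])
    }
    p
  }

  traces <- list()
  for (ch in spec$channels) {
    if (ch == "right" || length(spec$channels) == 1L) {
      traces[[ch]] <- base * sqrt(envelope_for(ch, t))
    } else {
      # left channel: delayed copy of the right-channel waveform
      tt <- t - lag
      base_l <- stats::approx(t, base, xout = tt, rule = 2)$y
      traces[[ch]] <- base_l * sqrt(envelope_for(ch, tt))
    }
  }
  truth <- ev
  attr(truth, "seed") <- spec$seed
  list(record = eeg_record(traces, spec$fs), truth = truth)
}

#' Write / read an EEG record as CSV
#'
#' Columns: `time` (s) then one column per channel (microvolts); the sampling
#' rate is recovered from the time column on read.
#'
#' @param record an [eeg_record()].
#' @param path CSV path.
#' @return `read_eeg_csv()` returns an [eeg_record()].
#' @export
write_eeg_csv <- function(record, path) {
  n <- length(record$traces[[1]])
  df <- c(list(time = (seq_len(n) - 1) / record$fs), record$traces)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  fs <- 1 / stats::median(diff(df$time))
  eeg_record(as.list(df[setdiff(names(df), "time")]), fs = fs)
}
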