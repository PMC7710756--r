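#' Sliding-window total EEG power
#'
#' Band-integrated (0.5-100 Hz) power per sliding window, computed by
#' periodogram integration: each window is FFT'd and one-sided spectral power
#' is summed over the band bins. For a pure sinusoid of amplitude A inside
#' the band the result is A^2/2; scaling the trace by k scales power by k^2
#' exactly.
#'
#' @param trace numeric EEG trace, microvolts.
#' @param fs sampling rate, Hz.
#' @param window_s,step_s sliding-window length and step, s. The defaults
#'   (2 s / 1 s) resolve the 15 s onset criterion of LVA detection.
#' @param band integration band `c(lo, hi)`, Hz.
#' @return A `power_series` tibble: `time` (window centre, s), `power`
#'   (microvolt^2), with window metadata attached as attributes.
#' @export
total_power_series <- function(trace, fs, window_s = 2, step_s = 1,
                               band = c(0.5, 100)) {
  if (window_s < 1) stopf("window must be >= 1 s")
  if (band[2] > fs / 2) stopf("band upper edge above Nyquist")
  n <- length(trace)
  nw <- round(window_s * fs)
  ns <- max(1L, round(step_s * fs))
  if (n < nw) stopf("trace (%.1f s) shorter than the window", n / fs)
  starts <- seq(1L, n - nw + 1L, by = ns)
  f <- (seq_len(nw) - 1) * fs / nw
  bins <- which(f >= band[1] & f <= band[2] & f <= fs / 2)
  out <- numeric(length(starts))
  chunk <- 4096L
  for (i0 in seq(1L, length(starts), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, length(starts))
    idx <- outer(0:(nw - 1L), starts[ii], `+`)
    W <- matrix(trace[idx], nrow = nw)
    X <- stats::mvfft(W)
    ps <- abs(X[bins, , drop = FALSE])^2 * (2 / nw^2)
    half <- f[bins] == 0 | abs(f[bins] - fs / 2) < 1e-9
    if (any(half)) ps[half, ] <- ps[half, ] / 2
    out[ii] <- colSums(ps)
  }
  res <- tibble::tibble(time = (starts - 1) / fs + window_s / 2,
                        power = out)
  attr(res, "window_s") <- window_s
  attr(res, "step_s") <- step_s
  attr(res, "fs") <- fs
  attr(res, "band") <- band
  class(res) <- c("power_series", class(res))
  res
}

# last downward crossing of `level` at or before index `hi`, searching back
# to index `lo`; returns interpolated time or NA
last_down_cross <- function(t, p, lo, hi, level) {
  i <- hi
  while (i > lo) {
    if (p[i - 1L] >= level && p[i] < level)
      return(cross_time(t, p, i - 1L, level))
    i <- i - 1L
  }
  NA_real_
}

#' Detect low-voltage-activity (LVA) events from a power series
#'
#' Implements the quantitative LVA criterion: a >75% reduction in total
#' 0.5-100 Hz power completed within 15 s, lasting under 10 min. The
#' baseline is the median power over the 60 s preceding the candidate (a
#' window ending 15 s before the drop crossing, so the decline itself does
#' not contaminate it). A candidate opens where power falls below
#' `(1 - reduction_threshold) * baseline`; its onset-transition time is
#' estimated as twice the span between the 25%- and 75%-of-depth downward
#' crossings (exact for a linear power decline and insensitive to the
#' analysis window); the event closes when power recovers above
#' `recovery_frac` of baseline. Candidates failing the reduction, transition,
#' or duration bound are discarded. Events separated by less than
#' `merge_gap_s` are merged.
#'
#' @param power a [total_power_series()] result.
#' @param reduction_threshold minimum power-reduction fraction (default 0.75,
#'   strict).
#' @param onset_window_s maximum onset-transition time, s.
#' @param max_duration_s maximum event duration, s (exclusive).
#' @param baseline_window_s baseline estimation window, s.
#' @param recovery_frac fraction of baseline power that closes an event.
#' @param merge_gap_s merge candidates separated by less than this, s.
#' @param channel label stored on the result.
#' @return Tibble of events: `onset`, `offset`, `duration`, `reduction`,
#'   `transition_s`, `baseline_power`, `channel`.
#' @export
detect_lva <- function(power, reduction_threshold = 0.75,
                       onset_window_s = 15, max_duration_s = 600,
                       baseline_window_s = 60, recovery_frac = 0.5,
                       merge_gap_s = 5, channel = "right") {
  t <- power$time; p <- power$power
  dt <- stats::median(diff(t))
  empty <- tibble::tibble(onset = numeric(), offset = numeric(),
                          duration = numeric(), reduction = numeric(),
                          transition_s = numeric(),
                          baseline_power = numeric(), channel = character())
  if (length(t) < 2L || (t[length(t)] - t[1]) < baseline_window_s + 15)
    stopf("record shorter than the baseline window")
  # trailing median baseline over (t - 75, t - 15]
  k1 <- as.integer(round((baseline_window_s + 15) / dt))
  k2 <- as.integer(round(15 / dt))
  nb <- length(p)
  b <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    lo <- i - k1 + 1L; hi <- i - k2
    if (lo < 1L || hi < lo) next
    b[i] <- stats::median(p[lo:hi])
  }
  core <- which(is.finite(b) & p < (1 - reduction_threshold) * b)
  if (!length(core)) return(empty)
  # group cores separated by more than merge_gap_s
  gaps <- which(diff(t[core]) > merge_gap_s + dt / 2)
  grp_start <- c(1L, gaps + 1L)
  grp_end <- c(gaps, length(core))

  rows <- list()
  for (g in seq_along(grp_start)) {
    i1 <- core[grp_start[g]]; i2 <- core[grp_end[g]]
    B <- b[i1]
    # full sub-recovery run around the cores
    lo <- i1; while (lo > 1L && p[lo - 1L] < recovery_frac * B) lo <- lo - 1L
    hi <- i2; while (hi < nb && p[hi + 1L] < recovery_frac * B) hi <- hi + 1L
    floor_p <- min(p[lo:hi])
    depth <- B - floor_p
    reduction <- 1 - floor_p / B
    # onset transition from the 25%/75%-depth downward crossings
    search_lo <- max(1L, i1 - as.integer(ceiling(
      (3 * onset_window_s + 2 * baseline_window_s) / dt)))
    t75 <- last_down_cross(t, p, search_lo, i1, B - 0.75 * depth)
    t25 <- last_down_cross(t, p, search_lo, i1, B - 0.25 * depth)
    transition <- if (is.finite(t25) && is.finite(t75))
      max(0, 2 * (t75 - t25)) else 0
    onset <- if (is.finite(t25)) t25 - 0.25 * transition else t[i1]
    # offset: recovery above recovery_frac * baseline
    offset <- if (hi < nb) cross_time(t, p, hi, recovery_frac * B)
    else t[nb]
    duration <- offset - onset
    if (reduction > reduction_threshold && transition <= onset_window_s &&
        duration < max_duration_s) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        onset = onset, offset = offset, duration = duration,
        reduction = reduction, transition_s = transition,
        baseline_power = B, channel = channel)
    }
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

#' Detect LVA events on every channel of an EEG record
#'
#' Convenience wrapper: computes the sliding total-power series per channel
#' and runs [detect_lva()] on each.
#'
#' @param record an [eeg_record()].
#' @param ... passed to [detect_lva()].
#' @return Tibble of per-channel events.
#' @export
detect_lva_record <- function(record, ...) {
  purrr::imap_dfr(record$traces, function(tr, ch) {
    ps <- total_power_series(tr, record$fs)
    detect_lva(ps, channel = ch, ...)
  })
}

#' Classify LVA laterality by left/right temporal overlap
#'
#' Left- and right-channel events overlapping by at least `overlap_min_s`
#' are merged (transitively) into single bilateral events; the rest stay
#' unilateral.
#'
#' @param events_left,events_right per-channel event tibbles from
#'   [detect_lva()].
#' @param overlap_min_s minimum overlap to call an event bilateral, s.
#' @return Tibble of events with a `laterality` column
#'   (`bilateral` / `unilateral-left` / `unilateral-right`).
#' @export
classify_laterality <- function(events_left, events_right,
                                overlap_min_s = 5) {
  ev <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(events_left), channel = "left"),
    dplyr::mutate(tibble::as_tibble(events_right), channel = "right"))
  n <- nrow(ev)
  if (!n) return(dplyr::mutate(ev, laterality = character(0)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || ev$channel[i] == ev$channel[j]) next
    ov <- interval_overlap(ev$onset[i], ev$offset[i],
                           ev$onset[j], ev$offset[j])
    if (ov >= overlap_min_s) parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  purrr::map_dfr(unique(comp), function(cid) {
    grp <- ev[comp == cid, ]
    chs <- unique(grp$channel)
    tibble::tibble(
      onset = min(grp$onset), offset = max(grp$offset),
      duration = max(grp$offset) - min(grp$onset),
      reduction = max(grp$reduction),
      laterality = if (length(chs) == 2L) "bilateral"
      else paste0("unilateral-", chs))
  }) |> dplyr::arrange(.data$onset)
}

#' Per-subject LVA event rates with group summary
#'
#' @param events tibble of events with a `subject` column.
#' @param hours tibble with `subject` and `hours` monitored (> 0); subjects
#'   with zero events must appear here to contribute 0/h.
#' @return List with `per_subject` (subject, n_events, hours, rate) and
#'   `summary` (mean, sem, n_subjects).
#' @export
event_frequency <- function(events, hours) {
  hrs <- tibble::as_tibble(hours)
  if (any(hrs$hours <= 0)) stopf("monitored hours must be > 0")
  counts <- dplyr::count(tibble::as_tibble(events), .data$subject,
                         name = "n_events")
  per <- dplyr::left_join(hrs, counts, by = "subject") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L),
                  rate = .data$n_events / .data$hours)
  list(per_subject = per,
       summary = tibble::tibble(mean_rate = mean(per$rate),
                                sem_rate = sem(per$rate),
                                n_subjects = nrow(per)))
}
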