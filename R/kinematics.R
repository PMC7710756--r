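#' Position-time plot of a hemisphere-averaged signal
#'
#' Collapses a map sequence into a `position x time` matrix by averaging the
#' signal over all in-mask pixels of the chosen hemisphere at each coordinate
#' along the spread axis. A travelling wave appears as a sloped ridge whose
#' slope (pixels/s) is its propagation speed.
#'
#' @param maps a `hemo_maps` object from [compute_hemo_maps()].
#' @param signal which map to collapse: `"hbt"`, `"calcium"`, `"hbo"`,
#'   `"hbr"`.
#' @param axis spread axis: rows of the plot are `y` (posterior-anterior) or
#'   `x` (medio-lateral) pixel coordinates.
#' @param hemisphere `"left"` (atlas x < 0), `"right"` (x > 0) or `"both"`.
#' @param window optional `c(t0, t1)` time window, s.
#' @return A `position_time_plot`: list with `values` (position x time),
#'   `positions_px`, `positions_mm`, `times`, and geometry metadata.
#' @export
build_position_time_plot <- function(maps, signal = "hbt",
                                     axis = c("y", "x"),
                                     hemisphere = c("right", "left", "both"),
                                     window = NULL) {
  axis <- match.arg(axis)
  hemisphere <- match.arg(hemisphere)
  a <- maps[[signal]] %||% stopf("unknown signal '%s'", signal)
  d <- dim(a)
  times <- (seq_len(d[1]) - 1) * maps$time_step
  if (!is.null(window)) {
    if (window[1] < times[1] - 1e-9 || window[2] > times[d[1]] + 1e-9)
      stopf("window [%.1f, %.1f] outside the record", window[1], window[2])
    sel <- times >= window[1] & times <= window[2]
    a <- a[sel, , , drop = FALSE]
    times <- times[sel]
  }
  hemi_cols <- switch(hemisphere,
                      both = rep(TRUE, d[3]),
                      left = maps$coords$x_mm < 0,
                      right = maps$coords$x_mm > 0)
  hemi_rows <- switch(hemisphere,
                      both = rep(TRUE, d[2]),
                      left = rep(TRUE, d[2]),
                      right = rep(TRUE, d[2]))
  a <- a[, , hemi_cols, drop = FALSE]
  if (!any(is.finite(a)))
    stopf("hemisphere '%s' contains no valid pixels", hemisphere)
  fin <- is.finite(a)
  af <- a; af[!fin] <- 0
  if (axis == "y") {
    # average over x within the hemisphere for each y row
    s <- rowSums(af, dims = 2)          # time x y
    n <- rowSums(fin, dims = 2)
    vals <- t(s / ifelse(n > 0, n, NA)) # position x time
    pos_px <- seq_len(d[2]) - 1
    pos_mm <- maps$coords$y_mm
  } else {
    s <- apply(af, c(1, 3), sum)        # time x x
    n <- apply(fin, c(1, 3), sum)
    vals <- t(s / ifelse(n > 0, n, NA))
    pos_px <- (seq_len(d[3]) - 1)[hemi_cols]
    pos_mm <- maps$coords$x_mm[hemi_cols]
  }
  structure(list(values = vals, positions_px = pos_px, positions_mm = pos_mm,
                 times = times, axis = axis, hemisphere = hemisphere,
                 pixel_pitch = maps$pixel_pitch,
                 time_step = maps$time_step, signal = signal),
            class = "position_time_plot")
}

#' @export
print.position_time_plot <- function(x, ...) {
  cat(sprintf("<position_time_plot> %s | axis %s | hemisphere %s | %d pos x %d t\n",
              x$signal, x$axis, x$hemisphere, nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' @export
as_tibble.position_time_plot <- function(x, ...) {
  tidyr::expand_grid(position_px = x$positions_px, time = x$times) |>
    dplyr::mutate(value = as.vector(t(x$values))) |>
    dplyr::arrange(.data$time, .data$position_px)
}

#' Extract the wavefront ridge from a position-time plot
#'
#' For each time column inside the transit window, locates the sub-pixel
#' position of the signal maximum above the per-row temporal baseline
#' (median over time). Columns whose peak prominence falls below
#' `min_prominence`, or whose peak sits within `edge_margin` rows of the plot
#' border (front outside the field), are excluded; the transit window is the
#' longest contiguous run of qualifying columns. Ties go to the earliest
#' position; sub-pixel refinement is quadratic three-point interpolation.
#'
#' @param plot a [build_position_time_plot()] result.
#' @param min_prominence minimum peak height above the row baseline; default
#'   `max(6 * mad, 0.2 * max)` of the baseline-subtracted plot.
#' @param edge_margin rows near the border within which peaks are discarded.
#' @return Tibble of ridge points: `time`, `position_px`, `position_mm`,
#'   `value`.
#' @export
extract_ridge <- function(plot, min_prominence = NULL, edge_margin = 2L) {
  v <- plot$values
  base <- apply(v, 1, function(r) stats::median(r[is.finite(r)]))
  rel <- v - base
  finite_rel <- rel[is.finite(rel)]
  if (!length(finite_rel)) stopf("no transient: empty plot")
  # second pass: per-row *linear* temporal baseline fitted to off-transient
  # columns; removes the slowly varying residual that per-pixel detrending
  # leaves under a transient occupying much of the record. The transient
  # block (contiguous region around the row maximum, including truncated
  # tails at the record edges) is excluded from the baseline fit.
  peak0 <- max(finite_rel)
  if (is.finite(peak0) && peak0 > 0 && ncol(v) >= 12) {
    tt <- plot$times
    nt <- ncol(v)
    for (i in seq_len(nrow(v))) {
      row <- v[i, ]
      reli <- rel[i, ]
      if (!any(is.finite(reli))) next
      rp <- max(reli, na.rm = TRUE)
      if (!is.finite(rp) || rp <= 0) next
      im <- which.max(reli)
      inblock <- rep(FALSE, nt)
      j <- im
      while (j >= 1 && is.finite(reli[j]) && reli[j] > 0.05 * rp) {
        inblock[j] <- TRUE; j <- j - 1L
      }
      j <- im
      while (j <= nt && is.finite(reli[j]) && reli[j] > 0.05 * rp) {
        inblock[j] <- TRUE; j <- j + 1L
      }
      off <- is.finite(row) & !inblock & (reli < 0.25 * rp)
      # fit only when the baseline support brackets the transient; a line
      # extrapolated from one side alone can manufacture fake peaks
      n_before <- sum(off & seq_len(nt) < im)
      n_after <- sum(off & seq_len(nt) > im)
      if (n_before >= 3 && n_after >= 3 && stats::sd(tt[off]) > 0) {
        cf <- stats::coef(stats::lm(row[off] ~ tt[off]))
        rel[i, ] <- row - (cf[1] + cf[2] * tt)
      }
    }
    finite_rel <- rel[is.finite(rel)]
  }
  if (is.null(min_prominence)) {
    # noise floor from temporal first differences (the transient is slow),
    # plus a fraction of the plot's dynamic range
    dv <- diff(t(v))
    sigma <- stats::mad(dv[is.finite(dv)]) / sqrt(2)
    min_prominence <- max(6 * sigma, 0.5 * max(finite_rel))
  }
  np <- nrow(rel); nt <- ncol(rel)
  peak_pos <- rep(NA_real_, nt); peak_val <- rep(NA_real_, nt)
  ok <- logical(nt)
  for (j in seq_len(nt)) {
    col <- rel[, j]
    if (!any(is.finite(col))) next
    pk <- max(col, na.rm = TRUE)
    if (!is.finite(pk) || pk < min_prominence) next
    i <- which(col == pk)[1L]           # tie-break: earliest position
    if (i <= edge_margin || i > np - edge_margin) next
    off <- if (i > 1L && i < np && is.finite(col[i - 1L]) &&
               is.finite(col[i + 1L])) {
      tri <- col[(i - 1L):(i + 1L)]
      # log-domain parabola is exact for a Gaussian transient profile
      if (all(tri > 0)) tri <- log(tri)
      quad_peak_offset(tri[1], tri[2], tri[3])
    } else 0
    peak_pos[j] <- plot$positions_px[i] +
      off * (plot$positions_px[min(i + 1L, np)] -
               plot$positions_px[max(i - 1L, 1L)]) / 2
    peak_val[j] <- pk
    ok[j] <- TRUE
  }
  if (sum(ok) < 3L) stopf("no transient exceeds the prominence threshold")
  # transit window: longest contiguous run of qualifying columns
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  sel <- (ends[best] - r$lengths[best] + 1L):ends[best]
  if (length(sel) < 3L) stopf("no transient exceeds the prominence threshold")
  step_mm <- stats::median(abs(diff(plot$positions_mm)))
  tibble::tibble(
    time = plot$times[sel],
    position_px = peak_pos[sel],
    position_mm = stats::approx(plot$positions_px, plot$positions_mm,
                                xout = peak_pos[sel], rule = 2)$y,
    value = peak_val[sel])
}

#' Fit a propagation speed to ridge points
#'
#' Ordinary least-squares regression of ridge position (pixels) on time (s);
#' the speed is `|slope| * 60 / pixels_per_mm` in mm/min (the measured
#' calibration of the emulated setup is 11 pixels/mm). Direction (slope sign)
#' is retained separately; speeds are reported as magnitudes.
#'
#' @param ridge tibble from [extract_ridge()] (>= 3 points).
#' @param pixels_per_mm spatial calibration.
#' @return A `ridge_fit` object; see [tidy()] / [glance()] methods.
#' @export
fit_speed <- function(ridge, pixels_per_mm = 11) {
  if (nrow(ridge) < 3L) stopf("need >= 3 ridge points")
  if (stats::sd(ridge$time) == 0) stopf("ridge has zero time variance")
  fit <- stats::lm(position_px ~ time, data = ridge)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ss_tot <- sum((ridge$position_px - mean(ridge$position_px))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  structure(list(points = ridge, slope_px_per_s = slope,
                 intercept_px = intercept, r_squared = r2,
                 direction = sign(slope),
                 speed_mm_min = abs(slope) * 60 / pixels_per_mm,
                 pixels_per_mm = pixels_per_mm, n_points = nrow(ridge)),
            class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("<ridge_fit> %.3f mm/min (slope %.4f px/s, r2 %.4f, n %d)\n",
              x$speed_mm_min, x$slope_px_per_s, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
tidy.ridge_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept_px", "slope_px_per_s"),
                 estimate = c(x$intercept_px, x$slope_px_per_s))
}

#' @export
glance.ridge_fit <- function(x, ...) {
  tibble::tibble(speed_mm_min = x$speed_mm_min, r_squared = x$r_squared,
                 n_points = x$n_points, direction = x$direction)
}

#' EEG propagation speed from inter-electrode cross-correlation lag
#'
#' Finds the lag maximizing the normalized cross-correlation between the two
#' electrode traces (sub-sample refinement by quadratic interpolation of the
#' correlation peak) and divides the electrode separation by the lag.
#'
#' @param trace_a,trace_b equal-length traces at equal sampling rate.
#' @param fs sampling rate, Hz.
#' @param separation_mm distance between the electrodes, mm (> 0).
#' @param max_lag_s optional search bound, s.
#' @return One-row tibble: `speed_mm_min`, `lag_s`, `peak_correlation`.
#' @export
eeg_speed <- function(trace_a, trace_b, fs, separation_mm,
                      max_lag_s = NULL) {
  if (length(trace_a) != length(trace_b))
    stopf("traces must have equal length")
  if (!is_scalar_num(separation_mm) || separation_mm <= 0)
    stopf("electrode separation must be > 0")
  n <- length(trace_a)
  a <- trace_a - mean(trace_a); b <- trace_b - mean(trace_b)
  nfft <- stats::nextn(2L * n, 2L)
  A <- fft(c(a, rep(0, nfft - n)))
  B <- fft(c(b, rep(0, nfft - n)))
  cc <- Re(fft(A * Conj(B), inverse = TRUE)) / nfft
  # lags: 0..(n-1) at head, -(n-1)..-1 at tail of the circular correlation
  lags <- c(0:(n - 1L), -(nfft - n):-1L)
  keep <- abs(lags) <= (n - 1L)
  if (!is.null(max_lag_s)) keep <- keep & abs(lags) <= max_lag_s * fs
  cc <- cc[keep]; lags <- lags[keep]
  norm <- sqrt(sum(a^2) * sum(b^2))
  if (norm == 0) stopf("constant trace: correlation undefined")
  cc <- cc / norm
  i <- which.max(cc)
  best_lag <- lags[i]
  if (cc[i] <= 0)
    warning("traces are only anticorrelated; returning the best lag anyway")
  # quadratic sub-sample refinement around the integer-lag peak
  im <- which(lags == best_lag - 1L); ip <- which(lags == best_lag + 1L)
  off <- if (length(im) && length(ip))
    quad_peak_offset(cc[im], cc[i], cc[ip]) else 0
  # sign convention: positive lag means trace_b lags trace_a
  lag_s <- -(best_lag + off) / fs
  if (abs(lag_s) < 1 / fs)
    stopf("unresolvable lag: |lag| below one sample")
  tibble::tibble(speed_mm_min = separation_mm / (abs(lag_s) / 60),
                 lag_s = lag_s, peak_correlation = cc[i])
}

#' Summarize one CSD event across modalities
#'
#' Collects per-modality ridge fits (total hemoglobin and/or corrected
#' calcium) into a flat one-row event record suitable for per-event and
#' per-mouse aggregation and CSV round-tripping.
#'
#' @param fits named list of [fit_speed()] results; names from
#'   `c("hbt", "calcium")`, at least one present.
#' @param hemisphere,axes qualitative spread annotation.
#' @param event_id identifier.
#' @param onset event onset time, s.
#' @return One-row tibble (CSDEvent record).
#' @export
summarize_event <- function(fits, hemisphere = "right", axes = "y",
                            event_id = 1L, onset = NA_real_) {
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stopf("need at least one modality fit")
  get <- function(mod, field)
    if (!is.null(fits[[mod]])) fits[[mod]][[field]] else NA_real_
  tibble::tibble(
    event_id = event_id, hemisphere = hemisphere, axes = axes,
    onset_s = onset,
    speed_hbt_mm_min = get("hbt", "speed_mm_min"),
    r2_hbt = get("hbt", "r_squared"),
    n_hbt = get("hbt", "n_points"),
    speed_calcium_mm_min = get("calcium", "speed_mm_min"),
    r2_calcium = get("calcium", "r_squared"),
    n_calcium = get("calcium", "n_points"))
}
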