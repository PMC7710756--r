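#' @keywords internal
behavior_labels <- c("sleeping", "eating", "normal ambulation",
                     "abnormal ambulation", "abnormal stationary posture",
                     "paralysis")
abnormal_labels <- c("abnormal ambulation", "abnormal stationary posture",
                     "paralysis")
# severity order used to break dominant-label ties (most severe first)
severity_order <- c("paralysis", "abnormal stationary posture",
                    "abnormal ambulation", "sleeping", "eating",
                    "normal ambulation")

#' Behavior track
#'
#' An interval-labelled behavior stream: a tibble of `start`, `end`, `label`
#' covering `[0, duration)` with labels from the six scored categories
#' (sleeping, eating, normal ambulation, abnormal ambulation = ataxic gait,
#' abnormal stationary posture, paralysis).
#'
#' @param intervals tibble/data frame with `start`, `end`, `label`.
#' @param duration record length, s.
#' @return A `behavior_track` tibble with a `duration` attribute.
#' @export
behavior_track <- function(intervals, duration) {
  x <- tibble::as_tibble(intervals)
  if (!all(c("start", "end", "label") %in% names(x)))
    stopf("intervals need columns start, end, label")
  if (!is_scalar_num(duration) || duration <= 0)
    stopf("duration must be > 0")
  if (nrow(x)) {
    if (any(!x$label %in% behavior_labels))
      stopf("unknown behavior label: %s",
            paste(setdiff(x$label, behavior_labels), collapse = ", "))
    if (any(x$end <= x$start)) stopf("intervals must have end > start")
    if (any(x$start < 0) || any(x$end > duration + 1e-9))
      stopf("intervals must lie within [0, duration)")
    x <- x[order(x$start), ]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)] - 1e-9))
      stopf("behavior intervals must not overlap")
  }
  structure(x, duration = duration,
            class = c("behavior_track", class(tibble::tibble())))
}

#' Generate a behavior track with known bouts
#'
#' Fills the gaps between the supplied bouts with `"normal ambulation"` so the
#' track covers `[0, duration)` completely.
#'
#' @param duration record length, s.
#' @param bouts tibble with `onset`, `offset`, `label` (may be empty).
#' @param seed recorded for provenance (the construction is deterministic).
#' @return A [behavior_track()].
#' @export
generate_behavior <- function(duration, bouts = NULL, seed = 1L) {
  if (is.null(bouts) || !nrow(tibble::as_tibble(bouts))) {
    tr <- tibble::tibble(start = 0, end = duration,
                         label = "normal ambulation")
    return(behavior_track(tr, duration))
  }
  b <- tibble::as_tibble(bouts)[order(tibble::as_tibble(bouts)$onset), ]
  if (any(!b$label %in% behavior_labels))
    stopf("unknown behavior label: %s",
          paste(setdiff(b$label, behavior_labels), collapse = ", "))
  if (nrow(b) > 1 && any(b$onset[-1] < b$offset[-nrow(b)]))
    stopf("bouts must not overlap")
  segs <- list(); cur <- 0
  for (i in seq_len(nrow(b))) {
    if (b$onset[i] > cur)
      segs[[length(segs) + 1L]] <-
        tibble::tibble(start = cur, end = b$onset[i],
                       label = "normal ambulation")
    segs[[length(segs) + 1L]] <-
      tibble::tibble(start = b$onset[i], end = b$offset[i],
                     label = b$label[i])
    cur <- b$offset[i]
  }
  if (cur < duration)
    segs[[length(segs) + 1L]] <-
      tibble::tibble(start = cur, end = duration,
                     label = "normal ambulation")
  tr <- dplyr::bind_rows(segs)
  out <- behavior_track(tr, duration)
  attr(out, "seed") <- seed
  out
}

#' Write / read behavior tracks as CSV
#'
#' @param track a [behavior_track()].
#' @param path CSV path with columns `start,end,label`.
#' @return `read_behavior_csv()` returns a [behavior_track()].
#' @export
write_behavior_csv <- function(track, path) {
  readr::write_csv(tibble::as_tibble(track), path)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @param duration record length, s; defaults to the last interval end.
#' @export
read_behavior_csv <- function(path, duration = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  behavior_track(x, duration %||% max(x$end))
}

#' Score paralysis bouts
#'
#' A paralysis bout is a maximal run of paralysis-labelled time lasting at
#' least `min_bout_s` (60 s by default: the animal must fail to right itself
#' within 60 s for the posture to count as paralysis). Shorter
#' paralysis-labelled intervals are not bouts and contribute no paralysis
#' time. Percent time paralyzed is total bout time over record duration.
#'
#' @param track a [behavior_track()].
#' @param min_bout_s righting-time criterion, s.
#' @return One-row tibble: `n_bouts`, `total_paralysis_s`, `percent_time`.
#' @export
score_paralysis <- function(track, min_bout_s = 60) {
  duration <- attr(track, "duration")
  if (is.null(duration) || duration <= 0)
    stopf("track has zero duration")
  p <- tibble::as_tibble(track)
  p <- p[p$label == "paralysis", , drop = FALSE]
  if (!nrow(p))
    return(tibble::tibble(n_bouts = 0L, total_paralysis_s = 0,
                          percent_time = 0))
  p <- p[order(p$start), ]
  # merge abutting/overlapping paralysis intervals into maximal runs
  starts <- p$start[1]; ends <- p$end[1]
  for (i in seq_len(nrow(p))[-1]) {
    if (p$start[i] <= ends[length(ends)] + 1e-9) {
      ends[length(ends)] <- max(ends[length(ends)], p$end[i])
    } else {
      starts <- c(starts, p$start[i]); ends <- c(ends, p$end[i])
    }
  }
  len <- ends - starts
  keep <- len >= min_bout_s
  tibble::tibble(n_bouts = sum(keep),
                 total_paralysis_s = sum(len[keep]),
                 percent_time = 100 * sum(len[keep]) / duration)
}

# overlap of [a0,a1) with [b0,b1)
interval_overlap <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}

# dominant behavior label during [t0, t1): largest time share, ties broken
# toward the more severe label
dominant_label <- function(track, t0, t1) {
  x <- tibble::as_tibble(track)
  ov <- interval_overlap(x$start, x$end, t0, t1)
  if (sum(ov) <= 0) stopf("event [%.1f, %.1f) lies outside the track", t0, t1)
  share <- tapply(ov, x$label, sum)
  share <- share[share > 0]
  best <- names(share)[share == max(share)]
  if (length(best) > 1)
    best <- best[order(match(best, severity_order))][1]
  best
}

#' Cross-tabulate behavior during LVA events against matched controls
#'
#' For each EEG event the dominant behavior label during `[onset, offset)` is
#' recorded; one control epoch of the same length is sampled uniformly (seeded)
#' from event-free time in the same record. Labels are collapsed to
#' normal (sleeping, eating, normal ambulation) vs abnormal (ataxic gait,
#' abnormal posture, paralysis) and tabulated as a 2x2 contingency table with
#' rows `normal EEG` (controls) and `LVA` (events).
#'
#' @param track a [behavior_track()].
#' @param events tibble with `onset`, `offset` (s).
#' @param seed seed for the control-epoch sampler.
#' @return A list of class `behavior_contingency`: `table` (2x2 integer
#'   matrix), `assignments` (per-epoch tibble).
#' @export
behavior_at_events <- function(track, events, seed = 1L) {
  duration <- attr(track, "duration")
  ev <- tibble::as_tibble(events)
  if (!nrow(ev)) stopf("no events supplied")
  if (any(ev$onset < 0) || any(ev$offset > duration + 1e-9))
    stopf("event outside the behavior record")
  # event-free gaps
  evs <- ev[order(ev$onset), ]
  gaps <- tibble::tibble(start = c(0, evs$offset),
                         end = c(evs$onset, duration))
  gaps <- gaps[gaps$end - gaps$start > 0, ]
  rows <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(ev)), function(i) {
      len <- ev$offset[i] - ev$onset[i]
      lab_ev <- dominant_label(track, ev$onset[i], ev$offset[i])
      # sample a control start uniformly over all feasible positions
      room <- pmax(0, (gaps$end - gaps$start) - len)
      if (sum(room) <= 0)
        stopf("no event-free epoch long enough for a matched control")
      u <- runif(1, 0, sum(room))
      g <- which(cumsum(room) >= u)[1]
      start <- gaps$start[g] + (u - c(0, cumsum(room))[g])
      lab_ct <- dominant_label(track, start, start + len)
      tibble::tibble(event = i,
                     event_label = lab_ev, control_label = lab_ct,
                     control_start = start, length = len)
    })
  })
  collapse <- function(l) ifelse(l %in% abnormal_labels, "abnormal", "normal")
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("normal EEG", "LVA"),
                                c("normal", "abnormal")))
  tc <- table(factor(collapse(rows$control_label),
                     levels = c("normal", "abnormal")))
  te <- table(factor(collapse(rows$event_label),
                     levels = c("normal", "abnormal")))
  tab["normal EEG", ] <- as.integer(tc)
  tab["LVA", ] <- as.integer(te)
  structure(list(table = tab, assignments = rows, seed = seed),
            class = "behavior_contingency")
}

#' @export
print.behavior_contingency <- function(x, ...) {
  cat("<behavior_contingency>\n")
  print(x$table)
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' Plain Pearson test without continuity correction,
#' `df = (rows - 1)(cols - 1)`; errors if any expected count is zero.
#'
#' @param table integer matrix or a [behavior_at_events()] result.
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
chi_squared <- function(table) {
  if (inherits(table, "behavior_contingency")) table <- table$table
  tab <- as.matrix(table)
  if (any(tab < 0)) stopf("counts must be non-negative")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stopf("zero expected count in contingency table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Compare per-subject event rates between two groups
#'
#' Two-sample two-tailed t test on per-subject rates; pooled variance by
#' default, Welch by flag. Group means and standard errors are reported
#' alongside.
#'
#' @param rates_a,rates_b numeric vectors of per-subject rates (events/h).
#' @param welch use the Welch (unequal-variance) test.
#' @return One-row tibble with `t`, `df`, `p_value`, group means and sems.
#' @export
compare_event_rates <- function(rates_a, rates_b, welch = FALSE) {
  if (length(rates_a) < 2 || length(rates_b) < 2)
    stopf("need at least two subjects per group")
  if (stats::sd(rates_a) == 0 && stats::sd(rates_b) == 0) {
    # both groups constant: t.test would refuse; the comparison is exact
    equal <- isTRUE(all.equal(mean(rates_a), mean(rates_b)))
    return(tibble::tibble(
      t = if (equal) 0 else sign(mean(rates_a) - mean(rates_b)) * Inf,
      df = length(rates_a) + length(rates_b) - 2,
      p_value = if (equal) 1 else 0,
      mean_a = mean(rates_a), sem_a = sem(rates_a),
      mean_b = mean(rates_b), sem_b = sem(rates_b)))
  }
  ht <- stats::t.test(rates_a, rates_b, var.equal = !welch)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 mean_a = mean(rates_a), sem_a = sem(rates_a),
                 mean_b = mean(rates_b), sem_b = sem(rates_b))
}
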