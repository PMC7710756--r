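test_that("paralysis scoring applies the 60 s righting criterion", {
  bouts <- tibble::tibble(onset = c(3600, 10800), offset = c(4500, 11700),
                          label = "paralysis")
  tr <- generate_behavior(4 * 3600, bouts)
  got <- score_paralysis(tr)
  expect_equal(got$n_bouts, 2L)
  expect_equal(got$percent_time, 12.5)

  short <- generate_behavior(3600, tibble::tibble(
    onset = 100, offset = 145, label = "paralysis"))
  got2 <- score_paralysis(short)
  expect_equal(got2$n_bouts, 0L)
  expect_equal(got2$percent_time, 0)

  empty <- generate_behavior(3600, NULL)
  got3 <- score_paralysis(empty)
  expect_equal(got3$n_bouts, 0L)
})

test_that("scoring is invariant to splitting intervals at arbitrary points", {
  set.seed(21)
  for (rep in 1:5) {
    onset <- sort(runif(3, 0, 3000))
    bouts <- tibble::tibble(onset = onset,
                            offset = onset + runif(3, 30, 400))
    bouts <- bouts[c(TRUE, diff(bouts$onset) > 500), ]
    bouts$label <- "paralysis"
    tr <- generate_behavior(3600, bouts)
    base <- score_paralysis(tr)
    # split every interval into abutting halves with the same label
    x <- tibble::as_tibble(tr)
    split_rows <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
      mid <- (x$start[i] + x$end[i]) / 2
      tibble::tibble(start = c(x$start[i], mid), end = c(mid, x$end[i]),
                     label = x$label[i])
    })
    tr2 <- behavior_track(split_rows, attr(tr, "duration"))
    expect_equal(score_paralysis(tr2), base)
  }
})

test_that("dominant event labels match a per-second majority oracle", {
  set.seed(5)
  for (rep in 1:5) {
    labs <- sample(csdwave:::behavior_labels, 6, replace = TRUE)
    edges <- c(0, sort(runif(5, 10, 590)), 600)
    tr <- behavior_track(tibble::tibble(
      start = edges[-7], end = edges[-1], label = labs), 600)
    t0 <- runif(1, 0, 500); t1 <- t0 + runif(1, 20, 90)
    got <- csdwave:::dominant_label(tr, t0, t1)
    want <- oracle_dominant(tibble::as_tibble(tr), t0, t1)
    # ties may legitimately differ; only compare when the majority is clear
    x <- tibble::as_tibble(tr)
    ov <- tapply(csdwave:::interval_overlap(x$start, x$end, t0, t1),
                 x$label, sum)
    ov <- sort(ov[ov > 0], decreasing = TRUE)
    if (length(ov) == 1 || ov[1] > ov[2] + 1) expect_equal(got, want)
  }
})

test_that("behavior/EEG contingency tables are built as designed", {
  # events cover paralysis; event-free time is sleeping
  tr <- behavior_track(tibble::tibble(
    start = c(0, 2000), end = c(2000, 4000),
    label = c("sleeping", "paralysis")), 4000)
  ev <- tibble::tibble(onset = seq(2000, 3800, by = 200),
                       offset = seq(2100, 3900, by = 200))
  ct <- behavior_at_events(tr, ev, seed = 4)
  n <- nrow(ev)
  expect_equal(unname(ct$table["LVA", "abnormal"]), n)
  expect_equal(unname(ct$table["normal EEG", "normal"]), n)
  expect_equal(sum(ct$table), 2 * n)

  # determinism under the seed
  ct2 <- behavior_at_events(tr, ev, seed = 4)
  expect_equal(ct$assignments$control_start, ct2$assignments$control_start)
  ct3 <- behavior_at_events(tr, ev, seed = 5)
  expect_false(isTRUE(all.equal(ct$assignments$control_start,
                                ct3$assignments$control_start)))

  expect_error(behavior_at_events(tr, tibble::tibble(onset = 3900,
                                                     offset = 4500),
                                  seed = 1), "outside")
})

test_that("chi-squared matches the closed-form Pearson oracle", {
  even <- matrix(c(10, 10, 10, 10), 2, 2)
  got <- chi_squared(even)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)

  diag40 <- matrix(c(20, 0, 0, 20), 2, 2)
  got2 <- chi_squared(diag40)
  expect_equal(got2$statistic, 40)
  expect_equal(got2$df, 1)

  set.seed(9)
  for (i in 1:25) {
    tab <- matrix(sample(1:40, 4, TRUE), 2, 2)
    got <- chi_squared(tab)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - e)^2 / e)
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$p_value, stats::pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # proportional rows give statistic 0
  prop <- matrix(c(6, 12, 9, 18), 2, 2)
  expect_equal(chi_squared(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_squared(matrix(c(0, 0, 5, 5), 2, 2)), "expected")
})

test_that("rate comparisons match the closed-form pooled t oracle", {
  same <- compare_event_rates(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  const <- compare_event_rates(c(0.1, 0.1, 0.1), c(0.1, 0.1, 0.1))
  expect_equal(const$t, 0)
  expect_equal(const$p_value, 1)

  set.seed(10)
  for (i in 1:25) {
    a <- rnorm(5); b <- rnorm(4, 0.4)
    got <- compare_event_rates(a, b)
    sp2 <- (4 * var(a) + 3 * var(b)) / 7
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 4))
    expect_equal(got$t, tt, tolerance = 1e-12)
    expect_equal(got$p_value, 2 * stats::pt(-abs(tt), 7), tolerance = 1e-12)
    welch <- compare_event_rates(a, b, welch = TRUE)
    expect_equal(welch$t, unname(stats::t.test(a, b)$statistic))
  }
  expect_error(compare_event_rates(1, c(1, 2)), "two subjects")
})

test_that("contingency totals are conserved when collapsing labels", {
  set.seed(3)
  labs <- sample(csdwave:::behavior_labels, 8, TRUE)
  edges <- c(0, sort(runif(7, 100, 7000)), 7200)
  tr <- behavior_track(tibble::tibble(start = edges[-9], end = edges[-1],
                                      label = labs), 7200)
  ev <- tibble::tibble(onset = c(500, 2500, 5000),
                       offset = c(560, 2590, 5100))
  ct <- behavior_at_events(tr, ev, seed = 8)
  expect_equal(sum(ct$table), 2 * nrow(ev))
  expect_true(all(rowSums(ct$table) == nrow(ev)))
})
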