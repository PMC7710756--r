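# construct a position_time_plot directly (bypassing the imaging chain)
fake_pt <- function(values, pitch = 1 / 11, dt = 1) {
  np <- nrow(values)
  structure(list(values = values, positions_px = 0:(np - 1),
                 positions_mm = (0:(np - 1)) * pitch,
                 times = (seq_len(ncol(values)) - 1) * dt,
                 axis = "y", hemisphere = "right",
                 pixel_pitch = pitch, time_step = dt, signal = "hbt"),
            class = "position_time_plot")
}

test_that("position-time plots average the hemisphere correctly", {
  scene <- tiny_scene(duration = 50)
  w <- wave_spec(speed = 6, origin = c(0, -1), hemisphere = "bilateral",
                 onset = 5)
  sim <- generate_wave_stack(scene, list(w))
  pre <- preprocess_stack(sim$stack)
  maps <- compute_hemo_maps(pre, gsr = FALSE)
  pt <- build_position_time_plot(maps, "hbt", "y", "right")
  # oracle: mean over the x > 0 columns at one row/time
  a <- maps$hbt
  xs <- maps$coords$x_mm > 0
  expect_equal(pt$values[10, 20], mean(a[20, 10, xs], na.rm = TRUE),
               tolerance = 1e-12)
  expect_equal(nrow(pt$values), 32)

  # a spatially uniform transient has identical rows
  u <- maps
  arr <- array(rep(sin((1:dim(a)[1]) / 3), prod(dim(a)[2:3])), dim(a))
  u$hbt <- arr
  ptu <- build_position_time_plot(u, "hbt", "y", "right")
  expect_lt(max(abs(sweep(ptu$values, 2, ptu$values[1, ]))), 1e-12)
})

test_that("a flat plot raises the documented no-transient error", {
  flat <- fake_pt(matrix(0, 20, 30))
  expect_error(extract_ridge(flat), "no transient")
  set.seed(2)
  noise <- fake_pt(matrix(rnorm(20 * 40, 0, 0.5), 20, 40))
  expect_error(extract_ridge(noise, min_prominence = 10), "no transient")
})

test_that("ridge positions on a synthetic Gaussian ridge are sub-pixel accurate", {
  np <- 41; nt <- 25
  true_pos <- 6 + 0.9 * (0:(nt - 1))
  v <- matrix(0, np, nt)
  for (j in seq_len(nt))
    v[, j] <- 3 * exp(-((0:(np - 1)) - true_pos[j])^2 / (2 * 2.5^2))
  ridge <- extract_ridge(fake_pt(v), min_prominence = 1)
  keep <- true_pos > 3 & true_pos < np - 4
  got <- ridge$position_px[match(ridge$time, 0:(nt - 1))]
  expect_true(all(abs(ridge$position_px -
                        true_pos[ridge$time + 1]) < 0.25))
  expect_gte(nrow(ridge), 3)
})

test_that("equal maxima resolve to the earliest position", {
  v <- matrix(0, 20, 8)
  v[5, 3:6] <- 2; v[12, 3:6] <- 2     # two equal transient ridges
  ridge <- extract_ridge(fake_pt(v), min_prominence = 1, edge_margin = 1)
  expect_true(all(ridge$position_px == 4))   # 0-based row 5 -> 4
})

test_that("speed fitting converts slope to mm/min with the 11 px/mm rule", {
  pts <- tibble::tibble(time = seq(0, 60, by = 5),
                        position_px = seq(0, 11, length.out = 13),
                        position_mm = NA, value = 1)
  fit <- fit_speed(pts, pixels_per_mm = 11)
  expect_equal(fit$speed_mm_min, 1.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(4)
  rnd <- tibble::tibble(time = 1:20,
                        position_px = 3 + 0.4 * (1:20) + rnorm(20, 0, 0.3),
                        position_mm = NA, value = 1)
  fit2 <- fit_speed(rnd, pixels_per_mm = 11)
  oracle <- oracle_ols(rnd$time, rnd$position_px)
  expect_equal(fit2$slope_px_per_s, oracle$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept_px, oracle$intercept, tolerance = 1e-12)
  expect_equal(fit2$r_squared, oracle$r2, tolerance = 1e-12)
  expect_equal(fit2$speed_mm_min, abs(oracle$slope) * 60 / 11,
               tolerance = 1e-12)

  expect_error(fit_speed(pts[1:2, ]), "3 ridge points")
  same_t <- tibble::tibble(time = rep(1, 5), position_px = 1:5,
                           position_mm = NA, value = 1)
  expect_error(fit_speed(same_t), "time variance")

  td <- tidy(fit2); gl <- glance(fit2)
  expect_equal(td$estimate[2], oracle$slope)
  expect_equal(gl$speed_mm_min, fit2$speed_mm_min)
})

test_that("EEG speed recovers known lags and flags degenerate cases", {
  set.seed(6)
  n <- 5000; fs <- 50
  base <- as.vector(stats::filter(rnorm(n + 3000), rep(1, 25) / 25,
                                  sides = 1))
  base <- base[!is.na(base)]
  a <- base[2001:(2000 + n)]
  b <- base[501:(500 + n)]                 # b leads a by 1500 samples (30 s)
  res <- eeg_speed(a, b, fs = fs, separation_mm = 2)
  expect_equal(abs(res$lag_s), 30, tolerance = 0.2)
  expect_equal(res$speed_mm_min, 2 / (30 / 60), tolerance = 0.05)

  expect_error(eeg_speed(a, a, fs = fs, separation_mm = 2),
               "unresolvable lag")

  # brute-force exhaustive-shift oracle on a short noisy pair
  set.seed(7)
  x <- as.vector(stats::filter(rnorm(700), rep(1, 9) / 9, sides = 1))
  x[is.na(x)] <- 0
  y <- c(rep(0, 37), x)[1:700] + rnorm(700, 0, 0.05)
  got <- eeg_speed(x, y, fs = 10, separation_mm = 1, max_lag_s = 30)
  oracle <- oracle_best_lag(x, y, 300)
  expect_equal(round(got$lag_s * 10), oracle, tolerance = 1.01)
})

test_that("event summaries hold per-modality speeds and round-trip CSV", {
  pts <- tibble::tibble(time = 0:10, position_px = 2 * (0:10),
                        position_mm = NA, value = 1)
  fit <- fit_speed(pts, 11)
  ev <- summarize_event(list(hbt = fit), hemisphere = "left", axes = "y",
                        event_id = 3L, onset = 12)
  expect_true(is.na(ev$speed_calcium_mm_min))
  expect_equal(ev$speed_hbt_mm_min, fit$speed_mm_min)

  path <- tempfile(fileext = ".csv")
  readr::write_csv(ev, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$speed_hbt_mm_min, ev$speed_hbt_mm_min)
  expect_equal(back$hemisphere, ev$hemisphere)

  expect_error(summarize_event(list()), "at least one")
})

test_that("both modalities agree on one simulated wave", {
  run <- simulate_speed_run(5, seed = 17, ny = 96, nx = 96, duration = 100)
  s1 <- run$fits$hbt$speed_mm_min
  s2 <- run$fits$calcium$speed_mm_min
  expect_lt(abs(s1 - s2) / s1, 0.10)
})
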