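test_that("a waveless noiseless scene is constant at baseline", {
  scene <- scene_config(nx = 8, ny = 8, frame_rate = 2, duration = 10,
                        noise_sigma = rep(0, 4), drift_amplitude = 0,
                        seed = 1)
  sim <- generate_wave_stack(scene, list())
  for (i in 1:4) {
    ch <- stack_channel(sim$stack, scene$channels[i])
    expect_equal(max(abs(ch - scene$baseline_counts[i])), 0)
  }
})

test_that("the generated front position matches the analytic argmax oracle", {
  scene <- tiny_scene(nx = 48, ny = 48, duration = 60)
  scene$drift_amplitude <- 0
  w <- wave_spec(speed = 4, origin = c(0, -1.8), direction = c(0, 1),
                 hemisphere = "bilateral", onset = 5)
  sim <- generate_wave_stack(scene, list(w))
  coords <- sim$stack$coords
  times <- (seq_len(dim(sim$stack$data)[1]) - 1) / scene$frame_rate
  r523 <- stack_channel(sim$stack, 523)
  checked <- 0L
  for (ti in seq_along(times)) {
    tfront <- -1.8 + (4 / 60) * (times[ti] - 5)
    if (times[ti] <= 5 || tfront > max(coords$y_mm) - 0.3) next
    prof <- -rowMeans(r523[ti, , ])          # 523 nm dips at the front
    iy <- which.max(prof)
    expect_lt(abs(coords$y_mm[iy] - tfront), scene$pixel_pitch / 2 + 1e-9)
    checked <- checked + 1L
  }
  expect_gt(checked, 50)
})

test_that("identical seed and config reproduce the scene bit for bit", {
  scene <- tiny_scene(seed = 42, noise = 0.01, nx = 16, ny = 16,
                      duration = 20)
  w <- wave_spec(speed = 4, origin = c(0, -0.5))
  a <- generate_wave_stack(scene, list(w))
  b <- generate_wave_stack(scene, list(w))
  expect_identical(a$stack$data, b$stack$data)
  scene2 <- tiny_scene(seed = 43, noise = 0.01, nx = 16, ny = 16,
                       duration = 20)
  c <- generate_wave_stack(scene2, list(w))
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("invalid scenes and waves are rejected", {
  scene <- tiny_scene(nx = 16, ny = 16, duration = 20)
  expect_error(generate_wave_stack(scene, list(wave_spec(4, origin = c(9, 0)))),
               "outside")
  expect_error(scene_config(duration = 0), "duration")
  expect_error(wave_spec(speed = -1), "speed")
  expect_error(wave_spec(speed = 4, half_width = 0), "half_width")
  expect_error(scene_config(channels = c(400, 500, 600, 700)), "channels")
})

test_that("EEG suppression scales band power by the specified fraction", {
  spec <- eeg_spec(duration = 400, channels = "right",
                   events = tibble::tibble(onset = 150, duration = 120,
                                           reduction = 0.80,
                                           laterality = "unilateral-right",
                                           transition_s = 2, recovery_s = 5),
                   seed = 5)
  eeg <- generate_eeg(spec)
  tr <- eeg$record$traces$right
  fs <- eeg$record$fs
  # direct PSD integration oracle on baseline vs mid-event windows
  band_power <- function(x) {
    n <- length(x)
    X <- fft(x - mean(x))
    f <- (seq_len(n) - 1) / n * fs
    sum((2 / n^2) * abs(X[f >= 0.5 & f <= 100])^2)
  }
  base_win <- tr[(50 * fs):(140 * fs)]
  ev_win <- tr[(170 * fs):(260 * fs)]
  ratio <- band_power(ev_win) / band_power(base_win)
  expect_equal(ratio, 0.20, tolerance = 0.02)
})

test_that("event-free EEG yields no LVA detections downstream", {
  spec <- eeg_spec(duration = 900, channels = "right", seed = 2)
  eeg <- generate_eeg(spec)
  expect_equal(nrow(detect_lva_record(eeg$record)), 0L)
})

test_that("a bilateral event with known lag gives the expected EEG speed", {
  spec <- eeg_spec(duration = 300, channels = c("left", "right"),
                   events = tibble::tibble(onset = 60, duration = 60,
                                           reduction = 0.9,
                                           laterality = "bilateral",
                                           lag_s = 30, transition_s = 2,
                                           recovery_s = 5),
                   seed = 3)
  eeg <- generate_eeg(spec)
  res <- eeg_speed(eeg$record$traces$right, eeg$record$traces$left,
                   fs = eeg$record$fs, separation_mm = 2)
  expect_equal(res$speed_mm_min, 4.0, tolerance = 1e-6)
})

test_that("overlapping or inconsistent EEG events are rejected", {
  ev <- tibble::tibble(onset = c(10, 30), duration = c(40, 40),
                       reduction = 0.9, laterality = "bilateral")
  expect_error(eeg_spec(duration = 200, events = ev), "overlap")
  expect_error(
    eeg_spec(duration = 200,
             events = tibble::tibble(onset = 10, duration = 20,
                                     reduction = 0.9,
                                     laterality = "bilateral", lag_s = 25)),
    "lag")
})

test_that("behavior generation fills gaps and round-trips through CSV", {
  tr <- generate_behavior(240 * 60, NULL)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$label, "normal ambulation")

  bouts <- tibble::tibble(onset = c(3600, 7200), offset = c(4500, 8100),
                          label = c("paralysis", "sleeping"))
  tr2 <- generate_behavior(4 * 3600, bouts)
  expect_equal(attr(tr2, "duration"), 14400)
  expect_equal(sum(tr2$end - tr2$start), 14400)
  path <- tempfile(fileext = ".csv")
  write_behavior_csv(tr2, path)
  back <- read_behavior_csv(path, duration = 14400)
  expect_equal(back$start, tr2$start)
  expect_equal(back$end, tr2$end)
  expect_equal(back$label, tr2$label)

  expect_error(generate_behavior(100, tibble::tibble(
    onset = c(0, 5), offset = c(10, 15), label = "eating")), "overlap")
})

test_that("frame stacks round-trip through multi-page TIFF", {
  scene <- tiny_scene(seed = 9, noise = 0.01, nx = 8, ny = 8, duration = 12)
  sim <- generate_wave_stack(scene,
                             list(wave_spec(4, origin = c(0, 0), onset = 2)))
  path <- tempfile(fileext = ".tif")
  write_frame_stack(sim$stack, path)
  back <- read_frame_stack(path)
  expect_equal(back$wavelengths, sim$stack$wavelengths)
  expect_equal(back$frame_rate, sim$stack$frame_rate)
  rel <- max(abs(back$data - sim$stack$data)) / diff(range(sim$stack$data))
  expect_lt(rel, 1e-6)
})

test_that("EEG records round-trip through CSV", {
  spec <- eeg_spec(duration = 5, fs = 250, channels = c("left", "right"),
                   seed = 4)
  eeg <- generate_eeg(spec)
  path <- tempfile(fileext = ".csv")
  write_eeg_csv(eeg$record, path)
  back <- read_eeg_csv(path)
  expect_equal(back$fs, 250, tolerance = 1e-9)
  expect_equal(back$traces$right, eeg$record$traces$right, tolerance = 1e-9)
})
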