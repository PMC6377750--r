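band_power <- function(x, fs, lo, hi) {
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) * fs / length(x)
  sum(spec[freqs >= lo & freqs <= hi & freqs <= fs / 2])
}

test_that("Hampel filter attenuates a 50 Hz line by at least 20 dB", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)[-1]
  set.seed(5)
  x <- sin(2 * pi * 50 * t) + rnorm(length(t), 0, 0.01)
  y <- hampel_powerline_filter(x, fs)
  before <- band_power(x, fs, 49.5, 50.5)
  after <- band_power(y, fs, 49.5, 50.5)
  expect_gt(10 * log10(before / after), 20)
  # broadband content away from the line is essentially untouched
  expect_equal(band_power(y, fs, 100, 900), band_power(x, fs, 100, 900),
               tolerance = 0.02)
})

test_that("Hampel filter is conservative on clean signals", {
  expect_equal(hampel_powerline_filter(rep(0, 4000), 2000), rep(0, 4000))
  set.seed(6)
  x <- rnorm(8000, 0, 1)
  y <- hampel_powerline_filter(x, 2000)
  expect_lt(abs(sum(y^2) - sum(x^2)) / sum(x^2), 0.01)
  expect_error(hampel_powerline_filter(x, fs = 90), "twice")
})

test_that("synchronization reproduces linear and smooth signals on the fast grid", {
  fs_e <- 2000; fs_g <- 25; dur <- 4
  ne <- dur * fs_e; ng <- dur * fs_g
  ts_g <- (seq_len(ng) - 1) / fs_g
  glove <- cbind(2 * ts_g + 1,                 # linear ramp
                 rep(3, ng),                   # constant
                 sin(2 * pi * 1 * ts_g))       # 1 Hz sine
  rec <- signal_recording("s", matrix(0, ne, 1), glove,
                          stimulus = integer(ne), repetition = integer(ne),
                          fs_emg = fs_e, fs_glove = fs_g)
  out <- synchronize(rec, target_fs = fs_e)
  expect_identical(out$emg, rec$emg)           # already on grid: untouched
  grid <- out$timestamps_glove
  inside <- grid <= max(ts_g)
  expect_equal(out$glove[inside, 1], 2 * grid[inside] + 1, tolerance = 1e-12)
  expect_equal(out$glove[, 2], rep(3, ne), tolerance = 1e-12)
  expect_lt(max(abs(out$glove[inside, 3] - sin(2 * pi * grid[inside]))), 0.01)

  bad <- rec
  bad$timestamps_glove[2] <- bad$timestamps_glove[1]
  expect_error(synchronize(bad), "strictly increasing")
})

test_that("windowing respects segments, stride and trailing-window dropping", {
  fs <- 2000
  # one 5 s repetition: floor((10000 - 400) / 200) + 1 = 49 windows
  n <- 5 * fs
  rec <- signal_recording("s", matrix(rnorm(n * 2), n, 2),
                          matrix(0, n, 1),
                          stimulus = rep(1L, n), repetition = rep(1L, n),
                          fs_emg = fs, fs_glove = fs)
  ws <- segment_windows(rec, "emg")
  expect_equal(n_windows(ws), 49L)
  expect_equal(ws$window_length, 400L)
  expect_true(all(ws$index$end - ws$index$start + 1L == 400L))

  # a segment shorter than one window yields zero windows
  n2 <- 300L
  rec2 <- signal_recording("s", matrix(0, n2, 1), matrix(0, n2, 1),
                           stimulus = rep(1L, n2), repetition = rep(1L, n2),
                           fs_emg = fs, fs_glove = fs)
  expect_equal(n_windows(segment_windows(rec2, "emg")), 0L)

  # windows never span repetition boundaries
  n3 <- 2 * fs
  rec3 <- signal_recording("s", matrix(0, 2 * n3, 1), matrix(0, 2 * n3, 1),
                           stimulus = rep(1L, 2 * n3),
                           repetition = rep(c(1L, 2L), each = n3),
                           fs_emg = fs, fs_glove = fs)
  ws3 <- segment_windows(rec3, "emg")
  for (i in seq_len(n_windows(ws3))) {
    reps <- rec3$repetition[ws3$index$start[i]:ws3$index$end[i]]
    expect_length(unique(reps), 1L)
  }
  # label purity: each window carries exactly one (grasp, repetition)
  expect_identical(ws3$index$repetition,
                   rec3$repetition[ws3$index$start])

  # rest and unlisted stimuli are excluded
  rec4 <- signal_recording("s", matrix(0, n3, 1), matrix(0, n3, 1),
                           stimulus = rep(c(0L, 9L), each = fs),
                           repetition = rep(c(0L, 1L), each = fs),
                           fs_emg = fs, fs_glove = fs)
  expect_equal(n_windows(segment_windows(rec4, "emg", grasp_set = gs4)), 0L)
  expect_error(segment_windows(rec4, "emg", window_ms = 100, overlap_ms = 100),
               "exceed")
})
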