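test_that("window features match hand-computed values", {
  x <- matrix(c(3, -4, 3), 3, 1)
  expect_equal(unname(window_features(x, feature_spec("RMS"))),
               sqrt(34 / 3), tolerance = 1e-12)
  expect_equal(unname(window_features(x, feature_spec("MAV"))),
               10 / 3, tolerance = 1e-12)
  expect_equal(unname(window_features(x, feature_spec("IAV"))), 10)
  expect_equal(unname(window_features(x, feature_spec("WL"))), 14)
  td <- window_features(x, feature_spec("TD", zc_threshold = 0.1,
                                        ssc_threshold = 0.1))
  expect_equal(unname(td[c("ZC.ch1", "SSC.ch1")]), c(2, 1))

  y <- matrix(c(5, 5, 5, 5), 4, 1)
  expect_equal(unname(window_features(y, feature_spec("RMS"))), 5)
  expect_equal(unname(window_features(y, feature_spec("MAV"))), 5)
  expect_equal(unname(window_features(y, feature_spec("IAV"))), 20)
  expect_equal(unname(window_features(y, feature_spec("WL"))), 0)
  tdy <- window_features(y, feature_spec("TD"))
  expect_equal(unname(tdy[c("ZC.ch1", "SSC.ch1")]), c(0, 0))

  z <- matrix(0, 3, 2)
  for (fam in c("RMS", "MAV", "IAV", "WL")) {
    expect_equal(unname(window_features(z, feature_spec(fam))), c(0, 0))
  }
  expect_error(window_features(matrix(1, 2, 1), feature_spec("RMS")),
               "at least 3")
  expect_error(feature_spec("RMS", zc_threshold = -1))
})

test_that("threshold gating of ZC and SSC works as specified", {
  # crossings exist but fall below the amplitude gate
  x <- matrix(c(0.01, -0.01, 0.01, -0.01), 4, 1)
  td_open <- window_features(x, feature_spec("TD"))
  td_gated <- window_features(x, feature_spec("TD", zc_threshold = 0.5,
                                              ssc_threshold = 0.5))
  expect_equal(unname(td_open["ZC.ch1"]), 3)
  expect_equal(unname(td_gated["ZC.ch1"]), 0)
  expect_equal(unname(td_gated["SSC.ch1"]), 0)
  # a sample equal to zero is not a strict crossing
  x0 <- matrix(c(1, 0, -1), 3, 1)
  expect_equal(unname(window_features(x0, feature_spec("TD"))["ZC.ch1"]), 0)
})

test_that("MAVS is a within-repetition forward difference", {
  expect_equal(mavs_series(c(2, 5, 4)), c(3, -1))
  expect_equal(mavs_series(c(0, 7)), 7)
  expect_equal(mavs_series(rep(4, 5)), rep(0, 4))
  expect_length(mavs_series(3), 0L)
  m <- matrix(c(1, 2, 4, 0, 0, 0), 3, 2)
  expect_equal(mavs_series(m), diff(m))
})

test_that("feature tables have the declared shape and drop the MAVS boundary", {
  set.seed(11)
  fs <- 2000; n <- 5 * fs
  rec <- signal_recording("s", matrix(rnorm(n * 3), n, 3), matrix(0, n, 1),
                          stimulus = rep(1L, n), repetition = rep(1L, n),
                          fs_emg = fs, fs_glove = fs)
  ws <- segment_windows(rec, "emg")
  expect_equal(n_windows(ws), 49L)

  rms <- build_feature_table(ws, feature_spec("RMS"))
  expect_equal(nrow(rms), 49L)
  expect_equal(ncol(feature_matrix(rms)), 3L)           # channels x 1

  td <- build_feature_table(ws, feature_spec("TD"))
  expect_equal(nrow(td), 48L)                           # last window dropped
  expect_equal(ncol(feature_matrix(td)), 5L * 3L)       # channels x 5
  expect_false(anyNA(feature_matrix(td)))

  # IAV table equals T * MAV table elementwise
  mav <- build_feature_table(ws, feature_spec("MAV"))
  iav <- build_feature_table(ws, feature_spec("IAV"))
  expect_equal(feature_matrix(iav),
               ws$window_length * feature_matrix(mav),
               tolerance = 1e-12, ignore_attr = TRUE)

  # RMS >= MAV on every window (power mean inequality), all non-negative
  expect_true(all(feature_matrix(rms) >= feature_matrix(mav) - 1e-12))
  expect_true(all(feature_matrix(rms) >= 0))
})
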