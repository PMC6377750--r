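test_that("profile generation is deterministic and respects the zero-variance limit", {
  cfg <- tiny_synth_config()
  p1 <- generate_profiles(cfg)
  p2 <- generate_profiles(cfg)
  expect_identical(p1, p2)

  cfg0 <- tiny_synth_config(profile_scale = 0)
  p0 <- generate_profiles(cfg0)
  expect_true(all(p0$emg_amplitude == p0$emg_amplitude[1, 1]))
  expect_true(all(p0$glove_posture == p0$glove_posture[1, 1]))

  nonbin <- grasp_tree(list("A", "B", "C", "D"))
  expect_error(generate_profiles(tiny_synth_config(planted_tree = nonbin)),
               "binary")
})

test_that("Brownian evolution makes near leaves more similar than far leaves", {
  # ((A,B),(C,D)): path A-B has 2 edges, A-C has 4; expected squared
  # distances 2 sigma^2 vs 4 sigma^2
  tree <- parse_newick("((A,B),(C,D));")
  set.seed(99)
  dd_ab <- dd_ac <- numeric(1500)
  for (i in seq_along(dd_ab)) {
    x <- grasptaxa:::brownian_on_tree(tree, 1L, sigma = 2)
    dd_ab[i] <- (x["A", ] - x["B", ])^2
    dd_ac[i] <- (x["A", ] - x["C", ])^2
  }
  expect_lt(mean(dd_ab), mean(dd_ac))
  expect_equal(mean(dd_ab), 2 * 4, tolerance = 0.15)
  expect_equal(mean(dd_ac), 4 * 4, tolerance = 0.15)
})

test_that("certified profiles express the planted topology", {
  cfg <- tiny_synth_config(grasp_set = gs8)
  prof <- generate_profiles(cfg)
  for (m in list(prof$emg_amplitude, prof$glove_posture)) {
    d <- as.matrix(dist(sweep(m, 2, sqrt(colMeans(m^2)), "/")))
    tr <- distance_tree(grasp_distance_matrix(d, rownames(m)))
    expect_identical(as_newick(tr), as_newick(cfg$planted_tree))
  }
})

test_that("generated recordings have the declared block structure", {
  cfg <- tiny_synth_config()
  rec <- generate_recording(cfg, 1)
  expect_s3_class(rec, "signal_recording")
  G <- length(cfg$grasp_set$grasp_ids); R <- cfg$n_repetitions
  me <- cfg$movement_s * cfg$fs_emg

  runs <- rle(rec$stimulus)
  mov <- runs$lengths[runs$values != 0L]
  expect_length(mov, G * R)                      # one block per repetition
  expect_true(all(mov == me))                    # of exactly movement_s * fs
  # repetition labels pair up with stimulus labels
  expect_identical(rec$repetition != 0L, rec$stimulus != 0L)

  # determinism of the full generator
  rec2 <- generate_recording(cfg, 1)
  expect_identical(rec$emg, rec2$emg)
  expect_identical(rec$glove, rec2$glove)
  # different subjects get different signals
  expect_false(identical(rec$emg, generate_recording(cfg, 2)$emg))
})

test_that("EMG amplitude is silent without activation and louder during movement", {
  # no activation, no noise, no line -> identically zero
  cfg0 <- tiny_synth_config(noise_sd = 0, powerline_amp = 0,
                            emg_amplitude_mv = 0, profile_scale = 0,
                            subject_sd = 0, rep_sd = 0)
  rec0 <- generate_recording(cfg0, 1)
  expect_true(all(rec0$emg == 0))

  # with activation, per-channel movement RMS exceeds rest RMS
  cfg <- tiny_synth_config()
  rec <- generate_recording(cfg, 1)
  mov <- rec$stimulus != 0L
  rms <- function(m) sqrt(colMeans(m^2))
  expect_true(all(rms(rec$emg[mov, ]) > rms(rec$emg[!mov, ])))
})

test_that("the 50 Hz line option adds narrowband power", {
  cfg <- tiny_synth_config(powerline_amp = 0.5)
  rec <- generate_recording(cfg, 1)
  x <- rec$emg[, 1]
  spec <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * cfg$fs_emg / length(x)
  band <- freqs > 49 & freqs < 51
  ref <- freqs > 60 & freqs < 80
  expect_gt(mean(spec[band]), 10 * mean(spec[ref]))
})
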