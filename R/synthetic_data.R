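#' @title Synthetic multi-subject grasp recordings
#'
#' @description
#' Generator for Ninapro-like recordings with a planted grasp-similarity
#' tree, so that every downstream stage (features, distances, trees,
#' supertrees) can be validated by parameter recovery. Grasp-specific
#' muscle-activation amplitudes and glove postures evolve by Brownian
#' motion along the planted tree; sEMG is modelled as amplitude-modulated
#' zero-mean broadband noise (the minimal model under which RMS, MAV, IAV
#' and WL all track activation amplitude), glove channels as smooth
#' logistic trajectories from the rest posture to the grasp posture.
#'
#' @name synthetic_data
NULL

#' Configuration of the synthetic cohort
#'
#' Defaults mirror the acquisition protocol of the Ninapro DB2-style study:
#' 6 repetitions per grasp, 5 s movement alternated with 3 s rest, 12 EMG
#' channels at 2 kHz and a 22-sensor glove at 25 Hz.
#'
#' @param n_subjects number of subjects
#' @param grasp_set a [grasp_set()]
#' @param n_repetitions repetitions per grasp (default 6)
#' @param movement_s,rest_s movement / rest durations in seconds (5 / 3)
#' @param fs_emg,fs_glove sampling rates, Hz (2000 / 25)
#' @param n_emg_channels,n_glove_sensors channel counts (12 / 22)
#' @param planted_tree `grasp_tree` over the grasp names (default: balanced)
#' @param profile_scale Brownian step s.d. per planted-tree edge (log-amplitude
#'   units for EMG, posture units for the glove; default 0.5)
#' @param subject_sd s.d. of per-subject profile perturbation (default 0.1)
#' @param rep_sd s.d. of per-repetition multiplicative amplitude / posture
#'   jitter, the intra-subject variability between repetitions (default 0.05)
#' @param noise_sd s.d. of additive within-repetition sensor noise (mV for
#'   EMG; default 0.05)
#' @param tremor_sd relative s.d. of the broadband postural micro-movement
#'   (physiological tremor) superimposed on held glove postures; gives
#'   waveform-length features their posture-proportional signal
#'   (default 0.05)
#' @param powerline_amp amplitude of an added 50 Hz sinusoid on the EMG, mV
#'   (default 0)
#' @param emg_amplitude_mv baseline movement activation amplitude, mV
#' @param seed RNG seed for the whole cohort
#' @return a validated `synth_config`
#' @export
synth_config <- function(n_subjects, grasp_set,
                         n_repetitions = 6L, movement_s = 5, rest_s = 3,
                         fs_emg = 2000, fs_glove = 25,
                         n_emg_channels = 12L, n_glove_sensors = 22L,
                         planted_tree = balanced_tree(grasp_set$grasp_names),
                         profile_scale = 0.5, subject_sd = 0.1,
                         rep_sd = 0.05, noise_sd = 0.05, tremor_sd = 0.05,
                         powerline_amp = 0, emg_amplitude_mv = 1,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, n_repetitions >= 1, movement_s > 0, rest_s >= 0,
            fs_emg > 0, fs_glove > 0, n_emg_channels >= 1, n_glove_sensors >= 1,
            profile_scale >= 0, subject_sd >= 0, rep_sd >= 0, noise_sd >= 0,
            tremor_sd >= 0, powerline_amp >= 0, emg_amplitude_mv >= 0)
  stopifnot(inherits(grasp_set, "grasp_set"), inherits(planted_tree, "grasp_tree"))
  if (!setequal(tree_leaves(planted_tree), grasp_set$grasp_names)) {
    stop("planted_tree leaves must equal the grasp names")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), grasp_set = grasp_set,
    n_repetitions = as.integer(n_repetitions),
    movement_s = movement_s, rest_s = rest_s,
    fs_emg = fs_emg, fs_glove = fs_glove,
    n_emg_channels = as.integer(n_emg_channels),
    n_glove_sensors = as.integer(n_glove_sensors),
    planted_tree = planted_tree,
    profile_scale = profile_scale, subject_sd = subject_sd,
    rep_sd = rep_sd, noise_sd = noise_sd, tremor_sd = tremor_sd,
    powerline_amp = powerline_amp, emg_amplitude_mv = emg_amplitude_mv,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# scramble (base, a, b) into a valid 32-bit seed
derive_seed <- function(base, a = 0L, b = 0L) {
  as.integer((as.numeric(base) * 48271 + as.numeric(a) * 16807 +
                as.numeric(b) * 69621 + 1) %% 2147483646) + 1L
}

# Brownian motion along the planted tree: one value per leaf per dimension.
# Root state 0; every edge adds N(0, sigma^2) independently per dimension.
brownian_on_tree <- function(tree, n_dims, sigma) {
  leaves <- sort(tree_leaves(tree), method = "radix")
  out <- matrix(0, nrow = length(leaves), ncol = n_dims,
                dimnames = list(leaves, NULL))
  walk <- function(node, state) {
    if (is.character(node)) {
      out[node, ] <<- state
      return(invisible(NULL))
    }
    for (ch in node) walk(ch, state + stats::rnorm(n_dims, 0, sigma))
    invisible(NULL)
  }
  walk(tree$node, rep(0, n_dims))
  out
}

#' Generate grasp profiles along the planted tree
#'
#' Draws, by Brownian evolution along the planted tree, one log-amplitude
#' vector (EMG channels) and one posture vector (glove sensors) per grasp.
#' When `profile_scale > 0` each modality's draw is certified:
#' average-linkage clustering of the realized profile distances — under
#' both the plain Euclidean metric and the per-channel normalized metric,
#' the two ends of the family of diagonal metrics the downstream
#' pooled-covariance whitening can induce — must reproduce the planted
#' topology, otherwise the draw is rejected and redrawn with a derived
#' seed (bounded attempts, deterministic). This keeps "planted tree" a
#' meaningful ground truth for recovery experiments: a Brownian
#' realization whose own geometry contradicts the planted topology cannot
#' certify any inference pipeline.
#'
#' @param config a [synth_config()]
#' @return list with `emg_amplitude` (G x channels, mV),
#'   `log_amplitude`, `glove_posture` (G x sensors), `attempts` (per
#'   modality)
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is_binary_tree(config$planted_tree)) {
    stop("planted tree must be binary")
  }
  gs <- config$grasp_set
  names_sorted <- sort(gs$grasp_names, method = "radix")
  ord <- match(gs$grasp_names, names_sorted)

  draw_certified <- function(n_dims, salt, transform, endpoints) {
    max_attempts <- 20000L
    for (attempt in seq_len(max_attempts)) {
      seed_a <- derive_seed(config$seed, salt, attempt)
      m <- with_seed(seed_a, {
        brownian_on_tree(config$planted_tree, n_dims, config$profile_scale)
      })
      if (config$profile_scale == 0 ||
          with_seed(derive_seed(seed_a, 3L, 1L),
                    profile_expresses_tree(transform(m), config$planted_tree,
                                           endpoints = endpoints))) {
        return(list(m = m, attempts = attempt))
      }
    }
    stop("could not realize the planted topology in ", max_attempts,
         " profile draws; increase profile_scale or simplify the planted tree")
  }
  # EMG within-group variability is amplitude-proportional, so its induced
  # metric is the channel-normalized one; glove variability mixes additive
  # sensor noise with multiplicative tremor/jitter, so both metric
  # endpoints are certified
  emg <- draw_certified(config$n_emg_channels, 7L,
                        function(m) config$emg_amplitude_mv * exp(m),
                        endpoints = "normalized")
  glove <- draw_certified(config$n_glove_sensors, 11L, exp,
                          endpoints = c("normalized", "raw"))
  list(log_amplitude = emg$m[ord, , drop = FALSE],
       emg_amplitude = (config$emg_amplitude_mv * exp(emg$m))[ord, , drop = FALSE],
       glove_posture = exp(glove$m)[ord, , drop = FALSE],
       attempts = c(emg = emg$attempts, glove = glove$attempts))
}

# Does UPGMA recover the planted topology from the realized profile
# matrix under the metric endpoints the pooled-covariance whitening can
# induce, and does the recovery survive multiplicative perturbation of
# the profile entries (the accepted draw then has a margin against the
# coherent group-mean estimation noise of a finite recording)?
profile_expresses_tree <- function(m, planted,
                                   endpoints = c("normalized", "raw"),
                                   n_perturb = 30L, perturb_sd = 0.08) {
  col_rms <- sqrt(colMeans(m^2))
  col_rms[col_rms == 0] <- 1
  mats <- list(normalized = sweep(m, 2L, col_rms, "/"), raw = m)[endpoints]
  recovers <- function(mm) {
    gd <- grasp_distance_matrix(as.matrix(stats::dist(mm)), rownames(m))
    robinson_foulds(to_phylo(agglomerate(gd, linkage = "average")),
                    planted) == 0L
  }
  for (mm in mats) {
    if (!recovers(mm)) return(FALSE)
    for (j in seq_len(n_perturb)) {
      mj <- mm * (1 + matrix(stats::rnorm(length(mm), 0, perturb_sd), nrow(mm)))
      if (!recovers(mj)) return(FALSE)
    }
  }
  TRUE
}

#' Generate one subject's synthetic recording
#'
#' Lays out `n_repetitions` movement blocks per grasp, each followed by a
#' rest block; labels mark exactly the movement blocks on the EMG grid.
#' EMG is per-channel amplitude-modulated Gaussian noise plus sensor noise
#' and an optional 50 Hz line component; the glove follows a smooth
#' logistic trajectory from the zero rest posture to the grasp posture.
#' As with re-labelled movement annotations on real recordings, the
#' labelled interval covers the held grasp: the activation ramp-up and the
#' reach movement of the hand complete just before the label onset (inside
#' the preceding rest), and release begins at label offset. Repetitions of
#' one grasp differ by a per-channel multiplicative jitter of s.d.
#' `rep_sd`, the intra-subject variability between repetitions.
#' Deterministic given `config$seed` and `subject`.
#'
#' @param config a [synth_config()]
#' @param subject subject index in `1:n_subjects`
#' @param profiles optional precomputed [generate_profiles()] output
#' @return a `signal_recording` with subject id `s<index>`
#' @export
generate_recording <- function(config, subject, profiles = generate_profiles(config)) {
  stopifnot(inherits(config, "synth_config"),
            subject >= 1, subject <= config$n_subjects)
  gs <- config$grasp_set
  G <- length(gs$grasp_ids); R <- config$n_repetitions
  C <- config$n_emg_channels; S <- config$n_glove_sensors
  me <- round(config$movement_s * config$fs_emg)
  re <- round(config$rest_s * config$fs_emg)
  mg <- round(config$movement_s * config$fs_glove)
  rg <- round(config$rest_s * config$fs_glove)
  n_blocks <- G * R
  Ne <- n_blocks * (me + re)
  Ng <- n_blocks * (mg + rg)

  with_seed(derive_seed(config$seed, 13L, subject), {
    # subject-specific profile perturbation
    amp <- profiles$emg_amplitude *
      exp(matrix(stats::rnorm(G * C, 0, config$subject_sd), G, C))
    posture <- profiles$glove_posture +
      matrix(stats::rnorm(G * S, 0, config$subject_sd), G, S)

    carrier <- matrix(stats::rnorm(Ne * C, 0, 1), Ne, C)
    act <- matrix(0, Ne, C)                  # activation amplitude envelope
    glove <- matrix(0, Ng, S)
    stimulus <- integer(Ne); repetition <- integer(Ne)

    # EMG ramps sit just outside the labelled block (100 ms raised cosine,
    # clipped into the neighbouring rest)
    nr <- min(round(0.1 * config$fs_emg), re %/% 2L)
    ramp_up <- if (nr > 0) 0.5 * (1 - cos(pi * seq_len(nr) / nr)) else numeric(0)
    # glove: logistic reach completing ~0.4 s before label onset; release
    # starting ~0.45 s after label offset
    tg_rel <- ((seq_len(mg + 2L * rg) - rg) - 0.5) / config$fs_glove
    bump <- stats::plogis((tg_rel + 0.4) / 0.07) *
      stats::plogis(-(tg_rel - config$movement_s - 0.45) / 0.07)

    blk <- 0L
    for (g in seq_len(G)) {
      for (r in seq_len(R)) {
        jit_e <- exp(stats::rnorm(C, 0, config$rep_sd))
        jit_g <- exp(stats::rnorm(S, 0, config$rep_sd))
        i0e <- blk * (me + re); i0g <- blk * (mg + rg)
        mov_e <- i0e + seq_len(me)
        a <- amp[g, ] * jit_e
        act[mov_e, ] <- matrix(a, me, C, byrow = TRUE)
        if (nr > 0) {
          if (i0e >= nr) act[i0e - nr + seq_len(nr), ] <- ramp_up %o% a
          act[i0e + me + seq_len(nr), ] <- rev(ramp_up) %o% a
        }
        stimulus[mov_e] <- gs$grasp_ids[g]
        repetition[mov_e] <- r
        jrange <- (i0g - rg + 1L):(i0g + mg + rg)
        inside <- jrange >= 1L & jrange <= Ng
        # held posture plus broadband postural micro-movement (tremor)
        wobble <- 1 + matrix(stats::rnorm(sum(inside) * S, 0, config$tremor_sd),
                             sum(inside), S)
        glove[jrange[inside], ] <- glove[jrange[inside], ] +
          (bump[inside] %o% (posture[g, ] * jit_g)) * wobble
        blk <- blk + 1L
      }
    }
    emg <- act * carrier
    if (config$noise_sd > 0) {
      emg <- emg + matrix(stats::rnorm(Ne * C, 0, config$noise_sd), Ne, C)
      glove <- glove + matrix(stats::rnorm(Ng * S, 0, config$noise_sd), Ng, S)
    }
    ts_e <- (seq_len(Ne) - 1) / config$fs_emg
    if (config$powerline_amp > 0) {
      phase <- stats::runif(C, 0, 2 * pi)
      line <- config$powerline_amp * sin(2 * pi * 50 * outer(ts_e, rep(1, C)) +
                                           matrix(phase, Ne, C, byrow = TRUE))
      emg <- emg + line
    }
    signal_recording(sprintf("s%02d", subject), emg, glove,
                     stimulus, repetition,
                     fs_emg = config$fs_emg, fs_glove = config$fs_glove,
                     timestamps_emg = ts_e,
                     timestamps_glove = (seq_len(Ng) - 1) / config$fs_glove)
  })
}

#' Generate the full synthetic cohort
#'
#' @param config a [synth_config()]
#' @return named list of `signal_recording`, one per subject
#' @export
generate_cohort <- function(config) {
  profiles <- generate_profiles(config)
  recs <- lapply(seq_len(config$n_subjects), function(s) {
    generate_recording(config, s, profiles = profiles)
  })
  names(recs) <- vapply(recs, function(r) r$subject_id, character(1))
  recs
}
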