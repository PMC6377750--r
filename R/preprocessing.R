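#' @title Preprocessing: line-noise removal, synchronization, windowing
#'
#' @description
#' The EMG electrodes are not shielded against power-line pickup, so a
#' Hampel identifier on the short-time spectrum attenuates the 50 Hz line
#' when (and only when) it is an outlier relative to neighbouring spectral
#' bins. Modalities recorded at different rates are brought onto the EMG
#' time grid by linear interpolation against their timestamps. Feature
#' windows (200 ms, 100 ms overlap by default) are cut strictly inside each
#' (grasp, repetition) segment so no window straddles a rest period or a
#' repetition boundary.
#'
#' @name preprocessing
NULL

#' Hampel filter for power-line interference
#'
#' Works block-wise on the short-time Fourier transform (default 1 s
#' blocks). In every block, bins within `band_hz` of `target_hz` whose
#' magnitude exceeds the local median by more than `n_sigma` * MAD
#' (median and MAD taken over a `context_hz` neighbourhood excluding the
#' band) are replaced by the local median magnitude, preserving phase.
#' Content outside the band is untouched up to reconstruction round-off.
#'
#' @param signal numeric matrix, samples x channels (a vector is treated
#'   as one channel)
#' @param fs sampling rate, Hz
#' @param target_hz line frequency to clean (default 50)
#' @param band_hz half-width of the cleaned band, Hz (default 1)
#' @param n_sigma Hampel threshold in MAD units (default 3)
#' @param block_s STFT block length, seconds (default 1)
#' @param context_hz half-width of the reference neighbourhood, Hz
#' @param harmonics also clean integer multiples of `target_hz` up to
#'   Nyquist (default FALSE: fundamental only)
#' @return filtered matrix, same shape as `signal`
#' @export
hampel_powerline_filter <- function(signal, fs, target_hz = 50,
                                    band_hz = 1, n_sigma = 3,
                                    block_s = 1, context_hz = 10,
                                    harmonics = FALSE) {
  vec_in <- is.null(dim(signal))
  x <- as.matrix(signal)
  if (fs <= 2 * target_hz) {
    stop("sampling rate (", fs, " Hz) must exceed twice the target frequency")
  }
  n <- nrow(x)
  blk <- max(16L, round(block_s * fs))
  targets <- if (harmonics) {
    seq(target_hz, fs / 2 - band_hz, by = target_hz)
  } else target_hz
  out <- x
  start <- 1L
  while (start <= n) {
    end <- min(start + blk - 1L, n)
    len <- end - start + 1L
    if (len < 16L) break                      # tail too short to resolve 50 Hz
    freqs <- (seq_len(len) - 1) * fs / len    # bin frequencies of this block
    for (ch in seq_len(ncol(x))) {
      X <- stats::fft(x[start:end, ch])
      mag <- Mod(X)
      for (f0 in targets) {
        band <- which(freqs > 0 & freqs <= fs / 2 &
                        abs(freqs - f0) <= band_hz)
        ref <- which(freqs > 0 & freqs <= fs / 2 &
                       abs(freqs - f0) <= context_hz &
                       abs(freqs - f0) > band_hz)
        if (length(band) == 0L || length(ref) < 4L) next
        med <- stats::median(mag[ref])
        s <- stats::mad(mag[ref])
        bad <- band[mag[band] - med > n_sigma * s]
        for (b in bad) {
          scale <- if (mag[b] > 0) med / mag[b] else 0
          X[b] <- X[b] * scale
          mirror <- len - b + 2L               # conjugate-symmetric partner
          if (mirror >= 1L && mirror <= len && mirror != b) {
            X[mirror] <- X[mirror] * scale
          }
        }
      }
      out[start:end, ch] <- Re(stats::fft(X, inverse = TRUE)) / len
    }
    start <- end + 1L
  }
  if (vec_in) out[, 1L] else out
}

#' Synchronize all modalities onto one time grid
#'
#' Upsamples every modality to the grid of the fastest device (default
#' 2 kHz) by linear interpolation against the per-sample timestamps,
#' mirroring timestamp-based post-hoc alignment of multi-device rigs.
#' Labels are carried on the EMG grid and are resampled by nearest
#' neighbour, never interpolated. A modality whose timestamps already lie
#' on the target grid is returned bit-identical.
#'
#' @param recording a `signal_recording`
#' @param target_fs target rate, Hz (default 2000)
#' @return a `signal_recording` with all modalities on the common grid
#' @export
synchronize <- function(recording, target_fs = 2000) {
  validate_recording(recording)
  # target grid: reuse the EMG timestamps when they already run at target_fs
  if (isTRUE(all.equal(recording$fs_emg, target_fs))) {
    grid <- recording$timestamps_emg
  } else {
    grid <- seq(from = min(recording$timestamps_emg[1], recording$timestamps_glove[1]),
                to = max(recording$timestamps_emg[length(recording$timestamps_emg)],
                         recording$timestamps_glove[length(recording$timestamps_glove)]),
                by = 1 / target_fs)
  }
  interp_mat <- function(m, ts) {
    if (length(ts) == length(grid) && isTRUE(all.equal(ts, grid))) return(m)
    apply(m, 2L, function(col) {
      stats::approx(ts, col, xout = grid, method = "linear", rule = 2)$y
    })
  }
  emg <- interp_mat(recording$emg, recording$timestamps_emg)
  glove <- interp_mat(recording$glove, recording$timestamps_glove)
  nn_resample <- function(lab, ts) {
    if (length(ts) == length(grid) && isTRUE(all.equal(ts, grid))) return(lab)
    pos <- stats::approx(ts, seq_along(ts), xout = grid,
                         method = "linear", rule = 2)$y
    lab[round(pos)]
  }
  stimulus <- nn_resample(recording$stimulus, recording$timestamps_emg)
  repetition <- nn_resample(recording$repetition, recording$timestamps_emg)
  signal_recording(recording$subject_id, emg, glove, stimulus, repetition,
                   fs_emg = target_fs, fs_glove = target_fs,
                   timestamps_emg = grid, timestamps_glove = grid)
}

#' Cut feature windows inside each (grasp, repetition) segment
#'
#' Windows are taken only within maximal runs of constant non-rest
#' (stimulus, repetition); the stride is `window_ms - overlap_ms` and
#' trailing partial windows are dropped so every window has the same
#' sample count. Segments shorter than one window contribute no windows.
#'
#' @param recording a synchronized `signal_recording`
#' @param modality `"emg"` or `"glove"`
#' @param window_ms window length, ms (default 200)
#' @param overlap_ms overlap between consecutive windows, ms (default 100)
#' @param grasp_set restrict to these stimulus ids (a [grasp_set()])
#' @return a `window_set`: shared data matrix plus one index row per window
#'   (`start`, `end`, `grasp_id`, `repetition`), with `window_length` and
#'   metadata attached
#' @export
segment_windows <- function(recording, modality = c("emg", "glove"),
                            window_ms = 200, overlap_ms = 100,
                            grasp_set = NULL) {
  modality <- match.arg(modality)
  if (window_ms <= overlap_ms) stop("window_ms must exceed overlap_ms")
  fs <- if (modality == "emg") recording$fs_emg else recording$fs_glove
  data <- recording[[modality]]
  if (nrow(data) != length(recording$stimulus)) {
    stop("recording must be synchronized before windowing (label grid mismatch)")
  }
  L <- round(window_ms * fs / 1000)
  stride <- round((window_ms - overlap_ms) * fs / 1000)
  if (L < 3L) stop("window too short at this sampling rate (", L, " samples)")

  key <- paste(recording$stimulus, recording$repetition)
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep_ids <- if (is.null(grasp_set)) NULL else grasp_set$grasp_ids

  idx <- list()
  for (i in seq_along(runs$lengths)) {
    stim <- recording$stimulus[starts[i]]
    rep_ <- recording$repetition[starts[i]]
    if (stim == 0L) next
    if (!is.null(keep_ids) && !(stim %in% keep_ids)) next
    seg_len <- runs$lengths[i]
    if (seg_len < L) next                       # too short: yields no windows
    n_win <- (seg_len - L) %/% stride + 1L
    w_start <- starts[i] + (seq_len(n_win) - 1L) * stride
    idx[[length(idx) + 1L]] <- data.frame(
      start = w_start, end = w_start + L - 1L,
      grasp_id = stim, repetition = rep_)
  }
  index <- if (length(idx)) do.call(rbind, idx) else
    data.frame(start = integer(), end = integer(),
               grasp_id = integer(), repetition = integer())
  structure(list(data = data, index = index, window_length = L,
                 fs = fs, modality = modality,
                 subject_id = recording$subject_id),
            class = "window_set")
}

#' Number of windows in a window_set
#' @param ws a `window_set`
#' @return integer
#' @export
n_windows <- function(ws) nrow(ws$index)

#' Extract one window
#' @param ws a `window_set`
#' @param i window number
#' @return a `window`: samples matrix (length x channels) plus metadata
#' @export
get_window <- function(ws, i) {
  row <- ws$index[i, ]
  structure(list(samples = ws$data[row$start:row$end, , drop = FALSE],
                 t_start = (row$start - 1L) / ws$fs,
                 grasp_id = row$grasp_id, repetition = row$repetition,
                 subject_id = ws$subject_id, modality = ws$modality),
            class = "window")
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set:", nrow(x$index), "windows of", x$window_length,
      "samples,", ncol(x$data), "channels (", x$modality, ")\n")
  invisible(x)
}
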