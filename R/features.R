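#' @title Time-domain signal features
#'
#' @description
#' The five feature families used throughout the analysis, computed per
#' window and per channel:
#' \describe{
#'   \item{RMS}{\eqn{\sqrt{\frac{1}{T}\sum_t x_t^2}} — amplitude, quasi-linear
#'     in muscle force under ideal conditions.}
#'   \item{MAV}{\eqn{\frac{1}{T}\sum_t |x_t|}.}
#'   \item{IAV}{\eqn{\sum_t |x_t|}; equal to \eqn{T \cdot MAV} whenever all
#'     windows share one length \eqn{T}, which the windowing guarantees.}
#'   \item{WL}{\eqn{\sum_{t=2}^{T} |x_t - x_{t-1}|} — waveform complexity.}
#'   \item{TD}{the time-domain statistics set \{MAV, MAVS, ZC, SSC, WL\},
#'     where MAVS is the MAV difference between adjacent windows of one
#'     repetition, ZC counts threshold-gated zero crossings and SSC
#'     threshold-gated slope sign changes.}
#' }
#' The same definitions are applied verbatim to glove channels.
#'
#' @name features
NULL

.feature_families <- c("RMS", "MAV", "IAV", "TD", "WL")

#' Specify a feature family and its thresholds
#'
#' @param family one of `"RMS"`, `"MAV"`, `"IAV"`, `"TD"`, `"WL"`
#' @param zc_threshold amplitude gate for zero crossings (signal units,
#'   default 0: pure sign-based count)
#' @param ssc_threshold slope gate for slope-sign changes (default 0)
#' @return a `feature_spec`
#' @export
feature_spec <- function(family, zc_threshold = 0, ssc_threshold = 0) {
  family <- match.arg(family, .feature_families)
  stopifnot(zc_threshold >= 0, ssc_threshold >= 0)
  structure(list(family = family, zc_threshold = zc_threshold,
                 ssc_threshold = ssc_threshold), class = "feature_spec")
}

# per-channel primitives on a samples x channels matrix ----------------------

feat_rms <- function(m) sqrt(colMeans(m^2))
feat_mav <- function(m) colMeans(abs(m))
feat_iav <- function(m) colSums(abs(m))
feat_wl  <- function(m) colSums(abs(diff(m)))

feat_zc <- function(m, threshold = 0) {
  a <- m[-nrow(m), , drop = FALSE]
  b <- m[-1L, , drop = FALSE]
  crossing <- (a > 0 & b < 0) | (a < 0 & b > 0)
  gated <- crossing & (abs(a - b) >= threshold)
  colSums(gated)
}

feat_ssc <- function(m, threshold = 0) {
  prev <- m[seq_len(nrow(m) - 2L), , drop = FALSE]
  mid  <- m[1L + seq_len(nrow(m) - 2L), , drop = FALSE]
  nxt  <- m[2L + seq_len(nrow(m) - 2L), , drop = FALSE]
  extremum <- (mid > prev & mid > nxt) | (mid < prev & mid < nxt)
  gated <- extremum & (abs(mid - nxt) >= threshold | abs(mid - prev) >= threshold)
  colSums(gated)
}

#' Features of a single window
#'
#' For the instantaneous families returns one value per channel; for `TD`
#' returns the stacked \{MAV, ZC, SSC, WL\} per channel (the MAVS component
#' is a between-window quantity and is assembled by
#' [build_feature_table()]).
#'
#' @param window a `window` (from [get_window()]) or a samples x channels
#'   matrix
#' @param spec a [feature_spec()]
#' @return named numeric vector
#' @export
window_features <- function(window, spec) {
  m <- if (inherits(window, "window")) window$samples else as.matrix(window)
  if (nrow(m) < 3L) stop("window must have at least 3 samples")
  if (!all(is.finite(m))) stop("non-finite samples in window")
  ch <- colnames(m)
  if (is.null(ch)) ch <- paste0("ch", seq_len(ncol(m)))
  val <- switch(spec$family,
    RMS = stats::setNames(feat_rms(m), paste0("RMS.", ch)),
    MAV = stats::setNames(feat_mav(m), paste0("MAV.", ch)),
    IAV = stats::setNames(feat_iav(m), paste0("IAV.", ch)),
    WL  = stats::setNames(feat_wl(m), paste0("WL.", ch)),
    TD  = c(stats::setNames(feat_mav(m), paste0("MAV.", ch)),
            stats::setNames(feat_zc(m, spec$zc_threshold), paste0("ZC.", ch)),
            stats::setNames(feat_ssc(m, spec$ssc_threshold), paste0("SSC.", ch)),
            stats::setNames(feat_wl(m), paste0("WL.", ch))))
  val
}

#' Mean-absolute-value slope over consecutive windows of one repetition
#'
#' `MAVS_w = MAV_{w+1} - MAV_w`; defined only between windows of the same
#' (grasp, repetition) segment, so the output is one shorter than the
#' input. A single window yields an empty result.
#'
#' @param mav_per_window numeric vector (or matrix, windows x channels) of
#'   MAV values of consecutive windows within one repetition
#' @return vector (or matrix) of length `n - 1`
#' @export
mavs_series <- function(mav_per_window) {
  if (is.null(dim(mav_per_window))) {
    if (length(mav_per_window) < 2L) return(numeric(0))
    return(diff(mav_per_window))
  }
  if (nrow(mav_per_window) < 2L) {
    return(mav_per_window[0L, , drop = FALSE])
  }
  diff(mav_per_window)
}

#' Build the per-window feature table for one subject and modality
#'
#' One row per retained window. For the `TD` family the last window of each
#' repetition is dropped so that MAVS (a forward difference) is defined on
#' every retained row; columns are then the stacked
#' \{MAV, MAVS, ZC, SSC, WL\} per channel.
#'
#' @param ws a `window_set` from [segment_windows()]
#' @param spec a [feature_spec()]
#' @return a `feature_table`: data.frame with metadata columns
#'   (`grasp_id`, `repetition`) and one column per channel x component,
#'   with attributes `subject_id`, `modality`, `family`, `window_length`
#' @export
build_feature_table <- function(ws, spec) {
  stopifnot(inherits(ws, "window_set"), inherits(spec, "feature_spec"))
  nw <- n_windows(ws)
  if (nw == 0L) stop("empty window set: no windows to featurize")
  rows <- vector("list", nw)
  for (i in seq_len(nw)) {
    m <- ws$data[ws$index$start[i]:ws$index$end[i], , drop = FALSE]
    rows[[i]] <- window_features(m, spec)
  }
  feat <- do.call(rbind, rows)
  meta <- ws$index[, c("grasp_id", "repetition")]

  if (spec$family == "TD") {
    seg <- paste(meta$grasp_id, meta$repetition)
    mav_cols <- grep("^MAV\\.", colnames(feat))
    mavs <- matrix(NA_real_, nw, length(mav_cols))
    keep <- logical(nw)
    for (s in unique(seg)) {
      ii <- which(seg == s)
      if (length(ii) < 2L) next              # lone window: MAVS undefined
      d <- mavs_series(feat[ii, mav_cols, drop = FALSE])
      hold <- ii[-length(ii)]
      mavs[hold, ] <- d
      keep[hold] <- TRUE
    }
    colnames(mavs) <- sub("^MAV\\.", "MAVS.", colnames(feat)[mav_cols])
    feat <- cbind(feat, mavs)[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    # canonical component order per channel family
    ord <- order(match(sub("\\..*$", "", colnames(feat)),
                       c("MAV", "MAVS", "ZC", "SSC", "WL")))
    feat <- feat[, ord, drop = FALSE]
  }
  out <- cbind(meta, as.data.frame(feat))
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"),
            subject_id = ws$subject_id, modality = ws$modality,
            family = spec$family, window_length = ws$window_length)
}

#' Feature columns of a feature table as a matrix
#' @param table a `feature_table`
#' @return numeric matrix (windows x features)
#' @export
feature_matrix <- function(table) {
  keep <- !(colnames(table) %in% c("grasp_id", "repetition"))
  as.matrix(table[, keep, drop = FALSE])
}

#' Write a feature table (with metadata columns) as TSV
#' @param table a `feature_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path, sep = "\t")
  invisible(path)
}
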