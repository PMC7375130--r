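#' Framewise displacement from rigid-body motion parameters
#'
#' Power-convention framewise displacement: the sum of absolute frame-to-
#' frame differences of the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a 50 mm sphere. The first frame has
#' FD 0 by definition.
#'
#' @param motion Frames x 6 matrix: translations x/y/z in mm, rotations in
#'   radians.
#' @param radius Rotational radius in mm (default 50).
#' @return Numeric FD vector (length = frames).
#' @export
framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2 || ncol(motion) != 6)
    abort("motion trace must be frames x 6 with >= 2 frames.")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion-based subject exclusion
#'
#' A run is dropped when the proportion of frames with FD strictly above
#' `fd_thresh` exceeds `max_prop` (strict inequality: exactly `max_prop`
#' still keeps the run).
#'
#' @param fd FD vector.
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @param max_prop Maximum tolerated proportion of over-threshold frames
#'   (default 0.25).
#' @return Logical: TRUE keep, FALSE drop.
#' @export
qc_exclude <- function(fd, fd_thresh = 0.5, max_prop = 0.25) {
  mean(fd > fd_thresh) <= max_prop
}

#' Motion scrubbing
#'
#' Removes frames whose FD exceeds the threshold from a time-series matrix.
#'
#' @param ts Frames x R time-series matrix.
#' @param fd FD vector aligned with the frames.
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @return The censored time-series matrix (attribute `kept` holds the
#'   retained frame indices).
#' @export
scrub_frames <- function(ts, fd, fd_thresh = 0.5) {
  ts <- as.matrix(ts)
  if (nrow(ts) != length(fd)) abort("fd and time series lengths differ.")
  keep <- which(fd <= fd_thresh)
  if (length(keep) == 0) abort("scrubbing removed every frame.")
  out <- ts[keep, , drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero phase) to each column.
#'
#' @param ts Frames x R time-series matrix.
#' @param low,high Band edges in Hz (defaults 0.01 and 0.1).
#' @param tr Repetition time in seconds.
#' @param order Filter order (default 4).
#' @return Filtered time-series matrix.
#' @export
bandpass_filter <- function(ts, low = 0.01, high = 0.1, tr, order = 4) {
  if (tr <= 0) abort("tr must be positive.")
  nyq <- 1 / (2 * tr)
  if (high >= nyq || low <= 0 || low >= high)
    abort("band must satisfy 0 < low < high < Nyquist (1/(2 tr)).")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  ts <- as.matrix(ts)
  apply(ts, 2, function(x) signal::filtfilt(bf, x))
}

#' Nuisance regression (CompCor style)
#'
#' Removes a linear trend and the top principal components of the supplied
#' noise-tissue surrogate signals (white matter/CSF) from each ROI time
#' series by ordinary least squares.
#'
#' @param ts Frames x R time-series matrix.
#' @param nuisance_signals Frames x q matrix of noise-tissue signals.
#' @param n_components Number of principal components to remove (default 5).
#' @return Residual time-series matrix.
#' @export
nuisance_regress <- function(ts, nuisance_signals, n_components = 5) {
  ts <- as.matrix(ts)
  nuisance_signals <- as.matrix(nuisance_signals)
  if (nrow(ts) != nrow(nuisance_signals)) abort("frame counts differ.")
  n_components <- min(n_components, ncol(nuisance_signals), nrow(ts) - 2)
  pcs <- stats::prcomp(nuisance_signals, center = TRUE,
                       scale. = FALSE)$x[, seq_len(n_components), drop = FALSE]
  D <- cbind(1, seq_len(nrow(ts)), pcs)
  qr.resid(qr(D), ts)
}

#' Connectome feature vector from ROI time series
#'
#' Pairwise Pearson correlations between ROI time series on the retained
#' frames, Fisher r-to-z transformed and vectorized over the upper triangle
#' in fixed row-major order (1-2, 1-3, ..., 1-R, 2-3, ...). Correlations at
#' +/-1 are clamped with a warning.
#'
#' @param ts Frames x R time-series matrix (>= 3 frames).
#' @return A `connectome_features` object: `z` (length R(R-1)/2), `n_rois`,
#'   `frames`.
#' @export
connectome <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) abort("need at least three retained frames.")
  if (any(apply(ts, 2, sd) == 0)) abort("zero-variance ROI time series.")
  R <- cor(ts)
  ut <- t(R)[lower.tri(R)]  # row-major upper triangle
  if (any(abs(ut) >= 1)) {
    warn("correlation(s) at +/-1 clamped before Fisher transform.")
    ut <- pmin(pmax(ut, -(1 - 1e-12)), 1 - 1e-12)
  }
  structure(list(z = atanh(ut), n_rois = ncol(ts), frames = nrow(ts)),
            class = "connectome_features")
}

#' @export
print.connectome_features <- function(x, ...) {
  cat("<connectome_features>", x$n_rois, "ROIs ->", length(x$z),
      "Fisher-z edges (", x$frames, "frames )\n")
  invisible(x)
}

#' Resting-state features for a whole cohort
#'
#' Applies the simplified resting-state stream to every subject of a
#' [generate_roi_timeseries()] set: linear detrend + CompCor-style nuisance
#' regression, zero-phase band-pass, FD-based scrubbing, QC exclusion, and
#' the Fisher-z connectome. The resulting subjects x edges matrix feeds the
#' same BBS/cross-validation machinery as contrast maps.
#'
#' @param ts_set A `roi_timeseries_set`.
#' @param fd_thresh Scrubbing/exclusion FD threshold in mm (default 0.5).
#' @param max_scrub_prop Maximum censored-frame proportion before a subject
#'   is excluded (default 0.10).
#' @param low,high Band edges in Hz.
#' @return A list: `features` (kept subjects x R(R-1)/2 matrix), `kept`
#'   (logical per subject), `frames_retained`.
#' @export
resting_features <- function(ts_set, fd_thresh = 0.5, max_scrub_prop = 0.10,
                             low = 0.01, high = 0.1) {
  n <- length(ts_set$timeseries)
  kept <- logical(n)
  frames <- integer(n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    fd <- framewise_displacement(ts_set$motion[[i]])
    if (!qc_exclude(fd, fd_thresh, max_scrub_prop)) next
    ts <- nuisance_regress(ts_set$timeseries[[i]], ts_set$nuisance[[i]])
    ts <- bandpass_filter(ts, low, high, tr = ts_set$tr)
    ts <- scrub_frames(ts, fd, fd_thresh)
    cf <- connectome(ts)
    feats[[i]] <- cf$z
    frames[i] <- cf$frames
    kept[i] <- TRUE
  }
  features <- do.call(rbind, feats[kept])
  if (!is.null(features)) rownames(features) <- ts_set$subjects[kept]
  list(features = features, kept = setNames(kept, ts_set$subjects),
       frames_retained = frames)
}
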