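# Segmentation and automated artifact rejection. The spectral stage consumes
# only complete, artifact-free 2 s windows.

#' Welch-style segmentation
#'
#' Segments a recording into windows of `win_s` seconds advancing by `hop_s`
#' seconds (defaults: 2 s windows overlapping 1 s), all initially kept.
#'
#' @param n_samples recording length in samples.
#' @param fs sampling rate in Hz.
#' @param win_s window length in seconds.
#' @param hop_s hop between window starts in seconds.
#' @return An object of class `segment_mask`: list with `starts` (0-based
#'   sample indices), `length` (samples per segment) and logical `keep`.
#' @export
segment_indices <- function(n_samples, fs, win_s = 2, hop_s = 1) {
  check_scalar_num(n_samples, "n_samples", lower = 1)
  check_scalar_num(fs, "fs", lower = .Machine$double.eps)
  check_scalar_num(win_s, "win_s", lower = .Machine$double.eps)
  check_scalar_num(hop_s, "hop_s", lower = .Machine$double.eps, upper = win_s)
  win <- round(win_s * fs)
  hop <- round(hop_s * fs)
  if (n_samples < win)
    stopf("recording too short for one %gs window (%d < %d samples)",
          win_s, n_samples, win)
  n_seg <- floor((n_samples - win) / hop) + 1
  structure(list(starts = (seq_len(n_seg) - 1) * hop, length = win,
                 keep = rep(TRUE, n_seg)),
            class = "segment_mask")
}

#' @export
print.segment_mask <- function(x, ...) {
  cat(sprintf("<segment mask> %d segment(s) of %d samples, %.1f%% kept\n",
              length(x$starts), x$length, 100 * mean(x$keep)))
  invisible(x)
}

#' Automated artifact rejection
#'
#' Surrogate for visual artifact screening: each segment is rejected when
#' any channel's within-segment peak absolute robust z-score (against the
#' whole-recording median and 1.4826 x MAD) exceeds `z_thresh`, or when a
#' channel is flat within the segment (peak-to-peak range below
#' `flat_thresh_uV`, e.g. a disconnected electrode).
#'
#' @param rec an [recording()].
#' @param z_thresh robust z-score threshold (default 6).
#' @param flat_thresh_uV flatness threshold in microvolts (default 0.5).
#' @param win_s,hop_s segmentation parameters, matching the spectral stage.
#' @param channels channels screened for artifacts. By default the EMG
#'   channel is excluded: large-amplitude muscle bursts are the phenomenon
#'   under study, not artifacts.
#' @return A `segment_mask` with rejected segments' `keep` set to `FALSE`.
#' @export
detect_artifacts <- function(rec, z_thresh = 6, flat_thresh_uV = 0.5,
                             win_s = 2, hop_s = 1,
                             channels = setdiff(rec$channel_labels, "EMG")) {
  stopifnot(inherits(rec, "ecog_recording"))
  check_scalar_num(z_thresh, "z_thresh", lower = 0)
  if (!length(channels)) channels <- rec$channel_labels
  dat <- rec$data[channels, , drop = FALSE]
  mask <- segment_indices(ncol(dat), rec$fs, win_s, hop_s)
  ctr <- apply(dat, 1, median)
  scl <- apply(dat, 1, mad)               # already scaled by 1.4826
  scl[scl == 0] <- Inf                    # flat channel: z undefined, flat rule decides
  for (i in seq_along(mask$starts)) {
    idx <- (mask$starts[i] + 1):(mask$starts[i] + mask$length)
    seg <- dat[, idx, drop = FALSE]
    zmax <- max(abs(seg - ctr) / scl)
    rng <- apply(seg, 1, function(x) diff(range(x)))
    if (zmax > z_thresh || any(rng < flat_thresh_uV)) mask$keep[i] <- FALSE
  }
  mask
}

#' Fraction of segments retained by a mask
#'
#' @param mask a `segment_mask`.
#' @return kept/total in \[0, 1\].
#' @export
retained_fraction <- function(mask) {
  stopifnot(inherits(mask, "segment_mask"))
  if (!length(mask$keep)) stopf("empty segment mask")
  mean(mask$keep)
}
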