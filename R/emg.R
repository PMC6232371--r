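# EMG descriptors over the 1-100 Hz range: spectral (mean and median
# frequency) and amplitude (RMS, ARV) estimators.

#' EMG power spectrum restricted to 1-100 Hz
#'
#' Welch PSD of the EMG channel truncated to the 1-100 Hz analysis range.
#' By default the raw signal is analyzed; set `rectify = TRUE` to analyze
#' the mean-removed rectified signal instead.
#'
#' @param x numeric EMG signal (microvolts).
#' @param fs sampling rate in Hz.
#' @param mask optional `segment_mask`.
#' @param params [spectral_params()].
#' @param rectify analyze `|x|` (mean removed) instead of `x`.
#' @return A `spectral_estimate` whose frequency grid spans 1-100 Hz.
#' @export
emg_spectrum <- function(x, fs, mask = NULL, params = spectral_params(),
                         rectify = FALSE) {
  if (rectify) x <- abs(x) - mean(abs(x))
  est <- welch_psd(x, fs, mask, params, channel = "EMG")
  idx <- which(est$freqs >= 1 - 1e-9 & est$freqs <= 100 + 1e-9)
  est$freqs <- est$freqs[idx]
  est$values <- est$values[idx]
  est
}

#' Mean (centroid) power frequency
#'
#' `MNF = sum(f_i P_i) / sum(P_i)` over the 1-100 Hz bins.
#'
#' @param spec a `spectral_estimate` (typically from [emg_spectrum()]).
#' @return Frequency in Hz.
#' @export
mean_frequency <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  p <- Re(spec$values)
  if (sum(p) <= 0) stopf("mean frequency undefined: zero total power")
  sum(spec$freqs * p) / sum(p)
}

#' Median power frequency
#'
#' The frequency splitting the 1-100 Hz power spectrum into two halves of
#' equal integrated power: the smallest frequency where the cumulative
#' power reaches half the total, linearly interpolated within the crossing
#' bin.
#'
#' @param spec a `spectral_estimate`.
#' @return Frequency in Hz.
#' @export
median_frequency <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  p <- Re(spec$values)
  tot <- sum(p)
  if (tot <= 0) stopf("median frequency undefined: zero total power")
  cum <- cumsum(p)
  half <- tot / 2
  i <- which(cum >= half)[1]
  if (i == 1L) return(spec$freqs[1])
  f0 <- spec$freqs[i - 1]; f1 <- spec$freqs[i]
  c0 <- cum[i - 1]
  f0 + (f1 - f0) * (half - c0) / (cum[i] - c0)
}

masked_samples <- function(x, mask) {
  if (is.null(mask)) return(x)
  starts <- mask$starts[mask$keep]
  if (!length(starts)) stopf("no kept samples")
  idx <- unique(unlist(lapply(starts, function(s) (s + 1):(s + mask$length))))
  x[sort(idx)]
}

#' Root-mean-square amplitude
#'
#' `sqrt(mean(x^2))` over artifact-free samples.
#'
#' @param x numeric signal (microvolts).
#' @param mask optional `segment_mask`; samples inside kept segments are used.
#' @return RMS in microvolts.
#' @export
rms_amplitude <- function(x, mask = NULL) {
  x <- masked_samples(x, mask)
  if (!length(x)) stopf("no kept samples")
  sqrt(mean(x^2))
}

#' Average rectified value
#'
#' `mean(|x|)` over artifact-free samples. Always `<=` RMS (power-mean
#' inequality, equality only for constant `|x|`).
#'
#' @inheritParams rms_amplitude
#' @return ARV in microvolts.
#' @export
arv_amplitude <- function(x, mask = NULL) {
  x <- masked_samples(x, mask)
  if (!length(x)) stopf("no kept samples")
  mean(abs(x))
}

#' All EMG descriptors for one session
#'
#' @param x numeric EMG signal.
#' @param fs sampling rate in Hz.
#' @param mask optional `segment_mask`.
#' @param params [spectral_params()].
#' @param session optional [session_key()].
#' @param rectify passed to [emg_spectrum()].
#' @return One-row data frame: session key fields, `mnf`, `mdf`, `rms`,
#'   `arv`.
#' @export
emg_metrics <- function(x, fs, mask = NULL, params = spectral_params(),
                        session = NULL, rectify = FALSE) {
  spec <- emg_spectrum(x, fs, mask, params, rectify = rectify)
  key <- if (is.null(session))
    data.frame(animal_id = NA, group = NA, day = NA, phase = NA)
  else session_key_df(session)
  cbind(key, data.frame(mnf = mean_frequency(spec),
                        mdf = median_frequency(spec),
                        rms = rms_amplitude(x, mask),
                        arv = arv_amplitude(x, mask)))
}
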