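# Welch auto/cross spectral estimation, band powers, and baseline-percentage
# normalization across recording days.

#' Spectral estimation parameters
#'
#' Welch parameters shared by the PSD, cross-spectral and coherence stages:
#' 2 s windows overlapping 1 s, Hamming taper, per-segment mean removal,
#' one-sided density scaling in uV^2/Hz. The 2 s window fixes the frequency
#' resolution at 0.5 Hz.
#'
#' @param win_s window length in seconds.
#' @param hop_s hop between window starts in seconds (`hop_s <= win_s`).
#' @param taper `"hamming"`, `"hann"` or `"rect"`.
#' @param detrend `"mean"` (remove per-segment mean) or `"none"`.
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(win_s = 2, hop_s = 1,
                            taper = c("hamming", "hann", "rect"),
                            detrend = c("mean", "none")) {
  check_scalar_num(win_s, "win_s", lower = .Machine$double.eps)
  check_scalar_num(hop_s, "hop_s", lower = .Machine$double.eps, upper = win_s)
  structure(list(win_s = win_s, hop_s = hop_s, taper = match.arg(taper),
                 detrend = match.arg(detrend)),
            class = "spectral_params")
}

taper_window <- function(name, n) {
  k <- seq_len(n) - 1
  switch(name,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         rect = rep(1, n),
         stopf("unknown taper '%s'", name))
}

# Shared Welch engine. Returns the segment-averaged one-sided spectrum of
# x (auto, y = NULL) or the cross-spectrum X conj(Y). Density scaling with
# window power correction: integrating the auto-PSD over frequency
# (sum * df) recovers the kept-segment variance.
welch_engine <- function(x, y = NULL, fs, mask, params) {
  win <- mask$length   # segment mask defines the window; params$win_s is used when building one
  starts <- mask$starts[mask$keep]
  if (!length(starts)) stopf("no kept segments to average")
  w <- taper_window(params$taper, win)
  U <- sum(w^2)
  nfreq <- floor(win / 2) + 1
  acc <- complex(nfreq)
  block <- 1024L
  for (b in seq(1, length(starts), by = block)) {
    bs <- starts[b:min(b + block - 1, length(starts))]
    segx <- vapply(bs, function(s) x[(s + 1):(s + win)], numeric(win))
    if (params$detrend == "mean") segx <- sweep(segx, 2, colMeans(segx))
    X <- mvfft(segx * w)[seq_len(nfreq), , drop = FALSE]
    if (is.null(y)) {
      acc <- acc + rowSums(Mod(X)^2)
    } else {
      segy <- vapply(bs, function(s) y[(s + 1):(s + win)], numeric(win))
      if (params$detrend == "mean") segy <- sweep(segy, 2, colMeans(segy))
      Y <- mvfft(segy * w)[seq_len(nfreq), , drop = FALSE]
      acc <- acc + rowSums(X * Conj(Y))
    }
  }
  S <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist for even windows)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (win %% 2 == 0) dbl[nfreq] <- 1
  S <- S * dbl
  list(freqs = (seq_len(nfreq) - 1) * fs / win, S = S, n_segments = length(starts))
}

new_spectral_estimate <- function(freqs, values, n_segments, params, fs,
                                  channels, kind) {
  structure(list(freqs = freqs, values = values, n_segments = n_segments,
                 params = params, fs = fs, channels = channels, kind = kind),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<%s spectrum> %s, %d frequencies (%.2g-%.5g Hz, df=%.2g), %d segment(s)\n",
              x$kind, paste(x$channels, collapse = " x "), length(x$freqs),
              min(x$freqs), max(x$freqs), diff(x$freqs[1:2]), x$n_segments))
  invisible(x)
}

#' Welch power spectral density
#'
#' Averages tapered periodograms over the kept segments of `mask`. The
#' result is a one-sided density in uV^2/Hz: `sum(psd) * df` approximates
#' the kept-segment signal variance (Parseval).
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate in Hz.
#' @param mask optional `segment_mask` from [segment_indices()] or
#'   [detect_artifacts()]; all complete windows kept if `NULL`.
#' @param params [spectral_params()].
#' @param channel label carried into the result.
#' @return A `spectral_estimate` with real non-negative `values`.
#' @export
welch_psd <- function(x, fs, mask = NULL, params = spectral_params(),
                      channel = "x") {
  if (is.null(mask)) mask <- segment_indices(length(x), fs, params$win_s, params$hop_s)
  eng <- welch_engine(x, NULL, fs, mask, params)
  new_spectral_estimate(eng$freqs, pmax(Re(eng$S), 0), eng$n_segments,
                        params, fs, channel, "auto")
}

#' Welch cross-spectral density
#'
#' Segment-averaged one-sided cross-spectrum `X(f) conj(Y(f))`, with the
#' same windowing, masking and density scaling as [welch_psd()] so that
#' auto- and cross-spectra are mutually consistent for coherence.
#'
#' @param x,y equal-length numeric signals.
#' @inheritParams welch_psd
#' @param channels length-2 label vector.
#' @return A `spectral_estimate` with complex `values`.
#' @export
cross_spectral_density <- function(x, y, fs, mask = NULL,
                                   params = spectral_params(),
                                   channels = c("x", "y")) {
  if (length(x) != length(y))
    stopf("x and y must have equal length (%d vs %d)", length(x), length(y))
  if (is.null(mask)) mask <- segment_indices(length(x), fs, params$win_s, params$hop_s)
  eng <- welch_engine(x, y, fs, mask, params)
  new_spectral_estimate(eng$freqs, eng$S, eng$n_segments, params, fs,
                        channels, "cross")
}

#' Canonical frequency-band scheme
#'
#' Delta 0.5-3.5, theta 4-12, beta 13-30, low gamma 30.5-48 and high gamma
#' 52-100 Hz. The 48-52 Hz region is excluded by construction, consistent
#' with 50 Hz mains contamination; no additional notch filtering is applied
#' anywhere in the pipeline.
#'
#' @param bands named list of `c(lower, upper)` Hz intervals, ascending and
#'   non-overlapping.
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(bands = list(delta = c(0.5, 3.5), theta = c(4, 12),
                                     beta = c(13, 30), low_gamma = c(30.5, 48),
                                     high_gamma = c(52, 100))) {
  if (!length(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stopf("bands must be a named list")
  lims <- do.call(rbind, bands)
  if (any(lims[, 2] <= lims[, 1])) stopf("each band needs upper > lower")
  if (any(diff(as.vector(t(lims))) < 0)) stopf("bands must be ascending and non-overlapping")
  structure(bands, class = "band_scheme")
}

band_bin_index <- function(freqs, band) {
  which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
}

#' Band power by trapezoidal integration
#'
#' Integrates a one-sided PSD over the closed band interval (trapezoid rule
#' on the frequency bins falling inside the band, both endpoints included).
#'
#' @param est an auto `spectral_estimate` from [welch_psd()].
#' @param band numeric `c(lower, upper)` in Hz, or a band name resolved in
#'   `scheme`.
#' @param scheme a [band_scheme()] used when `band` is a name.
#' @return Band power in uV^2.
#' @export
band_power <- function(est, band, scheme = band_scheme()) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (is.character(band)) {
    if (!band %in% names(scheme)) stopf("unknown band '%s'", band)
    band <- scheme[[band]]
  }
  if (band[1] < min(est$freqs) - 1e-9 || band[2] > max(est$freqs) + 1e-9)
    stopf("band [%g, %g] outside the frequency grid [%g, %g]",
          band[1], band[2], min(est$freqs), max(est$freqs))
  idx <- band_bin_index(est$freqs, band)
  if (length(idx) < 2L) stopf("band [%g, %g] covers fewer than two frequency bins",
                              band[1], band[2])
  f <- est$freqs[idx]; p <- Re(est$values[idx])
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Band powers for every channel of a recording
#'
#' Convenience wrapper: Welch PSD per channel (shared artifact mask), then
#' [band_power()] for every band of the scheme.
#'
#' @param rec an [recording()].
#' @param mask optional `segment_mask` shared across channels.
#' @param scheme a [band_scheme()].
#' @param params [spectral_params()].
#' @param channels channels to analyze (default: all).
#' @return Data frame: session key fields, `channel`, `band`, `power`.
#' @export
recording_band_powers <- function(rec, mask = NULL, scheme = band_scheme(),
                                  params = spectral_params(),
                                  channels = rec$channel_labels) {
  key <- if (is.null(rec$session))
    data.frame(animal_id = NA, group = NA, day = NA, phase = NA)
  else session_key_df(rec$session)
  do.call(rbind, lapply(channels, function(ch) {
    est <- welch_psd(rec$data[ch, ], rec$fs, mask, params, channel = ch)
    do.call(rbind, lapply(names(scheme), function(b) {
      cbind(key, data.frame(channel = ch, band = b,
                            power = band_power(est, b, scheme)))
    }))
  }))
}

#' Baseline-percentage normalization
#'
#' Expresses each measurement as a percentage of the same animal / channel /
#' band (/ pair) value on the baseline day, matching recording phase:
#' `normalized = 100 * value / baseline_value`.
#'
#' @param records data frame with columns `animal_id`, `group`, `day`,
#'   `phase`, the grouping columns in `by`, and the measurement column
#'   `value_col`.
#' @param baseline_day day index of the baseline (default 0).
#' @param value_col name of the measurement column (default `"power"`).
#' @param by extra grouping columns identifying one longitudinal series
#'   (default `c("channel", "band")`).
#' @return `records` with an added `normalized` column (percent of
#'   baseline).
#' @export
baseline_normalize <- function(records, baseline_day = 0, value_col = "power",
                               by = c("channel", "band")) {
  need <- c("animal_id", "group", "day", "phase", by, value_col)
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records missing column(s): %s", paste(miss, collapse = ", "))
  keycols <- c("animal_id", "group", "phase", by)
  key <- do.call(paste, c(records[keycols], sep = "|"))
  base <- records[records$day == baseline_day, , drop = FALSE]
  if (!nrow(base)) stopf("no baseline (day %d) records present", baseline_day)
  bkey <- do.call(paste, c(base[keycols], sep = "|"))
  if (anyDuplicated(bkey)) stopf("multiple baseline records for the same series")
  bval <- base[[value_col]][match(key, bkey)]
  if (anyNA(bval)) {
    i <- which(is.na(bval))[1]
    stopf("missing baseline record for series %s", key[i])
  }
  if (any(bval == 0))
    stopf("baseline value is zero for series %s; normalization undefined",
          key[which(bval == 0)[1]])
  records$normalized <- 100 * records[[value_col]] / bval
  records
}

#' Assemble a tidy band-power table
#'
#' Binds per-session band-power records into one table with a stable column
#' order, ready for CSV serialization.
#'
#' @param ... data frames (or a single list of them) as produced by
#'   [recording_band_powers()].
#' @return One data frame, columns `animal_id`, `group`, `day`, `phase`,
#'   `channel`, `band`, `power` and, when present, `normalized`.
#' @export
band_power_table <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]]))
    parts <- parts[[1]]
  cols <- c("animal_id", "group", "day", "phase", "channel", "band", "power")
  if (!length(parts))
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  tab <- do.call(rbind, parts)
  keep <- c(cols, intersect("normalized", names(tab)))
  tab <- tab[keep]
  rownames(tab) <- NULL
  tab
}
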