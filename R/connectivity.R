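# Cortico-cortical coherence: magnitude-squared coherence and the imaginary
# part of the coherency, which is insensitive to instantaneous (zero-lag)
# volume-conducted mixing.

#' Magnitude-squared coherence and complex coherency
#'
#' `msc(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))` with segment-averaged Welch
#' spectra; the complex coherency `C_xy = S_xy / sqrt(S_xx S_yy)` is kept so
#' its imaginary part can be examined (volume-conduction rejection). All
#' three spectra share one mask, taper and scaling. With a single averaged
#' segment msc is identically 1; such estimates are flagged `degenerate`.
#'
#' @param x,y equal-length numeric signals.
#' @param fs sampling rate in Hz.
#' @param mask optional `segment_mask`.
#' @param params [spectral_params()].
#' @param pair length-2 channel label vector.
#' @param session optional [session_key()].
#' @return An object of class `coherence_estimate`: `freqs`, `msc`,
#'   `coherency` (complex), `n_segments`, `degenerate`, `pair`, `session`.
#' @export
magnitude_squared_coherence <- function(x, y, fs, mask = NULL,
                                        params = spectral_params(),
                                        pair = c("x", "y"), session = NULL) {
  if (length(x) != length(y))
    stopf("x and y must have equal length (%d vs %d)", length(x), length(y))
  if (is.null(mask)) mask <- segment_indices(length(x), fs, params$win_s, params$hop_s)
  if (!any(mask$keep)) stopf("no kept segments for coherence")
  sxx <- welch_engine(x, NULL, fs, mask, params)
  syy <- welch_engine(y, NULL, fs, mask, params)
  sxy <- welch_engine(x, y, fs, mask, params)
  denom <- sqrt(pmax(Re(sxx$S), 0) * pmax(Re(syy$S), 0))
  coherency <- ifelse(denom > 0, sxy$S / denom, complex(real = 0))
  msc <- Mod(coherency)^2
  over <- msc - 1
  if (any(over > 1e-9))
    warning(sprintf("msc exceeded 1 by %.3g; check inputs", max(over)))
  msc <- pmin(msc, 1)
  degenerate <- sxx$n_segments < 2L
  if (degenerate)
    warning("coherence from a single segment is identically 1 (degenerate)")
  structure(list(freqs = sxx$freqs, msc = msc, coherency = coherency,
                 n_segments = sxx$n_segments, degenerate = degenerate,
                 pair = pair, session = session, params = params, fs = fs),
            class = "coherence_estimate")
}

#' @export
print.coherence_estimate <- function(x, ...) {
  cat(sprintf("<coherence> %s ~ %s, %d segment(s)%s, peak msc %.3f at %.1f Hz\n",
              x$pair[1], x$pair[2], x$n_segments,
              if (x$degenerate) " [degenerate]" else "",
              max(x$msc), x$freqs[which.max(x$msc)]))
  invisible(x)
}

#' Imaginary part of the coherency
#'
#' `Im(C_xy(f))`, in \[-1, 1\]. Instantaneous mixing of a common source
#' produces a real cross-spectrum, so its coherency has zero imaginary part;
#' genuinely lagged coupling does not. Antisymmetric under channel swap.
#'
#' @param est a `coherence_estimate`.
#' @return Numeric vector, one value per frequency.
#' @export
imaginary_coherence <- function(est) {
  stopifnot(inherits(est, "coherence_estimate"))
  Im(est$coherency)
}

#' Band-level coherence summaries
#'
#' Arithmetic mean over the frequency bins inside each band. For the
#' imaginary part the primary summary is the mean magnitude `mean(|Im C|)`
#' (band-level reporting has no sign convention); the signed mean is also
#' available.
#'
#' @param est a `coherence_estimate`.
#' @param scheme a [band_scheme()].
#' @param quantity `"msc"`, `"imag_abs"` or `"imag_signed"`.
#' @return Named numeric vector, one summary per band.
#' @export
band_coherence_summary <- function(est, scheme = band_scheme(),
                                   quantity = c("msc", "imag_abs", "imag_signed")) {
  stopifnot(inherits(est, "coherence_estimate"))
  quantity <- match.arg(quantity)
  vals <- switch(quantity,
                 msc = est$msc,
                 imag_abs = abs(Im(est$coherency)),
                 imag_signed = Im(est$coherency))
  out <- vapply(names(scheme), function(b) {
    idx <- band_bin_index(est$freqs, scheme[[b]])
    if (!length(idx)) stopf("band '%s' covers no frequency bins", b)
    mean(vals[idx])
  }, numeric(1))
  out
}

#' Coherence band summaries for one recording
#'
#' Computes the coherence for each requested channel pair and summarizes
#' per band (msc, mean |Im C| and signed mean Im C).
#'
#' @param rec an [recording()].
#' @param pairs list of length-2 character vectors of channel labels.
#' @param mask optional shared `segment_mask`.
#' @param scheme a [band_scheme()].
#' @param params [spectral_params()].
#' @return Data frame: session key fields, `pair`, `band`, `msc`,
#'   `imag_abs`, `imag_signed`, `n_segments`.
#' @export
recording_coherence <- function(rec, pairs, mask = NULL,
                                scheme = band_scheme(),
                                params = spectral_params()) {
  key <- if (is.null(rec$session))
    data.frame(animal_id = NA, group = NA, day = NA, phase = NA)
  else session_key_df(rec$session)
  do.call(rbind, lapply(pairs, function(p) {
    if (!all(p %in% rec$channel_labels))
      stopf("unknown channel(s) in pair: %s", paste(p, collapse = "~"))
    est <- magnitude_squared_coherence(rec$data[p[1], ], rec$data[p[2], ],
                                       rec$fs, mask, params, pair = p,
                                       session = rec$session)
    cbind(key, data.frame(
      pair = paste(p, collapse = "~"),
      band = names(scheme),
      msc = band_coherence_summary(est, scheme, "msc"),
      imag_abs = band_coherence_summary(est, scheme, "imag_abs"),
      imag_signed = band_coherence_summary(est, scheme, "imag_signed"),
      n_segments = est$n_segments, row.names = NULL))
  }))
}

#' Baseline-percentage normalization of coherence summaries
#'
#' As [baseline_normalize()], applied to per-band coherence summaries; the
#' longitudinal series is identified by (animal, phase, pair, band).
#'
#' @param records data frame as returned by [recording_coherence()] for a
#'   cohort.
#' @param baseline_day baseline day index (default 0).
#' @param value_col which summary to normalize (default `"msc"`).
#' @return `records` with an added `normalized` column.
#' @export
coherence_baseline_normalize <- function(records, baseline_day = 0,
                                         value_col = "msc") {
  baseline_normalize(records, baseline_day = baseline_day,
                     value_col = value_col, by = c("pair", "band"))
}
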