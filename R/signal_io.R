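# Session data model and signal file I/O (CSV and EDF).

#' Session identity
#'
#' Identifies one recording session by animal, experimental group, recording
#' day and injection phase. Day 0 is the baseline (pre-injection) day; days
#' 1-5 are consecutive kainate days. Phase `"pre"` is the short recording
#' before the injection, `"post"` the long recording after it (on the
#' baseline day both phases are uninjected).
#'
#' @param animal_id integer or character animal identifier.
#' @param group experimental group, `"motor-somatosensory"` or
#'   `"motor-parietal"` (which third cortical electrode the animal carries).
#' @param day recording day, 0 (baseline) to 5.
#' @param phase `"pre"` or `"post"`.
#' @return An object of class `session_key`.
#' @export
session_key <- function(animal_id, group = c("motor-somatosensory", "motor-parietal"),
                        day = 0L, phase = c("pre", "post")) {
  group <- match.arg(group)
  phase <- match.arg(phase)
  day <- as.integer(day)
  if (is.na(day) || day < 0L) stopf("'day' must be a non-negative integer")
  structure(list(animal_id = animal_id, group = group, day = day, phase = phase),
            class = "session_key")
}

#' @export
format.session_key <- function(x, ...) {
  sprintf("%s/animal%s/day%d/%s", x$group, x$animal_id, x$day, x$phase)
}

#' @export
print.session_key <- function(x, ...) {
  cat("<session>", format(x), "\n")
  invisible(x)
}

session_key_df <- function(key) {
  data.frame(animal_id = key$animal_id, group = key$group,
             day = key$day, phase = key$phase, stringsAsFactors = FALSE)
}

#' Multi-channel recording
#'
#' Container for one session's uniformly sampled multi-channel signal
#' (channels x samples, microvolts).
#'
#' @param data numeric matrix, channels in rows, samples in columns. Row
#'   names are used as channel labels when `channel_labels` is missing.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel labels.
#' @param session optional [session_key()].
#' @return An object of class `ecog_recording` with elements `data`, `fs`,
#'   `channel_labels`, `session`.
#' @export
recording <- function(data, fs, channel_labels = rownames(data), session = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("'data' must be a numeric channels x samples matrix")
  check_scalar_num(fs, "fs", lower = .Machine$double.eps)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stopf("need one channel label per row (%d labels, %d rows)",
          length(channel_labels), nrow(data))
  if (anyDuplicated(channel_labels))
    stopf("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 session = session),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$session)) cat("  session: ", format(x$session), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `ecog_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("edf", "rec")) "edf" else "csv"
}

#' Read a recording from disk
#'
#' CSV files must have a `time_s` column followed by one column per channel
#' (the layout written by [write_recording()]); the sampling rate is not
#' stored in CSV, so `fs` must be supplied (normally from the cohort
#' manifest). EDF files carry the rate in their header.
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#' @param fs sampling rate in Hz, required for CSV.
#' @param session optional [session_key()] to attach.
#' @return An [recording()] object in microvolt units.
#' @export
read_recording <- function(path, format = guess_format(path), fs = NULL,
                           session = NULL) {
  format <- match.arg(format, c("edf", "csv"))
  if (!file.exists(path)) stopf("recording file not found: %s", path)
  if (format == "csv") {
    if (is.null(fs))
      stopf("CSV recordings carry no sampling rate; supply 'fs' (from the manifest) for %s", path)
    df <- read.csv(path, check.names = FALSE)
    if (!"time_s" %in% names(df))
      stopf("malformed CSV recording (no 'time_s' column): %s", path)
    labels <- setdiff(names(df), "time_s")
    if (length(labels) == 0L) stopf("CSV recording has no channel columns: %s", path)
    if (nrow(df) > 1) {
      dt <- diff(df$time_s[1:2])
      if (abs(dt - 1 / fs) > 0.01 / fs)
        warning(sprintf("time_s step (%.6g s) disagrees with fs=%g Hz in %s",
                        dt, fs, path))
    }
    dat <- t(as.matrix(df[labels]))
    recording(dat, fs = fs, channel_labels = labels, session = session)
  } else {
    read_edf(path, session = session)
  }
}

#' Write a recording to disk
#'
#' CSV is lossless (full double precision); EDF quantizes each channel to 16
#' bits over its own symmetric physical range, so the worst-case error per
#' sample is full-scale/2^15.
#'
#' @param rec an [recording()] object.
#' @param path output path.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = guess_format(path)) {
  stopifnot(inherits(rec, "ecog_recording"))
  format <- match.arg(format, c("edf", "csv"))
  if (ncol(rec$data) == 0L) stopf("refusing to write zero-length recording to %s", path)
  if (format == "csv") {
    df <- data.frame(time_s = (seq_len(ncol(rec$data)) - 1) / rec$fs)
    for (ch in rec$channel_labels) df[[ch]] <- rec$data[ch, ]
    ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                   error = function(e) stopf("failed writing %s: %s", path, conditionMessage(e)))
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

## --- minimal EDF (European Data Format) support -------------------------
## Fixed-layout format: 256-byte ASCII header, 256 ASCII bytes per signal,
## then data records of int16 little-endian samples, channel-sequential
## within each record. Physical unit fixed to microvolts. The true sample
## count is stowed in the 44-byte reserved header field ("NSAMP=") so that
## zero-padding of the final 1-second record round-trips exactly.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

write_edf <- function(rec, path) {
  nch <- nrow(rec$data)
  n <- ncol(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- ceiling(n / fs)
  pm <- apply(rec$data, 1, function(x) max(abs(range(x)), 1e-6))
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_field("0", 8), edf_field("synthetic", 80), edf_field("ecogemg", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (nch + 1), 8), edf_field(paste0("NSAMP=", n), 44),
    edf_field(n_rec, 8), edf_field(1, 8), edf_field(nch, 4))
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field("uV", 8), nch), collapse = ""),
    paste(vapply(sprintf("%.6g", -pm), edf_field, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pm), edf_field, "", width = 8), collapse = ""),
    paste(rep(edf_field(-dig_max, 8), nch), collapse = ""),
    paste(rep(edf_field(dig_max, 8), nch), collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field(fs, 8), nch), collapse = ""),
    paste(rep(edf_field("", 32), nch), collapse = ""))
  writeChar(sig_hdr, con, eos = NULL)
  padded <- matrix(0, nch, n_rec * fs)
  padded[, seq_len(n)] <- rec$data
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- as.integer(pmax(pmin(round(padded[ch, idx] / pm[ch] * dig_max),
                                  dig_max), -dig_max))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path, session = NULL) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) {
    out <- readChar(con, width, useBytes = TRUE)
    if (length(out) == 0L || nchar(out, type = "bytes") < width)
      stopf("malformed EDF header (truncated): %s", path)
    trimws(out)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1L || is.na(n_rec) || n_rec < 1L)
    stopf("malformed EDF header (bad counts): %s", path)
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)               # transducer
  for (i in seq_len(nch)) rd(8)                # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)               # prefiltering
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)               # reserved
  if (any(is.na(spr)) || any(spr <= 0L)) stopf("malformed EDF header (samples/record): %s", path)
  dat <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      if (length(dig) < spr[ch]) stopf("EDF data truncated: %s", path)
      scale <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
      dat[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        pmin_[ch] + (dig - dmin_[ch]) * scale
    }
  }
  if (grepl("^NSAMP=", reserved)) {
    n_true <- as.integer(sub("^NSAMP=", "", reserved))
    if (!is.na(n_true) && n_true <= ncol(dat)) dat <- dat[, seq_len(n_true), drop = FALSE]
  }
  fs <- spr[1] / rec_dur
  recording(dat, fs = fs, channel_labels = labels, session = session)
}

## --- cohort manifest ----------------------------------------------------

#' Load a cohort manifest
#'
#' A manifest is a JSON file with a `fs` field and a `sessions` array; each
#' entry holds the session key fields (`animal_id`, `group`, `day`, `phase`)
#' plus relative paths `signal`, `behavior_scores`, `behavior_intervals`.
#' Paths are resolved relative to the manifest's directory.
#'
#' @param path path to the manifest JSON.
#' @param check_files verify that referenced signal files exist.
#' @return A data frame of class `cohort_manifest` (one row per session)
#'   with attributes `fs` and `missing_files` (character vector of paths
#'   that were referenced but absent).
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(m$sessions) || NROW(m$sessions) == 0L)
    stopf("manifest has no sessions: %s", path)
  df <- as.data.frame(m$sessions, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "phase", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("manifest missing fields: %s", paste(miss, collapse = ", "))
  key <- paste(df$group, df$animal_id, df$day, df$phase, sep = "|")
  if (anyDuplicated(key))
    stopf("duplicate session key in manifest: %s", key[duplicated(key)][1])
  root <- dirname(path)
  resolve <- function(p) ifelse(is.na(p) | p == "", NA_character_, file.path(root, p))
  df$signal <- resolve(df$signal)
  for (col in c("behavior_scores", "behavior_intervals"))
    if (col %in% names(df)) df[[col]] <- resolve(df[[col]])
  missing_files <- character(0)
  if (check_files) {
    refs <- c(df$signal,
              if ("behavior_scores" %in% names(df)) df$behavior_scores,
              if ("behavior_intervals" %in% names(df)) df$behavior_intervals)
    refs <- refs[!is.na(refs)]
    missing_files <- refs[!file.exists(refs)]
    if (any(!file.exists(df$signal)))
      stopf("manifest references missing signal file(s), e.g. %s",
            df$signal[!file.exists(df$signal)][1])
    if (length(missing_files))
      warning(sprintf("%d referenced behavior file(s) missing (see attr 'missing_files')",
                      length(missing_files)))
  }
  structure(df, fs = m$fs %||% NA_real_, missing_files = missing_files,
            class = c("cohort_manifest", "data.frame"))
}
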