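# Synthetic-cohort generator: 1/f background + narrowband oscillations with
# per-day gain profiles, lagged or instantaneous cross-channel coupling,
# line contamination, EMG with tonic/burst activation, behavior annotations
# and artifact spikes -- all with fully known ground truth, so every
# downstream stage has a parameter-recovery test.

#' Oscillatory component specification
#'
#' A narrowband component realized as band-limited Gaussian noise (zero-phase
#' 4th-order Butterworth magnitude response around `center_freq`). Its RMS on
#' day `d` is `amplitude * per_day_gain[d + 1]`.
#'
#' @param name component name (conventionally the band it occupies).
#' @param center_freq center frequency in Hz, inside (0, fs/2).
#' @param bandwidth full bandwidth in Hz.
#' @param amplitude baseline-day component RMS in microvolts.
#' @param per_day_gain non-negative RMS multipliers, baseline day first.
#' @return An object of class `osc_component`.
#' @export
osc_component <- function(name, center_freq, bandwidth, amplitude,
                          per_day_gain = rep(1, 6)) {
  check_scalar_num(center_freq, "center_freq", lower = 1e-9)
  check_scalar_num(bandwidth, "bandwidth", lower = 1e-9)
  check_scalar_num(amplitude, "amplitude", lower = 0)
  if (any(per_day_gain < 0)) stopf("per_day_gain must be non-negative")
  structure(list(name = name, center_freq = center_freq, bandwidth = bandwidth,
                 amplitude = amplitude, per_day_gain = per_day_gain),
            class = "osc_component")
}

#' Cross-channel coupling specification
#'
#' Adds `strength x` band-filtered, lag-delayed copy of the source channel
#' into the target channel. `lag_s = 0` reproduces instantaneous
#' (volume-conduction-like) mixing; lags are rounded to integer samples and
#' the realized lag is recorded in the ground truth.
#'
#' @param source_channel,target_channel channel labels.
#' @param band `c(lower, upper)` Hz interval of the coupled activity.
#' @param strength mixing coefficient in \[0, 1\].
#' @param lag_s lag in seconds (>= 0).
#' @param per_day_gain multipliers on `strength`, baseline day first.
#' @param phase_scope `"post"` (day gains apply to post-injection phases
#'   only; pre phases use the baseline gain) or `"both"`.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(source_channel, target_channel, band = c(13, 30),
                          strength = 0.6, lag_s = 0.01,
                          per_day_gain = rep(1, 6),
                          phase_scope = c("post", "both")) {
  check_scalar_num(strength, "strength", lower = 0, upper = 1)
  check_scalar_num(lag_s, "lag_s", lower = 0)
  if (any(per_day_gain < 0)) stopf("per_day_gain must be non-negative")
  structure(list(source_channel = source_channel, target_channel = target_channel,
                 band = band, strength = strength, lag_s = lag_s,
                 per_day_gain = per_day_gain,
                 phase_scope = match.arg(phase_scope)),
            class = "coupling_spec")
}

#' Background-noise specification
#'
#' 1/f^beta background plus optional mains-line contamination. The line
#' frequency defaults to 50 Hz, which falls inside the 48-52 Hz gap of the
#' default [band_scheme()].
#'
#' @param one_over_f_exponent spectral exponent beta in \[0, 3\].
#' @param noise_rms background RMS in microvolts.
#' @param line_freq mains frequency in Hz, or `NULL` for none.
#' @param line_rms line-component RMS in microvolts.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(one_over_f_exponent = 1, noise_rms = 20,
                       line_freq = 50, line_rms = 10) {
  check_scalar_num(one_over_f_exponent, "one_over_f_exponent", lower = 0, upper = 3)
  check_scalar_num(noise_rms, "noise_rms", lower = 0)
  if (!is.null(line_freq)) check_scalar_num(line_freq, "line_freq", lower = 1e-9)
  check_scalar_num(line_rms, "line_rms", lower = 0)
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 noise_rms = noise_rms, line_freq = line_freq,
                 line_rms = line_rms),
            class = "noise_spec")
}

#' EMG generator specification
#'
#' Band-limited noise inside `passband` whose baseline RMS is `base_rms`.
#' Post-injection sessions on day `d` are scaled by `tonic_gain_per_day[d+1]`
#' (tonic activation); short bursts multiply the envelope by `burst_gain`.
#'
#' @param burst_rate bursts per minute.
#' @param burst_duration_s burst length in seconds.
#' @param tonic_gain_per_day RMS multipliers for post-injection sessions,
#'   baseline day first.
#' @param passband `c(lower, upper)` Hz inside \[1, 100\].
#' @param base_rms baseline EMG RMS in microvolts.
#' @param burst_gain envelope multiplier during bursts.
#' @return An object of class `emg_spec`.
#' @export
emg_spec <- function(burst_rate = 2, burst_duration_s = 1,
                     tonic_gain_per_day = c(1, 1.5, 1.6, 1.4, 1.8, 1.7),
                     passband = c(20, 90), base_rms = 20, burst_gain = 3) {
  check_scalar_num(burst_rate, "burst_rate", lower = 0)
  check_scalar_num(burst_duration_s, "burst_duration_s", lower = 1e-9)
  if (passband[1] < 1 || passband[2] > 100 || passband[2] <= passband[1])
    stopf("passband must lie inside [1, 100] Hz")
  if (any(tonic_gain_per_day < 0)) stopf("tonic_gain_per_day must be non-negative")
  structure(list(burst_rate = burst_rate, burst_duration_s = burst_duration_s,
                 tonic_gain_per_day = tonic_gain_per_day, passband = passband,
                 base_rms = base_rms, burst_gain = burst_gain),
            class = "emg_spec")
}

#' Behavior generator specification
#'
#' Per-day mean dystonia score targets (post-injection phases; pre phases
#' and the baseline day score 0) and active-wake fraction targets for both
#' phases. Default profiles encode the qualitative study trends: dystonia
#' severity peaks on day 3 and falls to a minimum on day 5; post-injection
#' activity drops relative to baseline while pre-injection activity creeps
#' up across days. Within a session, severity rises to a peak around 50 min
#' and then declines.
#'
#' @param score_day_profile per-day mean dystonia score targets (0-4),
#'   baseline day first.
#' @param aw_pre_profile,aw_post_profile per-day active-wake fraction
#'   targets in \[0, 1\], baseline day first.
#' @param n_reviewers number of simulated independent reviewers.
#' @param reviewer_sd SD of the reviewer noise added before rounding to the
#'   integer 0-4 scale (0 = identical reviewers).
#' @param epoch_length_s scoring epoch length in seconds.
#' @param peak_minute within-session minute at which severity peaks.
#' @return An object of class `behavior_spec`.
#' @export
behavior_spec <- function(score_day_profile = c(0, 2.0, 2.6, 3.2, 2.6, 1.4),
                          aw_pre_profile = c(0.35, 0.38, 0.42, 0.45, 0.48, 0.50),
                          aw_post_profile = c(0.35, 0.22, 0.20, 0.18, 0.20, 0.22),
                          n_reviewers = 4, reviewer_sd = 0.5,
                          epoch_length_s = 600, peak_minute = 50) {
  if (any(score_day_profile < 0 | score_day_profile > 4))
    stopf("score_day_profile must lie in [0, 4]")
  if (any(c(aw_pre_profile, aw_post_profile) < 0) ||
      any(c(aw_pre_profile, aw_post_profile) > 1))
    stopf("active-wake fractions must lie in [0, 1]")
  structure(list(score_day_profile = score_day_profile,
                 aw_pre_profile = aw_pre_profile,
                 aw_post_profile = aw_post_profile,
                 n_reviewers = n_reviewers, reviewer_sd = reviewer_sd,
                 epoch_length_s = epoch_length_s, peak_minute = peak_minute),
            class = "behavior_spec")
}

#' Artifact-injection specification
#'
#' Injects brief large-amplitude spikes (multiple of the channel's robust
#' SD) placed so that a known fraction of the 2 s analysis segments is
#' contaminated; affected segment indices are recorded in the ground truth.
#'
#' @param segment_fraction target fraction of analysis segments
#'   contaminated (0 disables injection).
#' @param amplitude_sd spike peak amplitude as a multiple of the channel SD.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(segment_fraction = 0, amplitude_sd = 10) {
  check_scalar_num(segment_fraction, "segment_fraction", lower = 0, upper = 0.6)
  check_scalar_num(amplitude_sd, "amplitude_sd", lower = 0)
  structure(list(segment_fraction = segment_fraction, amplitude_sd = amplitude_sd),
            class = "artifact_spec")
}

default_components <- function() list(
  osc_component("delta", 2, 2.5, 40),
  osc_component("theta", 7, 5, 25),
  osc_component("beta", 20, 10, 12),
  osc_component("low_gamma", 39, 12, 8,
                per_day_gain = c(1, 1.05, 1.1, 1.15, 1.2, 1.25)),
  osc_component("high_gamma", 75, 20, 30,
                per_day_gain = c(1, 1.1, 1.2, 1.3, 1.4, 1.5)))

#' Cohort specification
#'
#' Study-design parameters of a synthetic cohort: two implant groups (the
#' third cortical electrode sits over somatosensory or parietal cortex), 6
#' recording days (baseline + 5 injection days), a short pre-injection and a
#' long post-injection recording per day, at 1 kHz.
#'
#' @param n_animals_per_group animals per group (default 10).
#' @param groups group labels.
#' @param days number of recording days, baseline first (default 6).
#' @param fs sampling rate in Hz (default 1000; must exceed 200 Hz so the
#'   1-100 Hz analysis range is below Nyquist).
#' @param pre_duration_s pre-injection recording length (default 600 s).
#' @param post_duration_s post-injection recording length (default 9000 s).
#' @param seed integer master seed; every session derives its own RNG
#'   stream from (seed, group, animal, day, phase).
#' @param components list of [osc_component()]s shared by all ECoG channels.
#' @param couplings list of [coupling_spec()]s; by default the left motor
#'   cortex drives the third electrode in the beta band with a 10 ms lag,
#'   halved after kainate (post-injection phases of days 1-5).
#' @param noise a [noise_spec()].
#' @param emg an [emg_spec()].
#' @param behavior a [behavior_spec()].
#' @param artifacts an [artifact_spec()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals_per_group = 10,
                        groups = c("motor-somatosensory", "motor-parietal"),
                        days = 6, fs = 1000,
                        pre_duration_s = 600, post_duration_s = 9000,
                        seed = 1,
                        components = default_components(),
                        couplings = NULL,
                        noise = noise_spec(),
                        emg = emg_spec(),
                        behavior = behavior_spec(),
                        artifacts = artifact_spec()) {
  check_scalar_num(fs, "fs", lower = 200 + 1e-9)
  check_scalar_num(pre_duration_s, "pre_duration_s", lower = 2)
  check_scalar_num(post_duration_s, "post_duration_s", lower = 2)
  check_scalar_num(days, "days", lower = 1)
  for (comp in components) {
    if (comp$center_freq >= fs / 2)
      stopf("component '%s' center_freq %g >= Nyquist", comp$name, comp$center_freq)
    if (length(comp$per_day_gain) < days)
      stopf("component '%s' needs at least %d per-day gains", comp$name, days)
  }
  structure(list(n_animals_per_group = n_animals_per_group, groups = groups,
                 days = days, fs = fs, pre_duration_s = pre_duration_s,
                 post_duration_s = post_duration_s, seed = seed,
                 components = components, couplings = couplings,
                 noise = noise, emg = emg, behavior = behavior,
                 artifacts = artifacts),
            class = "cohort_spec")
}

third_channel <- function(group) {
  if (group == "motor-somatosensory") "S1" else "P"
}

default_couplings <- function(group) list(
  coupling_spec("M1_L", third_channel(group), band = c(13, 30),
                strength = 0.6, lag_s = 0.01,
                per_day_gain = c(1, 0.5, 0.5, 0.5, 0.5, 0.5),
                phase_scope = "post"))

#' Generate 1/f^beta background noise
#'
#' Gaussian noise spectrally shaped to `1/f^beta` (flat below 0.5 Hz to
#' avoid the DC divergence), rescaled to `noise_rms`, with an optional
#' mains-line sinusoid at a random phase. Uses the current RNG stream.
#'
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz.
#' @param noise a [noise_spec()].
#' @return Zero-mean numeric vector.
#' @export
generate_background <- function(n_samples, fs, noise = noise_spec()) {
  check_scalar_num(n_samples, "n_samples", lower = 1)
  check_scalar_num(fs, "fs", lower = .Machine$double.eps)
  n <- as.integer(n_samples)
  x <- numeric(n)
  if (noise$noise_rms > 0) {
    w <- rnorm(n)
    beta <- noise$one_over_f_exponent
    if (beta > 0) {
      k <- 0:(n - 1)
      f <- k * fs / n
      f <- pmin(f, fs - f)
      f_floor <- 0.5
      g <- pmax(f, f_floor)^(-beta / 2)
      g[1] <- 0                     # remove DC
      w <- Re(fft(fft(w) * g, inverse = TRUE)) / n
    }
    w <- w - mean(w)
    x <- scale_to_rms(w, noise$noise_rms)
  }
  if (!is.null(noise$line_freq) && noise$line_rms > 0) {
    t <- (0:(n - 1)) / fs
    x <- x + sqrt(2) * noise$line_rms *
      sin(2 * pi * noise$line_freq * t + runif(1, 0, 2 * pi))
  }
  x
}

#' Generate one narrowband oscillatory component
#'
#' Band-pass-filtered Gaussian noise (zero-phase 4th-order Butterworth
#' magnitude response, `center_freq +/- bandwidth/2`), rescaled so the
#' realized RMS equals `amplitude * per_day_gain[day + 1]`.
#'
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz.
#' @param comp an [osc_component()].
#' @param day 0-based day index (baseline = 0).
#' @return Numeric vector.
#' @export
generate_oscillation <- function(n_samples, fs, comp, day = 0) {
  check_scalar_num(n_samples, "n_samples", lower = 1)
  if (comp$center_freq >= fs / 2)
    stopf("center_freq %g >= Nyquist (%g)", comp$center_freq, fs / 2)
  if (day + 1 > length(comp$per_day_gain))
    stopf("day %d outside the per_day_gain profile", day)
  target <- comp$amplitude * comp$per_day_gain[day + 1]
  n <- as.integer(n_samples)
  if (target <= 0) return(numeric(n))
  lo <- max(comp$center_freq - comp$bandwidth / 2, 1e-3)
  hi <- min(comp$center_freq + comp$bandwidth / 2, fs / 2 - 1e-3)
  y <- fd_bandpass(rnorm(n), fs, lo, hi, order = 4)
  scale_to_rms(y, target)
}

#' Apply cross-channel coupling
#'
#' Adds `strength x` band-filtered, integer-sample-delayed copy of the
#' source channel into the target channel. With `lag_s = 0` this is
#' instantaneous mixing: the resulting cross-spectrum is real, so the
#' imaginary coherency stays at its noise floor while the magnitude-squared
#' coherence does not.
#'
#' @param channels named list of equal-length numeric vectors.
#' @param fs sampling rate in Hz.
#' @param spec a [coupling_spec()].
#' @param day 0-based day index selecting the per-day gain.
#' @param phase `"pre"` or `"post"` (interacts with `spec$phase_scope`).
#' @return List with `channels` (modified map) and `realized` (data frame
#'   with the effective strength and realized integer-sample lag).
#' @export
apply_coupling <- function(channels, fs, spec, day = 0, phase = "post") {
  for (lbl in c(spec$source_channel, spec$target_channel))
    if (!lbl %in% names(channels)) stopf("unknown channel '%s' in coupling", lbl)
  gain <- if (spec$phase_scope == "post" && phase != "post") {
    spec$per_day_gain[1]
  } else {
    if (day + 1 > length(spec$per_day_gain))
      stopf("day %d outside the coupling per_day_gain profile", day)
    spec$per_day_gain[day + 1]
  }
  strength <- spec$strength * gain
  lag_samples <- as.integer(round(spec$lag_s * fs))
  realized <- data.frame(source = spec$source_channel,
                         target = spec$target_channel,
                         band_lo = spec$band[1], band_hi = spec$band[2],
                         strength = strength,
                         lag_samples = lag_samples, lag_s = lag_samples / fs)
  if (strength > 0) {
    src <- fd_bandpass(channels[[spec$source_channel]], fs,
                       spec$band[1], spec$band[2], order = 4)
    if (lag_samples > 0) {
      n <- length(src)
      src <- c(numeric(lag_samples), src[seq_len(n - lag_samples)])
    }
    channels[[spec$target_channel]] <-
      channels[[spec$target_channel]] + strength * src
  }
  list(channels = channels, realized = realized)
}

#' Generate behavior annotations for one session
#'
#' Dystonia scores: zero on the baseline day and in pre-injection phases;
#' in post-injection phases the per-epoch "true" severity follows a
#' rise-and-fall time course peaking near `peak_minute`, scaled to the
#' day's target mean, then each simulated reviewer reports
#' `round(true + noise)` clipped to the 0-4 scale. Active-wake intervals:
#' the session is tiled into 1-minute blocks and exactly
#' `round(fraction * n_blocks)` of them are marked active (so the realized
#' AW fraction matches the target up to block rounding), then adjacent
#' blocks are merged into intervals.
#'
#' @param day 0-based day index.
#' @param phase `"pre"` or `"post"`.
#' @param bspec a [behavior_spec()].
#' @param duration_s session duration in seconds.
#' @param session optional [session_key()] to attach.
#' @return A [behavior_track()].
#' @export
generate_behavior <- function(day, phase, bspec = behavior_spec(),
                              duration_s, session = NULL) {
  if (!phase %in% c("pre", "post")) stopf("phase must be 'pre' or 'post'")
  n_epochs <- max(1L, ceiling(duration_s / bspec$epoch_length_s))
  target <- if (phase == "post" && day > 0) bspec$score_day_profile[day + 1] else 0
  if (target > 0) {
    t_min <- (seq_len(n_epochs) - 0.5) * bspec$epoch_length_s / 60
    shape <- (t_min / bspec$peak_minute) * exp(1 - t_min / bspec$peak_minute)
    true_scores <- pmin(4, target * shape / mean(shape))
  } else {
    true_scores <- rep(0, n_epochs)
  }
  # Reviewer disagreement only where there is something to score: normal
  # motor behavior (true severity 0) is unambiguously scored 0.
  scores <- vapply(seq_len(bspec$n_reviewers), function(r) {
    noisy <- round(true_scores + rnorm(n_epochs, 0, bspec$reviewer_sd))
    ifelse(true_scores > 0, pmin(4, pmax(0, noisy)), 0)
  }, numeric(n_epochs))
  scores <- matrix(scores, nrow = n_epochs,
                   dimnames = list(NULL, paste0("reviewer", seq_len(bspec$n_reviewers))))
  frac <- if (phase == "pre") bspec$aw_pre_profile[day + 1] else bspec$aw_post_profile[day + 1]
  n_blocks <- max(1L, floor(duration_s / 60))
  n_active <- round(frac * n_blocks)
  active <- sort(sample.int(n_blocks, n_active))
  iv <- if (length(active)) {
    brk <- c(0, which(diff(active) > 1), length(active))
    do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
      blocks <- active[(brk[i] + 1):brk[i + 1]]
      data.frame(start_s = (blocks[1] - 1) * 60, end_s = blocks[length(blocks)] * 60)
    }))
  } else data.frame(start_s = numeric(0), end_s = numeric(0))
  behavior_track(session, scores, epoch_length_s = bspec$epoch_length_s,
                 aw_intervals = iv, duration_s = duration_s)
}

#' Generate one synthetic session
#'
#' Builds the four-channel recording (M1_L, M1_R, S1 or P, EMG), applies
#' couplings and artifact spikes, draws the behavior annotations, and
#' returns the exact injected ground truth. The RNG stream is derived from
#' `(spec$seed, group, animal, day, phase)`, so any session is reproducible
#' in isolation.
#'
#' @param spec a [cohort_spec()].
#' @param group group label.
#' @param animal 1-based animal index within the group.
#' @param day 0-based day index.
#' @param phase `"pre"` or `"post"`.
#' @return List with `recording`, `behavior` and `truth` (injected
#'   component RMS per channel, realized couplings, artifact segments,
#'   behavior targets).
#' @export
generate_session <- function(spec, group, animal, day, phase) {
  stopifnot(inherits(spec, "cohort_spec"))
  gi <- match(group, spec$groups)
  if (is.na(gi)) stopf("unknown group '%s'", group)
  key <- session_key(animal_id = sprintf("%s%02d", substr(group, 7, 7), animal),
                     group = group, day = day, phase = phase)
  set.seed(session_seed(spec$seed, gi, animal, day, phase))
  dur <- if (phase == "pre") spec$pre_duration_s else spec$post_duration_s
  n <- as.integer(round(dur * spec$fs))
  ecog_labels <- c("M1_L", "M1_R", third_channel(group))
  channels <- list()
  comp_truth <- list()
  for (ch in ecog_labels) {
    x <- generate_background(n, spec$fs, spec$noise)
    for (comp in spec$components) {
      x <- x + generate_oscillation(n, spec$fs, comp, day)
      comp_truth[[length(comp_truth) + 1L]] <- data.frame(
        channel = ch, component = comp$name,
        center_freq = comp$center_freq, bandwidth = comp$bandwidth,
        rms = comp$amplitude * comp$per_day_gain[day + 1])
    }
    channels[[ch]] <- x
  }
  couplings <- spec$couplings %||% default_couplings(group)
  realized <- list()
  for (cp in couplings) {
    res <- apply_coupling(channels, spec$fs, cp, day, phase)
    channels <- res$channels
    realized[[length(realized) + 1L]] <- res$realized
  }
  # EMG: band-limited noise, tonic gain on post days, multiplicative bursts
  emg <- spec$emg
  gain <- if (phase == "post") emg$tonic_gain_per_day[day + 1] else emg$tonic_gain_per_day[1]
  e <- fd_bandpass(rnorm(n), spec$fs, emg$passband[1], emg$passband[2])
  e <- scale_to_rms(e, emg$base_rms * gain)
  n_bursts <- min(stats::rpois(1, emg$burst_rate * dur / 60),
                  floor(dur / (2 * emg$burst_duration_s)))
  if (n_bursts > 0) {
    starts <- sort(runif(n_bursts, 0, dur - emg$burst_duration_s))
    for (s in starts) {
      idx <- (floor(s * spec$fs) + 1):min(n, floor((s + emg$burst_duration_s) * spec$fs))
      e[idx] <- e[idx] * emg$burst_gain
    }
  }
  channels[["EMG"]] <- e
  # Artifact spikes: placed on a 3 s grid of candidate seconds so each spike
  # contaminates exactly two overlapping 2 s segments (hop 1 s).
  art_segments <- integer(0)
  if (spec$artifacts$segment_fraction > 0 && dur >= 9) {
    n_seg <- floor((n - 2 * spec$fs) / spec$fs) + 1
    n_spikes <- round(spec$artifacts$segment_fraction * n_seg / 2)
    slots <- seq(2, floor(dur) - 3, by = 3)
    n_spikes <- min(n_spikes, length(slots))
    if (n_spikes > 0) {
      secs <- sort(sample(slots, n_spikes))
      amp <- spec$artifacts$amplitude_sd * sd(channels[["M1_L"]])
      half <- round(0.01 * spec$fs)  # 20 ms half-sine spike
      for (s in secs) {
        c0 <- as.integer(s * spec$fs + spec$fs / 2)
        idx <- (c0 - half):(c0 + half)
        channels[["M1_L"]][idx] <- channels[["M1_L"]][idx] +
          amp * sin(pi * seq(0, 1, length.out = length(idx)))
      }
      art_segments <- sort(unique(unlist(lapply(secs, function(s)
        pmax(1L, pmin(n_seg, c(s, s + 1L)))))))
    }
  }
  dat <- do.call(rbind, channels)
  rec <- recording(dat, fs = spec$fs, channel_labels = names(channels),
                   session = key)
  beh <- generate_behavior(day, phase, spec$behavior, dur, session = key)
  truth <- list(
    session = session_key_df(key),
    components = do.call(rbind, comp_truth),
    couplings = do.call(rbind, realized),
    artifact_segments = art_segments,
    behavior = list(
      score_target = if (phase == "post" && day > 0) spec$behavior$score_day_profile[day + 1] else 0,
      aw_fraction_target = if (phase == "pre") spec$behavior$aw_pre_profile[day + 1]
      else spec$behavior$aw_post_profile[day + 1]))
  list(recording = rec, behavior = beh, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Iterates [generate_session()] over every (group, animal, day, phase)
#' combination: `n_groups x n_animals x days x 2` sessions. With `out_dir`
#' the sessions are written to disk (signals as CSV or EDF, behavior as
#' CSV, manifest plus ground truth and the spec as JSON) and recordings are
#' not kept in memory; without it everything is returned in memory (only
#' sensible for small specs).
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @param format `"csv"` or `"edf"` signal format when writing.
#' @return List with `sessions` (list of `generate_session()` results, the
#'   `recording` element replaced by its file path when `out_dir` is used),
#'   `truth` (list of per-session ground truths) and `manifest_path`
#'   (or `NULL`).
#' @export
generate_cohort <- function(spec, out_dir = NULL, format = c("csv", "edf")) {
  stopifnot(inherits(spec, "cohort_spec"))
  format <- match.arg(format)
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- list()
  truths <- list()
  manifest_rows <- list()
  for (gi in seq_along(spec$groups)) for (animal in seq_len(spec$n_animals_per_group))
    for (day in 0:(spec$days - 1)) for (phase in c("pre", "post")) {
      ses <- generate_session(spec, spec$groups[gi], animal, day, phase)
      id <- sprintf("%s_a%02d_d%d_%s", gsub("[^a-z]", "", substr(spec$groups[gi], 7, 7)),
                    animal, day, phase)
      truths[[id]] <- ses$truth
      if (write_out) {
        sig <- paste0(id, ".", format)
        scp <- paste0(id, "_scores.csv")
        ivp <- paste0(id, "_aw.csv")
        write_recording(ses$recording, file.path(out_dir, sig), format)
        write_behavior(ses$behavior, file.path(out_dir, scp), file.path(out_dir, ivp))
        manifest_rows[[id]] <- data.frame(
          animal_id = ses$recording$session$animal_id,
          group = spec$groups[gi], day = day, phase = phase,
          duration_s = recording_duration(ses$recording),
          signal = sig, behavior_scores = scp, behavior_intervals = ivp)
        ses$recording <- file.path(out_dir, sig)
        ses$behavior <- NULL
      }
      sessions[[id]] <- ses
    }
  manifest_path <- NULL
  if (write_out) {
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(fs = spec$fs,
                              sessions = do.call(rbind, manifest_rows)),
                         manifest_path, auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(unclass_spec(spec), file.path(out_dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(sessions = sessions, truth = truths, manifest_path = manifest_path)
}

# Strip S3 classes recursively so a spec serializes cleanly to JSON.
unclass_spec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_spec) else x
}
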