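test_that("Welch PSD satisfies Parseval and resolves sinusoids", {
  set.seed(41)
  fs <- 1000
  x <- rnorm(300 * fs)
  est <- welch_psd(x, fs)
  df <- diff(est$freqs[1:2])
  expect_equal(df, 0.5)
  expect_lt(abs(sum(est$values) * df / var(x) - 1), 0.05)
  expect_true(all(est$values >= 0))
  # pure sinusoid: analytic power A^2/2, peak at 10 Hz
  s <- make_sine(10)
  es <- welch_psd(s, fs)
  expect_lt(abs(sum(es$values) * df - 0.5) / 0.5, 0.02)
  expect_equal(es$freqs[which.max(es$values)], 10)
  # all-zero signal
  expect_true(all(welch_psd(numeric(4000), fs)$values == 0))
  # no kept segments
  m <- segment_indices(4000, fs); m$keep[] <- FALSE
  expect_error(welch_psd(rnorm(4000), fs, m), "kept")
})

test_that("PSD scales quadratically with signal amplitude", {
  set.seed(42)
  x <- rnorm(60000)
  e1 <- welch_psd(x, 1000)
  e3 <- welch_psd(3 * x, 1000)
  expect_equal(e3$values, 9 * e1$values, tolerance = 1e-10)
})

test_that("cross-spectral density reduces to the PSD and carries delay phase", {
  set.seed(43)
  x <- rnorm(120000)
  auto <- welch_psd(x, 1000)
  cxx <- cross_spectral_density(x, x, 1000)
  expect_equal(Re(cxx$values), auto$values, tolerance = 1e-10)
  expect_lt(max(abs(Im(cxx$values))), 1e-12)
  cneg <- cross_spectral_density(x, -x, 1000)
  expect_equal(Re(cneg$values), -auto$values, tolerance = 1e-10)
  # delay: phase of S_xy ~ +2 pi f tau (x leads y by tau; tau small enough
  # that the phase stays unwrapped across 5-45 Hz)
  tau_s <- 3 / 1000
  y <- c(numeric(3), x[1:(length(x) - 3)])
  cxy <- cross_spectral_density(x, y, 1000)
  sel <- cxy$freqs >= 5 & cxy$freqs <= 45
  ph <- Arg(cxy$values[sel])
  fit <- coef(lm(ph ~ cxy$freqs[sel]))
  expect_lt(abs(abs(fit[2]) - 2 * pi * tau_s) / (2 * pi * tau_s), 0.02)
  expect_error(cross_spectral_density(x, x[-1], 1000), "equal length")
})

test_that("band powers integrate the PSD over the band scheme", {
  sch <- band_scheme()
  est <- welch_psd(make_sine(10, dur = 60), 1000)
  df <- 0.5
  total <- sum(est$values) * df
  expect_gte(band_power(est, "theta", sch) / total, 0.99)
  # flat PSD = c -> band power = c x width
  flat <- est
  flat$values <- rep(2, length(est$values))
  for (b in names(sch)) {
    width <- diff(sch[[b]])
    expect_equal(band_power(flat, b, sch), 2 * width, tolerance = 1e-9)
  }
  # zero PSD -> 0
  zero <- est; zero$values <- rep(0, length(est$values))
  expect_identical(band_power(zero, "delta", sch), 0)
  expect_error(band_power(est, c(400, 600)), "outside")
  # five bands never exceed the full-range integral (48-52 Hz gap)
  noise_est <- welch_psd(rnorm(60000), 1000)
  bands_sum <- sum(vapply(names(sch), band_power, 1, est = noise_est, scheme = sch))
  expect_lte(bands_sum, band_power(noise_est, c(0.5, 100)) + 1e-9)
})

test_that("baseline normalization expresses measures as percent of day 0", {
  rec <- expand.grid(animal_id = c("a1", "a2"), group = "motor-parietal",
                     day = 0:2, phase = "post", channel = "M1_L",
                     band = c("theta", "beta"), stringsAsFactors = FALSE)
  rec$power <- 2
  rec$power[rec$day == 1] <- 2    # equal to baseline -> 100
  rec$power[rec$day == 2] <- 3    # 3 vs 2 -> 150
  out <- baseline_normalize(rec)
  expect_true(all(out$normalized[out$day == 0] == 100))
  expect_true(all(out$normalized[out$day == 1] == 100))
  expect_true(all(out$normalized[out$day == 2] == 150))
  # normalized % invariant under a per-animal global gain
  rec2 <- rec
  gain <- ifelse(rec2$animal_id == "a1", 4, 0.25)
  rec2$power <- rec2$power * gain
  expect_equal(baseline_normalize(rec2)$normalized, out$normalized)
  # zero baseline and missing baseline are errors
  recz <- rec; recz$power[recz$day == 0] <- 0
  expect_error(baseline_normalize(recz), "zero")
  expect_error(baseline_normalize(rec[rec$day > 0, ]), "baseline")
})

test_that("band power tables are tidy and CSV round-trippable", {
  set.seed(44)
  spec <- cohort_spec(n_animals_per_group = 1, days = 1,
                      pre_duration_s = 4, post_duration_s = 4)
  ses <- generate_session(spec, "motor-parietal", 1, 0, "pre")
  bp <- recording_band_powers(ses$recording,
                              channels = setdiff(ses$recording$channel_labels, "EMG"))
  tab <- band_power_table(bp)
  expect_identical(nrow(tab), 3L * 5L)
  expect_identical(names(tab)[1:7],
                   c("animal_id", "group", "day", "phase", "channel", "band", "power"))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, p, row.names = FALSE)
  expect_equal(read.csv(p), tab, tolerance = 1e-12)
  expect_identical(nrow(band_power_table(list())), 0L)
})
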