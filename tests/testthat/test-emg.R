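test_that("EMG amplitude estimators match analytic sinusoid values", {
  s2 <- make_sine(35, dur = 10, amplitude = 2)
  expect_lt(abs(rms_amplitude(s2) - sqrt(2)), 1e-3)
  s1 <- make_sine(35, dur = 10)
  expect_lt(abs(arv_amplitude(s1) - 2 / pi), 1e-3)
  expect_identical(rms_amplitude(rep(-3, 100)), 3)
  expect_identical(arv_amplitude(rep(-3, 100)), 3)
  expect_identical(rms_amplitude(numeric(100)), 0)
  # masked estimators use kept samples only
  x <- c(rep(1, 2000), rep(100, 2000))
  m <- segment_indices(4000, 1000, 2, 2)
  m$keep <- c(TRUE, FALSE)
  expect_identical(rms_amplitude(x, m), 1)
})

test_that("rms >= arv with equality only for constant magnitude", {
  set.seed(61)
  for (i in 1:200) {
    x <- switch(1 + i %% 4,
                rnorm(500), rt(500, 3), runif(500, -2, 2), make_sine(7, dur = 0.5))
    expect_gte(rms_amplitude(x) + 1e-12, arv_amplitude(x))
  }
  expect_equal(rms_amplitude(rep(2, 50)), arv_amplitude(rep(2, 50)))
})

test_that("EMG spectrum is restricted to 1-100 Hz with the expected shape", {
  set.seed(62)
  sp <- emg_spectrum(make_sine(35), 1000)
  expect_gte(min(sp$freqs), 1)
  expect_lte(max(sp$freqs), 100)
  expect_equal(sp$freqs[which.max(sp$values)], 35)
  # white noise: flat within sampling error (compare band means)
  spw <- emg_spectrum(rnorm(300000), 1000)
  lo <- mean(spw$values[spw$freqs <= 50])
  hi <- mean(spw$values[spw$freqs > 50])
  se <- sd(spw$values) / sqrt(length(spw$values) / 2)
  expect_lt(abs(lo - hi), 3 * se)
  expect_true(all(emg_spectrum(numeric(4000), 1000)$values == 0))
})

test_that("mean and median frequency match their oracles", {
  sp <- emg_spectrum(make_sine(35), 1000)
  expect_lt(abs(mean_frequency(sp) - 35), 0.5)
  expect_lt(abs(median_frequency(sp) - 35), 0.5)
  # flat spectrum: both at the centre of the 1-100 grid
  flat <- sp
  flat$values <- rep(1, length(sp$values))
  expect_lt(abs(mean_frequency(flat) - 50.5), 0.5)
  expect_lt(abs(median_frequency(flat) - 50.5), 0.5)
  # equal peaks at 20 and 60 Hz: centroid at 40, median between the peaks
  two <- sp
  two$values <- rep(0, length(sp$values))
  two$values[sp$freqs == 20] <- 1
  two$values[sp$freqs == 60] <- 1
  expect_lt(abs(mean_frequency(two) - 40), 0.5)
  mdf <- median_frequency(two)
  expect_gte(mdf, 20); expect_lte(mdf, 60)
  # brute-force cumulative-sum oracle: the smallest frequency whose
  # cumulative power reaches half the total is the 20 Hz peak itself
  cum <- cumsum(two$values)
  oracle <- two$freqs[which(cum >= sum(two$values) / 2)[1]]
  expect_equal(mdf, oracle)
  expect_error(mean_frequency(two[c("freqs")]), "spectral_estimate")
  zero <- sp; zero$values <- rep(0, length(sp$values))
  expect_error(mean_frequency(zero), "zero total power")
  expect_error(median_frequency(zero), "zero total power")
})

test_that("spectral EMG metrics are scale invariant, amplitude metrics linear", {
  set.seed(63)
  x <- rnorm(60000)
  sp1 <- emg_spectrum(x, 1000); sp5 <- emg_spectrum(5 * x, 1000)
  expect_equal(mean_frequency(sp1), mean_frequency(sp5), tolerance = 1e-9)
  expect_equal(median_frequency(sp1), median_frequency(sp5), tolerance = 1e-9)
  expect_equal(rms_amplitude(5 * x), 5 * rms_amplitude(x), tolerance = 1e-12)
  expect_equal(arv_amplitude(5 * x), 5 * arv_amplitude(x), tolerance = 1e-12)
})

test_that("shifting the passband upward raises both frequency descriptors", {
  set.seed(64)
  spec_lo <- emg_spec(passband = c(20, 60))
  spec_hi <- emg_spec(passband = c(30, 70))
  s1 <- generate_session(cohort_spec(n_animals_per_group = 1, pre_duration_s = 30,
                                     post_duration_s = 30, emg = spec_lo),
                         "motor-parietal", 1, 1, "post")
  s2 <- generate_session(cohort_spec(n_animals_per_group = 1, pre_duration_s = 30,
                                     post_duration_s = 30, emg = spec_hi),
                         "motor-parietal", 1, 1, "post")
  m1 <- emg_metrics(s1$recording$data["EMG", ], 1000)
  m2 <- emg_metrics(s2$recording$data["EMG", ], 1000)
  expect_gt(m2$mnf, m1$mnf)
  expect_gt(m2$mdf, m1$mdf)
  expect_gte(m1$rms, m1$arv)
})
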