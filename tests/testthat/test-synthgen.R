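test_that("background noise has the requested RMS and spectral slope", {
  set.seed(11)
  # white: direct RMS oracle
  x <- generate_background(2^16, 1000, noise_spec(0, 1, line_freq = NULL))
  expect_lt(abs(sqrt(mean(x^2)) - 1), 0.05)
  # zero amplitude
  expect_identical(generate_background(1000, 1000, noise_spec(1, 0, line_freq = NULL)),
                   numeric(1000))
  # 1/f: least-squares slope of the periodogram over 2-80 Hz
  y <- generate_background(2^16, 1000, noise_spec(1, 1, line_freq = NULL))
  per <- Mod(fft(y))^2
  f <- (0:(2^16 - 1)) * 1000 / 2^16
  idx <- f >= 2 & f <= 80
  slope <- unname(coef(lm(log(per[idx]) ~ log(f[idx])))[2])
  expect_lt(abs(slope - (-1)), 0.15)
  expect_error(generate_background(0, 1000), "n_samples")
})

test_that("oscillatory components realize the per-day RMS and stay in band", {
  set.seed(12)
  comp <- osc_component("hg", 75, 10, 1, per_day_gain = c(1, 1.5, 0))
  # amplitude 1, gain 1.5 -> RMS 1.5 (exact by construction, spec allows 10%)
  y <- generate_oscillation(2^16, 1000, comp, day = 1)
  expect_lt(abs(sqrt(mean(y^2)) - 1.5), 0.15)
  # gain 0 -> zero contribution
  expect_identical(generate_oscillation(1000, 1000, comp, day = 2), numeric(1000))
  # >= 90% of power inside the high-gamma band (periodogram integration)
  est <- welch_psd(y, 1000)
  df <- diff(est$freqs[1:2])
  expect_gte(band_power(est, c(52, 100)) / (sum(est$values) * df), 0.90)
  expect_error(generate_oscillation(1000, 100, comp, 0), "Nyquist")
})

test_that("coupling adds the configured lagged band-limited source", {
  set.seed(13)
  n <- 60000
  ch <- list(A = rnorm(n), B = rnorm(n))
  # strength 0 -> unchanged
  res <- apply_coupling(ch, 1000, coupling_spec("A", "B", strength = 0,
                                                per_day_gain = 1, phase_scope = "both"))
  expect_identical(res$channels, ch)
  # unknown label
  expect_error(apply_coupling(ch, 1000, coupling_spec("A", "nope")), "unknown channel")
  # realized lag is integer samples
  res2 <- apply_coupling(ch, 1000, coupling_spec("A", "B", strength = 0.5,
                                                 lag_s = 0.0126, per_day_gain = 1,
                                                 phase_scope = "both"))
  expect_identical(res2$realized$lag_samples, 13L)
  expect_false(identical(res2$channels$B, ch$B))
  expect_identical(res2$channels$A, ch$A)
})

test_that("generated behavior matches its targets", {
  set.seed(14)
  # baseline day: normal motor behavior scores 0 for every reviewer
  tr0 <- generate_behavior(0, "post", behavior_spec(), 9000)
  expect_true(all(tr0$scores == 0))
  # AW fraction 0.2 over 150 min -> intervals summing to 30 +/- 2 min
  bs <- behavior_spec(aw_post_profile = rep(0.2, 6))
  tr <- generate_behavior(1, "post", bs, 9000)
  aw_min <- aw_percent(tr) * 9000 / 100 / 60
  expect_lt(abs(aw_min - 30), 2)
  # reviewer noise 0 -> identical reviewers
  bs0 <- behavior_spec(reviewer_sd = 0)
  tr2 <- generate_behavior(3, "post", bs0, 9000)
  expect_true(all(tr2$scores == tr2$scores[, 1]))
  expect_error(generate_behavior(1, "mid", duration_s = 600), "phase")
})

test_that("cohort generation is deterministic with complete ground truth", {
  spec <- cohort_spec(n_animals_per_group = 1, days = 2,
                      pre_duration_s = 4, post_duration_s = 6)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(lapply(g1$sessions, function(s) s$recording$data),
                   lapply(g2$sessions, function(s) s$recording$data))
  expect_identical(lapply(g1$sessions, function(s) s$behavior$scores),
                   lapply(g2$sessions, function(s) s$behavior$scores))
  # session count = groups x animals x days x phases
  expect_length(g1$sessions, 2 * 1 * 2 * 2)
  # every injected component and coupling appears in the truth
  for (tr in g1$truth) {
    expect_setequal(unique(tr$components$component),
                    vapply(spec$components, `[[`, "", "name"))
    expect_equal(nrow(tr$couplings), 1)
  }
  # group-appropriate channel labels
  labs <- lapply(g1$sessions, function(s) s$recording$channel_labels)
  expect_true(all(vapply(labs[1:4], function(l) "S1" %in% l, TRUE)))
  expect_true(all(vapply(labs[5:8], function(l) "P" %in% l, TRUE)))
})

test_that("independent components add their variances", {
  set.seed(15)
  n <- 2^16
  parts <- list(
    generate_background(n, 1000, noise_spec(1, 2, line_freq = NULL)),
    generate_oscillation(n, 1000, osc_component("t", 7, 5, 1.5), 0),
    generate_oscillation(n, 1000, osc_component("hg", 75, 20, 1), 0))
  total <- Reduce(`+`, parts)
  expect_lt(abs(var(total) - sum(vapply(parts, var, 1))) / var(total), 0.05)
})
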