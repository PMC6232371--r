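# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s] (got %s)", name, lower, upper, x)
  invisible(x)
}

# Deterministic 31-bit stream seed from a session identity, so every session
# is reproducible on its own without generating the rest of the cohort.
# Multipliers kept small enough that the product stays exact in doubles.
session_seed <- function(seed, group_index, animal, day, phase) {
  phase_idx <- match(phase, c("pre", "post"))
  h <- (abs(seed) %% 2147483647) * 7919 +
    group_index * 104729 + animal * 9973 + day * 227 + phase_idx * 31
  as.integer(h %% 2147483647L)
}

# Zero-phase band-pass: 4th-order Butterworth magnitude response applied in
# the frequency domain. Stable at arbitrarily narrow relative bandwidths
# (where the polynomial time-domain form of the same filter diverges).
fd_bandpass <- function(x, fs, lower, upper, order = 4) {
  stopifnot(lower > 0, upper > lower, upper < fs / 2)
  n <- length(x)
  if (n == 0L) return(x)
  k <- 0:(n - 1)
  f <- k * fs / n
  f <- pmin(f, fs - f)            # absolute frequency of each FFT bin
  bw <- upper - lower
  w2 <- lower * upper
  # |H|^2 = 1 / (1 + ((f^2 - w0^2) / (f bw))^(2 order)); H(0) = 0
  ratio <- ifelse(f > 0, (f^2 - w2) / (f * bw), Inf)
  H <- 1 / sqrt(1 + ratio^(2 * order))
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

rms <- function(x) sqrt(mean(x^2))

# Rescale a sequence to a target RMS; zero target or degenerate input -> zeros.
scale_to_rms <- function(x, target) {
  if (target <= 0) return(numeric(length(x)))
  r <- rms(x)
  if (r == 0) return(x)
  x * (target / r)
}
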