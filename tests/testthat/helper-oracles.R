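# Independent oracles used across test files.

# Mann-Whitney U of x against y: pairs with x > y (ties count half).
u_statistic <- function(x, y) {
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), 1))
}

# Exact two-sided p by full enumeration of all assignments of the pooled
# values into the two groups.
mw_brute_force_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  sel <- utils::combn(length(pooled), nx)
  us <- apply(sel, 2, function(s) u_statistic(pooled[s], pooled[-s]))
  u <- u_statistic(x, y)
  lo <- mean(us <= u)
  hi <- mean(us >= u)
  min(1, 2 * min(lo, hi))
}

# One-way ANOVA F from explicit sums of squares.
anova_f_oracle <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  (ssb / (k - 1)) / (ssw / (length(y) - k))
}

# Friedman chi-square from the rank formula (no ties).
friedman_oracle <- function(mat) {
  r <- t(apply(mat, 1, rank))
  n <- nrow(mat); k <- ncol(mat)
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

make_sine <- function(freq, fs = 1000, dur = 300, amplitude = 1) {
  amplitude * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs)
}
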