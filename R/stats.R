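# Statistical battery: normality routing, day-wise group comparisons
# (parametric and rank-based, with vs-control families), and
# behavior-signal correlations. Thin, uniformly shaped wrappers around the
# base R tests; comparisons against a control are Holm-adjusted t tests or
# Bonferroni-adjusted rank-sum tests (labelled approximations of the
# classical Dunnett / Dunn procedures, whose exact critical values need
# multivariate-t tables).

comparison_row <- function(test, statistic, df1 = NA, df2 = NA, p_value,
                           comparison = "", adjusted = FALSE, note = "") {
  data.frame(test = test, statistic = statistic, df1 = df1, df2 = df2,
             p_value = p_value, comparison = comparison,
             adjusted = adjusted, note = note, stringsAsFactors = FALSE)
}

#' Normality check for test routing
#'
#' Shapiro-Wilk at `alpha`; used to route day-wise comparisons to the
#' parametric or the rank-based branch. Constant samples (undefined W) are
#' routed to the rank branch with a warning.
#'
#' @param x numeric sample, `n >= 3`.
#' @param alpha decision level (default 0.05).
#' @return List with `normal` (logical), `statistic`, `p_value`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  if (length(x) < 3) stopf("normality check needs n >= 3 (got %d)", length(x))
  if (sd(x) == 0) {
    warning("constant sample: normality undefined, routing to rank tests")
    return(list(normal = FALSE, statistic = NA_real_, p_value = NA_real_))
  }
  sw <- shapiro.test(x)
  list(normal = unname(sw$p.value >= alpha), statistic = unname(sw$statistic),
       p_value = unname(sw$p.value))
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA: `F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom (via [stats::oneway.test()] with
#' equal variances). Degenerate inputs with zero within-group variance and
#' equal means return `F = 0, p = 1` with a warning.
#'
#' @param groups list of numeric samples, each `n >= 2`.
#' @return One-row comparison data frame (`test`, `statistic`, `df1`,
#'   `df2`, `p_value`, ...).
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2) stopf("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2)) stopf("each group needs n >= 2")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups); N <- length(y)
  if (all(vapply(groups, sd, 1) == 0)) {
    if (sd(vapply(groups, mean, 1)) == 0) {
      warning("zero variance everywhere: F defined as 0")
      return(comparison_row("oneway_anova", 0, k - 1, N - k, 1))
    }
    return(comparison_row("oneway_anova", Inf, k - 1, N - k, 0))
  }
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  comparison_row("oneway_anova", unname(ow$statistic),
                 unname(ow$parameter[1]), unname(ow$parameter[2]),
                 unname(ow$p.value))
}

#' Friedman rank test
#'
#' Rank-based test for consistent condition effects across subjects
#' (within-animal day effects), chi-square statistic on `k - 1` df with
#' average-rank tie correction (via [stats::friedman.test()]).
#'
#' @param mat numeric matrix, subjects in rows, conditions in columns; no
#'   missing cells.
#' @return One-row comparison data frame.
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stopf("friedman_test requires complete blocks (no NA)")
  if (nrow(mat) < 2 || ncol(mat) < 2) stopf("need >= 2 subjects and >= 2 conditions")
  fr <- friedman.test(mat)
  comparison_row("friedman", unname(fr$statistic), unname(fr$parameter), NA,
                 unname(fr$p.value))
}

#' Mann-Whitney rank-sum test
#'
#' U statistic (number of (x, y) pairs with x > y, ties counted half) and
#' two-sided p: exact by enumeration when `n_x + n_y <= 12` without ties,
#' normal approximation with tie correction otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   distribution.
#' @return One-row comparison data frame; `statistic` is U.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- !ties && (length(x) + length(y) <= 12)
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  comparison_row("mann_whitney", unname(wt$statistic), NA, NA,
                 unname(wt$p.value),
                 note = if (exact) "exact enumeration" else "normal approximation")
}

#' Comparisons of every group against a control
#'
#' Family of each non-control group vs the control group, with family-wise
#' adjustment: `"holm_t"` = Welch t tests with Holm adjustment (parametric
#' branch), `"dunn_bonferroni"` = rank-sum tests with Bonferroni adjustment
#' (rank branch). Both are labelled approximations of Dunnett's and Dunn's
#' classical procedures.
#'
#' @param groups named or unnamed list of numeric samples.
#' @param control_index index of the control group (default 1, e.g. the
#'   baseline day).
#' @param method `"holm_t"` or `"dunn_bonferroni"`.
#' @return Comparison data frame, one row per non-control group, with
#'   adjusted p-values and `adjusted = TRUE`.
#' @export
control_comparisons <- function(groups, control_index = 1,
                                method = c("holm_t", "dunn_bonferroni")) {
  method <- match.arg(method)
  if (length(groups) < 2) stopf("need at least two groups")
  if (control_index < 1 || control_index > length(groups))
    stopf("invalid control index %s", control_index)
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  ctrl <- groups[[control_index]]
  others <- setdiff(seq_along(groups), control_index)
  rows <- lapply(others, function(i) {
    if (method == "holm_t") {
      lbl <- sprintf("%s vs %s", nm[i], nm[control_index])
      tt <- tryCatch(t.test(groups[[i]], ctrl), error = function(e) NULL)
      if (is.null(tt)) {  # both samples constant: t undefined
        same <- mean(groups[[i]]) == mean(ctrl)
        comparison_row("t_vs_control", if (same) 0 else Inf, NA, NA,
                       if (same) 1 else 0, comparison = lbl)
      } else {
        comparison_row("t_vs_control", unname(tt$statistic),
                       unname(tt$parameter), NA, unname(tt$p.value),
                       comparison = lbl)
      }
    } else {
      wt <- suppressWarnings(wilcox.test(groups[[i]], ctrl))
      comparison_row("ranksum_vs_control", unname(wt$statistic), NA, NA,
                     unname(wt$p.value),
                     comparison = sprintf("%s vs %s", nm[i], nm[control_index]))
    }
  })
  out <- do.call(rbind, rows)
  out$p_value <- p.adjust(out$p_value,
                          method = if (method == "holm_t") "holm" else "bonferroni")
  out$adjusted <- TRUE
  out$note <- sprintf("%s-adjusted vs-control family (Dunnett/Dunn approximation)",
                      if (method == "holm_t") "Holm" else "Bonferroni")
  out
}

#' Pearson correlation with linear fit
#'
#' Pearson `r` with two-sided p from the t transform on `n - 2` df, plus the
#' least-squares slope and intercept of `y` on `x`.
#'
#' @param x,y numeric vectors, `n >= 3`, both non-constant.
#' @return One-row data frame: `n`, `r`, `p_value`, `slope`, `intercept`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("correlation needs n >= 3 (got %d)", length(x))
  if (sd(x) == 0 || sd(y) == 0) stopf("correlation undefined for constant input")
  ct <- cor.test(x, y, method = "pearson")
  fit <- coef(lm(y ~ x))
  data.frame(n = length(x), r = unname(ct$estimate), p_value = unname(ct$p.value),
             slope = unname(fit[2]), intercept = unname(fit[1]))
}

#' Behavior-signal correlations by stratum
#'
#' Joins a per-session signal table (band power or coherence summaries)
#' with a per-session behavior table and computes one Pearson correlation
#' per stratum (e.g. per band, or per day x band). Strata with `n < 3` or
#' zero variance on either side (e.g. every animal scoring 4 that day) are
#' reported as undefined (`NA` r/p) rather than dropped.
#'
#' @param signal data frame with the session key columns, the `strata`
#'   columns and `value_col`.
#' @param behavior data frame with the session key columns and
#'   `behavior_col` (e.g. per-session mean dystonia score or AW%).
#' @param value_col signal measurement column name.
#' @param behavior_col behavior measurement column name.
#' @param strata columns of `signal` defining one correlation each.
#' @param keys join keys (default animal/group/day/phase).
#' @return Data frame: strata columns, `n`, `r`, `p_value`, `slope`,
#'   `intercept`, `note`.
#' @export
correlate_behavior_signal <- function(signal, behavior, value_col,
                                      behavior_col = "mean_score",
                                      strata = "band",
                                      keys = c("animal_id", "group", "day", "phase")) {
  joined <- merge(signal, behavior[c(keys, behavior_col)], by = keys)
  if (!nrow(joined)) {
    warning("empty join between signal and behavior tables")
    return(data.frame())
  }
  parts <- split(joined, joined[strata], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    id <- d[1, strata, drop = FALSE]
    x <- d[[behavior_col]]; y <- d[[value_col]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      cbind(id, data.frame(n = sum(ok), r = NA_real_, p_value = NA_real_,
                           slope = NA_real_, intercept = NA_real_,
                           note = if (sum(ok) >= 3) "zero variance" else "n < 3"))
    } else {
      cbind(id, pearson_correlation(x, y), note = "")
    }
  }))
  rownames(out) <- NULL
  out
}
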