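# Normality-gated two-sample comparisons with effect sizes, producing the
# per-variable group-comparison table (means +/- SD, test, p, r, percent
# difference).

#' Shapiro-Wilk normality gate
#'
#' Both samples are tested with Shapiro-Wilk; the comparison is routed to
#' the t-test only if both pass at `alpha`, and to the Mann-Whitney U test
#' otherwise.
#'
#' @param sample_a,sample_b numeric vectors, each n >= 3.
#' @param alpha significance level (default 0.05).
#' @return `"normal"` or `"not_normal"`.
#' @export
normality_gate <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 3L || length(sample_b) < 3L) {
    stop("each sample needs n >= 3 for Shapiro-Wilk", call. = FALSE)
  }
  # constant samples: Shapiro-Wilk is undefined; treat as non-normal
  if (stats::sd(sample_a) == 0 || stats::sd(sample_b) == 0) return("not_normal")
  pa <- stats::shapiro.test(sample_a)$p.value
  pb <- stats::shapiro.test(sample_b)$p.value
  if (pa > alpha && pb > alpha) "normal" else "not_normal"
}

#' Effect size r from a t statistic
#'
#' r = sqrt(t^2 / (t^2 + df)); monotone in |t| and bounded in \[0, 1).
#'
#' @param t_stat t statistic. @param df degrees of freedom (>= 1).
#' @return effect size r (magnitude).
#' @export
effect_size_from_t <- function(t_stat, df) {
  stopifnot(df >= 1)
  sqrt(t_stat^2 / (t_stat^2 + df))
}

#' Effect size r from a Z statistic
#'
#' r = |Z| / sqrt(N), with N the total number of observations.
#'
#' @param z_stat Z statistic. @param n_total total sample size (>= 2).
#' @return effect size r (magnitude).
#' @export
effect_size_from_z <- function(z_stat, n_total) {
  stopifnot(n_total >= 2)
  abs(z_stat) / sqrt(n_total)
}

# Mann-Whitney U with tie-corrected normal approximation Z; exact
# two-sided p (via the Wilcoxon distribution) when both groups are small
# and there are no ties, asymptotic otherwise.
mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) (u1 - mu) / sqrt(sigma2) else 0
  exact_ok <- n1 <= 8 && n2 <= 8 && !any(duplicated(c(a, b)))
  p <- if (exact_ok) {
    stats::wilcox.test(a, b, exact = TRUE)$p.value
  } else if (sigma2 > 0) {
    2 * stats::pnorm(-abs(z))
  } else 1
  list(u = u1, z = z, p = min(p, 1))
}

#' Compare two groups with a normality-gated test
#'
#' Runs the Shapiro-Wilk gate, then either an independent-samples pooled-
#' variance t-test (both samples normal) or a Mann-Whitney U test. Effect
#' size r comes from the matching transformation: sqrt(t^2/(t^2+df)) for
#' the t path, |Z|/sqrt(N) for the U path. The percent difference is the
#' symmetrized statistic on the two group means.
#'
#' @param a,b numeric samples, each n >= 3.
#' @param variable variable name carried into the output.
#' @param alpha gate level for Shapiro-Wilk.
#' @return a list of class `group_comparison`: `variable`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `test` (`"t"` or `"mann_whitney"`), `statistic`,
#'   `p_value`, `effect_size_r`, `percent_difference`.
#' @export
compare_groups <- function(a, b, variable = "value", alpha = 0.05) {
  gate <- normality_gate(a, b, alpha)
  if (gate == "normal") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      stop("zero variance in both groups: t-test undefined", call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    test <- "t"
    stat <- unname(tt$statistic)
    p <- tt$p.value
    r <- effect_size_from_t(stat, unname(tt$parameter))
  } else {
    mw <- mann_whitney(a, b)
    test <- "mann_whitney"
    stat <- mw$u
    p <- mw$p
    r <- effect_size_from_z(mw$z, length(a) + length(b))
  }
  pd <- if (mean(a) + mean(b) != 0) {
    symmetrized_percent_difference(mean(a), mean(b))
  } else NA_real_
  structure(list(variable = variable,
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 test = test, statistic = stat, p_value = p,
                 effect_size_r = r, percent_difference = pd),
            class = "group_comparison")
}

#' Group-comparison summary table
#'
#' One gated comparison per variable, in the column order given, producing
#' a table of group means +/- SD, test used, p value, effect size r and
#' symmetrized percent difference. Variables with missing values or fewer
#' than 3 observations in either group are skipped with a message.
#'
#' @param data data.frame of per-subject variables plus a group column.
#' @param group_col name of the group column (two levels; the first level
#'   in order of appearance is group A).
#' @param variables variables to compare (default: all numeric columns
#'   except the group column).
#' @return a data.frame, one row per variable.
#' @export
summary_table <- function(data, group_col = "cohort", variables = NULL) {
  stopifnot(group_col %in% names(data))
  g <- data[[group_col]]
  lev <- unique(g)
  if (length(lev) != 2L) stop("group column must have exactly two levels", call. = FALSE)
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
    variables <- setdiff(variables, group_col)
  }
  rows <- list()
  for (v in variables) {
    a <- data[[v]][g == lev[1]]
    b <- data[[v]][g == lev[2]]
    if (anyNA(a) || anyNA(b) || length(a) < 3L || length(b) < 3L) {
      message("skipping variable with missing data or n < 3: ", v)
      next
    }
    cmp <- compare_groups(a, b, variable = v)
    rows[[v]] <- data.frame(
      variable = v, mean_a = cmp$mean_a, sd_a = cmp$sd_a,
      mean_b = cmp$mean_b, sd_b = cmp$sd_b, test = cmp$test,
      statistic = cmp$statistic, p_value = cmp$p_value,
      effect_size_r = cmp$effect_size_r,
      percent_difference = cmp$percent_difference,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
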