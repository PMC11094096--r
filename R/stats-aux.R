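#' Assumption-guided two-group comparison
#'
#' Routes a two-sample comparison the way slice-physiology studies commonly
#' do: if both samples pass Shapiro-Wilk and Anderson-Darling normality
#' tests (p > alpha each) and the variance-equality F-test passes, an
#' unpaired two-sided Student's t test is used; otherwise the Mann-Whitney
#' U test. (Anderson-Darling requires n >= 8; below that only Shapiro-Wilk
#' is consulted.) The report records the route taken and the assumption
#' p-values.
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param alpha level for the assumption checks.
#' @return An object of class `"stat_report"`: list with `test_name`,
#'   `statistic`, `p_value`, `group_summaries` (data.frame n, mean, sem),
#'   `assumptions` (normality and variance p-values), `route`.
#' @export
select_two_group_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 observations per group")
  norm_p <- function(x) {
    sw <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
    ad <- if (length(x) >= 8L)
      tryCatch(nortest::ad.test(x)$p.value, error = function(e) 0)
    else NA_real_
    c(shapiro = sw, anderson_darling = ad)
  }
  na <- norm_p(a); nb <- norm_p(b)
  normal <- all(stats::na.omit(c(na, nb)) > alpha)
  var_p <- tryCatch(stats::var.test(a, b)$p.value, error = function(e) 0)
  parametric <- normal && var_p > alpha
  if (parametric) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    nm <- "Student t (unpaired, two-sided)"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    nm <- "Mann-Whitney U"
  }
  structure(list(test_name = nm,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 group_summaries = data.frame(
                   group = c("a", "b"), n = c(length(a), length(b)),
                   mean = c(mean(a), mean(b)),
                   sem = c(stats::sd(a) / sqrt(length(a)),
                           stats::sd(b) / sqrt(length(b)))),
                 assumptions = list(normality_a = na, normality_b = nb,
                                    variance_f_p = var_p),
                 route = if (parametric) "t" else "mann-whitney"),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  invisible(x)
}

#' Sequential rank-based multiple-comparison correction
#'
#' The sequential rule in which the most significant of N p-values is
#' multiplied by N, the second most significant by N-1, the third by N-2,
#' and so on, each capped at 1. Corrected values are returned in the
#' original input order. (The rule is a published variant of the
#' Holm-Bonferroni step-down procedure, applied here exactly as the
#' multiply-by-rank recipe, without additional monotonicity enforcement.)
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return corrected p-values, same order as the input.
#' @export
holm_variant_correction <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pvals)
  o <- order(pvals)
  corrected <- numeric(n)
  corrected[o] <- pmin(1, pvals[o] * (n - seq_len(n) + 1L))
  corrected
}

#' Two-way fixed-effects ANOVA with Bonferroni post-hoc comparisons
#'
#' Standard two-way ANOVA (main effects + interaction, sums of squares via
#' `stats::aov`) followed by Bonferroni-adjusted pairwise comparisons of
#' factor A within each level of factor B.
#'
#' @param data data.frame containing the response and both factors.
#' @param response,factor_a,factor_b column names.
#' @return list with `anova_table` (data.frame term, df, sum_sq, F,
#'   p_value), `posthoc` (data.frame of within-level pairwise comparisons,
#'   Bonferroni-corrected), `fit`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  d <- data.frame(y = data[[response]],
                  A = factor(data[[factor_a]]),
                  B = factor(data[[factor_b]]))
  if (any(table(d$A, d$B) == 0L))
    stop("empty cells in the A x B design")
  fit <- stats::aov(y ~ A * B, data = d)
  an <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(an)), df = an[["Df"]],
                    sum_sq = an[["Sum Sq"]], F = an[["F value"]],
                    p_value = an[["Pr(>F)"]])
  ph <- do.call(rbind, lapply(levels(d$B), function(bl) {
    sub <- d[d$B == bl, ]
    if (nlevels(droplevels(sub$A)) < 2L) return(NULL)
    pt <- suppressWarnings(
      stats::pairwise.t.test(sub$y, sub$A, p.adjust.method = "none"))
    m <- pt$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(level_b = bl,
               group1 = rownames(m)[idx[, 1]], group2 = colnames(m)[idx[, 2]],
               p_raw = m[idx])
  }))
  if (!is.null(ph)) ph$p_bonferroni <- pmin(1, ph$p_raw * nrow(ph))
  list(anova_table = tab, posthoc = ph, fit = fit)
}

# exact two-sample two-sided t-test power via the noncentral t distribution
.t_power <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Minimal per-group sample size for a two-sample t test
#'
#' Smallest integer n >= 2 such that a two-sided two-sample t test at level
#' `alpha` has power at least `power` against a standardized effect
#' d = `effect_pct` / `sd_pct` (exact noncentral-t power).
#'
#' @param effect_pct expected effect size in percent of the control
#'   response.
#' @param sd_pct response standard deviation in the same percent units.
#' @param power target power.
#' @param alpha two-sided significance level.
#' @return list with `n_per_group`, `achieved_power`, `cohens_d`.
#' @export
power_sample_size <- function(effect_pct, sd_pct, power = 0.8,
                              alpha = 0.05) {
  if (sd_pct <= 0) stop("sd_pct must be positive")
  if (!(power > 0 && power < 1)) stop("power must be in (0, 1)")
  if (effect_pct == 0) stop("no finite sample size for a zero effect")
  d <- abs(effect_pct) / sd_pct
  n <- 2L
  while (.t_power(n, d, alpha) < power) {
    n <- n + 1L
    if (n > 1e6) stop("no attainable sample size below 1e6")
  }
  list(n_per_group = n, achieved_power = .t_power(n, d, alpha), cohens_d = d)
}

#' Discrimination index for novel object recognition
#'
#' `DI = 100 * (t_novel - t_familiar) / (t_novel + t_familiar)`, the
#' difference of the novel and familiar exploration-time fractions in
#' percent; +100 = only the novel object explored, 0 = no preference.
#'
#' @param t_novel,t_familiar exploration times in s (vectorized).
#' @return DI in \[-100, 100\].
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  total <- t_novel + t_familiar
  if (any(total <= 0)) stop("total exploration time must be positive")
  100 * (t_novel - t_familiar) / total
}

#' Normalize an analyte amount to total protein
#'
#' @param analyte_pg analyte amount in pg (values in ng can be passed with
#'   `units = "ng"` and are converted). `NA` (below detection) propagates.
#' @param protein_mg total protein in mg.
#' @param units units of `analyte_pg`.
#' @return analyte per protein, pg/mg.
#' @export
normalize_to_protein <- function(analyte_pg, protein_mg,
                                 units = c("pg", "ng")) {
  units <- match.arg(units)
  if (any(protein_mg <= 0)) stop("protein amount must be positive")
  if (units == "ng") analyte_pg <- analyte_pg * 1000
  analyte_pg / protein_mg
}
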