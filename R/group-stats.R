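#' Two-sample group comparison with pooled-variance t and Cohen's d
#'
#' Compares two groups on a per-observation metric. Observations are
#' hemisphere-collated: each subject contributes its left- and right-
#' hemisphere rows as separate observations, so two groups of `n_a` and
#' `n_b` subjects give `2 n_a + 2 n_b - 2` degrees of freedom (e.g. 66 for
#' 13 vs 21 subjects, 360 for 13 vs 168). The test is Student's t with
#' pooled variance by default (Welch by flag) and the effect size is
#' Cohen's d with pooled standard deviation,
#' `d = (mean_a - mean_b) / sd_pooled`.
#'
#' @param records Long-format data.frame (e.g. from [rsfc_cohort()] or
#'   [roi_percent_signal_change()]) with a `group` column and the metric in
#'   `value_col`.
#' @param group_a,group_b Group labels to compare (a minus b).
#' @param value_col Name of the metric column (default `"r"`).
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return Object of class `attnet_ttest`: test name, per-group means, SDs
#'   and ns, `t`, `dof`, `p`, `cohens_d`.
#' @export
compare_groups <- function(records, group_a, group_b, value_col = "r",
                           var_equal = TRUE) {
  if (!value_col %in% names(records)) .stopf("column '%s' not found", value_col)
  if (!"group" %in% names(records)) .stopf("records need a 'group' column")
  xa <- records[[value_col]][records$group == group_a]
  xb <- records[[value_col]][records$group == group_b]
  if (length(xa) < 2L || length(xb) < 2L) {
    .stopf("each group needs at least 2 observations (got %d and %d)",
           length(xa), length(xb))
  }
  if (!all(is.finite(c(xa, xb)))) .stopf("non-finite values in '%s'", value_col)

  tt <- stats::t.test(xa, xb, var.equal = var_equal)
  sd_pooled <- sqrt(((length(xa) - 1) * stats::var(xa) +
                       (length(xb) - 1) * stats::var(xb)) /
                      (length(xa) + length(xb) - 2))
  structure(
    list(
      test = sprintf("%s t-test: %s vs %s on %s",
                     if (var_equal) "pooled" else "Welch", group_a, group_b, value_col),
      group_a = group_a, group_b = group_b,
      mean_a = mean(xa), mean_b = mean(xb),
      sd_a = stats::sd(xa), sd_b = stats::sd(xb),
      n_a = length(xa), n_b = length(xb),
      t = unname(tt$statistic), dof = unname(tt$parameter),
      p = tt$p.value,
      cohens_d = (mean(xa) - mean(xb)) / sd_pooled
    ),
    class = "attnet_ttest"
  )
}

#' @export
print.attnet_ttest <- function(x, ...) {
  cat(sprintf("%s\n  %s: M = %.4f (SD %.4f, n %d); %s: M = %.4f (SD %.4f, n %d)\n  t(%g) = %.3f, p = %.4g, d = %.3f\n",
              x$test, x$group_a, x$mean_a, x$sd_a, x$n_a,
              x$group_b, x$mean_b, x$sd_b, x$n_b,
              x$dof, x$t, x$p, x$cohens_d))
  invisible(x)
}

#' Mixed-effects group x hemisphere ANOVA
#'
#' Fits `value ~ group * hemisphere + (1 | subject)` with
#' \pkg{lmerTest} (REML, sum-to-zero contrasts, Satterthwaite denominator
#' degrees of freedom) and reports F and p for the group, hemisphere and
#' interaction terms. The design must be balanced: exactly one left- and
#' one right-hemisphere observation per subject. For such balanced
#' split-plot data the F statistics coincide with the classical
#' repeated-measures ANOVA.
#'
#' @param records Long-format data.frame with columns `subject`, `group`,
#'   `hemisphere` and the metric in `value_col`.
#' @param value_col Name of the metric column.
#' @return Data.frame of class `attnet_anova` with `term`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
mixed_anova <- function(records, value_col = "percent_signal_change") {
  need <- c("subject", "group", "hemisphere", value_col)
  miss <- setdiff(need, names(records))
  if (length(miss)) .stopf("records are missing column(s): %s", paste(miss, collapse = ", "))
  d <- data.frame(
    subject = factor(records$subject),
    group = factor(records$group),
    hemisphere = factor(records$hemisphere),
    value = records[[value_col]]
  )
  tab <- table(d$subject, d$hemisphere)
  bad <- rownames(tab)[apply(tab, 1L, function(r) any(r != 1L))]
  if (length(bad)) {
    .stopf("unbalanced hemisphere data for subject(s): %s", paste(bad, collapse = ", "))
  }
  # With equal group sizes the split-plot REML optimum has a closed form
  # (the classical ANOVA variance-component estimator); evaluating the lmer
  # deviance exactly there avoids the optimizer's precision floor on the
  # numerically flat REML surface. Unequal group sizes fall back to bobyqa.
  subj_group <- unique(d[, c("subject", "group")])
  equal_n <- length(unique(table(subj_group$group))) == 1L
  ctr <- list(group = "contr.sum", hemisphere = "contr.sum")
  if (equal_n) {
    s <- summary(stats::aov(value ~ group * hemisphere + Error(subject), data = d))
    between <- s[["Error: subject"]][[1]]
    within <- s[["Error: Within"]][[1]]
    msb <- between[trimws(rownames(between)) == "Residuals", "Mean Sq"]
    msw <- within[trimws(rownames(within)) == "Residuals", "Mean Sq"]
    theta <- sqrt(max((msb - msw) / 2, 0) / msw)
    fm <- suppressMessages(lmerTest::lmer(
      value ~ group * hemisphere + (1 | subject), data = d, REML = TRUE,
      start = list(theta = theta), contrasts = ctr,
      control = lme4::lmerControl(optimizer = NULL, calc.derivs = FALSE)
    ))
  } else {
    fm <- suppressMessages(lmerTest::lmer(
      value ~ group * hemisphere + (1 | subject), data = d, REML = TRUE,
      contrasts = ctr,
      control = lme4::lmerControl(
        optimizer = "bobyqa", optCtrl = list(rhoend = 1e-14))
    ))
  }
  a <- stats::anova(fm, type = 3)
  out <- data.frame(
    term = rownames(a),
    F = a[["F value"]],
    df1 = a[["NumDF"]],
    df2 = a[["DenDF"]],
    p = a[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  class(out) <- c("attnet_anova", class(out))
  out
}

#' Pearson correlation between two per-subject metrics
#'
#' @param x,y Paired numeric vectors (n >= 3, finite, non-constant).
#' @return List with `r`, `p` (two-sided), `t`, `dof`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  if (length(x) < 3L) .stopf("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) .stopf("non-finite values")
  if (.safe_sd(x) == 0 || .safe_sd(y) == 0) .stopf("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       t = unname(ct$statistic), dof = unname(ct$parameter), n = length(x))
}
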