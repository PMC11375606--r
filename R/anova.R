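#' Mixed-design ANOVA with partial eta squared
#'
#' Fits the study's univariate mixed-model (split-plot) analysis of
#' variance: one two-level between-subjects factor (default `group`) and one
#' or two two-level within-subjects factors, with subjects nested in group.
#' Each effect is tested against its own error stratum — the between effect
#' against subjects-within-group, each within effect and its group
#' interaction against the corresponding factor-by-subject(group)
#' interaction. Unequal group sizes are allowed (sums of squares are
#' sequential within strata; with a single between factor and complete
#' two-level within factors this matches the standard split-plot analysis).
#' Sphericity corrections are unnecessary with two-level within factors and
#' are not applied.
#'
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`, using the
#' effect's own error stratum, and equals `F * df1 / (F * df1 + df2)` for
#' single-df effects.
#'
#' @param data Data frame with one row per subject x within-cell
#'   (e.g. the output of [cohort_metrics()]).
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-subject factor
#'   column names (each with exactly two levels).
#' @param between Between-subjects factor column name (two levels).
#' @param subject Subject identifier column name.
#' @return Tibble of class `anova_table` with one row per effect: `effect`,
#'   `SS`, `df`, `SS_error`, `df_error`, `F`, `p`, `partial_eta_sq`.
#'   A constant dependent variable yields zero sums of squares and missing
#'   F/p (degenerate, not an error).
#' @export
mixed_anova <- function(data, dv, within, between = "group",
                        subject = "participant_id") {
  data <- as.data.frame(data)
  cols <- c(dv, within, between, subject)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("data lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (!length(within) %in% 1:2) {
    abort_design("one or two within-subject factors are supported")
  }
  if (anyNA(data[[dv]])) {
    abort_validation(sprintf("dependent variable '%s' contains missing values", dv))
  }
  for (f in c(between, within)) {
    if (length(unique(data[[f]])) != 2) {
      abort_design(sprintf(
        "factor '%s' has %d levels; only two-level designs are supported",
        f, length(unique(data[[f]]))))
    }
  }
  # completeness: each subject must have every within-cell exactly once
  cell <- interaction(data[within], drop = FALSE)
  tab <- table(data[[subject]], cell)
  bad <- rownames(tab)[apply(tab, 1, function(r) any(r != 1))]
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "incomplete within-subject cells for subject(s): %s",
      paste(bad, collapse = ", ")))
  }
  grp_per_subj <- tapply(data[[between]], data[[subject]],
                         function(g) length(unique(g)))
  if (any(grp_per_subj != 1)) {
    abort_validation("each subject must belong to exactly one group")
  }

  d <- data.frame(.y = data[[dv]],
                  .s = factor(data[[subject]]),
                  .b = factor(data[[between]]))
  d$.w1 <- factor(data[[within[1]]])
  two_within <- length(within) == 2
  if (two_within) d$.w2 <- factor(data[[within[2]]])

  form <- if (two_within) {
    .y ~ .b * .w1 * .w2 + Error(.s / (.w1 * .w2))
  } else {
    .y ~ .b * .w1 + Error(.s / .w1)
  }
  fit <- aov(form, data = d)
  s <- summary(fit)

  rename <- c(".b" = between, ".w1" = within[1])
  if (two_within) rename[".w2"] <- within[2]
  translate <- function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    paste(rename[parts], collapse = ":")
  }

  # zero out numerically-degenerate sums of squares (constant dv)
  ss_floor <- 1e-10 * max(1, sum(d$.y^2))

  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    effs <- trimws(rownames(tab))
    resid <- which(effs == "Residuals")
    if (length(resid) == 0) next
    ss_err <- tab[resid, "Sum Sq"]
    df_err <- tab[resid, "Df"]
    if (ss_err < ss_floor) ss_err <- 0
    for (k in seq_along(effs)) {
      if (k == resid) next
      ss <- tab[k, "Sum Sq"]
      if (ss < ss_floor) ss <- 0
      df1 <- tab[k, "Df"]
      denom_ms <- if (df_err > 0) ss_err / df_err else NA_real_
      f_val <- if (!is.na(denom_ms) && denom_ms > 0) {
        (ss / df1) / denom_ms
      } else {
        NA_real_
      }
      p_val <- if (is.na(f_val)) NA_real_ else pf(f_val, df1, df_err,
                                                 lower.tail = FALSE)
      pes <- if (ss + ss_err > 0) ss / (ss + ss_err) else NA_real_
      rows[[length(rows) + 1]] <- tibble(
        effect = translate(effs[k]), SS = ss, df = df1,
        SS_error = ss_err, df_error = df_err,
        F = f_val, p = p_val, partial_eta_sq = pes)
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("anova_table", class(out))
  out
}

#' Partial eta squared from an F statistic
#'
#' For an effect with `df1` numerator degrees of freedom tested against
#' `df2` error degrees of freedom, `eta_p^2 = F * df1 / (F * df1 + df2)`.
#' This is the identity linking the printed F statistics of a report to
#' their effect sizes; with `df1 = 1` it reduces to `F / (F + df2)`.
#'
#' @param f_value F statistic(s), non-negative.
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0).
#' @return Numeric effect size(s) in `[0, 1]`.
#' @export
partial_eta_from_F <- function(f_value, df1, df2) {
  if (any(f_value < 0, na.rm = TRUE)) {
    abort_domain("F statistics must be non-negative")
  }
  if (any(df1 <= 0) || any(df2 <= 0)) {
    abort_domain("degrees of freedom must be positive")
  }
  f_value * df1 / (f_value * df1 + df2)
}

#' Independent two-sample t test
#'
#' Standard two-tailed independent-samples t test, either pooled-variance
#' (df = n1 + n2 - 2) or Welch (Welch-Satterthwaite df); both reporting
#' styles occur in practice and neither is inferred from the data.
#'
#' @param x,y Numeric samples (each length >= 2).
#' @param pooled Use the pooled-variance statistic (default `TRUE`);
#'   otherwise Welch.
#' @return Tibble with `t`, `df`, `p`, `pooled`. When both samples have
#'   zero variance and equal means the statistic is undefined and reported
#'   as missing.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    abort_domain("each sample must have at least two observations")
  }
  res <- tryCatch(
    t.test(x, y, var.equal = pooled),
    error = function(e) NULL)
  if (is.null(res)) {
    # degenerate: zero variance in both samples
    if (mean(x) == mean(y)) {
      rlang::warn("both samples constant with equal means; t undefined")
      return(tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                    pooled = pooled))
    }
    df <- if (pooled) length(x) + length(y) - 2 else NA_real_
    return(tibble(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0,
                  pooled = pooled))
  }
  tibble(t = unname(res$statistic), df = unname(res$parameter),
         p = res$p.value, pooled = pooled)
}

#' Format an ANOVA table in report style
#'
#' Renders each effect as `F(df1, df2) = ..., p = ..., eta_p^2 = ...` with
#' three-decimal display rounding (the underlying table keeps full
#' precision).
#'
#' @param anova An `anova_table` from [mixed_anova()].
#' @param label Optional measure label prefixed to each line.
#' @return Character vector, one line per effect.
#' @export
format_anova_report <- function(anova, label = NULL) {
  fmt_p <- function(p) {
    ifelse(is.na(p), "NA",
           ifelse(p < 0.001, "< 0.001", sprintf("= %.3f", p)))
  }
  lines <- sprintf("%s: F(%d, %d) = %.3f, p %s, eta_p^2 = %.3f",
                   anova$effect, anova$df, anova$df_error, anova$F,
                   fmt_p(anova$p), anova$partial_eta_sq)
  if (!is.null(label)) lines <- paste0(label, " - ", lines)
  lines
}
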