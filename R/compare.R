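#' Median split of a cohort variable
#'
#' Splits ids at the sample median (even n: mean of the two central order
#' statistics). Ties at the median go to the ">= median" group, so for a
#' 97-patient cohort of distinct values the groups have sizes 49 and 48.
#'
#' @param values Numeric vector.
#' @param ids Identifiers parallel to `values` (default positional).
#' @return A list with `median`, `ge_ids`, `lt_ids`.
#' @export
median_split <- function(values, ids = seq_along(values)) {
  stopifnot(length(values) == length(ids))
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (length(unique(values)) == 1) {
    stop("degenerate split: all values identical", call. = FALSE)
  }
  me <- stats::median(values)
  ge <- values >= me
  if (!any(ge) || all(ge)) {
    stop("degenerate split: all mass on one side of the median",
         call. = FALSE)
  }
  list(median = me, ge_ids = ids[ge], lt_ids = ids[!ge])
}

#' Normality-gated two-sample comparison
#'
#' Mirrors the classical clinical workflow: each group is screened with
#' the Shapiro-Wilk test at level `alpha`; if both groups pass, a
#' two-sided Student t-test is run (pooled variance by default, Welch
#' selectable), otherwise a two-sided Mann-Whitney U test with the normal
#' approximation and tie correction. Group means and SDs are reported
#' regardless of which test fired.
#'
#' @param outcome_ge,outcome_lt Numeric outcome values of the ">= median"
#'   and "< median" groups.
#' @param alpha Significance level for the two-sample test.
#' @param t_variant `"pooled"` (default) or `"welch"`.
#' @param normality_alpha Level of the Shapiro-Wilk screen. Held at the
#'   conventional 0.05 independently of `alpha`, so changing the reporting
#'   threshold does not change which test is run.
#' @return An object of class `subgroup_comparison`.
#' @export
compare_groups <- function(outcome_ge, outcome_lt, alpha = 0.05,
                           t_variant = c("pooled", "welch"),
                           normality_alpha = 0.05) {
  t_variant <- match.arg(t_variant)
  if (length(outcome_ge) < 3) stop("'>= median' group too small", call. = FALSE)
  if (length(outcome_lt) < 3) stop("'< median' group too small", call. = FALSE)
  normal_ge <- stats::shapiro.test(outcome_ge)$p.value > normality_alpha
  normal_lt <- stats::shapiro.test(outcome_lt)$p.value > normality_alpha
  if (normal_ge && normal_lt) {
    test_used <- "student_t"
    p <- stats::t.test(outcome_ge, outcome_lt,
                       var.equal = (t_variant == "pooled"))$p.value
  } else {
    test_used <- "mann_whitney_u"
    p <- stats::wilcox.test(outcome_ge, outcome_lt, exact = FALSE,
                            correct = TRUE)$p.value
  }
  structure(list(
    group_ge = list(n = length(outcome_ge), mean = mean(outcome_ge),
                    sd = stats::sd(outcome_ge)),
    group_lt = list(n = length(outcome_lt), mean = mean(outcome_lt),
                    sd = stats::sd(outcome_lt)),
    test_used = test_used,
    p_value = p,
    alpha = alpha,
    significant = p < alpha
  ), class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf(">= median: n = %d, %.2f +/- %.2f\n",
              x$group_ge$n, x$group_ge$mean, x$group_ge$sd))
  cat(sprintf("<  median: n = %d, %.2f +/- %.2f\n",
              x$group_lt$n, x$group_lt$mean, x$group_lt$sd))
  cat(sprintf("%s: p = %.4g (%s at alpha = %g)\n",
              x$test_used, x$p_value,
              if (x$significant) "significant" else "ns", x$alpha))
  invisible(x)
}

#' Median-split subgroup comparison table
#'
#' For each split variable, dichotomises the cohort at its median and
#' compares every outcome variable between the two subgroups with
#' [compare_groups()]. One row per (split, outcome) pair; significance is
#' rendered "<0.05"-style downstream.
#'
#' @param derived A derived cohort table from [derive_indices()].
#' @param split_vars Column names to split on.
#' @param outcome_vars Column names to compare.
#' @param alpha Significance level.
#' @param t_variant Passed to [compare_groups()].
#' @return A data frame with split/outcome names, the split median, group
#'   sizes, means, SDs, the test used, and the p-value.
#' @export
subgroup_table <- function(derived, split_vars, outcome_vars, alpha = 0.05,
                           t_variant = c("pooled", "welch")) {
  t_variant <- match.arg(t_variant)
  rows <- list()
  for (sv in split_vars) {
    sp <- median_split(derived[[sv]], derived$id)
    ge <- derived$id %in% sp$ge_ids
    for (ov in outcome_vars) {
      cmp <- compare_groups(derived[[ov]][ge], derived[[ov]][!ge],
                            alpha = alpha, t_variant = t_variant)
      rows[[length(rows) + 1]] <- data.frame(
        split_variable = sv, split_median = sp$median,
        outcome_variable = ov,
        n_ge = cmp$group_ge$n, mean_ge = cmp$group_ge$mean,
        sd_ge = cmp$group_ge$sd,
        n_lt = cmp$group_lt$n, mean_lt = cmp$group_lt$mean,
        sd_lt = cmp$group_lt$sd,
        test_used = cmp$test_used, p_value = cmp$p_value,
        significant = cmp$significant,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' EAT vs aortic-index correlation table
#'
#' Correlates each EAT measure (thickness, volume, thickness index, volume
#' index) with each aortic mechanical index (stiffness index, strain,
#' distensibility). Pearson product-moment correlation is the default --
#' the associations of interest are linear -- with Spearman as an option.
#'
#' @param derived A derived cohort table from [derive_indices()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A 4 x 3 matrix of correlation coefficients.
#' @export
correlation_table <- function(derived, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  eat_vars <- c("eat_thickness", "eat_volume", "eat_thickness_index",
                "eat_volume_index")
  ao_vars <- c("ao_stiffness_index", "ao_strain", "ao_distensibility")
  for (v in c(eat_vars, ao_vars)) {
    if (is.null(derived[[v]])) stop("missing derived column: ", v,
                                    call. = FALSE)
    if (stats::sd(derived[[v]]) == 0) {
      stop("correlation undefined: zero variance in ", v, call. = FALSE)
    }
  }
  out <- matrix(NA_real_, length(eat_vars), length(ao_vars),
                dimnames = list(eat_vars, ao_vars))
  for (i in eat_vars) {
    for (j in ao_vars) {
      out[i, j] <- stats::cor(derived[[i]], derived[[j]], method = method)
    }
  }
  out
}

#' Descriptive summary of a derived cohort
#'
#' Arithmetic mean and SD for every numeric column plus counts and
#' percentages for sex, the report-table convention for cohort
#' descriptions. SD for a single record is undefined and rendered as NA.
#'
#' @param derived A cohort or derived cohort data frame.
#' @return A list with `quantitative` (variable, mean, sd) and
#'   `categorical` (variable, level, n, percent) data frames.
#' @export
descriptive_table <- function(derived) {
  if (!nrow(derived)) stop("empty cohort", call. = FALSE)
  num_cols <- names(derived)[vapply(derived, is.numeric, logical(1))]
  quantitative <- data.frame(
    variable = num_cols,
    mean = vapply(num_cols, function(v) mean(derived[[v]]), numeric(1)),
    sd = vapply(num_cols, function(v) {
      if (nrow(derived) < 2) NA_real_ else stats::sd(derived[[v]])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab <- table(derived$sex)
  categorical <- data.frame(
    variable = "sex", level = names(tab), n = as.integer(tab),
    percent = 100 * as.integer(tab) / nrow(derived),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(quantitative = quantitative, categorical = categorical)
}
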