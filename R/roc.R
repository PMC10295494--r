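#' Dichotomise an aortic outcome at its median
#'
#' Positive cases (label 1) are the records on the "abnormal" side of the
#' sample median: at or above it for stiffness (`ge_median`), below it for
#' elasticity measures such as strain and distensibility (`lt_median`).
#' Consistent with [median_split()], ties at the median fall in the ">="
#' group.
#'
#' @param values Numeric outcome values.
#' @param direction `"ge_median"` or `"lt_median"`.
#' @return Integer 0/1 labels, with the split median as attribute
#'   `"median"`.
#' @export
dichotomize_outcome <- function(values, direction = c("ge_median", "lt_median")) {
  direction <- match.arg(direction)
  sp <- median_split(values)
  labels <- as.integer(values >= sp$median)
  if (direction == "lt_median") labels <- 1L - labels
  if (length(unique(labels)) < 2) {
    stop("degenerate outcome: a single class after dichotomisation",
         call. = FALSE)
  }
  attr(labels, "median") <- sp$median
  labels
}

#' ROC curve and AUC
#'
#' Builds the empirical ROC curve of a continuous predictor against binary
#' labels. Candidate thresholds are the descending unique scores preceded
#' by an `Inf` sentinel; a positive call is score >= threshold, so the
#' curve starts at (0, 0) and ends at (1, 1) with tied scores grouped into
#' single curve steps. The AUC is the trapezoidal integral, which equals
#' the tie-corrected Mann-Whitney U statistic divided by n1 * n0.
#'
#' @param scores Numeric predictor values.
#' @param labels 0/1 labels (1 = positive class).
#' @return A list of class `roc_curve` with `curve` (threshold, fpr, tpr),
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse tied scores into one step
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(1L - l)[last_of_tie]
  curve <- data.frame(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Select an operating threshold on a ROC curve
#'
#' Chooses the threshold maximising classification accuracy (default) or
#' the Youden index (sensitivity + specificity - 1). Accuracy weights the
#' curve coordinates by class prevalence. Ties are broken toward the
#' smallest threshold, i.e. the most sensitive operating point.
#'
#' @param roc A `roc_curve` object.
#' @param criterion `"max_accuracy"` (default) or `"youden"`.
#' @return A list with `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, and the confusion `counts` (tp, fp, tn, fn).
#' @export
select_operating_point <- function(roc,
                                   criterion = c("max_accuracy", "youden")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(roc, "roc_curve"))
  cv <- roc$curve
  sens <- cv$tpr
  spec <- 1 - cv$fpr
  acc <- (sens * roc$n_pos + spec * roc$n_neg) / (roc$n_pos + roc$n_neg)
  score <- switch(criterion,
                  max_accuracy = acc,
                  youden = sens + spec - 1)
  best <- which(score == max(score))
  pick <- best[which.min(cv$threshold[best])]
  tp <- round(sens[pick] * roc$n_pos)
  fn <- roc$n_pos - tp
  tn <- round(spec[pick] * roc$n_neg)
  fp <- roc$n_neg - tn
  list(threshold = cv$threshold[pick],
       sensitivity = sens[pick],
       specificity = spec[pick],
       accuracy = acc[pick],
       counts = list(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Full ROC analysis of one predictor against one outcome
#'
#' @param scores Predictor values (higher = more likely positive).
#' @param labels 0/1 outcome labels.
#' @param criterion Passed to [select_operating_point()].
#' @return A list of class `roc_result` with the curve, AUC, operating
#'   point, and counts.
#' @export
roc_analysis <- function(scores, labels,
                         criterion = c("max_accuracy", "youden")) {
  criterion <- match.arg(criterion)
  roc <- roc_curve(scores, labels)
  op <- select_operating_point(roc, criterion)
  structure(list(curve = roc$curve, auc = roc$auc,
                 n_pos = roc$n_pos, n_neg = roc$n_neg,
                 operating_point = op[c("threshold", "sensitivity",
                                        "specificity", "accuracy")],
                 counts = op$counts, criterion = criterion),
            class = "roc_result")
}

#' EAT predictors vs aortic-status outcomes: the full ROC grid
#'
#' Runs [roc_analysis()] for each of the four EAT measures (thickness,
#' volume, thickness index, volume index) against each of the three
#' dichotomised aortic outcomes: stiffness index at or above its median,
#' strain below its median, distensibility below its median. Twelve rows,
#' reported with 3-decimal rates in the rendered table while the
#' underlying counts and thresholds are kept unrounded.
#'
#' @param derived A derived cohort table from [derive_indices()].
#' @param criterion Operating-point criterion, see
#'   [select_operating_point()].
#' @return A data frame with predictor, outcome, direction, AUC, selected
#'   threshold, sensitivity, specificity, accuracy, and confusion counts;
#'   the individual `roc_result` objects are attached as attribute
#'   `"results"`.
#' @export
roc_report <- function(derived, criterion = c("max_accuracy", "youden")) {
  criterion <- match.arg(criterion)
  predictors <- c("eat_thickness", "eat_volume", "eat_thickness_index",
                  "eat_volume_index")
  outcomes <- data.frame(
    variable = c("ao_stiffness_index", "ao_strain", "ao_distensibility"),
    direction = c("ge_median", "lt_median", "lt_median"),
    stringsAsFactors = FALSE
  )
  rows <- list()
  results <- list()
  for (oi in seq_len(nrow(outcomes))) {
    labels <- dichotomize_outcome(derived[[outcomes$variable[oi]]],
                                  outcomes$direction[oi])
    for (pv in predictors) {
      res <- roc_analysis(derived[[pv]], labels, criterion)
      key <- paste(pv, outcomes$variable[oi], sep = "~")
      results[[key]] <- res
      rows[[length(rows) + 1]] <- data.frame(
        predictor = pv,
        outcome = outcomes$variable[oi],
        direction = outcomes$direction[oi],
        outcome_median = attr(labels, "median"),
        auc = res$auc,
        threshold = res$operating_point$threshold,
        sensitivity = res$operating_point$sensitivity,
        specificity = res$operating_point$specificity,
        accuracy = res$operating_point$accuracy,
        tp = res$counts$tp, fp = res$counts$fp,
        tn = res$counts$tn, fn = res$counts$fn,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
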