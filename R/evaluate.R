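#' Misclassification rate as a percentage
#'
#' `100 * (1 - correct / total)`, rounded to the requested number of
#' decimals (one, the reporting convention, by default).
#'
#' @param correct Number of correctly classified units.
#' @param total Total number of units (> 0).
#' @param digits Decimals to round to; `Inf` for no rounding.
#'
#' @return Percentage.
#' @export
#' @examples
#' misclassification_rate(89, 94)  # 5.3
misclassification_rate <- function(correct, total, digits = 1) {
  if (length(total) != 1 || total <= 0)
    stop("total must be a single positive count", call. = FALSE)
  if (correct < 0 || correct > total)
    stop("correct must lie in [0, total]", call. = FALSE)
  pct <- 100 * (1 - correct / total)
  if (is.finite(digits)) round(pct, digits) else pct
}

#' Sensitivity and specificity with exact binomial confidence intervals
#'
#' Clopper-Pearson (exact) 95% intervals for `sens = TP / (TP + FN)` and
#' `spec = TN / (TN + FP)`.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @param conf_level Confidence level, default 0.95.
#'
#' @return List with `sensitivity` and `specificity`, each a list holding
#'   `estimate`, `ci` (length-2 proportion vector), `x`, `n`; a metric
#'   whose denominator is 0 is `NULL` with a warning.
#' @export
sens_spec_ci <- function(tp, fp, tn, fn, conf_level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  one <- function(x, n) {
    if (n == 0) return(NULL)
    ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
    list(estimate = x / n, ci = as.numeric(ci), x = x, n = n)
  }
  sens <- one(tp, tp + fn)
  spec <- one(tn, tn + fp)
  if (is.null(sens)) warning("no positive units; sensitivity undefined")
  if (is.null(spec)) warning("no negative units; specificity undefined")
  list(sensitivity = sens, specificity = spec)
}

#' ROC curve, AUC and Hanley-McNeil confidence interval
#'
#' Sweeps the decision threshold over the unique score values (ties step
#' simultaneously), integrates the curve by the trapezoidal rule, and
#' attaches the Hanley-McNeil 95% interval for the AUC, clipped to
#' [0, 1]. Higher scores are treated as more malignant.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/"malignant" = positive); both classes
#'   must be present.
#'
#' @return An object of class `roc_curve`: data frame `points` with
#'   columns `fpr`, `tpr`; `auc`; `ci95`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "malignant") else as.integer(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  tp <- cumsum(yy == 1); fp <- cumsum(yy == 0)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last_of_tie] / n1)
  fpr <- c(0, fp[last_of_tie] / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, ci95 = ci, se = se, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and two-sided p value. When both groups are constant the test
#' degenerates: equal means give `t = 0, p = 1`; distinct means give an
#' infinite statistic with `p = 0`.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#'
#' @return List with `t`, `df`, `p`, and the group means.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}
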