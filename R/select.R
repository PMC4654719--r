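## A labeled feature table is a data frame with columns nodule_id,
## slice_id, label ("benign"/"malignant"), followed by numeric feature
## columns; helpers below pull out the pieces.

feature_columns <- function(table) {
  setdiff(colnames(table), c("nodule_id", "slice_id", "label"))
}

feature_matrix <- function(table, features = feature_columns(table)) {
  as.matrix(table[, features, drop = FALSE])
}

label_vector <- function(table) {
  lab <- table$label
  if (is.numeric(lab)) return(as.integer(lab != 0))
  as.integer(lab == "malignant")
}

check_labeled_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("nodule_id", "slice_id", "label") %in% colnames(table)))
  y <- label_vector(table)
  if (sum(y == 0) < 2 || sum(y == 1) < 2)
    stop("need at least 2 slices per class", call. = FALSE)
  X <- feature_matrix(table)
  if (anyNA(X))
    stop("feature table contains missing values; drop incomplete slices first",
         call. = FALSE)
  invisible(table)
}

#' Fisher coefficient of a single feature
#'
#' Ratio of squared class-mean difference to the sum of the unbiased
#' within-class variances, `F = (m1 - m2)^2 / (s1^2 + s2^2)`. Larger is
#' better. Zero pooled variance with equal means gives 0; zero variance
#' with distinct means gives `Inf`.
#'
#' @param x Numeric feature values.
#' @param labels Binary labels (0 = benign, 1 = malignant), or a character
#'   vector with level `"malignant"` as the positive class.
#'
#' @return Non-negative score (possibly `Inf`).
#' @export
fisher_coefficient <- function(x, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "malignant") else as.integer(labels)
  stopifnot(length(x) == length(y))
  if (sum(y == 0) < 2 || sum(y == 1) < 2)
    stop("need at least 2 samples per class", call. = FALSE)
  d2 <- (mean(x[y == 1]) - mean(x[y == 0]))^2
  v <- stats::var(x[y == 1]) + stats::var(x[y == 0])
  if (v == 0) {
    if (d2 == 0) 0 else Inf
  } else d2 / v
}

#' Mutual information between a feature and the class label
#'
#' Discretizes the feature by equal-frequency binning (when the feature
#' has no more distinct values than bins, the values themselves are the
#' bins) and returns the plug-in mutual information with the label, in
#' nats. A constant feature scores 0.
#'
#' @inheritParams fisher_coefficient
#' @param n_bins Number of bins, >= 2; default 10.
#'
#' @return Non-negative score in nats.
#' @export
mutual_information <- function(x, labels, n_bins = 10L) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "malignant") else as.integer(labels)
  stopifnot(length(x) == length(y), n_bins >= 2)
  ux <- unique(x)
  if (length(ux) < 2) return(0)
  if (length(ux) <= n_bins) {
    bins <- match(x, sort(ux))
  } else {
    br <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1),
                                 type = 7, names = FALSE))
    if (length(br) < 3) return(0)
    bins <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  }
  tab <- table(bins, y)
  p <- tab / sum(tab)
  pr <- rowSums(p); pc <- colSums(p)
  pe <- outer(pr, pc)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / pe[pos]))
}

## POE of one feature: resubstitution error of a nearest-class-mean
## classifier on the standardized feature.
poe_single <- function(x, y) {
  s <- stats::sd(x)
  z <- if (s > 0) (x - mean(x)) / s else x * 0
  m0 <- mean(z[y == 0]); m1 <- mean(z[y == 1])
  pred <- as.integer(abs(z - m1) < abs(z - m0))
  mean(pred != y)
}

#' Rank features by POE + ACC greedy forward selection
#'
#' MaZda-style ranking combining the probability of classification error
#' (POE: resubstitution error of a nearest-class-mean classifier on the
#' standardized single feature) with the average absolute Pearson
#' correlation (ACC) to the features already selected. The first feature
#' minimizes POE alone; each subsequent feature minimizes POE + ACC. Ties
#' are broken by registry (column) order.
#'
#' @param table Labeled feature table (see [extract_feature_table()]).
#' @param k Number of features to return, in selection order.
#'
#' @return An object of class `feature_ranking`: list with `method`,
#'   `features` and `scores` (the minimized criterion at each step).
#' @export
poe_acc_rank <- function(table, k = 10L) {
  check_labeled_table(table)
  feats <- feature_columns(table)
  stopifnot(length(feats) >= k)
  X <- feature_matrix(table)
  y <- label_vector(table)
  poe <- apply(X, 2, poe_single, y = y)
  selected <- character(0)
  scores <- numeric(0)
  remaining <- feats
  while (length(selected) < k) {
    if (length(selected) == 0) {
      crit <- poe[remaining]
    } else {
      S <- X[, selected, drop = FALSE]
      acc <- vapply(remaining, function(f) {
        r <- suppressWarnings(stats::cor(X[, f], S))
        r[is.na(r)] <- 1  # constant feature: maximally penalized
        mean(abs(r))
      }, numeric(1))
      crit <- poe[remaining] + acc
    }
    best <- remaining[which.min(crit)]  # which.min takes first on ties
    scores <- c(scores, min(crit))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  structure(list(method = "poe_acc", features = selected, scores = scores),
            class = "feature_ranking")
}

#' Rank all features by Fisher coefficient or mutual information
#'
#' @param table Labeled feature table.
#' @param method `"fisher"` or `"mutual_information"`.
#' @param k Number of top features to keep.
#' @param n_bins Bins for the mutual-information estimate.
#'
#' @return A `feature_ranking` (best first).
#' @export
rank_features <- function(table, method = c("fisher", "mutual_information"),
                          k = 10L, n_bins = 10L) {
  method <- match.arg(method)
  check_labeled_table(table)
  X <- feature_matrix(table)
  y <- label_vector(table)
  score <- switch(method,
    fisher = apply(X, 2, fisher_coefficient, labels = y),
    mutual_information = apply(X, 2, mutual_information, labels = y,
                               n_bins = n_bins))
  ord <- order(-score)  # stable: ties keep registry order
  ord <- ord[seq_len(min(k, length(ord)))]
  structure(list(method = method, features = colnames(X)[ord],
                 scores = unname(score[ord]), all_scores = score),
            class = "feature_ranking")
}

#' Merge the three top-k ranking lists into one candidate list
#'
#' Takes the union of the Fisher, mutual-information and POE+ACC top-k
#' lists (at most `3 * k_each` features) and orders it by mean
#' within-method rank, a feature absent from a method's list receiving
#' rank `k_each + 1`. Ties are broken by Fisher score (larger first), then
#' registry order.
#'
#' @param r_fisher,r_mi,r_poe `feature_ranking` objects over the same
#'   feature set.
#' @param k_each Per-method list length (default 10, for a combined list
#'   of up to 30).
#'
#' @return An object of class `selected_subset` with the ordered
#'   `candidates` and their `combined_rank`.
#' @export
combine_rankings <- function(r_fisher, r_mi, r_poe, k_each = 10L) {
  lists <- list(fisher = r_fisher$features[seq_len(min(k_each, length(r_fisher$features)))],
                mi = r_mi$features[seq_len(min(k_each, length(r_mi$features)))],
                poe = r_poe$features[seq_len(min(k_each, length(r_poe$features)))])
  cand <- unique(unlist(lists))
  rank_in <- function(f, lst) {
    i <- match(f, lst)
    ifelse(is.na(i), k_each + 1L, i)
  }
  mean_rank <- (rank_in(cand, lists$fisher) + rank_in(cand, lists$mi) +
                  rank_in(cand, lists$poe)) / 3
  fisher_score <- if (!is.null(r_fisher$all_scores))
    r_fisher$all_scores[cand] else
      -rank_in(cand, lists$fisher)
  fisher_score[is.na(fisher_score)] <- -Inf
  ord <- order(mean_rank, -fisher_score)
  structure(list(candidates = cand[ord],
                 combined_rank = mean_rank[ord]),
            class = "selected_subset")
}

#' Backward elimination against LDA misclassification
#'
#' Starting from the combined candidate list (best first), evaluates the
#' nested subsets made of the top `m` candidates for `m` from the full
#' list down to 2, refitting the linear discriminant and recording the
#' slice-level resubstitution misclassification rate of each subset. The
#' subset with the lowest rate wins; ties go to the smallest `m`. A
#' subset whose within-class covariance cannot be stabilized is skipped
#' and logged.
#'
#' @param table Labeled feature table.
#' @param candidates Character vector of candidate features, best first
#'   (e.g. `combine_rankings(...)$candidates`).
#'
#' @return A `selected_subset` with `subset` (the winning features), `k`,
#'   `error_rate`, the per-m `curve` (data frame of `m` and `error`), and
#'   `skipped` (values of m with degenerate fits).
#' @export
backward_eliminate <- function(table, candidates) {
  check_labeled_table(table)
  stopifnot(length(candidates) >= 2,
            all(candidates %in% feature_columns(table)))
  y <- label_vector(table)
  ms <- seq(length(candidates), 2)
  err <- rep(NA_real_, length(ms))
  for (i in seq_along(ms)) {
    sub <- candidates[seq_len(ms[i])]
    fit <- tryCatch(fit_lda(table, sub), error = function(e) NULL)
    if (is.null(fit)) next
    pred <- classify_slices(fit, table, cutoff = 0)
    ## during elimination the raw sign of the centred score is the call
    err[i] <- mean(as.integer(pred$mdf1 > 0) != y)
  }
  if (all(is.na(err)))
    stop("no candidate subset produced a valid discriminant fit",
         call. = FALSE)
  best_err <- min(err, na.rm = TRUE)
  k <- min(ms[!is.na(err) & err == best_err])  # ties -> smallest subset
  structure(list(subset = candidates[seq_len(k)], k = k,
                 error_rate = best_err,
                 curve = data.frame(m = ms, error = err),
                 skipped = ms[is.na(err)],
                 candidates = candidates),
            class = "selected_subset")
}
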