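#' Fit a two-class Fisher linear discriminant on selected features
#'
#' Features are z-scored with the training means and standard deviations,
#' the pooled within-class covariance `S_w` is formed (with a ridge
#' `lambda * mean(diag(S_w)) * I` stepped up from 1e-8 until the condition
#' number falls below 1e8), and the projection is
#' `w  proportional to  S_w^{-1} (mu_mal - mu_ben)`, scaled to unit norm
#' and oriented so the malignant training mean projects above the benign
#' one. The offset places the midpoint of the projected class means at 0,
#' so the score (MDF1, most discriminant factor 1) of a slice is
#' `w . z(x) + offset` and a trained cutoff lies near 0.
#'
#' @param table Labeled feature table (see [extract_feature_table()]).
#' @param subset Character vector of feature names to use.
#'
#' @return An object of class `lda_model`: `features`, `center`, `scale`
#'   (standardization), `w`, `offset`, `cutoff` (0 until
#'   [choose_cutoff()] is applied), `lambda` (ridge actually used).
#' @export
fit_lda <- function(table, subset = feature_columns(table)) {
  check_labeled_table(table)
  if (!all(subset %in% colnames(table))) {
    miss <- setdiff(subset, colnames(table))
    stop("features not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- feature_matrix(table, subset)
  y <- label_vector(table)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl <= 0))
    stop("feature(s) with zero variance: ",
         paste(subset[scl <= 0], collapse = ", "), call. = FALSE)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  Z0 <- Z[y == 0, , drop = FALSE]; Z1 <- Z[y == 1, , drop = FALSE]
  m0 <- colMeans(Z0); m1 <- colMeans(Z1)
  Sw <- ((n0 - 1) * stats::cov(Z0) + (n1 - 1) * stats::cov(Z1)) /
    (n0 + n1 - 2)
  lambda <- 0
  step <- 1e-8
  repeat {
    Swr <- Sw + diag(lambda * mean(diag(Sw)), ncol(Sw))
    ev <- eigen(Swr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < 1e8) break
    lambda <- if (lambda == 0) step else lambda * 10
    if (lambda > 1)
      stop("within-class covariance singular even after maximal shrinkage",
           call. = FALSE)
  }
  w <- solve(Swr, m1 - m0)
  w <- w / sqrt(sum(w^2))
  if (sum(w * (m1 - m0)) < 0) w <- -w   # malignant side is positive
  offset <- -sum(w * (m0 + m1) / 2)
  structure(list(features = subset, center = ctr, scale = scl,
                 w = w, offset = offset, cutoff = 0, lambda = lambda),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("Two-class linear discriminant (MDF1)\n")
  cat(sprintf("  features: %d, ridge lambda: %g, cutoff: %g\n",
              length(x$features), x$lambda, x$cutoff))
  invisible(x)
}

#' Choose the MDF1 cutoff minimizing training misclassification
#'
#' Scans the midpoints between adjacent distinct training scores (plus
#' one cutoff below all scores and one above) with the decision rule
#' `malignant iff score > cutoff`, and returns the cutoff with the fewest
#' training errors. Ties are broken by maximizing Youden's J
#' (sensitivity + specificity - 1), then by the smallest cutoff value.
#'
#' @param scores Numeric MDF1 scores of the training slices.
#' @param labels Binary labels (1/"malignant" = positive).
#'
#' @return A single cutoff value.
#' @export
choose_cutoff <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "malignant") else as.integer(labels)
  stopifnot(length(scores) == length(y), any(y == 1), any(y == 0))
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stats_at <- vapply(cand, function(c) {
    call <- scores > c
    tp <- sum(call & y == 1); tn <- sum(!call & y == 0)
    err <- (n1 - tp) + (n0 - tn)
    c(err, tp / n1 + tn / n0 - 1)
  }, numeric(2))
  err <- stats_at[1, ]; j <- stats_at[2, ]
  best <- err == min(err)
  best <- best & j == max(j[best])
  cand[which(best)[1]]
}

#' Score and classify slices with a fitted discriminant
#'
#' Computes `MDF1 = w . z(x) + offset` for each slice and calls it
#' malignant when MDF1 exceeds the cutoff.
#'
#' @param model An [fit_lda()] model.
#' @param table Feature table containing at least the model's features
#'   (extra columns are ignored; `label` is optional).
#' @param cutoff Cutoff override; defaults to `model$cutoff`.
#'
#' @return Data frame with `nodule_id`, `slice_id`, `mdf1`, `call`.
#' @export
classify_slices <- function(model, table, cutoff = model$cutoff) {
  stopifnot(inherits(model, "lda_model"))
  miss <- setdiff(model$features, colnames(table))
  if (length(miss))
    stop("table is missing model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(table[, model$features, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  mdf1 <- as.numeric(Z %*% model$w) + model$offset
  data.frame(nodule_id = table$nodule_id, slice_id = table$slice_id,
             mdf1 = mdf1,
             call = ifelse(mdf1 > cutoff, "malignant", "benign"),
             stringsAsFactors = FALSE)
}

#' Aggregate slice scores to nodule calls by the lowest-scoring slice
#'
#' A nodule's score is the minimum MDF1 over its slices; the nodule is
#' called malignant only when that minimum exceeds the cutoff. Taking the
#' lowest rather than the highest slice suppresses false positives: a
#' single high-scoring slice cannot flip a nodule to malignant.
#'
#' @param predictions Data frame from [classify_slices()] (needs
#'   `nodule_id` and `mdf1`).
#' @param cutoff The MDF1 cutoff.
#'
#' @return Data frame with `nodule_id`, `min_mdf1`, `call`.
#' @export
classify_nodules_lowest_slice <- function(predictions, cutoff) {
  stopifnot(is.data.frame(predictions),
            all(c("nodule_id", "mdf1") %in% colnames(predictions)),
            nrow(predictions) > 0)
  mins <- tapply(predictions$mdf1, predictions$nodule_id, min)
  data.frame(nodule_id = names(mins), min_mdf1 = as.numeric(mins),
             call = ifelse(mins > cutoff, "malignant", "benign"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize / restore a fitted discriminant model
#'
#' The model (features, standardization, weights, offset, cutoff and the
#' texture configuration it expects) is stored as plain JSON so a frozen
#' model can be applied to an independent test set.
#'
#' @param model An `lda_model`, optionally with a `$texture_config`
#'   attached by the training pipeline.
#' @param path File path.
#'
#' @return `write_lda_model` returns `path` invisibly; `read_lda_model`
#'   returns the `lda_model`.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  obj <- unclass(model)
  if (!is.null(obj$texture_config)) obj$texture_config <-
      unclass(obj$texture_config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(features = obj$features,
                center = stats::setNames(as.numeric(obj$center),
                                         obj$features),
                scale = stats::setNames(as.numeric(obj$scale),
                                        obj$features),
                w = stats::setNames(as.numeric(obj$w), obj$features),
                offset = obj$offset, cutoff = obj$cutoff,
                lambda = obj$lambda)
  if (!is.null(obj$texture_config)) {
    tc <- obj$texture_config
    model$texture_config <- texture_config(
      bits = tc$bits, normalization = tc$normalization,
      distances = tc$distances, scales = tc$scales,
      families = tc$families, source = tc$source)
  }
  structure(model, class = "lda_model")
}
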