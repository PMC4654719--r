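#' Per-slice and per-nodule ADC summary of a cohort
#'
#' Runs [compute_adc()] on every slice pair, averages over the ROI, and
#' pools slices into each nodule's area-weighted mean ADC.
#'
#' @param nodules List of [generate_nodule()] results (e.g.
#'   `cohort$training`), or nodule-like lists with `slices`, `masks`,
#'   `label`, `nodule_id`.
#' @param noise_floor Noise floor for the ADC rectification; `NULL`
#'   (default) uses each nodule's recorded acquisition noise SD when
#'   available, else 0.
#'
#' @return List with `slices` (data frame: nodule_id, slice_id, label,
#'   area_px, mean_adc) and `nodules` (data frame: nodule_id, label,
#'   weighted_mean_adc, n_slices).
#' @export
cohort_adc_summary <- function(nodules, noise_floor = NULL) {
  slice_rows <- list()
  nod_rows <- list()
  for (nd in nodules) {
    nf <- if (!is.null(noise_floor)) noise_floor
          else if (!is.null(nd$noise_sd)) nd$noise_sd else 0
    sums <- vector("list", length(nd$slices))
    for (s in seq_along(nd$slices)) {
      adc <- compute_adc(nd$slices[[s]], noise_floor = nf)
      sums[[s]] <- roi_mean_adc(adc, nd$masks[[s]])
      slice_rows[[length(slice_rows) + 1L]] <- data.frame(
        nodule_id = nd$nodule_id, slice_id = nd$slices[[s]]$slice_id,
        label = nd$label, area_px = sums[[s]]$area,
        mean_adc = sums[[s]]$mean_adc, stringsAsFactors = FALSE)
    }
    nod_rows[[length(nod_rows) + 1L]] <- data.frame(
      nodule_id = nd$nodule_id, label = nd$label,
      weighted_mean_adc = weighted_mean_adc(sums),
      n_slices = length(nd$slices), stringsAsFactors = FALSE)
  }
  list(slices = do.call(rbind, slice_rows),
       nodules = do.call(rbind, nod_rows))
}

#' Extract the labeled texture feature table of a cohort
#'
#' For each slice, computes the ADC map (noise-rectified), restricts the
#' ROI to valid ADC pixels, and extracts the full texture catalogue from
#' the configured source raster (`"adc"` or raw `"dwi"`). Slices with any
#' undefined feature are dropped from the returned table and recorded in
#' the `excluded` attribute with the features that failed, mirroring the
#' exclusion bookkeeping of a clinical analysis.
#'
#' @inheritParams cohort_adc_summary
#' @param config A [texture_config()].
#'
#' @return Data frame with `nodule_id`, `slice_id`, `label` and one
#'   column per registered feature; attribute `excluded` is a data frame
#'   of dropped slices.
#' @export
extract_feature_table <- function(nodules, config = texture_config(),
                                  noise_floor = NULL) {
  reg <- feature_registry(config)
  rows <- list(); meta <- list(); excluded <- list()
  for (nd in nodules) {
    nf <- if (!is.null(noise_floor)) noise_floor
          else if (!is.null(nd$noise_sd)) nd$noise_sd else 0
    for (s in seq_along(nd$slices)) {
      pair <- nd$slices[[s]]
      adc <- compute_adc(pair, noise_floor = nf)
      eff <- nd$masks[[s]]$mask & adc$valid_mask
      if (!any(eff)) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          nodule_id = nd$nodule_id, slice_id = pair$slice_id,
          reason = "no valid ADC pixel in ROI", stringsAsFactors = FALSE)
        next
      }
      raster <- switch(config$source, adc = adc$values, dwi = pair$sb)
      raster[is.na(raster)] <- 0  # invalid pixels; outside the ROI
      fv <- extract_all(raster, eff, config)
      if (anyNA(fv)) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          nodule_id = nd$nodule_id, slice_id = pair$slice_id,
          reason = paste("undefined feature(s):",
                         paste(names(fv)[is.na(fv)], collapse = ";")),
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- fv
      meta[[length(meta) + 1L]] <- data.frame(
        nodule_id = nd$nodule_id, slice_id = pair$slice_id,
        label = nd$label, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("every slice was excluded during extraction", call. = FALSE)
  X <- do.call(rbind, rows)
  out <- cbind(do.call(rbind, meta),
               as.data.frame(X, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
    else data.frame(nodule_id = character(0), slice_id = integer(0),
                    reason = character(0))
  attr(out, "registry") <- reg
  out
}

#' Train the full stratification model on a labeled cohort
#'
#' End-to-end training: texture extraction, the three feature rankings
#' (Fisher coefficient, mutual information, POE+ACC), merging into the
#' combined candidate list, backward elimination against resubstitution
#' linear-discriminant misclassification, cutoff training, slice and
#' nodule classification, and the evaluation report (slice
#' misclassification, sensitivity/specificity with exact intervals,
#' ROC/AUC, nodule accuracy under the lowest-scoring-slice rule, and the
#' weighted-mean-ADC comparison with its Welch t test).
#'
#' @param nodules List of labeled nodules (e.g. `cohort$training`).
#' @param texture A [texture_config()].
#' @param k_each Per-method list length for the ranking merge.
#' @param noise_floor Passed to [extract_feature_table()].
#'
#' @return An object of class `thyrotex_training`: `feature_table`,
#'   `rankings`, `candidates`, `elimination`, `model` (with trained
#'   cutoff and the texture config attached), `slice_predictions`,
#'   `nodule_predictions`, `metrics`, `adc`.
#' @export
run_training <- function(nodules, texture = texture_config(),
                         k_each = 10L, noise_floor = NULL) {
  labs <- vapply(nodules, function(nd) nd$label, character(1))
  if (sum(labs == "benign") < 2 || sum(labs == "malignant") < 2)
    stop("need at least 2 nodules per class", call. = FALSE)
  ft <- extract_feature_table(nodules, texture, noise_floor)
  ## drop features constant across the cohort (uninformative, and they
  ## break standardization)
  Xall <- feature_matrix(ft)
  keep <- apply(Xall, 2, function(v) stats::sd(v) > 0)
  ft_model <- ft[, c("nodule_id", "slice_id", "label",
                     colnames(Xall)[keep])]
  r_fisher <- rank_features(ft_model, "fisher", k = k_each)
  r_mi <- rank_features(ft_model, "mutual_information", k = k_each)
  r_poe <- poe_acc_rank(ft_model, k = k_each)
  cand <- combine_rankings(r_fisher, r_mi, r_poe, k_each = k_each)
  elim <- backward_eliminate(ft_model, cand$candidates)
  model <- fit_lda(ft_model, elim$subset)
  sl <- classify_slices(model, ft_model, cutoff = 0)
  model$cutoff <- choose_cutoff(sl$mdf1, ft_model$label)
  model$texture_config <- texture
  sl <- classify_slices(model, ft_model)
  nod <- classify_nodules_lowest_slice(sl, model$cutoff)
  adc <- cohort_adc_summary(nodules, noise_floor)
  metrics <- evaluate_predictions(sl, ft_model$label, nod,
                                  labs_by_nodule(nodules), model$cutoff)
  metrics$adc_t_test <- welch_t_test(
    adc$nodules$weighted_mean_adc[adc$nodules$label == "benign"],
    adc$nodules$weighted_mean_adc[adc$nodules$label == "malignant"])
  structure(list(feature_table = ft, rankings = list(
                   fisher = r_fisher, mutual_information = r_mi,
                   poe_acc = r_poe),
                 candidates = cand, elimination = elim, model = model,
                 slice_predictions = sl, nodule_predictions = nod,
                 metrics = metrics, adc = adc),
            class = "thyrotex_training")
}

labs_by_nodule <- function(nodules) {
  stats::setNames(vapply(nodules, function(nd) nd$label, character(1)),
                  vapply(nodules, function(nd) nd$nodule_id, character(1)))
}

## Shared metric block for training and test reports.
evaluate_predictions <- function(slice_pred, slice_labels, nodule_pred,
                                 nodule_labels, cutoff) {
  y <- as.integer(slice_labels == "malignant")
  call <- as.integer(slice_pred$call == "malignant")
  tp <- sum(call == 1 & y == 1); fn <- sum(call == 0 & y == 1)
  tn <- sum(call == 0 & y == 0); fp <- sum(call == 1 & y == 0)
  ny <- nodule_labels[nodule_pred$nodule_id]
  nod_correct <- sum(nodule_pred$call == ny)
  list(
    n_slices = length(y),
    slice_correct = tp + tn,
    slice_misclassification_pct =
      misclassification_rate(tp + tn, length(y)),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    sens_spec = sens_spec_ci(tp, fp, tn, fn),
    roc = roc_auc(slice_pred$mdf1, y),
    n_nodules = nrow(nodule_pred),
    nodule_correct = nod_correct,
    nodule_accuracy_pct = round(100 * nod_correct / nrow(nodule_pred), 1),
    cutoff = cutoff)
}

#' Apply a frozen model to an independent test cohort
#'
#' Extracts features with the texture configuration stored in the model,
#' applies the frozen standardization, weights and cutoff (no statistic
#' of the test data enters the model), and reports the same metric block
#' as training.
#'
#' @param nodules List of labeled test nodules.
#' @param model A trained `lda_model` with `$texture_config` (as produced
#'   by [run_training()] or [read_lda_model()]).
#' @param noise_floor Passed to [extract_feature_table()].
#'
#' @return An object of class `thyrotex_test`: `feature_table`,
#'   `slice_predictions`, `nodule_predictions`, `metrics`.
#' @export
run_test <- function(nodules, model, noise_floor = NULL) {
  stopifnot(inherits(model, "lda_model"))
  texture <- model$texture_config
  if (is.null(texture))
    stop("model carries no texture configuration", call. = FALSE)
  ft <- extract_feature_table(nodules, texture, noise_floor)
  miss <- setdiff(model$features, colnames(ft))
  if (length(miss))
    stop("test table is missing model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sl <- classify_slices(model, ft)
  nod <- classify_nodules_lowest_slice(sl, model$cutoff)
  metrics <- evaluate_predictions(sl, ft$label, nod,
                                  labs_by_nodule(nodules), model$cutoff)
  structure(list(feature_table = ft, slice_predictions = sl,
                 nodule_predictions = nod, metrics = metrics),
            class = "thyrotex_test")
}

#' @export
print.thyrotex_training <- function(x, ...) {
  m <- x$metrics
  cat("Training run\n")
  cat(sprintf("  slices: %d, correct: %d (misclassification %.1f%%)\n",
              m$n_slices, m$slice_correct, m$slice_misclassification_pct))
  cat(sprintf("  slice AUC: %.3f; nodules correct: %d/%d (%.1f%%)\n",
              m$roc$auc, m$nodule_correct, m$n_nodules,
              m$nodule_accuracy_pct))
  cat(sprintf("  selected %d features; MDF1 cutoff %.5f\n",
              length(x$model$features), x$model$cutoff))
  invisible(x)
}

#' @export
print.thyrotex_test <- function(x, ...) {
  m <- x$metrics
  cat("Frozen-model test run\n")
  cat(sprintf("  slices: %d, correct: %d (misclassification %.1f%%)\n",
              m$n_slices, m$slice_correct, m$slice_misclassification_pct))
  cat(sprintf("  slice AUC: %.3f; nodules correct: %d/%d (%.1f%%)\n",
              m$roc$auc, m$nodule_correct, m$n_nodules,
              m$nodule_accuracy_pct))
  invisible(x)
}
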