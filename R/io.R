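#' Read a slice raster from NIfTI, TIFF or PNG
#'
#' Dispatch on the file extension: `.nii`/`.nii.gz` via RNifti, `.tif`/
#' `.tiff` via the tiff package, `.png` via the png package. The raster
#' is returned as a numeric matrix indexed `[row, column]` with row 1 at
#' the top.
#'
#' @param path File path.
#'
#' @return Numeric matrix.
#' @export
read_slice_image <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    m <- as.matrix(drop(as.array(img)))
  } else if (grepl("\\.tiff?$", lp)) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3) m <- m[, , 1]
  } else if (grepl("\\.png$", lp)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
  } else stop("unsupported image format: ", path, call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Read a binary ROI mask image
#'
#' Any non-zero pixel is in-ROI.
#'
#' @param path File path (same formats as [read_slice_image()]).
#' @param pixel_spacing Pixel edge in mm for area reporting.
#'
#' @return A [roi_mask()].
#' @export
read_roi_mask <- function(path, pixel_spacing = 1) {
  roi_mask(read_slice_image(path) != 0, pixel_spacing)
}

#' Write an ADC map to NIfTI or 32-bit float TIFF
#'
#' @param adc An `adc_map` from [compute_adc()]; invalid pixels are
#'   written as 0.
#' @param path Output path ending in `.nii`, `.nii.gz` or `.tif`.
#'
#' @return `path`, invisibly.
#' @export
write_adc_map <- function(adc, path) {
  stopifnot(inherits(adc, "adc_map"))
  v <- adc$values
  v[is.na(v)] <- 0
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    RNifti::writeNifti(RNifti::asNifti(v), path)
  } else if (grepl("\\.tiff?$", lp)) {
    tiff::writeTIFF(v, path, bits.per.sample = 32L)
  } else stop("unsupported output format: ", path, call. = FALSE)
  invisible(path)
}

#' Write / read a labeled feature table as CSV
#'
#' Column order is `nodule_id`, `slice_id`, `label`, then the feature
#' names exactly as registered (names are quoted because they contain
#' punctuation).
#'
#' @param table Feature table from [extract_feature_table()].
#' @param path CSV path.
#'
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write the feature registry of a configuration to a text file
#'
#' @param config A [texture_config()].
#' @param path Output path (tab-separated text).
#'
#' @return `path`, invisibly.
#' @export
write_feature_registry <- function(config, path) {
  utils::write.table(feature_registry(config), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes each slice's b = 0 and b > 0 rasters as NIfTI, the ROI masks as
#' PNG, and a manifest CSV linking files, nodules, sites, labels and the
#' generator's ground truth.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#'
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (nd in c(cohort$training, cohort$test)) {
    for (s in seq_along(nd$slices)) {
      pair <- nd$slices[[s]]
      base <- sprintf("%s_s%02d", nd$nodule_id, pair$slice_id)
      f0 <- file.path(dir, paste0(base, "_b0.nii.gz"))
      fb <- file.path(dir, paste0(base, "_b500.nii.gz"))
      fm <- file.path(dir, paste0(base, "_mask.png"))
      RNifti::writeNifti(RNifti::asNifti(pair$s0), f0)
      RNifti::writeNifti(RNifti::asNifti(pair$sb), fb)
      png::writePNG(nd$masks[[s]]$mask * 1, fm)
      rows[[length(rows) + 1L]] <- data.frame(
        nodule_id = nd$nodule_id,
        site = if (startsWith(nd$nodule_id, "train")) "training" else
          "test",
        slice_id = pair$slice_id, label = nd$label,
        b0_file = basename(f0), b500_file = basename(fb),
        mask_file = basename(fm),
        b_value = pair$b_value, pixel_spacing = pair$pixel_spacing,
        noise_sd = nd$noise_sd,
        true_slice_adc = nd$true_slice_adc[s],
        seed = cohort$config$seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path Path to the manifest CSV (images are resolved
#'   relative to its directory).
#'
#' @return List of nodule-like lists (`label`, `nodule_id`, `slices`,
#'   `masks`, `noise_sd`, `true_slice_adc`) usable by
#'   [extract_feature_table()] and [run_training()], plus the manifest as
#'   attribute `manifest`.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  out <- lapply(split(man, man$nodule_id), function(g) {
    g <- g[order(g$slice_id), , drop = FALSE]
    slices <- vector("list", nrow(g))
    masks <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      s0 <- read_slice_image(file.path(dir, g$b0_file[i]))
      sb <- read_slice_image(file.path(dir, g$b500_file[i]))
      slices[[i]] <- dwi_slice_pair(s0, sb, b_value = g$b_value[i],
                                    pixel_spacing = g$pixel_spacing[i],
                                    slice_id = g$slice_id[i],
                                    nodule_id = g$nodule_id[i])
      masks[[i]] <- read_roi_mask(file.path(dir, g$mask_file[i]),
                                  pixel_spacing = g$pixel_spacing[i])
    }
    list(label = g$label[1], nodule_id = g$nodule_id[1],
         slices = slices, masks = masks, noise_sd = g$noise_sd[1],
         true_slice_adc = g$true_slice_adc)
  })
  out <- unname(out)
  attr(out, "manifest") <- man
  out
}

#' Write an evaluation metric block as JSON
#'
#' @param metrics The `metrics` element of a [run_training()] or
#'   [run_test()] result.
#' @param path Output JSON path.
#'
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  out <- metrics
  out$roc <- list(auc = metrics$roc$auc, ci95 = metrics$roc$ci95)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
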