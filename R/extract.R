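#' Texture extraction configuration
#'
#' Fixes every knob of the texture catalogue so that extraction is
#' deterministic and the feature registry is known before any image is
#' seen.
#'
#' @param bits Quantization bit depth for the co-occurrence and run-length
#'   families (levels `G = 2^bits`); default 6 (64 levels).
#' @param normalization Intensity window for quantization; see
#'   [quantize_roi()]. Default `"mu3sigma"`.
#' @param distances Co-occurrence displacement distances, default `1:5`;
#'   each distance contributes the four directions 0, 45, 90, 135 degrees.
#' @param scales Haar decomposition scales, default `1:3`.
#' @param families Character vector of enabled families among `"glcm"`,
#'   `"rlm"`, `"histogram"`, `"gradient"`, `"ar"`, `"wavelet"`,
#'   `"geometry"`.
#' @param source Raster the features are computed from when extracting
#'   from a cohort: `"adc"` (the ADC map, default) or `"dwi"` (the raw
#'   b > 0 signal).
#'
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(bits = 6L,
                           normalization = c("mu3sigma", "minmax",
                                             "perc1_99"),
                           distances = 1:5,
                           scales = 1:3,
                           families = c("glcm", "rlm", "histogram",
                                        "gradient", "ar", "wavelet",
                                        "geometry"),
                           source = c("adc", "dwi")) {
  normalization <- match.arg(normalization)
  source <- match.arg(source)
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(all(distances >= 1), all(distances <= 5), all(scales >= 1))
  structure(list(bits = as.integer(bits), normalization = normalization,
                 distances = as.integer(distances),
                 scales = as.integer(scales),
                 families = families, source = source),
            class = "texture_config")
}

rlm_direction_prefix <- c("0" = "Horzl_", "45" = "45dgr_",
                          "90" = "Vertl_", "135" = "135dr_")

#' Registry of feature names implied by a configuration
#'
#' Enumerates, in extraction order, every feature name the configuration
#' produces, together with its family. Written alongside feature tables so
#' that each name maps to a documented formula.
#'
#' @param config A [texture_config()].
#'
#' @return Data frame with columns `name` and `family`.
#' @export
feature_registry <- function(config = texture_config()) {
  stopifnot(inherits(config, "texture_config"))
  nm <- character(0); fam <- character(0)
  add <- function(names, family) {
    nm <<- c(nm, names); fam <<- c(fam, rep(family, length(names)))
  }
  if ("glcm" %in% config$families) {
    glcm_nm <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
                 "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc",
                 "DifEntrp")
    for (off in glcm_offsets(config$distances))
      add(paste0(offset_token(off), glcm_nm), "glcm")
  }
  if ("rlm" %in% config$families)
    for (d in c("0", "45", "90", "135"))
      add(paste0(rlm_direction_prefix[[d]],
                 c("ShrtREmp", "LngREmph", "GLevNonUni", "RLNonUni",
                   "Fraction")), "rlm")
  if ("histogram" %in% config$families)
    add(c("Mean", "Variance", "Skewness", "Kurtosis", "Perc.01%",
          "Perc.10%", "Perc.50%", "Perc.90%", "Perc.99%"), "histogram")
  if ("gradient" %in% config$families)
    add(c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros"),
        "gradient")
  if ("ar" %in% config$families)
    add(c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma"), "ar")
  if ("wavelet" %in% config$families)
    add(as.vector(t(outer(sort(config$scales), c("LL", "LH", "HL", "HH"),
                          function(s, b) sprintf("WavEn%s_s-%d", b, s)))),
        "wavelet")
  if ("geometry" %in% config$families)
    add(c("GeoX", "GeoY", "GeoXo", "GeoYo", "GeoXYo", "GeoS2", "GeoM2xy"),
        "geometry")
  data.frame(name = nm, family = fam, stringsAsFactors = FALSE)
}

#' Extract the full texture feature vector of one masked raster
#'
#' Concatenates all enabled families over one ROI: co-occurrence features
#' for every configured offset, run-length features in four directions,
#' histogram, gradient, autoregressive, Haar-wavelet energies and mask
#' geometry. The co-occurrence and run-length families operate on the
#' quantized region; the remaining intensity families operate on the raw
#' in-ROI values. Output is deterministic given `raster`, `roi` and
#' `config`, with names exactly matching [feature_registry()].
#'
#' @param raster Numeric matrix (e.g. an ADC map's `values`).
#' @param roi A [roi_mask()] or logical matrix.
#' @param config A [texture_config()].
#'
#' @return Named numeric vector; a feature undefined for this ROI (e.g. a
#'   wavelet scale larger than the mask bounding box) is `NA`.
#' @export
extract_all <- function(raster, roi, config = texture_config()) {
  stopifnot(inherits(config, "texture_config"))
  raster <- as.matrix(raster)
  roi <- as_roi_mask(roi)
  reg <- feature_registry(config)
  out <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  need_q <- any(c("glcm", "rlm") %in% config$families)
  if (need_q)
    q <- quantize_roi(raster, roi, bits = config$bits,
                      normalization = config$normalization)
  if ("glcm" %in% config$families)
    for (off in glcm_offsets(config$distances)) {
      f <- glcm_features(glcm(q, off), prefix = offset_token(off))
      out[names(f)] <- f
    }
  if ("rlm" %in% config$families)
    for (d in c("0", "45", "90", "135")) {
      f <- rlm_features(q, as.numeric(d),
                        prefix = rlm_direction_prefix[[d]])
      out[names(f)] <- f
    }
  if ("histogram" %in% config$families) {
    f <- histogram_features(raster, roi); out[names(f)] <- f
  }
  if ("gradient" %in% config$families) {
    f <- gradient_features(raster, roi); out[names(f)] <- f
  }
  if ("ar" %in% config$families) {
    f <- ar_features(raster, roi); out[names(f)] <- f
  }
  if ("wavelet" %in% config$families) {
    f <- wavelet_features(raster, roi, scales = config$scales)
    out[names(f)] <- f
  }
  if ("geometry" %in% config$families) {
    f <- geometry_features(roi); out[names(f)] <- f
  }
  out
}
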