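#' Paired diffusion-weighted slice
#'
#' Bundle the co-registered b = 0 and b > 0 signal rasters for one image
#' slice, together with the diffusion weighting and the pixel spacing.
#' Rasters are numeric matrices indexed `[row, column]` with row 1 at the
#' top of the image.
#'
#' @param s0 Numeric matrix, signal at b = 0 s/mm^2 (arbitrary units, >= 0).
#' @param sb Numeric matrix of the same dimensions, signal at `b_value`.
#' @param b_value Diffusion weighting in s/mm^2; must be > 0.
#' @param pixel_spacing Edge length of a pixel in mm; must be > 0.
#' @param slice_id,nodule_id Identifiers carried through the pipeline.
#'
#' @return An object of class `dwi_slice_pair`.
#' @export
#' @examples
#' s0 <- matrix(100, 4, 4)
#' sb <- s0 * exp(-500 * 2e-3)
#' pair <- dwi_slice_pair(s0, sb, b_value = 500, pixel_spacing = 0.86)
dwi_slice_pair <- function(s0, sb, b_value = 500, pixel_spacing = 1,
                           slice_id = 1L, nodule_id = 1L) {
  s0 <- as.matrix(s0); sb <- as.matrix(sb)
  if (!identical(dim(s0), dim(sb)))
    stop("s0 and sb must have identical dimensions", call. = FALSE)
  if (!is.numeric(b_value) || length(b_value) != 1L || b_value <= 0)
    stop("b_value must be a single positive number", call. = FALSE)
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("pixel_spacing must be a single positive number", call. = FALSE)
  if (any(s0 < 0, na.rm = TRUE) || any(sb < 0, na.rm = TRUE))
    stop("signals must be non-negative", call. = FALSE)
  structure(
    list(s0 = s0, sb = sb, b_value = b_value,
         pixel_spacing = pixel_spacing,
         slice_id = slice_id, nodule_id = nodule_id),
    class = "dwi_slice_pair")
}

#' Region-of-interest mask
#'
#' A binary mask on the slice grid. Any non-zero / `TRUE` pixel belongs to
#' the region of interest.
#'
#' @param mask Logical or numeric matrix; non-zero means in-ROI.
#' @param pixel_spacing Pixel edge in mm, used to report the area in mm^2.
#'
#' @return An object of class `roi_mask` with elements `mask` (logical
#'   matrix), `area_px` and `area_mm2`.
#' @export
roi_mask <- function(mask, pixel_spacing = 1) {
  mask <- as.matrix(mask)
  m <- mask != 0
  m[is.na(m)] <- FALSE
  area <- sum(m)
  if (area < 1L) stop("ROI mask must contain at least one pixel", call. = FALSE)
  structure(
    list(mask = m, area_px = area, area_mm2 = area * pixel_spacing^2,
         pixel_spacing = pixel_spacing),
    class = "roi_mask")
}

as_roi_mask <- function(x, pixel_spacing = 1) {
  if (inherits(x, "roi_mask")) x else roi_mask(x, pixel_spacing)
}

#' Compute a noise-rectified ADC map from a b-value pair
#'
#' Inverts the mono-exponential decay `S(b) = S(0) * exp(-b * ADC)` pixel by
#' pixel. Magnitude signals are first rectified for the noise floor by
#' quadrature subtraction, `S' = sqrt(max(S^2 - noise_floor^2, 0))`, which
#' reduces the upward bias of Rician magnitude noise and degenerates to the
#' plain log-quotient when `noise_floor = 0`. A pixel is valid when both
#' rectified signals are positive; valid pixels with `sb' > s0'` (which
#' would give a negative ADC) are clipped to 0 and counted in `n_clipped`.
#'
#' @param pair A [dwi_slice_pair()].
#' @param noise_floor Non-negative signal level subtracted in quadrature.
#'
#' @return An object of class `adc_map`: list with `values` (matrix of ADC
#'   in mm^2/s, `NA` where invalid), `valid_mask` (logical matrix) and
#'   `n_clipped` (count of negative-ADC pixels clipped to 0).
#' @export
#' @examples
#' s0 <- matrix(100, 2, 2)
#' sb <- s0 * exp(-500 * 0.002)
#' compute_adc(dwi_slice_pair(s0, sb))$values  # all 0.002
compute_adc <- function(pair, noise_floor = 0) {
  stopifnot(inherits(pair, "dwi_slice_pair"))
  if (!is.numeric(noise_floor) || length(noise_floor) != 1L || noise_floor < 0)
    stop("noise_floor must be a single non-negative number", call. = FALSE)
  s0r <- sqrt(pmax(pair$s0^2 - noise_floor^2, 0))
  sbr <- sqrt(pmax(pair$sb^2 - noise_floor^2, 0))
  valid <- s0r > 0 & sbr > 0
  values <- matrix(NA_real_, nrow(s0r), ncol(s0r))
  values[valid] <- log(s0r[valid] / sbr[valid]) / pair$b_value
  neg <- valid & values < 0
  n_clipped <- sum(neg)
  values[neg] <- 0
  structure(list(values = values, valid_mask = valid, n_clipped = n_clipped),
            class = "adc_map")
}

#' Mean ADC over a region of interest
#'
#' Averages the ADC map over the valid pixels of the ROI and reports the ROI
#' area in pixels (the weight used when pooling slices into a nodule mean).
#'
#' @param adc An `adc_map` from [compute_adc()].
#' @param roi A [roi_mask()] (or bare logical matrix) on the same grid.
#'
#' @return An object of class `roi_summary`: list with `area` (pixels) and
#'   `mean_adc` (mm^2/s).
#' @export
roi_mean_adc <- function(adc, roi) {
  stopifnot(inherits(adc, "adc_map"))
  roi <- as_roi_mask(roi)
  if (!identical(dim(roi$mask), dim(adc$values)))
    stop("ROI mask and ADC map dimensions differ", call. = FALSE)
  sel <- roi$mask & adc$valid_mask
  if (!any(sel))
    stop("no valid ADC pixel inside the ROI", call. = FALSE)
  structure(list(area = sum(roi$mask), mean_adc = mean(adc$values[sel])),
            class = "roi_summary")
}

#' Area-weighted mean ADC over the slices of a nodule
#'
#' Pools per-slice ROI mean ADC values `x_i` with their ROI areas `w_i` into
#' the overall weighted mean `sum(w_i * x_i) / sum(w_i)`. Because only the
#' ratio of weights matters, areas may be given in pixels or mm^2.
#'
#' @param summaries A list of `roi_summary` objects (or lists with `area`
#'   and `mean_adc`).
#'
#' @return The weighted mean ADC in mm^2/s.
#' @export
#' @examples
#' weighted_mean_adc(list(list(area = 1, mean_adc = 2),
#'                        list(area = 3, mean_adc = 1)))  # 1.25
weighted_mean_adc <- function(summaries) {
  if (!is.list(summaries) || length(summaries) == 0L)
    stop("summaries must be a non-empty list", call. = FALSE)
  w <- vapply(summaries, function(s) as.numeric(s$area), numeric(1))
  x <- vapply(summaries, function(s) as.numeric(s$mean_adc), numeric(1))
  if (any(w <= 0)) stop("all ROI areas must be positive", call. = FALSE)
  sum(w * x) / sum(w)
}
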