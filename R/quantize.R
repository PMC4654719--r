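#' Quantize an image region to discrete gray levels
#'
#' Maps the in-ROI intensities of a raster onto integer gray levels
#' `1..G` with `G = 2^bits`, the preprocessing step shared by the
#' co-occurrence and run-length texture families. Three normalization
#' windows are supported:
#'
#' * `"minmax"`: the window is the in-ROI `[min, max]`;
#' * `"mu3sigma"`: `[mu - 3*sigma, mu + 3*sigma]` with values outside
#'   clipped to the window;
#' * `"perc1_99"`: the 1st to 99th in-ROI percentile window, clipped.
#'
#' A constant region maps to level 1 everywhere.
#'
#' @param raster Numeric matrix of intensities.
#' @param roi A [roi_mask()] or logical matrix on the same grid.
#' @param bits Bit depth, 4..12 in routine use (lower values allowed for
#'   worked examples); `G = 2^bits`.
#' @param normalization One of `"minmax"`, `"mu3sigma"`, `"perc1_99"`.
#'
#' @return An object of class `quantized_roi`: list with `levels` (integer
#'   matrix, `NA` outside the mask), `G`, `mask` (logical matrix) and
#'   `normalization`.
#' @export
quantize_roi <- function(raster, roi, bits = 6L,
                         normalization = c("mu3sigma", "minmax", "perc1_99")) {
  normalization <- match.arg(normalization)
  raster <- as.matrix(raster)
  roi <- as_roi_mask(roi)
  mask <- roi$mask
  if (!identical(dim(mask), dim(raster)))
    stop("ROI mask and raster dimensions differ", call. = FALSE)
  if (!any(mask)) stop("ROI is empty", call. = FALSE)
  if (bits < 1 || bits > 12) stop("bits must be in 1..12", call. = FALSE)
  G <- as.integer(2^bits)
  x <- raster[mask]
  win <- switch(normalization,
    minmax   = range(x),
    mu3sigma = {
      mu <- mean(x); s <- stats::sd(x)
      if (is.na(s)) s <- 0
      c(mu - 3 * s, mu + 3 * s)
    },
    perc1_99 = as.numeric(stats::quantile(x, c(0.01, 0.99), type = 7)))
  lv <- matrix(NA_integer_, nrow(raster), ncol(raster))
  if (win[2] <= win[1]) {
    lv[mask] <- 1L
  } else {
    xc <- pmin(pmax(x, win[1]), win[2])
    lv[mask] <- pmin(G, as.integer(floor((xc - win[1]) /
                                           (win[2] - win[1]) * G)) + 1L)
  }
  structure(list(levels = lv, G = G, mask = mask,
                 normalization = normalization, window = win),
            class = "quantized_roi")
}
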