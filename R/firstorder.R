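#' Histogram (first-order) texture features
#'
#' Moments and percentiles of the raw in-ROI intensity distribution: mean,
#' variance, skewness, excess kurtosis and the 1st, 10th, 50th, 90th and
#' 99th percentiles (linear interpolation, the type-7 quantile rule).
#' Moments are population moments (denominator `n`); skewness and kurtosis
#' of a constant region are defined as 0 and flagged degenerate.
#'
#' @param raster Numeric matrix of intensities.
#' @param roi A [roi_mask()] or logical matrix.
#'
#' @return Named numeric vector: `Mean`, `Variance`, `Skewness`,
#'   `Kurtosis`, `Perc.01%`, `Perc.10%`, `Perc.50%`, `Perc.90%`,
#'   `Perc.99%`.
#' @export
histogram_features <- function(raster, roi) {
  raster <- as.matrix(raster)
  roi <- as_roi_mask(roi)
  if (!identical(dim(roi$mask), dim(raster)))
    stop("ROI mask and raster dimensions differ", call. = FALSE)
  x <- raster[roi$mask]
  if (!length(x)) stop("ROI is empty", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  q <- stats::quantile(x, c(0.01, 0.10, 0.50, 0.90, 0.99), type = 7,
                       names = FALSE)
  stats::setNames(c(mu, m2, skew, kurt, q),
                  c("Mean", "Variance", "Skewness", "Kurtosis",
                    "Perc.01%", "Perc.10%", "Perc.50%", "Perc.90%",
                    "Perc.99%"))
}

#' Absolute gradient texture features
#'
#' Gradient magnitude by central differences, `gx = (x[r, c+1] -
#' x[r, c-1]) / 2` and similarly along rows, evaluated at in-ROI pixels
#' whose four edge neighbours are also in-ROI. Returns the population
#' mean, variance, skewness and excess kurtosis of the magnitudes and the
#' fraction of nonzero gradients. A region with no interior pixel yields
#' `NA` features (flagged for exclusion upstream).
#'
#' @inheritParams histogram_features
#'
#' @return Named numeric vector: `GrMean`, `GrVariance`, `GrSkewness`,
#'   `GrKurtosis`, `GrNonZeros`.
#' @export
gradient_features <- function(raster, roi) {
  raster <- as.matrix(raster)
  roi <- as_roi_mask(roi)
  m <- roi$mask
  if (!identical(dim(m), dim(raster)))
    stop("ROI mask and raster dimensions differ", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  nm <- c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros")
  if (nr < 3 || nc < 3)
    return(stats::setNames(rep(NA_real_, 5), nm))
  core <- 2:(nr - 1)
  corc <- 2:(nc - 1)
  interior <- m[core, corc] &
    m[core - 1, corc] & m[core + 1, corc] &
    m[core, corc - 1] & m[core, corc + 1]
  if (!any(interior))
    return(stats::setNames(rep(NA_real_, 5), nm))
  gx <- (raster[core, corc + 1] - raster[core, corc - 1]) / 2
  gy <- (raster[core + 1, corc] - raster[core - 1, corc]) / 2
  g <- sqrt(gx^2 + gy^2)[interior]
  mu <- mean(g)
  m2 <- mean((g - mu)^2)
  if (m2 > 0) {
    skew <- mean((g - mu)^3) / m2^1.5
    kurt <- mean((g - mu)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  stats::setNames(c(mu, m2, skew, kurt, mean(g != 0)), nm)
}
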