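#' Geometric (mask moment) features
#'
#' Moment-based descriptors of the binary ROI mask itself, in pixel units
#' with 1-based image coordinates (`x` = column, `y` = row, row 1 at the
#' top): the centroid in the image frame (`GeoX`, `GeoY`), the centroid
#' offsets relative to the mask bounding-box origin (`GeoXo`, `GeoYo`) and
#' their product (`GeoXYo`), the area-normalized second central moment
#' `GeoS2 = (mu20 + mu02) / A` (mean squared distance of mask pixels from
#' the centroid), and the area-normalized mixed second central moment
#' `GeoM2xy = mu11 / A`.
#'
#' `GeoX`/`GeoY` encode nodule position in the image frame; in study
#' designs where position could correlate spuriously with class the family
#' can be disabled in [texture_config()].
#'
#' @param roi A [roi_mask()] or logical matrix.
#'
#' @return Named numeric vector: `GeoX`, `GeoY`, `GeoXo`, `GeoYo`,
#'   `GeoXYo`, `GeoS2`, `GeoM2xy`.
#' @export
geometry_features <- function(roi) {
  roi <- as_roi_mask(roi)
  m <- roi$mask
  if (!any(m)) stop("ROI is empty", call. = FALSE)
  ridx <- row(m)[m]
  cidx <- col(m)[m]
  A <- length(ridx)
  cy <- mean(ridx); cx <- mean(cidx)
  mu20 <- sum((cidx - cx)^2)
  mu02 <- sum((ridx - cy)^2)
  mu11 <- sum((cidx - cx) * (ridx - cy))
  xo <- cx - min(cidx)
  yo <- cy - min(ridx)
  stats::setNames(c(cx, cy, xo, yo, xo * yo,
                    (mu20 + mu02) / A, mu11 / A),
                  c("GeoX", "GeoY", "GeoXo", "GeoYo", "GeoXYo",
                    "GeoS2", "GeoM2xy"))
}
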