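#' Causal autoregressive model texture features
#'
#' Fits by least squares the four-neighbour causal model
#' `x(i, j) = t1 x(i, j-1) + t2 x(i-1, j-1) + t3 x(i-1, j) +
#' t4 x(i-1, j+1) + e` over mean-centred in-ROI intensities, using every
#' pixel whose four causal neighbours are also in-ROI. Returns the model
#' coefficients `Teta1..Teta4` and `Sigma`, the residual standard
#' deviation (population form). With fewer than 5 usable pixels the
#' features are `NA` (flagged undefined).
#'
#' @inheritParams histogram_features
#'
#' @return Named numeric vector: `Teta1`, `Teta2`, `Teta3`, `Teta4`,
#'   `Sigma`.
#' @export
ar_features <- function(raster, roi) {
  raster <- as.matrix(raster)
  roi <- as_roi_mask(roi)
  m <- roi$mask
  if (!identical(dim(m), dim(raster)))
    stop("ROI mask and raster dimensions differ", call. = FALSE)
  nm <- c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma")
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2 || nc < 3)
    return(stats::setNames(rep(NA_real_, 5), nm))
  x <- raster
  x[m] <- x[m] - mean(x[m])
  r <- 2:nr; c <- 2:(nc - 1)
  usable <- m[r, c] & m[r, c - 1] & m[r - 1, c - 1] & m[r - 1, c] &
    m[r - 1, c + 1]
  if (sum(usable) < 5)
    return(stats::setNames(rep(NA_real_, 5), nm))
  y  <- x[r, c][usable]
  X <- cbind(x[r, c - 1][usable],
             x[r - 1, c - 1][usable],
             x[r - 1, c][usable],
             x[r - 1, c + 1][usable])
  fit <- stats::lm.fit(X, y)
  theta <- as.numeric(fit$coefficients)
  theta[is.na(theta)] <- 0   # aliased regressors contribute nothing
  res <- y - X %*% theta
  stats::setNames(c(theta, sqrt(mean(res^2))), nm)
}
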