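#' Haar wavelet subband energies over a masked region
#'
#' Runs a decimated 2D Haar multiresolution transform over the ROI
#' bounding box (padded to dyadic size by edge replication) and reports,
#' per scale `s` and subband `B` in LL, LH, HL, HH, the mean of squared
#' coefficients whose `2^s x 2^s` spatial support overlaps the mask. In a
#' subband name the first letter is the filter applied along rows
#' (vertical direction) and the second along columns, so HL carries
#' horizontal-edge detail. Names follow the `WavEn{B}_s-{s}` convention,
#' e.g. `WavEnHH_s-3`. A scale whose bounding box is smaller than `2^s`
#' in either dimension is flagged undefined (`NA`).
#'
#' @inheritParams histogram_features
#' @param scales Integer vector of decomposition scales, default `1:3`.
#'
#' @return Named numeric vector of `4 * length(scales)` energies.
#' @export
wavelet_features <- function(raster, roi, scales = 1:3) {
  raster <- as.matrix(raster)
  roi <- as_roi_mask(roi)
  m <- roi$mask
  if (!identical(dim(m), dim(raster)))
    stop("ROI mask and raster dimensions differ", call. = FALSE)
  if (!any(m)) stop("ROI is empty", call. = FALSE)
  scales <- sort(as.integer(scales))
  bands <- c("LL", "LH", "HL", "HH")
  nm <- as.vector(t(outer(scales, bands,
                          function(s, b) sprintf("WavEn%s_s-%d", b, s))))
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)

  rr <- range(which(rowSums(m) > 0))
  cc <- range(which(colSums(m) > 0))
  box <- raster[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mbox <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  bnr <- nrow(box); bnc <- ncol(box)
  smax <- max(scales)
  # pad to the next power of two >= max(dim, 2^smax) by edge replication
  dy <- 2^max(smax, ceiling(log2(max(bnr, 1))))
  dx <- 2^max(smax, ceiling(log2(max(bnc, 1))))
  ridx <- c(seq_len(bnr), rep(bnr, dy - bnr))
  cidx <- c(seq_len(bnc), rep(bnc, dx - bnc))
  xs <- box[ridx, cidx, drop = FALSE]
  ms <- mbox[ridx, cidx, drop = FALSE]
  # padding replicates intensities but not mask membership
  ms[seq_len(dy) > bnr, ] <- FALSE
  ms[, seq_len(dx) > bnc] <- FALSE

  ll <- xs
  msk <- ms
  for (s in seq_len(smax)) {
    w <- haar_step(ll)
    msk <- mask_downsample(msk)
    if (s %in% scales && bnr >= 2^s && bnc >= 2^s && any(msk)) {
      for (b in bands)
        out[sprintf("WavEn%s_s-%d", b, s)] <- mean(w[[b]][msk]^2)
    }
    ll <- w$LL
    if (nrow(ll) < 2 || ncol(ll) < 2) break
  }
  out
}

## One level of the decimated orthonormal Haar transform; input has even
## dimensions.
haar_step <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  o <- seq(1, nr, 2); e <- seq(2, nr, 2)
  L <- (x[o, , drop = FALSE] + x[e, , drop = FALSE]) / sqrt(2)
  H <- (x[o, , drop = FALSE] - x[e, , drop = FALSE]) / sqrt(2)
  oc <- seq(1, nc, 2); ec <- seq(2, nc, 2)
  list(LL = (L[, oc, drop = FALSE] + L[, ec, drop = FALSE]) / sqrt(2),
       LH = (L[, oc, drop = FALSE] - L[, ec, drop = FALSE]) / sqrt(2),
       HL = (H[, oc, drop = FALSE] + H[, ec, drop = FALSE]) / sqrt(2),
       HH = (H[, oc, drop = FALSE] - H[, ec, drop = FALSE]) / sqrt(2))
}

## 2x2 block OR: TRUE where the coefficient support overlaps the mask.
mask_downsample <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  o <- seq(1, nr, 2); e <- seq(2, nr, 2)
  v <- m[o, , drop = FALSE] | m[e, , drop = FALSE]
  oc <- seq(1, nc, 2); ec <- seq(2, nc, 2)
  v[, oc, drop = FALSE] | v[, ec, drop = FALSE]
}
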