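#' Gray-level co-occurrence matrix over a masked region
#'
#' Counts pairs of quantized gray levels at a fixed pixel displacement,
#' restricted to pairs whose both endpoints lie inside the mask. Pairs are
#' accumulated symmetrically (each pair counted in both orders) and the
#' matrix is normalized to sum to 1. The offset is given as `(dx, dy)`
#' where `dx` is the column displacement (positive rightward) and `dy` the
#' row displacement (positive downward), matching the `S(dx,dy)` tokens of
#' the feature registry: direction 0 deg is `(d, 0)`, 90 deg is `(0, d)`,
#' 45 deg is `(d, -d)` and 135 deg is `(d, d)` for distances `d = 1..5`.
#'
#' @param q A [quantize_roi()] result.
#' @param offset Integer vector `c(dx, dy)`, not both zero.
#'
#' @return An object of class `glc_matrix`: list with `p` (G x G matrix
#'   summing to 1), `offset`, `n_pairs` and `degenerate` (TRUE when no
#'   in-mask pair exists, in which case `p` is all zero).
#' @export
glcm <- function(q, offset) {
  stopifnot(inherits(q, "quantized_roi"))
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stop("offset must be a nonzero (dx, dy) pair", call. = FALSE)
  dx <- offset[1]; dy <- offset[2]
  lv <- q$levels; G <- q$G
  nr <- nrow(lv); nc <- ncol(lv)
  r1 <- max(1L, 1L - dy):min(nr, nr - dy)
  c1 <- max(1L, 1L - dx):min(nc, nc - dx)
  counts <- integer(G * G)
  n_pairs <- 0L
  if (length(r1) >= 1L && length(c1) >= 1L && r1[1] <= r1[length(r1)] &&
      c1[1] <= c1[length(c1)]) {
    a <- lv[r1, c1, drop = FALSE]
    b <- lv[r1 + dy, c1 + dx, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      i <- a[ok]; j <- b[ok]
      counts <- tabulate((i - 1L) * G + j, nbins = G * G)
      n_pairs <- length(i)
    }
  }
  p <- matrix(counts, G, G, byrow = TRUE)
  p <- p + t(p)                        # symmetric accumulation
  tot <- sum(p)
  degenerate <- tot == 0
  if (!degenerate) p <- p / tot
  structure(list(p = p, offset = c(dx = dx, dy = dy),
                 n_pairs = n_pairs, degenerate = degenerate),
            class = "glc_matrix")
}

#' Haralick-type features of a co-occurrence matrix
#'
#' Computes the 11-feature co-occurrence set used by MaZda-style texture
#' reports: angular second moment, contrast, correlation, sum of squares
#' (variance), inverse difference moment, sum average, sum variance, sum
#' entropy, entropy, difference variance and difference entropy. Diagonal
#' marginals `p_{x+y}` and `p_{x-y}` are used for the sum/difference
#' statistics; entropies use the natural logarithm with the convention
#' `0 * log 0 = 0`. For a degenerate (all-zero) matrix every feature is 0;
#' correlation is defined as 0 when either marginal standard deviation is 0.
#'
#' @param m A [glcm()] result.
#' @param prefix Optional string prepended to the feature names, e.g.
#'   `"S(1,0)"`.
#'
#' @return Named numeric vector of 11 features.
#' @export
glcm_features <- function(m, prefix = "") {
  stopifnot(inherits(m, "glc_matrix"))
  nm <- paste0(prefix, c("AngScMom", "Contrast", "Correlat", "SumOfSqs",
                         "InvDfMom", "SumAverg", "SumVarnc", "SumEntrp",
                         "Entropy", "DifVarnc", "DifEntrp"))
  p <- m$p
  G <- nrow(p)
  out <- stats::setNames(numeric(11), nm)
  if (m$degenerate) return(out)
  i <- row(p); j <- col(p)
  px <- rowSums(p)                     # symmetric: px == py
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  sig <- sqrt(sig2)
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  # p_{x+y}(k), k = 2..2G ; p_{x-y}(k), k = 0..G-1
  psum <- vapply(2:(2 * G), function(k) sum(p[i + j == k]), numeric(1))
  pdif <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * G)
  kdif <- 0:(G - 1)
  sum_avg <- sum(ksum * psum)
  dif_avg <- sum(kdif * pdif)
  out[nm[1]]  <- sum(p^2)
  out[nm[2]]  <- sum((i - j)^2 * p)
  out[nm[3]]  <- if (sig > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  out[nm[4]]  <- sig2
  out[nm[5]]  <- sum(p / (1 + (i - j)^2))
  out[nm[6]]  <- sum_avg
  out[nm[7]]  <- sum((ksum - sum_avg)^2 * psum)
  out[nm[8]]  <- -sum(xlogx(psum))
  out[nm[9]]  <- -sum(xlogx(p))
  out[nm[10]] <- sum((kdif - dif_avg)^2 * pdif)
  out[nm[11]] <- -sum(xlogx(pdif))
  out
}

## The 20 displacement offsets of the co-occurrence family:
## directions 0, 90, 45, 135 degrees at distances 1..5.
glcm_offsets <- function(distances = 1:5) {
  out <- list()
  for (d in distances) {
    out[[length(out) + 1L]] <- c(d, 0)    # 0 deg
    out[[length(out) + 1L]] <- c(0, d)    # 90 deg
    out[[length(out) + 1L]] <- c(d, -d)   # 45 deg
    out[[length(out) + 1L]] <- c(d, d)    # 135 deg
  }
  out
}

offset_token <- function(offset) sprintf("S(%d,%d)", offset[1], offset[2])
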