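## Independent brute-force oracles, deliberately written as plain loops
## over pixels so they share no code path with the package internals.

## Symmetric normalized co-occurrence matrix by exhaustive pair
## enumeration. `levels` is an integer matrix with NA outside the mask.
oracle_glcm <- function(levels, G, dx, dy) {
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, G, G)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    i <- levels[r, c]; j <- levels[r2, c2]
    if (is.na(i) || is.na(j)) next
    counts[i, j] <- counts[i, j] + 1
    counts[j, i] <- counts[j, i] + 1
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

## Textbook Haralick formulas by direct double summation.
oracle_glcm_features <- function(p) {
  G <- nrow(p)
  asm <- 0; con <- 0; ent <- 0; idm <- 0; pij <- 0
  mx <- 0
  for (i in 1:G) for (j in 1:G) mx <- mx + i * p[i, j]
  vx <- 0
  for (i in 1:G) for (j in 1:G) vx <- vx + (i - mx)^2 * p[i, j]
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    asm <- asm + v^2
    con <- con + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    pij <- pij + i * j * v
    if (v > 0) ent <- ent - v * log(v)
  }
  corr <- if (vx > 0) (pij - mx^2) / vx else 0
  psum <- numeric(2 * G)
  pdif <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  savg <- 0
  for (k in 2:(2 * G)) savg <- savg + k * psum[k]
  svar <- 0; sent <- 0
  for (k in 2:(2 * G)) {
    svar <- svar + (k - savg)^2 * psum[k]
    if (psum[k] > 0) sent <- sent - psum[k] * log(psum[k])
  }
  davg <- 0
  for (k in 0:(G - 1)) davg <- davg + k * pdif[k + 1]
  dvar <- 0; dent <- 0
  for (k in 0:(G - 1)) {
    dvar <- dvar + (k - davg)^2 * pdif[k + 1]
    if (pdif[k + 1] > 0) dent <- dent - pdif[k + 1] * log(pdif[k + 1])
  }
  c(AngScMom = asm, Contrast = con, Correlat = corr, SumOfSqs = vx,
    InvDfMom = idm, SumAverg = savg, SumVarnc = svar, SumEntrp = sent,
    Entropy = ent, DifVarnc = dvar, DifEntrp = dent)
}

## Run-length features by explicit line walking.
oracle_rlm <- function(levels, direction) {
  nr <- nrow(levels); nc <- ncol(levels)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "90" = c(1, 0),
                 "45" = c(-1, 1), "135" = c(1, 1))
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]
    if (pr < 1 || pr > nr || pc < 1 || pc > nc)
      starts[[length(starts) + 1]] <- c(r, c)
  }
  runs_level <- integer(0); runs_len <- integer(0)
  for (st in starts) {
    r <- st[1]; c <- st[2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) {
          runs_level <- c(runs_level, cur); runs_len <- c(runs_len, len)
        }
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur)) {
      runs_level <- c(runs_level, cur); runs_len <- c(runs_len, len)
    }
  }
  C <- length(runs_len)
  n_px <- sum(!is.na(levels))
  if (C == 0)
    return(c(ShrtREmp = 0, LngREmph = 0, GLevNonUni = 0, RLNonUni = 0,
             Fraction = 0))
  c(ShrtREmp = sum(1 / runs_len^2) / C,
    LngREmph = sum(runs_len^2) / C,
    GLevNonUni = sum(table(runs_level)^2) / C,
    RLNonUni = sum(table(runs_len)^2) / C,
    Fraction = C / n_px)
}

## First-order statistics from the sorted sample.
oracle_histogram <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  pct <- function(p) {
    s <- sort(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  c(Mean = mu, Variance = m2,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    `Perc.01%` = pct(0.01), `Perc.10%` = pct(0.10),
    `Perc.50%` = pct(0.50), `Perc.90%` = pct(0.90),
    `Perc.99%` = pct(0.99))
}

## Gradient magnitudes at interior pixels by explicit loops.
oracle_gradient_mags <- function(raster, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  g <- c()
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    if (mask[r, c] && mask[r - 1, c] && mask[r + 1, c] &&
        mask[r, c - 1] && mask[r, c + 1]) {
      gx <- (raster[r, c + 1] - raster[r, c - 1]) / 2
      gy <- (raster[r + 1, c] - raster[r - 1, c]) / 2
      g <- c(g, sqrt(gx^2 + gy^2))
    }
  }
  g
}

## Mask moments by pixel summation.
oracle_geometry <- function(mask) {
  sx <- 0; sy <- 0; A <- 0
  nr <- nrow(mask); nc <- ncol(mask)
  for (r in seq_len(nr)) for (c in seq_len(nc)) if (mask[r, c]) {
    A <- A + 1; sx <- sx + c; sy <- sy + r
  }
  cx <- sx / A; cy <- sy / A
  m20 <- 0; m02 <- 0; m11 <- 0
  rmin <- Inf; cmin <- Inf
  for (r in seq_len(nr)) for (c in seq_len(nc)) if (mask[r, c]) {
    m20 <- m20 + (c - cx)^2
    m02 <- m02 + (r - cy)^2
    m11 <- m11 + (c - cx) * (r - cy)
    rmin <- min(rmin, r); cmin <- min(cmin, c)
  }
  c(GeoX = cx, GeoY = cy, GeoXo = cx - cmin, GeoYo = cy - rmin,
    GeoXYo = (cx - cmin) * (cy - rmin),
    GeoS2 = (m20 + m02) / A, GeoM2xy = m11 / A)
}

## One Haar level by explicit 2x2 block arithmetic.
oracle_haar_level <- function(x) {
  nr <- nrow(x) / 2; nc <- ncol(x) / 2
  LL <- LH <- HL <- HH <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- x[2 * i - 1, 2 * j - 1]; b <- x[2 * i - 1, 2 * j]
    c_ <- x[2 * i, 2 * j - 1]; d <- x[2 * i, 2 * j]
    LL[i, j] <- (a + b + c_ + d) / 2
    LH[i, j] <- (a - b + c_ - d) / 2   # high-pass along columns
    HL[i, j] <- (a + b - c_ - d) / 2   # high-pass along rows
    HH[i, j] <- (a - b - c_ + d) / 2
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

## Fisher discriminant direction via the generalized eigenproblem
## Sw^{-1} Sb, solved with eigen() -- an independent route to the
## projection.
oracle_lda_direction <- function(X, y) {
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  Sw <- ((n0 - 1) * cov(X[y == 0, , drop = FALSE]) +
           (n1 - 1) * cov(X[y == 1, , drop = FALSE])) / (n0 + n1 - 2)
  Sb <- outer(m1 - m0, m1 - m0)
  e <- eigen(solve(Sw) %*% Sb)
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sqrt(sum(v^2))
}

## Mann-Whitney AUC with half-weight ties.
oracle_auc_mw <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

## Random raster + random connected-ish mask for oracle sweeps.
random_masked_raster <- function(n = 8, p_mask = 0.7) {
  repeat {
    mask <- matrix(runif(n * n) < p_mask, n, n)
    if (sum(mask) >= 8) break
  }
  list(raster = matrix(rnorm(n * n), n, n), mask = mask)
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
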