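#' Run-length texture features
#'
#' Builds the gray-level run-length matrix of a quantized region along one
#' of the four principal directions and returns the classical five
#' statistics: short-run emphasis, long-run emphasis, gray-level
#' non-uniformity, run-length non-uniformity, and the fraction of the
#' region in runs (number of runs divided by the number of in-mask pixels).
#' Runs are maximal sequences of equal gray level along the direction,
#' broken wherever the line leaves the mask.
#'
#' @param q A [quantize_roi()] result.
#' @param direction One of 0, 45, 90, 135 (degrees). 0 runs along image
#'   rows, 90 along columns, 45 along up-right diagonals, 135 along
#'   down-right diagonals.
#' @param prefix Optional string prepended to the feature names; the
#'   registry uses `"Horzl_"`, `"45dgr_"`, `"Vertl_"`, `"135dr_"`.
#'
#' @return Named numeric vector of 5 features.
#' @export
rlm_features <- function(q, direction = 0, prefix = "") {
  stopifnot(inherits(q, "quantized_roi"))
  if (!direction %in% c(0, 45, 90, 135))
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE)
  runs <- rlm_runs(q, direction)
  nm <- paste0(prefix, c("ShrtREmp", "LngREmph", "GLevNonUni",
                         "RLNonUni", "Fraction"))
  out <- stats::setNames(numeric(5), nm)
  n_px <- sum(q$mask)
  if (nrow(runs) == 0L) return(out)
  C <- sum(runs$count)
  out[nm[1]] <- sum(runs$count / runs$length^2) / C
  out[nm[2]] <- sum(runs$count * runs$length^2) / C
  gl <- tapply(runs$count, runs$level, sum)
  rl <- tapply(runs$count, runs$length, sum)
  out[nm[3]] <- sum(gl^2) / C
  out[nm[4]] <- sum(rl^2) / C
  out[nm[5]] <- C / n_px
  out
}

## Enumerate maximal in-mask runs along `direction`; returns a data frame
## with columns level, length, count.
rlm_runs <- function(q, direction) {
  lv <- q$levels
  nr <- nrow(lv); nc <- ncol(lv)
  lines <- switch(as.character(direction),
    "0"   = lapply(seq_len(nr), function(r) lv[r, ]),
    "90"  = lapply(seq_len(nc), function(c) lv[, c]),
    ## 45 deg: travel (dx = +1, dy = -1); lines of constant row + col,
    ## ordered by increasing column.
    "45"  = {
      rc <- row(lv) + col(lv)
      lapply(split(seq_along(lv)[order(col(lv))], rc[order(col(lv))]),
             function(idx) lv[idx])
    },
    ## 135 deg: travel (dx = +1, dy = +1); lines of constant col - row.
    "135" = {
      rc <- col(lv) - row(lv)
      lapply(split(seq_along(lv)[order(col(lv))], rc[order(col(lv))]),
             function(idx) lv[idx])
    })
  lev <- integer(0); len <- integer(0)
  for (line in lines) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    lev <- c(lev, r$values[keep])
    len <- c(len, r$lengths[keep])
  }
  if (!length(lev))
    return(data.frame(level = integer(0), length = integer(0),
                      count = integer(0)))
  agg <- stats::aggregate(list(count = rep(1L, length(lev))),
                          by = list(level = lev, length = len), FUN = sum)
  agg
}
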