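#' Configuration of a synthetic DW-MRI thyroid cohort
#'
#' All distributional parameters of the simulated study. Defaults encode
#' the population structure the analysis assumes: benign nodules with a
#' mean ADC of 2.24e-3 mm^2/s and malignant (papillary-carcinoma-like)
#' nodules with 1.92e-3 mm^2/s; maximum diameters of 29.3 +/- 8.0 mm
#' (benign) and 33.3 +/- 10.4 mm (malignant); 1 to 7 slices per nodule
#' with mean 4; a 256 x 256 reconstructed matrix over a 220 mm field of
#' view; and b-values of 0 and 500 s/mm^2. Class-dependent texture is
#' injected as a Gaussian random field added to the nodule ADC: malignant
#' nodules carry a coarser (longer correlation length) and stronger
#' (larger heterogeneity SD) field, so that texture and not only the mean
#' ADC separates the classes. Nodule position is uniform and independent
#' of class.
#'
#' @param n_benign,n_malignant Nodule counts of the training sub-cohort.
#' @param n_benign_test,n_malignant_test Nodule counts of the independent
#'   test sub-cohort (second site).
#' @param adc_mean_benign,adc_mean_malignant Class mean ADC, mm^2/s.
#' @param adc_between_sd Between-nodule SD of the nodule mean ADC.
#' @param adc_within_sd Slice-to-slice SD of the per-slice mean ADC
#'   within a nodule (not reported by the study design; exposed as a
#'   parameter).
#' @param adc_floor Lower truncation of drawn ADC means and fields.
#' @param corr_length_benign,corr_length_malignant Correlation length of
#'   the intranodular ADC field, mm.
#' @param het_sd_benign,het_sd_malignant Heterogeneity SD of the
#'   intranodular ADC field, mm^2/s.
#' @param diam_mean_benign,diam_sd_benign,diam_mean_malignant,diam_sd_malignant
#'   Maximum-diameter distributions, mm.
#' @param min_diameter Smallest admissible diameter, mm (smaller nodules
#'   are excluded from such studies).
#' @param slices_min,slices_max Range of slices per nodule; counts are
#'   drawn as `1 + Binomial(slices_max - 1, 0.5)`, giving mean 4 for the
#'   default 1..7.
#' @param matrix_size Reconstructed image matrix (square).
#' @param fov Field of view, mm.
#' @param b_value Diffusion weighting of the high-b image, s/mm^2.
#' @param s0_level Baseline b = 0 signal level, arbitrary units.
#' @param noise_sd Rician noise SD of the training-site acquisition.
#' @param noise_sd_test Rician noise SD of the test site (modestly
#'   different SNR emulating a second scanner).
#' @param background_adc ADC of tissue outside the nodule, mm^2/s.
#' @param seed Integer seed; every generated artifact records it.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_benign = 16L, n_malignant = 8L,
                          n_benign_test = 10L, n_malignant_test = 8L,
                          adc_mean_benign = 2.24e-3,
                          adc_mean_malignant = 1.92e-3,
                          adc_between_sd = 0.30e-3,
                          adc_within_sd = 0.08e-3,
                          adc_floor = 0.2e-3,
                          corr_length_benign = 1.8,
                          corr_length_malignant = 4.5,
                          het_sd_benign = 0.10e-3,
                          het_sd_malignant = 0.28e-3,
                          diam_mean_benign = 29.3, diam_sd_benign = 8.0,
                          diam_mean_malignant = 33.3,
                          diam_sd_malignant = 10.4,
                          min_diameter = 12,
                          slices_min = 1L, slices_max = 7L,
                          matrix_size = 256L, fov = 220,
                          b_value = 500, s0_level = 500,
                          noise_sd = 5, noise_sd_test = 6,
                          background_adc = 1.5e-3,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_benign >= 1, cfg$n_malignant >= 1,
            cfg$adc_between_sd >= 0, cfg$adc_within_sd >= 0,
            cfg$het_sd_benign >= 0, cfg$het_sd_malignant >= 0,
            cfg$noise_sd >= 0, cfg$fov > 0, cfg$matrix_size > 0,
            cfg$slices_min >= 1, cfg$slices_max >= cfg$slices_min,
            cfg$b_value > 0, cfg$s0_level > 0)
  cfg$pixel_spacing <- cfg$fov / cfg$matrix_size
  structure(cfg, class = "cohort_config")
}

## Gaussian random field with unit pixel variance and Gaussian
## autocorrelation of SD `corr_px` pixels, over an nr x nc grid.
gaussian_random_field <- function(nr, nc, corr_px) {
  if (corr_px <= 0) return(matrix(stats::rnorm(nr * nc), nr, nc))
  half <- max(1L, ceiling(3 * corr_px))
  k <- stats::dnorm(seq(-half, half), sd = corr_px)
  k <- k / sqrt(sum(k^2))              # unit variance after filtering
  pr <- nr + 2L * half; pc <- nc + 2L * half
  w <- matrix(stats::rnorm(pr * pc), pr, pc)
  A <- matrix(0, nr, pr)
  for (i in seq_len(nr)) A[i, i:(i + 2L * half)] <- k
  B <- matrix(0, nc, pc)
  for (j in seq_len(nc)) B[j, j:(j + 2L * half)] <- k
  A %*% w %*% t(B)
}

## Elliptical mask on the full grid; a, b in pixels, phi in radians.
ellipse_mask <- function(n, cy, cx, a, b, phi) {
  r <- matrix(seq_len(n), n, n) - cy
  c <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  u <- c * cos(phi) + r * sin(phi)
  v <- -c * sin(phi) + r * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

rician <- function(s, sd) {
  if (sd <= 0) return(s)
  sqrt((s + stats::rnorm(length(s), sd = sd))^2 +
         stats::rnorm(length(s), sd = sd)^2)
}

#' Generate one synthetic nodule
#'
#' Draws a nodule diameter and a nodule-level mean ADC from the class
#' distributions (truncated below at `adc_floor`), places an elliptical
#' ROI (eccentricity U(0.6, 1), random orientation) at a class-independent
#' uniform position, and for each slice synthesizes a true ADC field as
#' slice mean + heterogeneity * Gaussian random field with the class
#' correlation length. Slice ROIs shrink towards the nodule ends with an
#' ellipsoidal profile. Signals are `S0` (baseline with a mild planar
#' shading) and `Sb = S0 * exp(-b * ADC)`, both subjected to Rician
#' magnitude noise. A geometry draw whose smallest slice ROI falls below
#' 17 pixels is redrawn (and counted in `n_redraws`).
#'
#' @param config A [cohort_config()].
#' @param label `"benign"` or `"malignant"`.
#' @param nodule_id Identifier stamped on the slices.
#' @param noise_sd Rician noise SD override (site-dependent); defaults to
#'   `config$noise_sd`.
#' @param seed Optional integer; when given, the nodule is generated from
#'   a local RNG state so the same seed reproduces it bit for bit.
#'
#' @return An object of class `synthetic_nodule`: `label`, `slices` (list
#'   of [dwi_slice_pair()]), `masks` (list of [roi_mask()]),
#'   `true_slice_adc` (ROI mean of the noise-free field per slice),
#'   `nodule_mean_adc` (the drawn mean), `diameter`, `n_redraws`.
#' @export
generate_nodule <- function(config, label = c("benign", "malignant"),
                            nodule_id = "N1", noise_sd = config$noise_sd,
                            seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  label <- match.arg(label)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  mal <- label == "malignant"
  n <- config$matrix_size
  sp <- config$pixel_spacing
  adc_mu <- if (mal) config$adc_mean_malignant else config$adc_mean_benign
  d_mu <- if (mal) config$diam_mean_malignant else config$diam_mean_benign
  d_sd <- if (mal) config$diam_sd_malignant else config$diam_sd_benign
  corr <- if (mal) config$corr_length_malignant else
    config$corr_length_benign
  het <- if (mal) config$het_sd_malignant else config$het_sd_benign

  nodule_mean <- max(stats::rnorm(1, adc_mu, config$adc_between_sd),
                     config$adc_floor)
  k <- config$slices_min +
    stats::rbinom(1, config$slices_max - config$slices_min, 0.5)

  n_redraws <- 0L
  repeat {
    diameter <- stats::rnorm(1, d_mu, d_sd)
    if (diameter < config$min_diameter) { n_redraws <- n_redraws + 1L; next }
    a_px <- (diameter / 2) / sp
    ecc <- stats::runif(1, 0.6, 1.0)
    b_px <- a_px * ecc
    phi <- stats::runif(1, 0, pi)
    margin <- ceiling(a_px) + 2
    if (2 * margin >= n)
      stop("nodule too large for the image matrix", call. = FALSE)
    cy <- stats::runif(1, margin, n - margin)
    cx <- stats::runif(1, margin, n - margin)
    s_idx <- seq_len(k)
    t <- (2 * s_idx - k - 1) / (k + 1)
    scale <- sqrt(1 - t^2)
    masks <- lapply(scale, function(sc)
      ellipse_mask(n, cy, cx, a_px * sc, b_px * sc, phi))
    if (all(vapply(masks, sum, numeric(1)) >= 17)) break
    n_redraws <- n_redraws + 1L
  }

  corr_px <- corr / sp
  slices <- vector("list", k)
  roi <- vector("list", k)
  true_slice <- numeric(k)
  shade <- config$s0_level *
    (1 + 0.1 * (matrix(seq_len(n), n, n, byrow = TRUE) / n - 0.5))
  for (s in seq_len(k)) {
    m <- masks[[s]]
    slice_mean <- nodule_mean + stats::rnorm(1, 0, config$adc_within_sd)
    adc_true <- matrix(config$background_adc, n, n)
    rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
    fld <- gaussian_random_field(rr[2] - rr[1] + 1, cc[2] - cc[1] + 1,
                                 corr_px)
    sub <- matrix(slice_mean, rr[2] - rr[1] + 1, cc[2] - cc[1] + 1) +
      het * fld
    full <- matrix(0, n, n)
    full[rr[1]:rr[2], cc[1]:cc[2]] <- sub
    adc_true[m] <- pmax(full[m], config$adc_floor)
    s0_true <- shade
    sb_true <- s0_true * exp(-config$b_value * adc_true)
    s0 <- matrix(rician(s0_true, noise_sd), n, n)
    sb <- matrix(rician(sb_true, noise_sd), n, n)
    slices[[s]] <- dwi_slice_pair(s0, sb, b_value = config$b_value,
                                  pixel_spacing = sp,
                                  slice_id = s, nodule_id = nodule_id)
    roi[[s]] <- roi_mask(m, pixel_spacing = sp)
    true_slice[s] <- mean(adc_true[m])
  }
  structure(list(label = label, nodule_id = nodule_id,
                 slices = slices, masks = roi,
                 true_slice_adc = true_slice,
                 nodule_mean_adc = nodule_mean,
                 diameter = diameter, noise_sd = noise_sd,
                 n_redraws = n_redraws),
            class = "synthetic_nodule")
}

#' Generate a two-site synthetic cohort
#'
#' Produces a training sub-cohort and an independent test sub-cohort
#' (generated with the test-site noise level) from one seed, together
#' with a manifest linking nodules, sites, labels and ground truth.
#'
#' @param config A [cohort_config()].
#'
#' @return An object of class `synthetic_cohort`: lists `training` and
#'   `test` of [generate_nodule()] results, the `manifest` data frame and
#'   the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  make_site <- function(nb, nm, noise_sd, site) {
    labels <- c(rep("benign", nb), rep("malignant", nm))
    ids <- sprintf("%s_%03d", site, seq_along(labels))
    ## interleave draws in a label-independent order
    ord <- sample(seq_along(labels))
    nod <- vector("list", length(labels))
    for (i in ord)
      nod[[i]] <- generate_nodule(config, labels[i], nodule_id = ids[i],
                                  noise_sd = noise_sd)
    nod
  }
  training <- make_site(config$n_benign, config$n_malignant,
                        config$noise_sd, "train")
  test <- make_site(config$n_benign_test, config$n_malignant_test,
                    config$noise_sd_test, "test")
  manifest <- do.call(rbind, lapply(c(training, test), function(nd)
    data.frame(nodule_id = nd$nodule_id,
               site = if (startsWith(nd$nodule_id, "train")) "training"
                      else "test",
               label = nd$label, n_slices = length(nd$slices),
               diameter_mm = nd$diameter,
               nodule_mean_adc = nd$nodule_mean_adc,
               noise_sd = nd$noise_sd, seed = config$seed,
               stringsAsFactors = FALSE)))
  structure(list(training = training, test = test, manifest = manifest,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic DW-MRI cohort: %d training / %d test nodules, seed %d\n",
    length(x$training), length(x$test), x$config$seed))
  invisible(x)
}
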