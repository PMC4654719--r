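# A reduced matrix keeps the pixel spacing of the full 256 x 220 mm
# geometry while making repeated generation cheap.
small_cfg <- function(...) {
  cohort_config(matrix_size = 96L, fov = 96 * 220 / 256, ...)
}

test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- small_cfg(n_benign = 3L, n_malignant = 2L,
                   n_benign_test = 2L, n_malignant_test = 2L, seed = 41L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$training[[1]]$slices[[1]]$sb,
                   c2$training[[1]]$slices[[1]]$sb)
  expect_identical(c1$test[[2]]$masks[[1]]$mask,
                   c2$test[[2]]$masks[[1]]$mask)
  # a different seed changes the data
  c3 <- generate_cohort(small_cfg(n_benign = 3L, n_malignant = 2L,
                                  n_benign_test = 2L,
                                  n_malignant_test = 2L, seed = 42L))
  expect_false(identical(c1$training[[1]]$slices[[1]]$sb,
                         c3$training[[1]]$slices[[1]]$sb))
})

test_that("a seeded nodule is reproducible and restores the RNG stream", {
  cfg <- small_cfg()
  n1 <- generate_nodule(cfg, "malignant", seed = 77L)
  n2 <- generate_nodule(cfg, "malignant", seed = 77L)
  expect_identical(n1$slices[[1]]$s0, n2$slices[[1]]$s0)
  set.seed(5)
  ref <- runif(3)
  set.seed(5)
  invisible(generate_nodule(cfg, "benign", seed = 77L))
  expect_identical(runif(3), ref)
})

test_that("noise-free acquisition recovers the planted slice ADC exactly", {
  cfg <- small_cfg(n_benign = 3L, n_malignant = 3L,
                   n_benign_test = 1L, n_malignant_test = 1L,
                   noise_sd = 0, noise_sd_test = 0, seed = 43L)
  co <- generate_cohort(cfg)
  summ <- cohort_adc_summary(c(co$training, co$test), noise_floor = 0)
  truth <- unlist(lapply(c(co$training, co$test),
                         function(nd) nd$true_slice_adc))
  expect_equal(summ$slices$mean_adc, truth, tolerance = 1e-10)
  # weighted pooling matches the manual area-weighted sum
  one <- summ$slices[summ$slices$nodule_id == co$training[[1]]$nodule_id, ]
  manual <- sum(one$area_px * one$mean_adc) / sum(one$area_px)
  expect_equal(
    summ$nodules$weighted_mean_adc[
      summ$nodules$nodule_id == co$training[[1]]$nodule_id],
    manual, tolerance = 1e-12)
})

test_that("geometry respects the configured constraints", {
  cfg <- small_cfg(n_benign = 6L, n_malignant = 6L,
                   n_benign_test = 1L, n_malignant_test = 1L,
                   noise_sd = 0, noise_sd_test = 0, seed = 44L)
  co <- generate_cohort(cfg)
  man <- co$manifest
  expect_true(all(man$diameter_mm >= cfg$min_diameter))
  expect_true(all(man$n_slices >= 1 & man$n_slices <= 7))
  for (nd in co$training) {
    areas <- vapply(nd$masks, function(m) m$area_px, numeric(1))
    expect_true(all(areas >= 17))
    # ellipsoidal profile: the central slice carries the largest ROI
    k <- length(areas)
    expect_equal(max(areas), areas[ceiling(k / 2)])
    # area bounded by the circumscribing circle of the max diameter
    sp <- cfg$pixel_spacing
    expect_lte(max(areas), pi * (nd$diameter / 2 / sp + 1.5)^2)
  }
})

test_that("slice counts average four and position is class-independent", {
  cfg <- small_cfg(slices_max = 1L, noise_sd = 0, noise_sd_test = 0)
  set.seed(45)
  n_per <- 110
  cls <- rep(c("benign", "malignant"), each = n_per)
  cyx <- t(vapply(cls, function(lab) {
    nd <- generate_nodule(cfg, lab)
    w <- which(nd$masks[[1]]$mask, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  # centroid quadrant vs class: no association
  quad <- paste(cyx[, 1] > cfg$matrix_size / 2,
                cyx[, 2] > cfg$matrix_size / 2)
  p <- suppressWarnings(chisq.test(table(quad, cls))$p.value)
  expect_gt(p, 0.01)
  # and each coordinate mean matches between classes
  expect_lt(abs(mean(cyx[cls == "benign", 1]) -
                  mean(cyx[cls == "malignant", 1])),
            5 * sd(cyx[, 1]) / sqrt(n_per / 2))
  # slice-count distribution: 1 + Binomial(6, 1/2), mean 4
  set.seed(46)
  ks <- replicate(300, 1L + rbinom(1, 6, 0.5))
  cfg7 <- small_cfg(noise_sd = 0)
  set.seed(46)
  ks_gen <- replicate(40, length(generate_nodule(cfg7, "benign")$slices))
  expect_true(all(ks_gen >= 1 & ks_gen <= 7))
  expect_lt(abs(mean(ks_gen) - 4), 4 * sqrt(6 * 0.25) / sqrt(40))
  expect_lt(abs(mean(ks) - 4), 4 * sqrt(6 * 0.25) / sqrt(300))
})

test_that("class means of the drawn nodule ADC match the design values", {
  cfg <- small_cfg(slices_max = 1L, noise_sd = 0)
  set.seed(47)
  mb <- replicate(80, generate_nodule(cfg, "benign")$nodule_mean_adc)
  mm <- replicate(80, generate_nodule(cfg, "malignant")$nodule_mean_adc)
  se <- cfg$adc_between_sd / sqrt(80)
  expect_lt(abs(mean(mb) - 2.24e-3), 4 * se)
  expect_lt(abs(mean(mm) - 1.92e-3), 4 * se)
  expect_gt(mean(mb), mean(mm))
})

test_that("the Rician and random-field primitives have the stated moments", {
  set.seed(48)
  # Rician of zero signal: mean = sd * sqrt(pi / 2)
  z <- thyrotex:::rician(rep(0, 40000), sd = 5)
  expect_equal(mean(z), 5 * sqrt(pi / 2), tolerance = 0.02)
  # zero noise passes the signal through
  expect_identical(thyrotex:::rician(c(1, 2, 3), 0), c(1, 2, 3))
  # GRF: unit marginal variance and positive neighbour correlation
  f <- thyrotex:::gaussian_random_field(120, 120, corr_px = 3)
  expect_equal(sd(as.vector(f)), 1, tolerance = 0.1)
  r <- cor(as.vector(f[-1, ]), as.vector(f[-120, ]))
  expect_gt(r, exp(-1 / (2 * 9)) - 0.1)   # Gaussian ACF at lag 1
  # white field at corr 0
  f0 <- thyrotex:::gaussian_random_field(120, 120, corr_px = 0)
  expect_lt(abs(cor(as.vector(f0[-1, ]), as.vector(f0[-120, ]))), 0.05)
})

test_that("malignant texture fields are coarser and stronger by design", {
  cfg <- small_cfg()
  # heterogeneity SD and correlation length enter as configured
  expect_gt(cfg$het_sd_malignant, cfg$het_sd_benign)
  expect_gt(cfg$corr_length_malignant, cfg$corr_length_benign)
  # visible in the data: in-ROI SD of the noise-free ADC is larger for
  # malignant nodules on average
  cfgs <- small_cfg(slices_max = 1L, noise_sd = 0, adc_between_sd = 0)
  set.seed(49)
  sd_of <- function(lab) {
    nd <- generate_nodule(cfgs, lab)
    adc <- compute_adc(nd$slices[[1]], noise_floor = 0)
    stats::sd(adc$values[nd$masks[[1]]$mask])
  }
  sb <- replicate(25, sd_of("benign"))
  sm <- replicate(25, sd_of("malignant"))
  expect_gt(mean(sm), 2 * mean(sb))
})
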