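gauss_table <- function(n_per_class, p, delta, seed) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n_per_class)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  X[y == 1, ] <- X[y == 1, ] + matrix(delta, n_per_class, p, byrow = TRUE)
  colnames(X) <- paste0("f", seq_len(p))
  cbind(data.frame(nodule_id = paste0("n", seq_along(y)), slice_id = 1L,
                   label = ifelse(y == 1, "malignant", "benign"),
                   stringsAsFactors = FALSE),
        as.data.frame(X, check.names = FALSE))
}

test_that("spherical classes give a projection parallel to the mean difference", {
  tab <- gauss_table(500, 2, c(3, 1.5), seed = 111)
  fit <- fit_lda(tab)
  X <- as.matrix(tab[, c("f1", "f2")])
  y <- as.integer(tab$label == "malignant")
  # with spherical within-class covariance the discriminant direction in
  # the *original* coordinates is the raw mean difference; undo the
  # per-feature standardization before comparing
  w_orig <- fit$w / fit$scale
  dmu <- colMeans(X[y == 1, ]) - colMeans(X[y == 0, ])
  expect_gt(cosine(w_orig, dmu), 0.999)
})

test_that("label swap flips the weights but not the calls", {
  tab <- gauss_table(40, 4, c(1, 0.5, 0, -0.5), seed = 112)
  fit1 <- fit_lda(tab)
  tab2 <- tab
  tab2$label <- ifelse(tab$label == "malignant", "benign", "malignant")
  fit2 <- fit_lda(tab2)
  # orientation rule keeps the (relabelled) malignant mean positive
  expect_equal(fit1$w, -fit2$w, tolerance = 1e-10)
  p1 <- classify_slices(fit1, tab)
  p2 <- classify_slices(fit2, tab2)
  expect_equal(p1$mdf1, -p2$mdf1, tolerance = 1e-10)
})

test_that("the fitted projection matches the generalized-eigenvector oracle", {
  tab <- gauss_table(60, 5, c(1, -0.6, 0.3, 0, 0.8), seed = 113)
  fit <- fit_lda(tab)
  Z <- scale(as.matrix(tab[, fit$features]))
  y <- as.integer(tab$label == "malignant")
  v <- oracle_lda_direction(Z, y)
  expect_gt(cosine(fit$w, v), 1 - 1e-8)
  # and the MASS implementation agrees on the direction
  if (requireNamespace("MASS", quietly = TRUE)) {
    ml <- MASS::lda(Z, grouping = y)
    expect_gt(cosine(fit$w, ml$scaling[, 1]), 1 - 1e-6)
  }
})

test_that("MDF1 equals the hand-computed dot product and is affine-invariant", {
  tab <- gauss_table(30, 3, c(1, 0, -1), seed = 114)
  fit <- fit_lda(tab)
  pred <- classify_slices(fit, tab)
  i <- 7
  z <- (as.numeric(tab[i, fit$features]) - fit$center) / fit$scale
  expect_equal(pred$mdf1[i], sum(z * fit$w) + fit$offset, tolerance = 1e-12)
  # duplicated rows predict identically
  pred2 <- classify_slices(fit, tab[c(i, i), ])
  expect_equal(pred2$mdf1[1], pred2$mdf1[2])
  # rescaling an input feature is absorbed by standardization
  tab_scaled <- tab
  tab_scaled$f2 <- tab$f2 * 1000 + 5
  fit_s <- fit_lda(tab_scaled)
  pred_s <- classify_slices(fit_s, tab_scaled)
  expect_equal(pred$mdf1, pred_s$mdf1, tolerance = 1e-8)
  # missing feature errors by name
  expect_error(classify_slices(fit, tab[, -which(names(tab) == "f2")]),
               "f2")
})

test_that("cutoff training minimizes errors with the documented tie rules", {
  # perfectly separated scores: midpoint of the gap
  expect_equal(choose_cutoff(c(-3, -2, 2, 4), c(0, 0, 1, 1)), 0)
  expect_equal(choose_cutoff(c(-1, 1), c(0, 1)), 0)
  # brute-force threshold sweep oracle on scrambled scores
  set.seed(115)
  for (rep in 1:20) {
    s <- rnorm(30)
    y <- sample(0:1, 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    cut <- choose_cutoff(s, y)
    err <- function(c) sum((s > c) != y)
    grid <- c(min(s) - 1, sort(s), max(s) + 1)
    expect_equal(err(cut), min(vapply(grid, err, numeric(1))))
  }
})

test_that("slice scores near the benign training mean classify benign", {
  tab <- gauss_table(50, 3, c(2, 2, 2), seed = 116)
  fit <- fit_lda(tab)
  fit$cutoff <- choose_cutoff(classify_slices(fit, tab)$mdf1, tab$label)
  ben_mean <- tab[1, ]
  ben_mean[, c("f1", "f2", "f3")] <-
    as.list(colMeans(tab[tab$label == "benign", c("f1", "f2", "f3")]))
  expect_equal(classify_slices(fit, ben_mean)$call, "benign")
})

test_that("the lowest-scoring-slice rule aggregates nodules conservatively", {
  cutoff <- 0.03265
  pred <- data.frame(nodule_id = c("a", "a", "b", "b"),
                     slice_id = c(1, 2, 1, 2),
                     mdf1 = c(0.5, 1.2, -0.2, 3.0))
  nod <- classify_nodules_lowest_slice(pred, cutoff)
  expect_equal(nod$call[nod$nodule_id == "a"], "malignant")  # min 0.5 > cutoff
  expect_equal(nod$call[nod$nodule_id == "b"], "benign")     # one hot slice is not enough
  # grouped-min oracle on random score sets
  set.seed(117)
  for (rep in 1:10) {
    pr <- data.frame(nodule_id = sample(letters[1:5], 40, replace = TRUE),
                     slice_id = 1:40, mdf1 = rnorm(40))
    nd <- classify_nodules_lowest_slice(pr, 0)
    ref <- tapply(pr$mdf1, pr$nodule_id, min)
    expect_equal(nd$min_mdf1, as.numeric(ref[nd$nodule_id]))
  }
})

test_that("model serialization round-trips through JSON", {
  tab <- gauss_table(25, 4, c(1, 1, 0, 0), seed = 118)
  fit <- fit_lda(tab)
  fit$cutoff <- 0.123
  fit$texture_config <- texture_config(bits = 5, families = c("glcm",
                                                              "histogram"))
  path <- tempfile(fileext = ".json")
  write_lda_model(fit, path)
  back <- read_lda_model(path)
  expect_equal(back$w, fit$w, tolerance = 1e-12)
  expect_equal(back$center, fit$center, tolerance = 1e-12)
  expect_equal(back$cutoff, fit$cutoff)
  expect_equal(back$texture_config$bits, 5L)
  p1 <- classify_slices(fit, tab)
  p2 <- classify_slices(back, tab)
  expect_equal(p1$mdf1, p2$mdf1, tolerance = 1e-12)
})
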