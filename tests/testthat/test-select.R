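make_table <- function(X, y) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  cbind(data.frame(nodule_id = paste0("n", seq_along(y)),
                   slice_id = 1L,
                   label = ifelse(y == 1, "malignant", "benign"),
                   stringsAsFactors = FALSE),
        as.data.frame(X, check.names = FALSE))
}

test_that("Fisher coefficient behaves as a standardized separation", {
  set.seed(91)
  y <- rep(c(0, 1), each = 50)
  # identical class distributions -> 0 exactly when values repeat
  x0 <- rep(c(1, 2), 50)
  expect_equal(fisher_coefficient(rep(x0[1:50], 2), y), 0)
  # N(0,1) vs N(1,1): F -> 1/2 at large n
  yb <- rep(c(0, 1), each = 20000)
  xb <- rnorm(40000) + yb
  expect_equal(fisher_coefficient(xb, yb), 0.5, tolerance = 0.05)
  # scale invariance
  x <- rnorm(100) + y
  expect_equal(fisher_coefficient(x, y), fisher_coefficient(13 * x, y))
  # zero variance, distinct means -> Inf
  expect_equal(fisher_coefficient(y, y), Inf)
})

test_that("mutual information matches analytic and oracle values", {
  set.seed(92)
  y <- rep(c(0, 1), each = 500)
  # feature equal to the label, balanced classes: ln 2
  expect_equal(mutual_information(as.numeric(y), y), log(2),
               tolerance = 1e-12)
  # independent feature: near 0
  expect_lt(mutual_information(rnorm(1000), y), 0.02)
  # constant feature: exactly 0
  expect_equal(mutual_information(rep(3, 1000), y), 0)
  # exhaustive contingency-sum oracle on a small discrete table
  x <- sample(1:4, 60, replace = TRUE)
  ys <- sample(0:1, 60, replace = TRUE)
  tab <- table(x, ys) / 60
  ref <- 0
  for (i in rownames(tab)) for (j in colnames(tab)) {
    p <- tab[i, j]
    if (p > 0) ref <- ref + p * log(p / (sum(tab[i, ]) * sum(tab[, j])))
  }
  expect_equal(mutual_information(x, ys, n_bins = 10), ref,
               tolerance = 1e-12)
})

test_that("ranking scores are invariant to affine rescaling of a feature", {
  set.seed(93)
  y <- rep(c(0, 1), each = 30)
  x <- rnorm(60) + 0.8 * y
  for (aff in list(c(2, 0), c(1, 5), c(-0.3, 2))) {
    xa <- aff[1] * x + aff[2]
    expect_equal(fisher_coefficient(x, y), fisher_coefficient(xa, y),
                 tolerance = 1e-12)
    expect_equal(mutual_information(x, y), mutual_information(abs(aff[1]) * x + aff[2], y),
                 tolerance = 1e-12)
    expect_equal(thyrotex:::poe_single(x, y), thyrotex:::poe_single(xa, y))
  }
})

test_that("POE+ACC selects a perfect separator first and shuns duplicates", {
  set.seed(94)
  y <- rep(c(0, 1), each = 20)
  X <- matrix(rnorm(40 * 5), 40, 5)
  X[, 3] <- y * 10 + rnorm(40, sd = 0.01)  # perfect separator
  X <- cbind(X, X[, 3])                    # exact duplicate as f6
  tab <- make_table(X, y)
  r <- poe_acc_rank(tab, k = 3)
  expect_equal(r$features[1], "f3")
  expect_equal(r$scores[1], 0)             # POE = 0
  expect_false(r$features[2] == "f6")      # ACC = 1 penalty blocks the copy
})

test_that("with shuffled labels the first POE is the best null error", {
  set.seed(95)
  y <- sample(rep(c(0, 1), each = 25))
  X <- matrix(rnorm(50 * 8), 50, 8)
  tab <- make_table(X, y)
  r <- poe_acc_rank(tab, k = 1)
  poe_all <- apply(X, 2, thyrotex:::poe_single, y = y)
  expect_equal(r$scores[1], min(poe_all))
})

test_that("ranking merge follows the mean-rank rule", {
  mk <- function(f, method = "fisher", scores = NULL) {
    structure(list(method = method, features = f,
                   scores = scores,
                   all_scores = if (!is.null(scores))
                     stats::setNames(scores, f)),
              class = "feature_ranking")
  }
  ten <- paste0("f", 1:10)
  # three identical lists: preserved order, 10 candidates
  s <- combine_rankings(mk(ten, scores = 10:1), mk(ten), mk(ten))
  expect_equal(s$candidates, ten)
  # fully disjoint lists: 30 candidates
  s2 <- combine_rankings(mk(paste0("a", 1:10), scores = 10:1),
                         mk(paste0("b", 1:10)), mk(paste0("c", 1:10)))
  expect_equal(length(s2$candidates), 30)
  # overlapping lists: candidate count equals the union cardinality
  s3 <- combine_rankings(mk(paste0("f", 1:10), scores = 10:1),
                         mk(paste0("f", 6:15)), mk(paste0("f", 11:20)))
  expect_equal(sort(s3$candidates), sort(paste0("f", 1:20)))
  # a feature in all three lists outranks one in a single list
  expect_lt(match("f6", s3$candidates), match("f20", s3$candidates))
})

test_that("backward elimination returns the smallest subset at minimal error", {
  set.seed(96)
  y <- rep(c(0, 1), each = 30)
  # f1 separates perfectly; the rest are noise
  X <- cbind(y * 4 + rnorm(60, sd = 0.05), matrix(rnorm(60 * 5), 60, 5))
  tab <- make_table(X, y)
  res <- backward_eliminate(tab, paste0("f", 1:6))
  expect_equal(res$error_rate, 0)
  expect_equal(res$k, 2)                # tie rule: smallest subset
  expect_equal(res$subset, c("f1", "f2"))
  # returned rate never exceeds the full-candidate-set rate
  expect_lte(res$error_rate, res$curve$error[res$curve$m == 6])
})

test_that("pure-noise candidates yield roughly the minority-class error", {
  set.seed(97)
  y <- rep(c(0, 1), times = c(62, 32))      # 94 slices, minority 34%
  X <- matrix(rnorm(94 * 8), 94, 8)
  tab <- make_table(X, y)
  res <- backward_eliminate(tab, paste0("f", 1:8))
  # elimination scores subsets at the fixed midpoint cutoff, so the
  # in-sample error on pure noise hovers near the class imbalance: well
  # above zero (no leakage) and below chance
  expect_lt(res$error_rate, 0.5)
  expect_gt(res$error_rate, 0.05)
})

test_that("a planted 21-feature signal is recovered exactly", {
  set.seed(98)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 30), n, 30)
  # features 1..20 weakly informative, feature 21 essential, 22..30 noise
  for (i in 1:20) X[, i] <- X[, i] + 0.25 * y
  X[, 21] <- y + rnorm(n, sd = 0.01)
  tab <- make_table(X, y)
  res <- backward_eliminate(tab, paste0("f", 1:30))
  expect_equal(res$k, 21)
  expect_equal(res$error_rate, 0)
})

test_that("label permutation keeps selected-subset error at chance levels", {
  set.seed(99)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10)
  errs <- replicate(25, {
    y <- sample(rep(c(0, 1), each = n / 2))
    tab <- make_table(X, y)
    res <- backward_eliminate(tab, paste0("f", 1:10))
    res$error_rate
  })
  # overfit in-sample error is below 0.5 but its mean must stay well
  # above 0: no systematic leakage of the labels into the features
  expect_gt(mean(errs), 0.05)
  expect_lt(mean(errs), 0.5)
})
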