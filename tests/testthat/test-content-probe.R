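test_that("pca_reduce matches an independent covariance eigensolver", {
  withr::with_seed(3, X <- matrix(rnorm(20 * 6), 20))
  red <- pca_reduce(X, target_variance = 1.0)
  # brute-force oracle: eigendecomposition of the sample covariance
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(red$explained_variance, ev / sum(ev), tolerance = 1e-8)
  # dual (p >> n) route agrees with the primal route
  withr::with_seed(4, W <- matrix(rnorm(8 * 300), 8))
  dual <- pca_reduce(W, 0.9)
  evw <- eigen(stats::cov(W), symmetric = TRUE)$values
  evw <- evw[evw > max(evw) * 1e-12]
  expect_equal(dual$explained_variance, evw / sum(evw), tolerance = 1e-8)
})

test_that("pca_reduce selects the minimal component count", {
  # points exactly on a line through the mean: one component, 100% variance
  t <- seq(-2, 2, length.out = 15)
  line <- cbind(3 + 2 * t, 1 - t, 0.5 * t)
  red <- pca_reduce(line, target_variance = 0.8)
  expect_equal(red$n_components, 1L)
  expect_equal(red$explained_variance[1], 1, tolerance = 1e-10)

  withr::with_seed(5, X <- matrix(rnorm(12 * 5), 12))
  full <- pca_reduce(X, target_variance = 1.0)
  expect_equal(full$n_components, qr(scale(X, scale = FALSE))$rank)
  part <- pca_reduce(X, target_variance = 0.8)
  cum <- cumsum(part$explained_variance)
  expect_gte(cum[part$n_components], 0.8 - 1e-12)
  if (part$n_components > 1)
    expect_lt(cum[part$n_components - 1], 0.8)

  expect_error(pca_reduce(matrix(1, 5, 3)), "zero variance")
  expect_error(pca_reduce(matrix(rnorm(3), 1)), "at least 2 rows")
  expect_error(pca_reduce(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("svm_cv_accuracy evaluates every sample once with stratified folds", {
  blobs <- separable_blobs(20, gap = 20, seed = 6)
  acc <- svm_cv_accuracy(blobs$x, blobs$y, n_folds = 10, seed = 1)
  expect_length(acc, 10L)
  expect_true(all(acc == 1))
  fold <- attr(acc, "fold_assignment")
  expect_equal(sort(unique(fold)), 1:10)
  # stratification: each fold holds 2 per class of each class's 20
  for (k in 1:10)
    for (cl in c("a", "b"))
      expect_equal(sum(fold == k & blobs$y == cl), 2L)

  # permuted labels collapse to the majority-class rate
  withr::with_seed(8, {
    perm_acc <- replicate(20, {
      yp <- sample(blobs$y)
      mean(svm_cv_accuracy(blobs$x, yp, n_folds = 10, seed = 1))
    })
  })
  expect_lt(abs(mean(perm_acc) - dummy_accuracy(blobs$y)), 0.12)

  # leave-one-out: 0/1-valued fold accuracies
  small <- separable_blobs(5, gap = 20, seed = 7)
  loo <- svm_cv_accuracy(small$x, small$y, n_folds = 10, seed = 1)
  expect_length(loo, 10L)
  expect_true(all(loo %in% c(0, 1)))

  expect_error(svm_cv_accuracy(small$x, small$y, n_folds = 7, seed = 1),
               "lower n_folds")
})

test_that("the PCA + SVM pipeline is invariant to feature reordering", {
  withr::with_seed(9, {
    X <- matrix(rnorm(40 * 30), 40)
    y <- rep(c("a", "b"), each = 20)
    X[y == "b", 1:5] <- X[y == "b", 1:5] + 2
  })
  base <- probe_features_accuracy <- function(M) {
    red <- pca_reduce(M, 0.8)
    svm_cv_accuracy(scribbleprobe:::standardize_scores(red$scores), y,
                    n_folds = 5, seed = 2)
  }
  perm <- withr::with_seed(10, sample.int(30))
  expect_equal(base(X), base(X[, perm]), tolerance = 1e-8)
})

test_that("probe_layers returns one row per layer with retained variance >= target", {
  bb <- fixture_backbone()
  ds <- fixture_dataset("paperlike", 3, 41)  # 12 images
  layers <- c("conv1", "conv2", "conv8", "FC1", "FC2")
  pr <- probe_layers(ds, bb, layers = layers, n_folds = 3, seed = 2)
  expect_s3_class(pr, "layer_probe_results")
  expect_equal(nrow(pr), length(layers))
  expect_equal(pr$layer_id, layers)
  expect_equal(pr$depth_index, c(1L, 2L, 8L, 17L, 18L))
  expect_true(all(pr$n_components >= 1))
  expect_true(all(vapply(pr$fold_accuracies, length, 1L) == 3))
  expect_equal(pr$mean_accuracy,
               vapply(pr$fold_accuracies, mean, numeric(1)))
  expect_equal(pr$sd_accuracy, vapply(pr$fold_accuracies, sd, numeric(1)))
  # conv1/conv2 carry a passing subsample report; others none
  expect_true(pr$subsample_report[[1]]$passed)
  expect_true(pr$subsample_report[[2]]$passed)
  expect_null(pr$subsample_report[[3]])
  td <- tidy(pr)
  expect_equal(nrow(td), length(layers) * 3L)
})

test_that("slope_test agrees with a closed-form OLS oracle", {
  # hand-computable toy profile over 18 layers
  x <- 1:18
  withr::with_seed(12, y <- 0.3 + 0.004 * x + rnorm(18, sd = 0.02))
  res <- slope_test(tibble::tibble(depth_index = x, mean_accuracy = y))
  # closed form: slope = Sxy/Sxx, t = slope / sqrt(RSS/(n-2)/Sxx)
  sxx <- sum((x - mean(x))^2)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) - slope_hand * mean(x)) - slope_hand * x
  se_hand <- sqrt(sum(resid^2) / 16 / sxx)
  expect_equal(res$slope, slope_hand, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(slope_hand / se_hand), 16),
               tolerance = 1e-10)

  flat <- slope_test(tibble::tibble(depth_index = 1:5,
                                    mean_accuracy = rep(0.4, 5)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)

  exact <- slope_test(tibble::tibble(depth_index = 1:5,
                                     mean_accuracy = 0.2 + 0.05 * (1:5)))
  expect_equal(exact$slope, 0.05, tolerance = 1e-12)
  expect_equal(exact$p_value, 0)

  expect_error(slope_test(tibble::tibble(depth_index = 1:2,
                                         mean_accuracy = c(0.1, 0.2))),
               "at least 3")
})

test_that("leakage-free probing also runs and stays near the standard mode", {
  bb <- fixture_backbone()
  ds <- fixture_dataset("color-only", 3, 41)
  std <- probe_layers(ds, bb, layers = "conv8", n_folds = 3, seed = 2)
  lf <- probe_layers(ds, bb, layers = "conv8", n_folds = 3, seed = 2,
                     leakage_free = TRUE)
  expect_equal(nrow(lf), 1L)
  expect_true(is.finite(lf$mean_accuracy))
  expect_lte(abs(std$mean_accuracy - lf$mean_accuracy), 0.5)
})
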