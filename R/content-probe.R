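#' PCA reduction to a target explained variance
#'
#' Centers `X` and keeps the smallest number of principal components whose
#' cumulative explained variance reaches `target_variance` (default 80%).
#' When there are far more features than images the decomposition uses the
#' n x n inner-product (dual) form, so activation matrices with millions of
#' columns stay tractable.
#'
#' @param X Numeric matrix, images x features, at least 2 rows, finite.
#' @param target_variance Fraction in `(0, 1]` of variance to retain.
#' @return List: `scores` (n x k), `n_components`, `explained_variance`
#'   (fraction per component over all computed components), `cumulative`.
#' @export
pca_reduce <- function(X, target_variance = 0.80) {
  if (nrow(X) < 2) stopf("pca_reduce needs at least 2 rows")
  if (!all(is.finite(X))) stopf("pca_reduce requires finite entries")
  if (target_variance <= 0 || target_variance > 1)
    stopf("target_variance must be in (0, 1]")
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  if (ncol(X) <= n) {
    sv <- svd(Xc)
    lambda <- sv$d^2
    scores_full <- sv$u %*% diag(sv$d, length(sv$d))
  } else {
    K <- tcrossprod(Xc)
    eg <- eigen(K, symmetric = TRUE)
    lambda <- pmax(eg$values, 0)
    scores_full <- eg$vectors %*% diag(sqrt(lambda), length(lambda))
  }
  total <- sum(lambda)
  if (total <= 1e-12 * length(X)) stopf("pca_reduce: matrix has zero variance")
  keep_rank <- lambda > max(lambda) * 1e-12
  lambda <- lambda[keep_rank]
  scores_full <- scores_full[, keep_rank, drop = FALSE]
  # deterministic sign: largest-magnitude score of each component positive
  for (j in seq_len(ncol(scores_full))) {
    mx <- which.max(abs(scores_full[, j]))
    if (scores_full[mx, j] < 0) scores_full[, j] <- -scores_full[, j]
  }
  frac <- lambda / total
  cum <- cumsum(frac)
  k <- which(cum >= target_variance - 1e-12)[1]
  if (is.na(k)) k <- length(frac)
  list(scores = scores_full[, seq_len(k), drop = FALSE],
       n_components = as.integer(k),
       explained_variance = frac, cumulative = cum)
}

#' Stratified k-fold cross-validated SVM accuracy
#'
#' Linear-kernel SVM (cost 1 by default, via [e1071::svm()]) evaluated by
#' stratified k-fold cross-validation: every sample is predicted exactly once,
#' and per-fold class proportions match the dataset's within one sample.
#' `n_folds` equal to the sample count gives leave-one-out.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Class labels.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param kernel,cost SVM settings.
#' @return Numeric vector of `n_folds` fold accuracies.
#' @export
svm_cv_accuracy <- function(features, labels, n_folds = 10L, seed = 1L,
                            kernel = "linear", cost = 1) {
  labels <- factor(as.character(labels))
  n <- length(labels)
  fold <- integer(n)
  if (n_folds == n) {
    fold <- seq_len(n)  # leave-one-out
  } else {
    if (min(table(labels)) < n_folds)
      stopf(paste("every class needs at least n_folds samples for stratified",
                  "cross-validation; lower n_folds"))
    withr::with_seed(derive_seed(seed, 1L, stream = 6L), {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
      }
    })
  }
  acc <- vapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    fit <- e1071::svm(x = features[tr, , drop = FALSE], y = labels[tr],
                      kernel = kernel, cost = cost, scale = FALSE)
    mean(predict(fit, features[!tr, , drop = FALSE]) == labels[!tr])
  }, numeric(1))
  attr(acc, "fold_assignment") <- fold
  acc
}

# Standardize PCA scores to zero mean / unit variance per component
# (constant columns left at zero) before the margin-based classifier.
standardize_scores <- function(S) {
  mu <- colMeans(S)
  sdev <- apply(S, 2, sd)
  sdev[sdev == 0] <- 1
  sweep(sweep(S, 2, mu), 2, sdev, "/")
}

# Activation feature matrix for one layer across a dataset. conv layers are
# streamed image by image; layers listed in subsample_layers are reduced to
# `fraction` of their activations with a shared sorted index set while the
# per-repeat means for the subsampling sanity check are accumulated from
# running column sums (mathematically identical to gathering full vectors).
activation_feature_matrix <- function(backbone, dataset, layer_id,
                                      subsample = FALSE, fraction = 0.5,
                                      n_repeats = 50L, seed = 1L) {
  info <- parse_layer_id(layer_id)
  pxs <- dataset$pixels
  n <- length(pxs)
  if (startsWith(layer_id, "FC")) {
    P <- matrix(0, n, 7L * 7L * 512L)
    for (i in seq_len(n)) {
      fp <- forward_keep(backbone, pxs[[i]], final_pool = TRUE)$final_pool
      P[i, ] <- flatten_final_pool(fp)
    }
    return(list(X = fc_forward(backbone, P, upto = if (layer_id == "FC1") 1L else 2L),
                report = NULL))
  }
  l <- info$depth_index
  p <- info$vector_length
  if (!subsample) {
    X <- matrix(0, n, p)
    for (i in seq_len(n)) {
      act <- forward_keep(backbone, pxs[[i]], keep = l)[[1]]
      X[i, ] <- as.vector(feature_map_matrix(act))
    }
    return(list(X = X, report = NULL))
  }
  m <- max(1L, as.integer(round(p * fraction)))
  idx1 <- sort(withr::with_seed(derive_seed(seed, 1L, stream = 4L),
                                sample.int(p, m)))
  X <- matrix(0, n, m)
  acc <- numeric(p)
  for (i in seq_len(n)) {
    act <- forward_keep(backbone, pxs[[i]], keep = l)[[1]]
    f <- as.vector(feature_map_matrix(act))
    acc <- acc + f
    X[i, ] <- f[idx1]
  }
  mu <- sum(acc) / (n * p)
  means <- numeric(n_repeats)
  means[1] <- sum(acc[idx1]) / (n * m)
  for (r in 2:n_repeats) {
    idx <- sort(withr::with_seed(derive_seed(seed, r, stream = 4L),
                                 sample.int(p, m)))
    means[r] <- sum(acc[idx]) / (n * m)
  }
  tt <- one_sample_ttest(means, mu)
  report <- structure(
    list(fraction = fraction, n_repeats = n_repeats, repeat_means = means,
         mu_original = mu, t_statistic = tt$t, p_value = tt$p,
         passed = tt$p > 0.05),
    class = "subsample_report")
  list(X = X, report = report)
}

probe_one <- function(features, labels, layer_id, depth_index, feature_type,
                      color_mode, target_variance, n_folds, seed,
                      n_features_in, subsample_report = NULL) {
  red <- pca_reduce(features, target_variance)
  scores <- standardize_scores(red$scores)
  folds <- svm_cv_accuracy(scores, labels, n_folds = n_folds, seed = seed)
  tibble::tibble(
    layer_id = layer_id, depth_index = depth_index,
    feature_type = feature_type, color_mode = color_mode,
    n_features = n_features_in, n_components = red$n_components,
    mean_accuracy = mean(folds), sd_accuracy = sd(folds),
    fold_accuracies = list(folds),
    subsample_report = list(subsample_report))
}

#' Layer-wise linear probing of backbone activations
#'
#' For each requested layer: extract every image's flattened activation
#' vector, optionally convert images to NTSC grayscale first, subsample the
#' two widest layers (conv1, conv2) to 50% of their activations with a
#' passing mean-preservation check, reduce by PCA to the target explained
#' variance, standardize the scores, and measure stratified 10-fold
#' cross-validated SVM accuracy.
#'
#' PCA is fitted on all images before cross-validation (the protocol this
#' package mirrors); `leakage_free = TRUE` refits PCA inside each training
#' fold instead.
#'
#' @param dataset A `drawing_dataset` of standardized images.
#' @param backbone A [build_backbone()] object.
#' @param layers Character vector of layer ids (default all 18 probe points).
#' @param color_mode `"rgb"` or `"gray"` (gray applies [to_grayscale_ntsc()]).
#' @param target_variance PCA retained-variance target (default 0.80).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed (folds and subsampling).
#' @param subsample_layers Layers subsampled before PCA (default conv1/conv2).
#' @param subsample_fraction Fraction kept at those layers (default 0.5).
#' @param leakage_free Refit PCA per training fold (default FALSE).
#' @return A `layer_probe_results` tibble: layer_id, depth_index,
#'   feature_type, color_mode, n_features, n_components, mean_accuracy,
#'   sd_accuracy, fold_accuracies (list), subsample_report (list).
#' @export
probe_layers <- function(dataset, backbone,
                         layers = layer_shape_table()$layer_id,
                         color_mode = c("rgb", "gray"),
                         target_variance = 0.80, n_folds = 10L, seed = 1L,
                         subsample_layers = c("conv1", "conv2"),
                         subsample_fraction = 0.5, leakage_free = FALSE) {
  color_mode <- match.arg(color_mode)
  ds <- if (color_mode == "gray") dataset_to_grayscale(dataset) else dataset
  shape <- layer_shape_table()
  rows <- lapply(layers, function(lid) {
    info <- shape[shape$layer_id == lid, ]
    if (nrow(info) == 0) stopf("unknown layer_id '%s'", lid)
    fm <- activation_feature_matrix(
      backbone, ds, lid, subsample = lid %in% subsample_layers,
      fraction = subsample_fraction, seed = seed)
    if (leakage_free) {
      folds <- cv_accuracy_pca_per_fold(fm$X, ds$label, target_variance,
                                        n_folds, seed)
      tibble::tibble(
        layer_id = lid, depth_index = info$depth_index,
        feature_type = "activation", color_mode = color_mode,
        n_features = ncol(fm$X), n_components = NA_integer_,
        mean_accuracy = mean(folds), sd_accuracy = sd(folds),
        fold_accuracies = list(folds), subsample_report = list(fm$report))
    } else {
      probe_one(fm$X, ds$label, lid, info$depth_index, "activation",
                color_mode, target_variance, n_folds, seed,
                ncol(fm$X), fm$report)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("layer_probe_results", class(out))
  out
}

# Leakage-free variant: PCA and score scaling refitted on each training fold.
cv_accuracy_pca_per_fold <- function(X, labels, target_variance, n_folds, seed) {
  labels <- factor(as.character(labels))
  n <- length(labels)
  if (min(table(labels)) < n_folds)
    stopf("every class needs at least n_folds samples; lower n_folds")
  fold <- integer(n)
  withr::with_seed(derive_seed(seed, 1L, stream = 6L), {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  vapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    Xtr <- X[tr, , drop = FALSE]
    ctr <- colMeans(Xtr)
    Xtr_c <- sweep(Xtr, 2, ctr)
    sv <- if (ncol(X) <= sum(tr)) svd(Xtr_c) else NULL
    if (is.null(sv)) {
      K <- tcrossprod(Xtr_c)
      eg <- eigen(K, symmetric = TRUE)
      lambda <- pmax(eg$values, 0)
      frac <- lambda / sum(lambda)
      kcomp <- which(cumsum(frac) >= target_variance - 1e-12)[1]
      V <- crossprod(Xtr_c, eg$vectors[, seq_len(kcomp), drop = FALSE])
      V <- sweep(V, 2, sqrt(lambda[seq_len(kcomp)]), "/")
    } else {
      lambda <- sv$d^2
      frac <- lambda / sum(lambda)
      kcomp <- which(cumsum(frac) >= target_variance - 1e-12)[1]
      V <- sv$v[, seq_len(kcomp), drop = FALSE]
    }
    Str <- Xtr_c %*% V
    Ste <- sweep(X[!tr, , drop = FALSE], 2, ctr) %*% V
    mu <- colMeans(Str); sdev <- apply(Str, 2, sd); sdev[sdev == 0] <- 1
    Str <- sweep(sweep(Str, 2, mu), 2, sdev, "/")
    Ste <- sweep(sweep(Ste, 2, mu), 2, sdev, "/")
    fit <- e1071::svm(x = Str, y = labels[tr], kernel = "linear", cost = 1,
                      scale = FALSE)
    mean(predict(fit, Ste) == labels[!tr])
  }, numeric(1))
}

#' Accuracy-versus-depth slope test
#'
#' Ordinary least squares of mean probe accuracy on layer depth index, with a
#' two-sided t-test on the slope. Degenerate inputs (zero slope with zero
#' residual variance) return `p = 1` by convention; an exact nonzero-slope
#' line returns `p = 0`.
#'
#' @param results A `layer_probe_results` tibble (or any data frame with
#'   `depth_index` and `mean_accuracy`), at least 3 rows.
#' @param layers Optional subset of layer ids to include.
#' @return A `slope_test` object: `slope`, `p_value`, `intercept`,
#'   `std_error`, `layer_indices`.
#' @export
slope_test <- function(results, layers = NULL) {
  if (!is.null(layers)) results <- results[results$layer_id %in% layers, ]
  x <- results$depth_index
  y <- results$mean_accuracy
  if (length(x) < 3) stopf("slope_test needs at least 3 layers")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  sxx <- sum((x - mean(x))^2)
  if (rss < 1e-24) {
    p <- if (abs(slope) < 1e-12) 1 else 0
    se <- 0
  } else {
    se <- sqrt(rss / (length(x) - 2) / sxx)
    p <- 2 * pt(-abs(slope / se), df = length(x) - 2)
  }
  structure(list(slope = slope, p_value = p,
                 intercept = unname(coef(fit)[1]), std_error = se,
                 layer_indices = x),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("<slope_test> slope = %.5f accuracy/layer, p = %.4g (%d layers)\n",
              x$slope, x$p_value, length(x$layer_indices)))
  invisible(x)
}

#' @export
tidy.slope_test <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "depth_index"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(NA_real_, x$std_error),
                 p.value = c(NA_real_, x$p_value))
}

#' @export
glance.slope_test <- function(x, ...) {
  tibble::tibble(slope = x$slope, p_value = x$p_value,
                 n_layers = length(x$layer_indices))
}

#' Compare a layer's probe against the dummy baseline with the 5x2cv test
#'
#' Runs [paired_5x2cv_ttest()] between the linear SVM and the
#' most-frequent-class dummy on the layer's standardized PCA scores.
#'
#' @param features Feature matrix for the layer (activations or Gram vectors).
#' @param labels Class labels.
#' @param target_variance PCA retained-variance target.
#' @param seed Integer seed.
#' @return A `paired_cv_test`.
#' @export
layer_dummy_test <- function(features, labels, target_variance = 0.80,
                             seed = 1L) {
  red <- pca_reduce(features, target_variance)
  scores <- standardize_scores(red$scores)
  paired_5x2cv_ttest(classifier_svm(), classifier_dummy(), scores, labels,
                     seed = seed)
}

#' @export
tidy.layer_probe_results <- function(x, ...) {
  tidyr::unnest(
    dplyr::mutate(
      tibble::as_tibble(x)[, c("layer_id", "depth_index", "feature_type",
                               "color_mode", "fold_accuracies")],
      fold = purrr::map(.data$fold_accuracies, seq_along)),
    c("fold", "fold_accuracies")) |>
    dplyr::rename(accuracy = "fold_accuracies")
}
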