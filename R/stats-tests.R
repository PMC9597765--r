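#' Dummy-classifier baseline accuracy
#'
#' Accuracy of the baseline that always predicts the most frequent class:
#' the modal class share. On the emulated corpus counts (374/269/284/372)
#' this is 374/1299 = 28.8%.
#'
#' @param labels Vector (or factor) of class labels.
#' @return Fraction in `(0, 1]`.
#' @export
dummy_accuracy <- function(labels) {
  if (length(labels) == 0) stopf("labels must be non-empty")
  max(table(labels)) / length(labels)
}

#' One-sample t-test with explicit degenerate-case conventions
#'
#' Standard two-sided one-sample t-test of `mean(values) == mu` (delegated to
#' [stats::t.test()]). Degenerate zero-variance inputs follow a fixed
#' contract: `sd = 0` with mean equal to `mu` gives `t = 0, p = 1`; `sd = 0`
#' with mean different from `mu` gives `p = 0` with a degeneracy flag.
#'
#' @param values Numeric vector, length >= 2.
#' @param mu Null-hypothesis mean.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
one_sample_ttest <- function(values, mu = 0) {
  if (length(values) < 2) stopf("one_sample_ttest needs at least 2 values")
  s <- sd(values)
  if (s == 0) {
    if (mean(values) == mu)
      return(list(t = 0, p = 1, df = length(values) - 1L, degenerate = TRUE))
    return(list(t = Inf * sign(mean(values) - mu), p = 0,
                df = length(values) - 1L, degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = mu)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Classifier constructors for procedure comparisons
#'
#' Each constructor returns a procedure: a function
#' `f(train_x, train_y, test_x)` yielding predicted labels, the shape
#' [paired_5x2cv_ttest()] consumes.
#'
#' @param kernel,cost Passed to [e1071::svm()].
#' @return A procedure function.
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
classifier_svm <- function(kernel = "linear", cost = 1) {
  function(train_x, train_y, test_x) {
    fit <- e1071::svm(x = train_x, y = factor(train_y), kernel = kernel,
                      cost = cost, scale = FALSE)
    as.character(predict(fit, test_x))
  }
}

#' @rdname classifiers
#' @export
classifier_dummy <- function() {
  function(train_x, train_y, test_x) {
    modal <- names(which.max(table(train_y)))
    rep(modal, nrow(test_x))
  }
}

#' @rdname classifiers
#' @export
classifier_nearest_centroid <- function() {
  function(train_x, train_y, test_x) {
    classes <- sort(unique(as.character(train_y)))
    cents <- t(vapply(classes,
                      function(cl) colMeans(train_x[train_y == cl, , drop = FALSE]),
                      numeric(ncol(train_x))))
    d2 <- outer(rowSums(test_x^2), rep(1, length(classes))) -
      2 * test_x %*% t(cents) + outer(rep(1, nrow(test_x)), rowSums(cents^2))
    classes[max.col(-d2, ties.method = "first")]
  }
}

#' @rdname classifiers
#' @param k Neighborhood size.
#' @export
classifier_knn <- function(k = 1L) {
  function(train_x, train_y, test_x) {
    n <- nrow(train_x)
    d2 <- outer(rowSums(test_x^2), rep(1, n)) -
      2 * test_x %*% t(train_x) + outer(rep(1, nrow(test_x)), rowSums(train_x^2))
    ty <- as.character(train_y)
    apply(d2, 1, function(row) {
      nb <- ty[order(row)[seq_len(k)]]
      names(which.max(table(nb)))
    })
  }
}

#' 5x2cv paired t-test comparing two classification procedures
#'
#' Five replicated 2-fold cross-validations: in each replication the data are
#' split 50/50 (stratified, seeded), each procedure is trained on one half and
#' evaluated on the other, then the roles are reversed; both procedures always
#' see identical splits. With fold differences `d_ij` (replication i, fold j)
#' and per-replication variances `s_i^2 = (d_i1 - dbar_i)^2 + (d_i2 -
#' dbar_i)^2`, the statistic is `t = d_11 / sqrt(mean(s_i^2))` with 5 degrees
#' of freedom (the numerator is the first fold difference of the first
#' replication, so the statistic depends on the seeded replication order).
#' Swapping the procedures negates `t` and leaves `p` unchanged.
#'
#' @param procedure_a,procedure_b Functions `f(train_x, train_y, test_x)`
#'   returning predicted labels (see [classifiers]).
#' @param features Numeric matrix, samples x features.
#' @param labels Class labels.
#' @param seed Integer seed fixing the five splits.
#' @return A `paired_cv_test`: list with `t_statistic`, `p_value`, `df = 5`,
#'   `accuracies` (5 x 2 x 2 array), `differences` (5 x 2), `degenerate`.
#' @export
paired_5x2cv_ttest <- function(procedure_a, procedure_b, features, labels,
                               seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (min(table(labels)) < 4)
    stopf("each class needs at least 4 samples (2 per half)")
  acc <- array(NA_real_, c(5, 2, 2), dimnames = list(NULL, NULL, c("A", "B")))
  d <- matrix(NA_real_, 5, 2)
  for (i in 1:5) {
    half1 <- withr::with_seed(derive_seed(seed, i, stream = 5L), {
      take <- logical(n)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        take[sample(idx, floor(length(idx) / 2))] <- TRUE
      }
      # top up to an exact 50/50 split from the remainder
      short <- floor(n / 2) - sum(take)
      if (short > 0) take[sample(which(!take), short)] <- TRUE
      take
    })
    for (j in 1:2) {
      tr <- if (j == 1) half1 else !half1
      a_pred <- procedure_a(features[tr, , drop = FALSE], labels[tr],
                            features[!tr, , drop = FALSE])
      b_pred <- procedure_b(features[tr, , drop = FALSE], labels[tr],
                            features[!tr, , drop = FALSE])
      acc[i, j, "A"] <- mean(a_pred == labels[!tr])
      acc[i, j, "B"] <- mean(b_pred == labels[!tr])
      d[i, j] <- acc[i, j, "A"] - acc[i, j, "B"]
    }
  }
  st <- t_5x2cv_from_differences(d)
  structure(
    list(t_statistic = st$t, p_value = st$p, df = 5L, accuracies = acc,
         differences = d, degenerate = st$degenerate,
         seed = as.integer(seed)),
    class = "paired_cv_test")
}

# The 5x2cv statistic from the 5 x 2 matrix of fold differences:
# t = d_11 / sqrt(mean(s_i^2)), s_i^2 the per-replication variance of the two
# fold differences, two-sided p on 5 df. Zero denominator: t = 0, p = 1 when
# the numerator is also zero, else p = 0 with a degeneracy flag.
t_5x2cv_from_differences <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == 5, ncol(d) == 2)
  s2 <- (d[, 1] - rowMeans(d))^2 + (d[, 2] - rowMeans(d))^2
  denom <- sqrt(mean(s2))
  if (denom == 0) {
    if (d[1, 1] == 0) return(list(t = 0, p = 1, degenerate = FALSE))
    return(list(t = Inf * sign(d[1, 1]), p = 0, degenerate = TRUE))
  }
  t_stat <- d[1, 1] / denom
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = 5), degenerate = FALSE)
}

#' @export
print.paired_cv_test <- function(x, ...) {
  cat(sprintf("<paired_cv_test> t(5) = %.3f, p = %.4f%s\n", x$t_statistic,
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  cat("  mean accuracy A:", round(mean(x$accuracies[, , "A"]), 3),
      " B:", round(mean(x$accuracies[, , "B"]), 3), "\n")
  invisible(x)
}

#' @export
tidy.paired_cv_test <- function(x, ...) {
  tibble::tibble(
    replication = rep(1:5, 2), fold = rep(1:2, each = 5),
    accuracy_a = as.vector(x$accuracies[, , "A"]),
    accuracy_b = as.vector(x$accuracies[, , "B"]),
    difference = as.vector(x$differences))
}

#' @export
glance.paired_cv_test <- function(x, ...) {
  tibble::tibble(t_statistic = x$t_statistic, p_value = x$p_value, df = x$df,
                 mean_accuracy_a = mean(x$accuracies[, , "A"]),
                 mean_accuracy_b = mean(x$accuracies[, , "B"]),
                 degenerate = x$degenerate)
}

#' Holm-corrected p-value column for a table of per-layer tests
#'
#' No correction is applied to the primary per-layer p-values (matching the
#' uncorrected per-layer comparisons of the analysis this package implements);
#' this helper adds a Holm-adjusted column for transparency.
#'
#' @param tests Tibble with a `p_value` column.
#' @return The tibble with an extra `p_holm` column.
#' @export
add_holm_column <- function(tests) {
  tests$p_holm <- stats::p.adjust(tests$p_value, method = "holm")
  tests
}
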