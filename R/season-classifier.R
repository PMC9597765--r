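#' Configuration of the transfer-learning classification head
#'
#' Defaults follow the reference training protocol: a fully connected layer of
#' width 2048 with L2 penalty 0.1, dropout 0.2, SGD with learning rate 0.1 and
#' batch size 16, early stopping after 3 epochs without validation-accuracy
#' improvement, and flip augmentation of the training stream.
#'
#' @param n_classes Number of output classes.
#' @param fc_width Hidden layer width.
#' @param l2_strength L2 penalty on the hidden layer weights.
#' @param dropout_rate Dropout probability after the hidden layer.
#' @param lr SGD learning rate.
#' @param batch_size Minibatch size.
#' @param patience_epochs Early-stopping patience.
#' @param max_epochs Epoch cap (early stopping is the operative control).
#' @param augment Add horizontal/vertical flips of the training images.
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @return A `head_config` list.
#' @export
head_config <- function(n_classes = 4L, fc_width = 2048L, l2_strength = 0.1,
                        dropout_rate = 0.2, lr = 0.1, batch_size = 16L,
                        patience_epochs = 3L, max_epochs = 50L,
                        augment = TRUE, seed = 1L) {
  stopifnot(n_classes >= 2, fc_width >= 1, l2_strength >= 0,
            dropout_rate >= 0, dropout_rate < 1, lr >= 0, batch_size >= 1,
            patience_epochs >= 1, max_epochs >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 fc_width = as.integer(fc_width), l2_strength = l2_strength,
                 dropout_rate = dropout_rate, lr = lr,
                 batch_size = as.integer(batch_size),
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs), augment = augment,
                 seed = as.integer(seed)),
            class = "head_config")
}

flip_pixels <- function(px, horizontal = FALSE, vertical = FALSE) {
  if (horizontal) px <- px[, dim(px)[2]:1, , drop = FALSE]
  if (vertical) px <- px[dim(px)[1]:1, , , drop = FALSE]
  px
}

# Deterministic enumeration of the flip group on the frozen features:
# because the backbone never changes, augmenting with all flip variants of
# every training image is the fixed-point of per-epoch random flipping.
augmented_features <- function(backbone, dataset) {
  feats <- list(pooled_features(backbone, dataset))
  for (fl in list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
    pxs <- lapply(dataset$pixels, flip_pixels, horizontal = fl[1], vertical = fl[2])
    feats[[length(feats) + 1]] <- pooled_features(backbone, pxs)
  }
  do.call(rbind, feats)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

head_forward_eval <- function(par, X) {
  xhat <- sweep(sweep(X, 2, par$run_mean), 2, sqrt(par$run_var + 1e-5), "/")
  h0 <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  A1 <- pmax(h0 %*% par$W1 + rep(par$b1, each = nrow(X)), 0)
  softmax_rows(A1 %*% par$W2 + rep(par$b2, each = nrow(X)))
}

#' Train the classification head on frozen backbone features
#'
#' The head is: global average pooling of the last convolutional block (512
#' features, precomputed once because the backbone is frozen) -> batch
#' normalization -> fully connected layer (ReLU, L2-penalized) -> dropout ->
#' softmax output, trained with SGD on the categorical cross-entropy and early
#' stopping on validation accuracy; the weights of the best validation epoch
#' are returned. Augmentation (flips) only ever touches the training stream.
#'
#' @param backbone A [build_backbone()] object (its weights are never touched).
#' @param train,val Disjoint `drawing_dataset`s.
#' @param config A [head_config()].
#' @return A `season_head` model with a `history` tibble (epoch, train_loss,
#'   val_accuracy) and `val_accuracy` of the returned weights.
#' @export
train_head <- function(backbone, train, val, config = head_config()) {
  if (nrow(train) == 0 || nrow(val) == 0) stopf("empty train or val split")
  classes <- sort(unique(train$label))
  if (length(classes) != config$n_classes)
    stopf("config$n_classes (%d) does not match training labels (%d classes)",
          config$n_classes, length(classes))
  Xtr <- if (config$augment) augmented_features(backbone, train)
         else pooled_features(backbone, train)
  ytr <- factor(rep(train$label, if (config$augment) 4 else 1), levels = classes)
  Xval <- pooled_features(backbone, val)
  yval <- factor(val$label, levels = classes)
  if (any(is.na(yval))) stopf("validation labels outside training classes")

  d <- ncol(Xtr); K <- config$n_classes; H <- config$fc_width
  par <- withr::with_seed(derive_seed(config$seed, 1L, stream = 7L), list(
    gamma = rep(1, d), beta = rep(0, d),
    run_mean = rep(0, d), run_var = rep(1, d),
    W1 = matrix(rnorm(d * H, sd = sqrt(2 / d)), d, H), b1 = rep(0, H),
    W2 = matrix(rnorm(H * K, sd = sqrt(1 / H)), H, K), b2 = rep(0, K)))
  Y <- diag(K)[as.integer(ytr), , drop = FALSE]

  best <- list(val_acc = -Inf, par = par, epoch = 0L)
  history <- list()
  stall <- 0L
  n <- nrow(Xtr)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- withr::with_seed(derive_seed(config$seed, epoch, stream = 8L),
                            sample.int(n))
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      X <- Xtr[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      m <- nrow(X)
      # batch norm (training mode)
      mu <- colMeans(X)
      v <- colMeans(sweep(X, 2, mu)^2)
      inv <- 1 / sqrt(v + 1e-5)
      xhat <- sweep(sweep(X, 2, mu), 2, inv, "*")
      h0 <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
      Z1 <- h0 %*% par$W1 + rep(par$b1, each = m)
      A1 <- pmax(Z1, 0)
      keep <- withr::with_seed(
        derive_seed(config$seed, epoch * 10007L + b0, stream = 9L),
        matrix(runif(m * ncol(A1)) >= config$dropout_rate, m))
      A1d <- A1 * keep / (1 - config$dropout_rate)
      P <- softmax_rows(A1d %*% par$W2 + rep(par$b2, each = m))
      loss <- -mean(log(pmax(rowSums(P * Yb), 1e-12))) +
        config$l2_strength * sum(par$W1^2)
      ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
      # backward
      dZ2 <- (P - Yb) / m
      dW2 <- crossprod(A1d, dZ2); db2 <- colSums(dZ2)
      dA1 <- tcrossprod(dZ2, par$W2) * keep / (1 - config$dropout_rate) *
        (Z1 > 0)
      dW1 <- crossprod(h0, dA1) + 2 * config$l2_strength * par$W1
      db1 <- colSums(dA1)
      dh0 <- tcrossprod(dA1, par$W1)
      dgamma <- colSums(dh0 * xhat); dbeta <- colSums(dh0)
      lr <- config$lr
      par$W2 <- par$W2 - lr * dW2; par$b2 <- par$b2 - lr * db2
      par$W1 <- par$W1 - lr * dW1; par$b1 <- par$b1 - lr * db1
      par$gamma <- par$gamma - lr * dgamma; par$beta <- par$beta - lr * dbeta
      if (lr > 0) {  # running stats only move when the head is actually training
        par$run_mean <- 0.9 * par$run_mean + 0.1 * mu
        par$run_var <- 0.9 * par$run_var + 0.1 * v
      }
    }
    val_pred <- classes[max.col(head_forward_eval(par, Xval), ties.method = "first")]
    val_acc <- mean(val_pred == as.character(yval))
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = ep_loss / n_batches,
                                       val_accuracy = val_acc)
    if (val_acc > best$val_acc) {
      best <- list(val_acc = val_acc, par = par, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience_epochs) break
    }
  }
  structure(list(par = best$par, classes = classes, config = config,
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, val_accuracy = best$val_acc),
            class = "season_head")
}

#' @export
print.season_head <- function(x, ...) {
  cat(sprintf(
    "<season_head> %d classes (%s); best epoch %d, val accuracy %.3f\n",
    length(x$classes), paste(x$classes, collapse = ", "), x$best_epoch,
    x$val_accuracy))
  invisible(x)
}

#' @export
tidy.season_head <- function(x, ...) x$history

#' @export
glance.season_head <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), best_epoch = x$best_epoch,
                 epochs_run = nrow(x$history), val_accuracy = x$val_accuracy)
}

#' Predict classes for a dataset with a trained head
#' @param object A `season_head`.
#' @param backbone The backbone used at training time.
#' @param dataset A `drawing_dataset`.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict_head <- function(object, backbone, dataset, ...) {
  X <- pooled_features(backbone, dataset)
  object$classes[max.col(head_forward_eval(object$par, X),
                         ties.method = "first")]
}

#' Evaluate a trained head: accuracy and confusion matrix
#'
#' @param model A `season_head`.
#' @param backbone The backbone used at training time.
#' @param dataset A labeled `drawing_dataset`.
#' @return List with `accuracy` (trace/total) and `confusion` (a
#'   `confusion_matrix`: rows = true label, columns = predicted label).
#' @export
evaluate_head <- function(model, backbone, dataset) {
  if (!all(dataset$label %in% model$classes))
    stopf("dataset contains labels unseen at training time")
  pred <- predict_head(model, backbone, dataset)
  conf <- confusion_matrix(dataset$label, pred, classes = model$classes)
  list(accuracy = sum(diag(conf)) / sum(conf), confusion = conf)
}

#' Confusion matrix (rows = true label, columns = predicted)
#' @param truth,pred Label vectors of equal length.
#' @param classes Class ordering (default: sorted union).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  m <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Merge classes of a dataset
#'
#' Maps each label through `grouping` (e.g. autumn+winter -> "cold",
#' spring+summer -> "warm", or a coverage median split), preserving the image
#' count; new class counts are the summed old counts.
#'
#' @param dataset A `drawing_dataset`.
#' @param grouping Named character vector `c(old_label = new_label, ...)`
#'   covering every label present.
#' @return The dataset with relabeled images.
#' @export
relabel <- function(dataset, grouping) {
  missing <- setdiff(unique(dataset$label), names(grouping))
  if (length(missing) > 0)
    stopf("grouping is missing labels: %s", paste(missing, collapse = ", "))
  dataset$label <- unname(grouping[dataset$label])
  dataset
}

#' Median-coverage binary relabeling
#'
#' Splits the dataset at its median coverage into `"low"` and `"high"`
#' coverage classes (sizes differing by at most one image).
#'
#' @param dataset A `drawing_dataset`.
#' @return The dataset with labels `"low"`/`"high"` and attribute `threshold`.
#' @export
relabel_by_coverage <- function(dataset) {
  cov <- dataset_coverage(dataset)
  thr <- median(cov)
  r <- rank(cov, ties.method = "first")
  dataset$label <- ifelse(r <= nrow(dataset) / 2, "low", "high")
  attr(dataset, "threshold") <- thr
  dataset
}
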