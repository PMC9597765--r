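# Canonical VGG19 convolutional geometry: 16 conv stages in 5 blocks
# (2,2,4,4,4), all 3x3 kernels with padding 1, 2x2 max pool after each block.
VGG_WIDTHS <- c(64L, 64L, 128L, 128L, rep(256L, 4), rep(512L, 4), rep(512L, 4))
VGG_POOL_AFTER <- c(2L, 4L, 8L, 12L, 16L)
FC_WIDTH <- 4096L

#' Shape table of the backbone's probed layers
#'
#' One row per probe point: the 16 convolutional stages (activations taken
#' post-ReLU, before the block's pooling) and the two hidden fully connected
#' stages of the canonical published architecture. `vector_length` is the
#' length of the flattened activation vector; it decreases monotonically with
#' depth over the conv stack (224^2 x 64 = 3,211,264 at conv1 down to
#' 14^2 x 512 = 100,352 at conv16).
#'
#' @return Tibble: layer_id, depth_index, channels, height, width,
#'   vector_length.
#' @export
layer_shape_table <- function() {
  sides <- rep(c(224L, 112L, 56L, 28L, 14L), times = c(2L, 2L, 4L, 4L, 4L))
  conv <- tibble::tibble(
    layer_id = paste0("conv", 1:16), depth_index = 1:16,
    channels = VGG_WIDTHS, height = sides, width = sides,
    vector_length = VGG_WIDTHS * sides^2)
  fc <- tibble::tibble(
    layer_id = c("FC1", "FC2"), depth_index = 17:18,
    channels = c(FC_WIDTH, FC_WIDTH), height = NA_integer_,
    width = NA_integer_, vector_length = c(FC_WIDTH, FC_WIDTH))
  dplyr::bind_rows(conv, fc)
}

parse_layer_id <- function(layer_id) {
  tab <- layer_shape_table()
  if (!layer_id %in% tab$layer_id)
    stopf("unknown layer_id '%s' (use conv1..conv16, FC1, FC2)", layer_id)
  tab[tab$layer_id == layer_id, ]
}

#' Build the frozen VGG19-style feature extractor
#'
#' @param weights_source `"seeded_random"` (He-scaled Gaussian kernels, zero
#'   biases, fully reproducible from `seed`; the download-free mode every test
#'   runs with) or `"pretrained"`, which requires `pretrained_weights`: a path
#'   to an RDS file holding a list of 16 matrices of dimensions
#'   `(9 * C_in) x C_out` (row order channel-major over the 3 x 3 kernel) plus
#'   an optional `biases` attribute.
#' @param seed Integer seed for `"seeded_random"` weights.
#' @param pretrained_weights Optional RDS path, see above.
#' @return A `vgg_backbone` object.
#' @export
build_backbone <- function(weights_source = c("seeded_random", "pretrained"),
                           seed = 1L, pretrained_weights = NULL) {
  weights_source <- match.arg(weights_source)
  cin <- c(3L, VGG_WIDTHS[-16])
  if (weights_source == "pretrained") {
    if (is.null(pretrained_weights) || !file.exists(pretrained_weights))
      stopf(paste(
        "pretrained ImageNet weights are not bundled with this package;",
        "pass pretrained_weights = <RDS path> or use",
        'weights_source = "seeded_random" (the mode the test suite runs with)'))
    w <- readRDS(pretrained_weights)
    weights <- w$weights %||% w
    biases <- w$biases %||% lapply(VGG_WIDTHS, function(k) numeric(k))
    for (l in 1:16)
      if (!all(dim(weights[[l]]) == c(9L * cin[l], VGG_WIDTHS[l])))
        stopf("pretrained weight matrix %d has wrong dimensions", l)
  } else {
    weights <- vector("list", 16L)
    for (l in 1:16) {
      fan_in <- 9L * cin[l]
      weights[[l]] <- withr::with_seed(
        derive_seed(seed, l, stream = 1L),
        matrix(rnorm(fan_in * VGG_WIDTHS[l], sd = sqrt(2 / fan_in)),
               fan_in, VGG_WIDTHS[l]))
    }
    biases <- lapply(VGG_WIDTHS, function(k) numeric(k))
  }
  structure(
    list(weights = weights, biases = biases, widths = VGG_WIDTHS,
         pool_after = VGG_POOL_AFTER, weights_source = weights_source,
         seed = as.integer(seed), fc_widths = c(FC_WIDTH, FC_WIDTH)),
    class = "vgg_backbone")
}

#' @export
print.vgg_backbone <- function(x, ...) {
  cat(sprintf(paste0(
    "<vgg_backbone> 16 conv stages (3x3, widths %d..%d, pools after %s),\n",
    "  2 FC stages of width %d; weights: %s (seed %d)\n"),
    x$widths[1], x$widths[16], paste(x$pool_after, collapse = "/"),
    x$fc_widths[1], x$weights_source, x$seed))
  invisible(x)
}

# Forward one image; returns named list of kept post-ReLU conv activation
# arrays (H x W x C) and optionally the final pooled 7 x 7 x 512 block.
forward_keep <- function(backbone, pixels, keep = integer(0), final_pool = FALSE) {
  px <- as_pixels(pixels)
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  cpp_vgg_forward(px / 255, backbone$weights, backbone$biases,
                  backbone$pool_after, as.integer(keep), final_pool)
}

# Row-major flattening of each H x W feature map, maps as columns: N x C.
feature_map_matrix <- function(act) {
  d <- dim(act)
  matrix(aperm(act, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

# Flattened pool5 output in the package's canonical order (length 25088).
flatten_final_pool <- function(fp) as.vector(feature_map_matrix(fp))

# FC activations for a matrix of flattened pool5 vectors (n x 25088).
# Weights are He-scaled Gaussians generated chunk-wise from the backbone seed
# so the 25088 x 4096 matrix never has to be held in memory.
fc_forward <- function(backbone, P, upto = 1L) {
  if (backbone$weights_source != "seeded_random")
    stopf("FC activations require seeded_random weights or a bundled FC head")
  n_in <- ncol(P)
  chunk <- 512L
  H <- matrix(0, nrow(P), FC_WIDTH)
  for (j in seq_len(FC_WIDTH %/% chunk)) {
    Wj <- withr::with_seed(
      derive_seed(backbone$seed, j, stream = 2L),
      matrix(rnorm(n_in * chunk, sd = sqrt(2 / n_in)), n_in, chunk))
    H[, ((j - 1L) * chunk + 1L):(j * chunk)] <- P %*% Wj
  }
  H[H < 0] <- 0
  if (upto == 2L) {
    W2 <- withr::with_seed(
      derive_seed(backbone$seed, 1L, stream = 3L),
      matrix(rnorm(FC_WIDTH * FC_WIDTH, sd = sqrt(2 / FC_WIDTH)),
             FC_WIDTH, FC_WIDTH))
    H <- H %*% W2
    H[H < 0] <- 0
  }
  H
}

#' Extract the flattened activation vector of one image at one layer
#'
#' Convolutional feature maps are taken post-ReLU, flattened row-major and
#' concatenated in channel order; FC activations are already vectors.
#'
#' @param backbone A [build_backbone()] object.
#' @param image 224 x 224 x 3 array or `drawing_image` (standardized).
#' @param layer_id `"conv1"`..`"conv16"`, `"FC1"` or `"FC2"`.
#' @return Numeric vector of length `layer_shape_table()$vector_length`.
#' @export
extract_activation_vector <- function(backbone, image, layer_id) {
  info <- parse_layer_id(layer_id)
  if (startsWith(layer_id, "conv")) {
    l <- info$depth_index
    act <- forward_keep(backbone, image, keep = l)[[1]]
    as.vector(feature_map_matrix(act))
  } else {
    fp <- forward_keep(backbone, image, final_pool = TRUE)$final_pool
    P <- matrix(flatten_final_pool(fp), nrow = 1)
    as.vector(fc_forward(backbone, P, upto = if (layer_id == "FC1") 1L else 2L))
  }
}

#' Global-average-pooled backbone features
#'
#' Mean of each of the 512 final feature maps (after the last pooling stage),
#' the frozen representation the transfer head is trained on.
#'
#' @param backbone A [build_backbone()] object.
#' @param dataset A `drawing_dataset` (or list of pixel arrays).
#' @return Numeric matrix, one row per image, 512 columns.
#' @export
pooled_features <- function(backbone, dataset) {
  pxs <- if (is.data.frame(dataset)) dataset$pixels else dataset
  out <- matrix(0, length(pxs), 512L)
  for (i in seq_along(pxs)) {
    fp <- forward_keep(backbone, pxs[[i]], final_pool = TRUE)$final_pool
    out[i, ] <- apply(fp, 3, mean)
  }
  out
}

#' Shared random subsampling of activation vectors, with its sanity check
#'
#' Draws `n_repeats` index sets of size `fraction * p` without replacement
#' (the same set applied to every image, preserving feature correspondence),
#' keeps the first set as the reduction, and checks that subsampling leaves
#' the mean activation unchanged: the `n_repeats` pooled means of the reduced
#' vectors are compared to the pooled mean of the original vectors with a
#' one-sample t-test (pass = not significant at alpha = 0.05).
#'
#' @param X Numeric matrix, images x activations.
#' @param fraction Fraction in `(0, 1]` of activations kept (default 0.5).
#' @param n_repeats Number of repeated draws entering the check (default 50).
#' @param seed Integer seed.
#' @return List with `reduced` (images x `round(fraction * p)` matrix) and
#'   `report` (a `subsample_report`).
#' @export
subsample_activations <- function(X, fraction = 0.5, n_repeats = 50L, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  p <- ncol(X)
  m <- max(1L, as.integer(round(p * fraction)))
  s <- colSums(X)
  n <- nrow(X)
  mu <- sum(s) / (n * p)
  idx1 <- NULL
  means <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    idx <- sort(withr::with_seed(derive_seed(seed, r, stream = 4L),
                                 sample.int(p, m)))
    if (r == 1L) idx1 <- idx
    means[r] <- sum(s[idx]) / (n * m)
  }
  tt <- one_sample_ttest(means, mu)
  report <- structure(
    list(fraction = fraction, n_repeats = n_repeats, repeat_means = means,
         mu_original = mu, t_statistic = tt$t, p_value = tt$p,
         passed = tt$p > 0.05),
    class = "subsample_report")
  list(reduced = X[, idx1, drop = FALSE], report = report)
}

#' @export
print.subsample_report <- function(x, ...) {
  cat(sprintf(
    "<subsample_report> fraction=%.2f repeats=%d t=%.3f p=%.3f -> %s\n",
    x$fraction, x$n_repeats, x$t_statistic, x$p_value,
    if (x$passed) "pass (mean preserved)" else "FAIL"))
  invisible(x)
}
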