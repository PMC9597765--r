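#' Gram matrix of a layer's feature maps
#'
#' With the layer's C flattened feature maps arranged as the columns of an
#' N x C matrix F (N spatial positions), the Gram matrix is `G = t(F) %*% F`:
#' `G[i, j]` is the inner product of feature maps i and j, the texture/style
#' summary that discards all spatial layout. No normalization by N or C is
#' applied by default.
#'
#' @param feature_maps N x C matrix, H x W x C array, or list of equal-length
#'   numeric vectors (one per map).
#' @param normalize Divide by N (the style-transfer literature's convention);
#'   default FALSE.
#' @return Symmetric positive semi-definite C x C matrix.
#' @export
gram_matrix <- function(feature_maps, normalize = FALSE) {
  if (is.list(feature_maps) && !is.matrix(feature_maps)) {
    lens <- lengths(feature_maps)
    if (length(unique(lens)) != 1) stopf("all feature maps must have equal length")
    feature_maps <- do.call(cbind, feature_maps)
  } else if (is.array(feature_maps) && length(dim(feature_maps)) == 3) {
    feature_maps <- feature_map_matrix(feature_maps)
  }
  if (nrow(feature_maps) < 1) stopf("feature maps must be non-empty")
  G <- crossprod(feature_maps)
  if (normalize) G <- G / nrow(feature_maps)
  G
}

#' Flattened Gram vector of one image at one convolutional layer
#'
#' Row-major flattening of the full C x C Gram matrix (length C^2). Gram
#' matrices are only defined for convolutional layers: FC activations are
#' plain vectors, not collections of feature maps.
#'
#' @param image 224 x 224 x 3 array or `drawing_image`.
#' @param backbone A [build_backbone()] object.
#' @param layer_id `"conv1"`..`"conv16"`.
#' @param normalize Passed to [gram_matrix()].
#' @return Numeric vector of length `channels^2`.
#' @export
gram_feature_vector <- function(image, backbone, layer_id, normalize = FALSE) {
  info <- parse_layer_id(layer_id)
  if (!startsWith(layer_id, "conv"))
    stopf("Gram matrices cannot be computed for FC layers ('%s')", layer_id)
  act <- forward_keep(backbone, image, keep = info$depth_index)[[1]]
  G <- gram_matrix(act, normalize = normalize)
  as.vector(t(G))
}

# One forward pass per image, Gram vectors for every requested conv layer.
gram_feature_matrices <- function(backbone, dataset, layers, normalize = FALSE) {
  shape <- layer_shape_table()
  info <- shape[match(layers, shape$layer_id), ]
  if (any(is.na(info$depth_index)) || any(!startsWith(layers, "conv")))
    stopf("gram probing is defined for conv layers only")
  pxs <- dataset$pixels
  n <- length(pxs)
  mats <- lapply(info$channels, function(C) matrix(0, n, C^2))
  names(mats) <- layers
  for (i in seq_len(n)) {
    acts <- forward_keep(backbone, pxs[[i]], keep = info$depth_index)
    for (lid in layers) {
      G <- gram_matrix(acts[[lid]], normalize = normalize)
      mats[[lid]][i, ] <- as.vector(t(G))
    }
  }
  mats
}

#' Layer-wise style probing with Gram matrices
#'
#' For every requested convolutional layer, represents each image by its
#' flattened Gram matrix and runs the same PCA + stratified 10-fold SVM
#' machinery as [probe_layers()]. FC layers are refused.
#'
#' @inheritParams probe_layers
#' @param layers Conv layer ids (default all 16).
#' @param normalize Passed to [gram_matrix()].
#' @return A `layer_probe_results` tibble with `feature_type = "gram"`.
#' @export
gram_probe_layers <- function(dataset, backbone,
                              layers = paste0("conv", 1:16),
                              target_variance = 0.80, n_folds = 10L,
                              seed = 1L, normalize = FALSE) {
  mats <- gram_feature_matrices(backbone, dataset, layers, normalize)
  shape <- layer_shape_table()
  rows <- lapply(layers, function(lid) {
    info <- shape[shape$layer_id == lid, ]
    probe_one(mats[[lid]], dataset$label, lid, info$depth_index, "gram",
              "rgb", target_variance, n_folds, seed, ncol(mats[[lid]]))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("layer_probe_results", class(out))
  out
}

#' Two-component PCA scatter of Gram vectors at one layer
#'
#' The per-image Gram vectors of one convolutional layer projected onto their
#' first two principal components, with the explained-variance fractions --
#' the representation in which early-layer drawings separate into style
#' clusters.
#'
#' @inheritParams gram_probe_layers
#' @param layer_id A single conv layer id.
#' @param n_components Number of components returned (default 2).
#' @return Tibble (id, label, PC1, PC2, ...) with attribute
#'   `explained_variance` (fraction per returned component).
#' @export
gram_pca_scatter <- function(dataset, backbone, layer_id = "conv1",
                             n_components = 2L, normalize = FALSE) {
  mats <- gram_feature_matrices(backbone, dataset, layer_id, normalize)
  red <- pca_reduce(mats[[layer_id]], target_variance = 1.0)
  k <- min(n_components, ncol(red$scores))
  scores <- red$scores[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(
    tibble::tibble(id = dataset$id, label = dataset$label),
    tibble::as_tibble(scores))
  attr(out, "explained_variance") <- red$explained_variance[seq_len(k)]
  out
}
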