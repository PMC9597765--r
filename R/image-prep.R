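as_pixels <- function(image) {
  if (inherits(image, "drawing_image")) image$pixels else image
}

#' Standardize a raster to the backbone input geometry
#'
#' Reshapes any 3-channel raster to a 224 x 224 x 3 array. Non-square inputs
#' are stretched (both axes resampled independently with bilinear
#' interpolation) by default; `mode = "crop"` instead center-crops to a square
#' before resizing.
#'
#' @param image 3-channel array (any height/width, values in `[0, 255]` or
#'   `[0, 1]`) or a `drawing_image`.
#' @param mode `"stretch"` (default) or `"crop"`.
#' @return A 224 x 224 x 3 integer array in `[0, 255]`.
#' @export
standardize <- function(image, mode = c("stretch", "crop")) {
  mode <- match.arg(mode)
  px <- as_pixels(image)
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stopf("standardize() needs a 3-channel raster; got dims [%s]",
          paste(dim(px), collapse = ", "))
  if (max(px) <= 1 && min(px) >= 0 && !all(px == as.integer(px)))
    px <- px * 255
  side <- CANVAS_SIDE
  if (mode == "crop" && dim(px)[1] != dim(px)[2]) {
    s <- min(dim(px)[1:2])
    r0 <- (dim(px)[1] - s) %/% 2
    c0 <- (dim(px)[2] - s) %/% 2
    px <- px[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), , drop = FALSE]
  }
  if (dim(px)[1] == side && dim(px)[2] == side)
    return(array(as.integer(round(px)), c(side, side, 3)))
  res <- EBImage::resize(EBImage::Image(aperm(px / 255, c(2, 1, 3)),
                                        colormode = "Color"),
                         w = side, h = side)
  out <- aperm(EBImage::imageData(res), c(2, 1, 3))
  array(as.integer(pmin(pmax(round(out * 255), 0), 255)), c(side, side, 3))
}

#' NTSC grayscale conversion
#'
#' Converts RGB pixels to luminance `Y = 0.299 R + 0.587 G + 0.114 B`
#' (the analog-television standard), rounds half away from zero, clamps to
#' `[0, 255]`, and replicates the single gray channel three times so the
#' result still fits the 3-channel backbone input.
#'
#' @param image 224 x 224 x 3 array or `drawing_image`.
#' @return Same type as the input, with all three channels equal and (for
#'   `drawing_image`) `color_mode = "gray"`.
#' @export
to_grayscale_ntsc <- function(image) {
  px <- as_pixels(image)
  y <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  y <- pmin(pmax(trunc(y + 0.5), 0), 255)  # half away from zero (y >= 0)
  out <- array(as.integer(y), dim = dim(px))
  out[, , 2] <- out[, , 1]
  out[, , 3] <- out[, , 1]
  if (inherits(image, "drawing_image"))
    new_drawing_image(out, image$label, image$id, "gray")
  else out
}

#' Convert every image of a dataset to NTSC grayscale
#' @param dataset A `drawing_dataset`.
#' @return The dataset with grayscale pixels and `color_mode = "gray"`.
#' @export
dataset_to_grayscale <- function(dataset) {
  dataset$pixels <- lapply(dataset$pixels, to_grayscale_ntsc)
  dataset$color_mode <- "gray"
  dataset
}

#' Inked fraction of the canvas
#'
#' Coverage is the fraction of pixels whose maximum per-channel distance from
#' the background color exceeds `tolerance`. On the hard-edged synthetic
#' scribbles this is an exact pixel count.
#'
#' @param image Array or `drawing_image` (RGB or gray).
#' @param background_color RGB background (default the generator's near-white).
#' @param tolerance Non-negative channel distance below which a pixel counts
#'   as background.
#' @return Fraction in `[0, 1]`.
#' @export
compute_coverage <- function(image, background_color = BACKGROUND_RGB,
                             tolerance = 10) {
  if (tolerance < 0) stopf("tolerance must be >= 0")
  px <- as_pixels(image)
  d <- pmax(abs(px[, , 1] - background_color[1]),
            abs(px[, , 2] - background_color[2]),
            abs(px[, , 3] - background_color[3]))
  mean(d > tolerance)
}

#' Coverage of every image in a dataset
#' @inheritParams compute_coverage
#' @param dataset A `drawing_dataset`.
#' @return Numeric vector of per-image coverages.
#' @export
dataset_coverage <- function(dataset, background_color = BACKGROUND_RGB,
                             tolerance = 10) {
  vapply(dataset$pixels, compute_coverage, numeric(1),
         background_color = background_color, tolerance = tolerance)
}

#' Stratified train/validation split
#'
#' Partitions a dataset into a training and a validation set of exact sizes.
#' Under stratification each class's share of either set matches its share of
#' the whole dataset to within one image (largest-remainder allocation), the
#' idiom behind the emulated 907/392 split of the 1299-drawing corpus.
#'
#' @param dataset A `drawing_dataset` (any tibble with a `label` column works).
#' @param train_count,val_count Sizes; must sum to `nrow(dataset)`.
#' @param stratified Keep per-class proportions (default TRUE).
#' @param seed Integer seed controlling membership.
#' @return List with elements `train` and `val` (same class as the input) and
#'   a `split` tibble (id, label, subset).
#' @export
split_train_val <- function(dataset, train_count = 907L, val_count = 392L,
                            stratified = TRUE, seed = 1L) {
  n <- nrow(dataset)
  if (train_count + val_count != n)
    stopf("train_count + val_count (%d) must equal dataset size (%d)",
          train_count + val_count, n)
  withr::with_seed(seed, {
    take <- logical(n)
    if (stratified) {
      labs <- dataset$label
      classes <- sort(unique(labs))
      n_by <- vapply(classes, function(cl) sum(labs == cl), integer(1))
      exact <- n_by * train_count / n
      base <- floor(exact)
      rem <- train_count - sum(base)
      extra_order <- order(exact - base, decreasing = TRUE)
      alloc <- base
      if (rem > 0) alloc[extra_order[seq_len(rem)]] <- alloc[extra_order[seq_len(rem)]] + 1
      for (k in seq_along(classes)) {
        idx <- which(labs == classes[k])
        take[sample(idx, alloc[k])] <- TRUE
      }
    } else {
      take[sample.int(n, train_count)] <- TRUE
    }
  })
  split <- tibble::tibble(id = dataset$id, label = dataset$label,
                          subset = ifelse(take, "train", "val"))
  list(train = dataset[take, ], val = dataset[!take, ], split = split)
}
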