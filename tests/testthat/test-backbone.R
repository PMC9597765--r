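test_that("the backbone has the canonical 16-stage geometry", {
  bb <- fixture_backbone()
  expect_length(bb$weights, 16L)
  expect_equal(bb$widths[1], 64L)
  expect_equal(max(bb$widths), 512L)
  expect_equal(bb$widths[13:16], rep(512L, 4))
  # all kernels 3x3: weight rows = 9 * C_in
  cin <- c(3L, bb$widths[-16])
  for (l in 1:16) expect_equal(nrow(bb$weights[[l]]), 9L * cin[l])

  tab <- layer_shape_table()
  expect_equal(tab$vector_length[tab$layer_id == "conv1"], 3211264L)
  expect_equal(tab$vector_length[tab$layer_id == "conv16"], 100352L)
  # activation vector length never grows with conv depth and strictly
  # shrinks at every block boundary (pooling dominates channel growth)
  expect_true(all(diff(tab$vector_length[1:16]) <= 0))
  for (b in c(2L, 4L, 8L, 12L)) # last layer of each pooled block
    expect_lt(tab$vector_length[b + 1L], tab$vector_length[b])
})

test_that("seeded weights are reproducible and pretrained mode errors usefully", {
  b1 <- build_backbone("seeded_random", seed = 7)
  b2 <- build_backbone("seeded_random", seed = 7)
  expect_identical(b1$weights, b2$weights)
  b3 <- build_backbone("seeded_random", seed = 8)
  expect_false(identical(b1$weights[[1]], b3$weights[[1]]))
  expect_error(build_backbone("pretrained"), "seeded_random")
})

test_that("activation extraction matches the shape table and flattening contract", {
  bb <- fixture_backbone()
  img <- fixture_dataset("paperlike", 1, 5)$pixels[[1]]
  f1 <- extract_activation_vector(bb, img, "conv1")
  expect_length(f1, 3211264L)
  expect_true(all(is.finite(f1)))
  expect_true(all(f1 >= 0))  # post-ReLU
  f16 <- extract_activation_vector(bb, img, "conv16")
  expect_length(f16, 100352L)
  expect_error(extract_activation_vector(bb, img, "conv17"), "unknown layer_id")

  # determinism across calls
  expect_identical(f1, extract_activation_vector(bb, img, "conv1"))

  # zero image through the bias-free backbone: all-zero activations
  z <- array(0L, c(224, 224, 3))
  expect_true(all(extract_activation_vector(bb, z, "conv3") == 0))

  # channel-order flattening: permuting output channels permutes vector blocks
  perm <- c(2L, 1L, seq(3L, 64L))
  bbp <- bb
  bbp$weights[[1]] <- bb$weights[[1]][, perm]
  fp <- extract_activation_vector(bbp, img, "conv1")
  n <- 224L * 224L
  blocks <- function(v) lapply(seq_len(64L), function(c) v[((c - 1) * n + 1):(c * n)])
  expect_identical(blocks(fp), blocks(f1)[perm])
})

test_that("FC activations exist with the canonical head width", {
  bb <- fixture_backbone()
  img <- fixture_dataset("paperlike", 1, 5)$pixels[[1]]
  fc1 <- extract_activation_vector(bb, img, "FC1")
  expect_length(fc1, 4096L)
  expect_true(all(fc1 >= 0))
  expect_identical(fc1, extract_activation_vector(bb, img, "FC1"))
})

test_that("subsampling halves the vector, shares indices, and preserves the mean", {
  withr::with_seed(1, X <- matrix(rnorm(6 * 1000), 6))
  out <- subsample_activations(X, fraction = 0.5, n_repeats = 50, seed = 2)
  expect_equal(ncol(out$reduced), 500L)
  expect_length(out$report$repeat_means, 50L)
  expect_true(out$report$passed)
  # the same index set applies to every image: reduced columns are original
  # columns, identically selected across rows
  hit <- vapply(seq_len(ncol(out$reduced)), function(j) {
    cand <- which(abs(X[1, ] - out$reduced[1, j]) < 1e-12)
    any(vapply(cand, function(c0) all(X[, c0] == out$reduced[, j]), logical(1)))
  }, logical(1))
  expect_true(all(hit))

  # fraction 1: reduction is the identity, t exactly 0 against its own mean
  full <- subsample_activations(X, fraction = 1, seed = 3)
  expect_identical(full$reduced, X)
  expect_equal(full$report$t_statistic, 0)
  expect_equal(full$report$p_value, 1)

  # constant input: every subsample mean equals the original mean
  C <- matrix(2.5, 4, 100)
  rc <- subsample_activations(C, fraction = 0.5, seed = 4)
  expect_true(rc$report$passed)
  expect_equal(rc$report$t_statistic, 0)

  expect_error(subsample_activations(X, fraction = 0), "fraction")
  expect_error(subsample_activations(X, fraction = 1.2), "fraction")
})

test_that("conv1 subsampling at 50% yields the documented reduced length", {
  # 3,211,264 / 2 = 1,605,632: checked on the real streaming path
  bb <- fixture_backbone()
  ds <- fixture_dataset("paperlike", 1, 5)
  fm <- scribbleprobe:::activation_feature_matrix(
    bb, ds[rep(1, 2), ], "conv1", subsample = TRUE, fraction = 0.5, seed = 1)
  expect_equal(ncol(fm$X), 1605632L)
  expect_true(fm$report$passed)
})
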