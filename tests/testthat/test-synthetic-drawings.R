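test_that("presets encode the intended class differences", {
  pp <- make_season_params("paperlike")
  dominant <- function(p) {
    w <- vapply(p$palette, function(e) e$weight, numeric(1))
    p$palette[[which.max(w)]]$rgb
  }
  # green-dominant summer/winter, pink-dominant spring/autumn
  expect_equal(dominant(pp$summer), c(34L, 139L, 34L))
  expect_equal(dominant(pp$winter), c(34L, 139L, 34L))
  expect_equal(dominant(pp$spring), c(255L, 105L, 180L))
  expect_equal(dominant(pp$autumn), c(255L, 105L, 180L))
  # stroke statistics also differ across seasons in paperlike
  expect_gt(length(unique(vapply(pp, function(p) p$curvature_scale, 1))), 1)

  nn <- make_season_params("null")
  for (s in SEASONS[-1]) {
    expect_equal(nn[[s]]$palette, nn$autumn$palette)
    expect_equal(nn[[s]]$stroke_count_range, nn$autumn$stroke_count_range)
    expect_equal(nn[[s]]$stroke_width_range, nn$autumn$stroke_width_range)
    expect_equal(nn[[s]]$curvature_scale, nn$autumn$curvature_scale)
  }

  co <- make_season_params("color-only")
  for (s in SEASONS[-1]) {
    expect_equal(co[[s]]$stroke_count_range, co$autumn$stroke_count_range)
    expect_equal(co[[s]]$stroke_width_range, co$autumn$stroke_width_range)
    expect_equal(co[[s]]$curvature_scale, co$autumn$curvature_scale)
    expect_false(identical(co[[s]]$palette, co$autumn$palette))
  }
  # color-only hues are iso-luminant: identical NTSC Y for every season
  ys <- vapply(co, function(p) {
    rgb <- p$palette[[1]]$rgb
    0.299 * rgb[1] + 0.587 * rgb[2] + 0.114 * rgb[3]
  }, numeric(1))
  expect_equal(unname(diff(range(ys))), 0)

  so <- make_season_params("style-only")
  for (s in SEASONS[-1]) {
    expect_equal(so[[s]]$palette, so$autumn$palette)
    expect_equal(so[[s]]$stroke_width_range, so$autumn$stroke_width_range)
    expect_equal(so[[s]]$coverage_target, so$autumn$coverage_target)
  }
  expect_equal(length(unique(vapply(so, function(p) p$curvature_scale, 1))), 4)

  expect_error(make_season_params("nope"), "unknown preset")
})

test_that("style parameter validation enforces its invariants", {
  good <- list(list(rgb = c(1L, 2L, 3L), weight = 1))
  expect_error(season_style_params("autumn",
    list(list(rgb = c(1L, 2L, 3L), weight = 0.5))), "sum to 1")
  expect_error(season_style_params("autumn", good,
    stroke_count_range = c(5L, 2L)), "stroke_count_range")
  expect_error(season_style_params("autumn", good, curvature_scale = -1),
               "curvature_scale")
  expect_error(season_style_params("autumn", good, coverage_target = 1.5),
               "coverage_target")
})

test_that("rendering is deterministic and zero strokes give a blank canvas", {
  p <- make_season_params("paperlike")$summer
  a <- render_scribble(p, seed = 123)
  b <- render_scribble(p, seed = 123)
  expect_identical(a$pixels, b$pixels)
  expect_equal(dim(a$pixels), c(224L, 224L, 3L))
  expect_true(all(a$pixels >= 0 & a$pixels <= 255))

  p0 <- season_style_params("winter",
    list(list(rgb = c(34L, 139L, 34L), weight = 1)),
    stroke_count_range = c(0L, 0L))
  blank <- render_scribble(p0, seed = 1)
  expect_equal(compute_coverage(blank), 0)
  expect_true(all(blank$pixels[, , 1] == 245L))
})

test_that("coverage is non-decreasing in stroke count at fixed width", {
  mk <- function(k) season_style_params("autumn",
    list(list(rgb = c(205L, 50L, 50L), weight = 1)),
    stroke_count_range = c(k, k), stroke_width_range = c(4L, 4L),
    curvature_scale = 0.3)
  mean_cov <- vapply(c(1L, 5L, 20L, 50L), function(k) {
    mean(vapply(1:20, function(s) compute_coverage(render_scribble(mk(k), s)),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cov) > 0))
})

test_that("generate_dataset honors counts, seeds, and determinism", {
  pp <- make_season_params("paperlike")
  counts <- stats::setNames(rep(2L, 4), SEASONS)
  d1 <- generate_dataset(pp, counts, seed = 5)
  expect_equal(nrow(d1), 8L)
  expect_equal(unname(class_counts(d1)), rep(2L, 4))
  d2 <- generate_dataset(pp, counts, seed = 5)
  expect_identical(d1$id, d2$id)
  expect_identical(d1$pixels, d2$pixels)
  d3 <- generate_dataset(pp, counts, seed = 6)
  expect_false(identical(d1$pixels, d3$pixels))
  expect_error(generate_dataset(pp, stats::setNames(c(-1L, 1L, 1L, 1L), SEASONS)),
               "non-negative")
})

test_that("datasets round-trip through PNG files and the manifest", {
  d <- fixture_dataset("paperlike", 1, 5)
  dir <- withr::local_tempdir()
  man <- write_dataset(d, dir, preset = "paperlike")
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), nrow(d))
  back <- read_dataset(dir)
  expect_identical(back$id, d$id)
  expect_identical(back$pixels, d$pixels)
})
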