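# Memoized fixtures shared across test files: the backbone and rendered
# datasets are expensive relative to the assertions, so each is built once
# per test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

fixture_backbone <- function() {
  memo("backbone", build_backbone("seeded_random", seed = 7L))
}

fixture_dataset <- function(preset, n_per_class, seed) {
  memo(paste(preset, n_per_class, seed, sep = "_"),
       generate_dataset(make_season_params(preset),
                        stats::setNames(rep(as.integer(n_per_class), 4), SEASONS),
                        seed = seed))
}

# Two linearly separable Gaussian blobs with a wide margin.
separable_blobs <- function(n_per_class = 20, gap = 20, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * 2), ncol = 2),
               matrix(rnorm(n_per_class * 2, mean = gap), ncol = 2))
    list(x = x, y = rep(c("a", "b"), each = n_per_class))
  })
}
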