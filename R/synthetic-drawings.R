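#' Season names used throughout the package
#' @export
SEASONS <- c("autumn", "spring", "summer", "winter")

#' Per-season drawing counts of the emulated corpus
#'
#' The study corpus holds 1299 drawings: 374 autumn, 269 spring, 284 summer
#' and 372 winter (modal class autumn, 28.8% of the corpus). These counts are
#' the default class sizes of [generate_dataset()].
#'
#' @return Named integer vector over [SEASONS].
#' @export
season_counts <- function() {
  c(autumn = 374L, spring = 269L, summer = 284L, winter = 372L)
}

# Crayon-like colors used by the presets (RGB in 0..255).
CRAYON <- list(
  green  = c(34, 139, 34),  pink   = c(255, 105, 180),
  red    = c(205, 50, 50),  orange = c(240, 140, 40),
  yellow = c(235, 200, 60), blue   = c(65, 105, 225),
  brown  = c(139, 90, 43),  purple = c(140, 80, 170)
)

# Iso-luminant hues: all four have NTSC luminance exactly 110.000, so their
# grayscale renderings are pixel-identical. Used by the "color-only" preset
# to guarantee that any grayscale class signal is zero by construction.
ISOLUM <- list(
  green  = c(16, 174, 27),  pink = c(241, 39, 132),
  blue   = c(66, 106, 246), orange = c(244, 60, 16)
)

#' Style parameters controlling how one season's scribbles are rendered
#'
#' @param season_label One of [SEASONS] (or any class label).
#' @param palette List of entries `list(rgb = <3 ints>, weight = <num>)`;
#'   weights must be non-negative and sum to 1. One color is drawn per stroke.
#' @param stroke_count_range Integer interval `c(min, max)`, strokes per image.
#' @param stroke_width_range Integer interval `c(min, max)`, stroke width in
#'   pixels.
#' @param curvature_scale Standard deviation (radians) of the Gaussian
#'   turning-angle increments of the constant-speed random walk tracing each
#'   stroke; 0 gives straight lines, large values tight squiggles.
#' @param coverage_target Optional fraction in `[0, 1]`; when set, strokes are
#'   added until the inked fraction of the canvas reaches the target (capped
#'   at `max(stroke_count_range)` strokes), so classes can share coverage.
#' @param background_color RGB background, near-white by default so inked
#'   pixels are unambiguously countable.
#' @return A `season_style_params` object.
#' @export
season_style_params <- function(season_label, palette,
                                stroke_count_range = c(10L, 24L),
                                stroke_width_range = c(3L, 8L),
                                curvature_scale = 0.35,
                                coverage_target = NULL,
                                background_color = BACKGROUND_RGB) {
  p <- structure(
    list(
      season_label = season_label,
      palette = palette,
      stroke_count_range = as.integer(stroke_count_range),
      stroke_width_range = as.integer(stroke_width_range),
      curvature_scale = curvature_scale,
      coverage_target = coverage_target,
      background_color = as.integer(background_color)
    ),
    class = "season_style_params"
  )
  validate_season_style_params(p)
}

validate_season_style_params <- function(p) {
  w <- vapply(p$palette, function(e) e$weight, numeric(1))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stopf("palette weights must be non-negative and sum to 1")
  for (e in p$palette) {
    if (length(e$rgb) != 3 || any(e$rgb < 0) || any(e$rgb > 255))
      stopf("palette colors must be RGB triples in [0, 255]")
  }
  if (length(p$stroke_count_range) != 2 || diff(p$stroke_count_range) < 0 ||
      p$stroke_count_range[1] < 0)
    stopf("stroke_count_range must be a non-empty non-negative interval")
  if (length(p$stroke_width_range) != 2 || diff(p$stroke_width_range) < 0 ||
      p$stroke_width_range[1] < 1)
    stopf("stroke_width_range must be a non-empty interval of widths >= 1")
  if (p$curvature_scale < 0) stopf("curvature_scale must be >= 0")
  if (!is.null(p$coverage_target) &&
      (p$coverage_target < 0 || p$coverage_target > 1))
    stopf("coverage_target must lie in [0, 1]")
  p
}

#' @export
print.season_style_params <- function(x, ...) {
  cols <- vapply(x$palette, function(e) paste(e$rgb, collapse = ","), "")
  w <- vapply(x$palette, function(e) e$weight, numeric(1))
  cat("<season_style_params> ", x$season_label, "\n",
      "  palette: ", paste(sprintf("(%s) w=%.2f", cols, w), collapse = " "), "\n",
      "  strokes: ", x$stroke_count_range[1], "-", x$stroke_count_range[2],
      "  width: ", x$stroke_width_range[1], "-", x$stroke_width_range[2],
      "  curvature: ", x$curvature_scale,
      if (!is.null(x$coverage_target)) paste0("  coverage_target: ", x$coverage_target),
      "\n", sep = "")
  invisible(x)
}

pal <- function(...) {
  entries <- list(...)
  lapply(entries, function(e) list(rgb = as.integer(e[[1]]), weight = e[[2]]))
}

#' Preset style parameters for the four seasons
#'
#' Presets isolate which image statistic separates the seasonal classes:
#' \describe{
#'   \item{`"paperlike"`}{Seasons differ in palette AND stroke statistics,
#'     emulating the reported corpus: green is the dominant crayon in summer
#'     and winter, pink in spring and autumn, and stroke shape also varies.}
#'   \item{`"null"`}{All four seasons share identical parameters; any
#'     classifier should sit at the dummy baseline.}
#'   \item{`"color-only"`}{Stroke statistics identical; each season paints in
#'     one distinct hue, all four hues having NTSC luminance exactly 110, so
#'     grayscale conversions of the classes are statistically identical.}
#'   \item{`"shape-only"`}{Shared palette; stroke count, width and curvature
#'     differ across seasons.}
#'   \item{`"style-only"`}{Shared palette, shared stroke width, shared
#'     coverage target (0.25): seasons differ only in walk curvature, i.e. in
#'     large-scale stroke layout rather than local ink statistics.}
#' }
#'
#' @param profile Preset name.
#' @return Named list of [season_style_params()] over [SEASONS].
#' @export
make_season_params <- function(profile = c("paperlike", "null", "color-only",
                                           "shape-only", "style-only")) {
  if (!is.character(profile) || !profile[1] %in%
      c("paperlike", "null", "color-only", "shape-only", "style-only"))
    stopf("unknown preset '%s'", as.character(profile)[1])
  profile <- profile[1]

  mixed <- pal(list(CRAYON$green, 0.25), list(CRAYON$pink, 0.25),
               list(CRAYON$blue, 0.25), list(CRAYON$orange, 0.25))

  params <- switch(
    profile,
    "paperlike" = list(
      autumn = season_style_params(
        "autumn",
        pal(list(CRAYON$pink, 0.45), list(CRAYON$red, 0.20),
            list(CRAYON$orange, 0.20), list(CRAYON$brown, 0.15)),
        stroke_count_range = c(12L, 28L), stroke_width_range = c(4L, 9L),
        curvature_scale = 0.55),
      spring = season_style_params(
        "spring",
        pal(list(CRAYON$pink, 0.45), list(CRAYON$yellow, 0.20),
            list(CRAYON$green, 0.20), list(CRAYON$purple, 0.15)),
        stroke_count_range = c(8L, 20L), stroke_width_range = c(3L, 7L),
        curvature_scale = 0.15),
      summer = season_style_params(
        "summer",
        pal(list(CRAYON$green, 0.45), list(CRAYON$blue, 0.20),
            list(CRAYON$yellow, 0.20), list(CRAYON$orange, 0.15)),
        stroke_count_range = c(10L, 24L), stroke_width_range = c(5L, 10L),
        curvature_scale = 0.25),
      winter = season_style_params(
        "winter",
        pal(list(CRAYON$green, 0.45), list(CRAYON$blue, 0.25),
            list(CRAYON$purple, 0.15), list(CRAYON$brown, 0.15)),
        stroke_count_range = c(14L, 32L), stroke_width_range = c(2L, 6L),
        curvature_scale = 0.9)
    ),
    "null" = {
      one <- function(s) season_style_params(s, mixed)
      stats::setNames(lapply(SEASONS, one), SEASONS)
    },
    "color-only" = {
      hue <- list(autumn = ISOLUM$orange, spring = ISOLUM$pink,
                  summer = ISOLUM$green, winter = ISOLUM$blue)
      one <- function(s) season_style_params(s, pal(list(hue[[s]], 1)))
      stats::setNames(lapply(SEASONS, one), SEASONS)
    },
    "shape-only" = list(
      autumn = season_style_params("autumn", mixed,
        stroke_count_range = c(6L, 12L), stroke_width_range = c(8L, 12L),
        curvature_scale = 0.1),
      spring = season_style_params("spring", mixed,
        stroke_count_range = c(10L, 20L), stroke_width_range = c(5L, 8L),
        curvature_scale = 0.3),
      summer = season_style_params("summer", mixed,
        stroke_count_range = c(18L, 30L), stroke_width_range = c(3L, 5L),
        curvature_scale = 0.6),
      winter = season_style_params("winter", mixed,
        stroke_count_range = c(28L, 44L), stroke_width_range = c(2L, 3L),
        curvature_scale = 1.1)
    ),
    "style-only" = {
      curv <- c(autumn = 0.04, spring = 0.18, summer = 0.5, winter = 1.2)
      one <- function(s) season_style_params(
        s, mixed, stroke_count_range = c(1L, 60L),
        stroke_width_range = c(4L, 6L), curvature_scale = curv[[s]],
        coverage_target = 0.25)
      stats::setNames(lapply(SEASONS, one), SEASONS)
    }
  )
  params
}

# Uniform integer in [lo, hi]; safe against R's sample(n, 1) scalar expansion.
rint <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L

disc_offsets <- function(width) {
  r <- width / 2
  R <- ceiling(r)
  g <- expand.grid(dy = -R:R, dx = -R:R)
  g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
}

#' Render one synthetic scribble
#'
#' Strokes are constant-speed random walks with Gaussian turning angles
#' (spread `curvature_scale`), drawn as hard-edged (non-anti-aliased) thick
#' polylines by stamping a disc of the stroke width at every step, one palette
#' color per stroke, over a near-white background. Rendering is bit-exactly
#' reproducible from `(params, seed)`.
#'
#' @param params A [season_style_params()] object.
#' @param seed Integer seed for this image.
#' @param id Image id string.
#' @return A `drawing_image`: list with `pixels` (224 x 224 x 3 integer array
#'   in `[0, 255]`), `label`, `id`, `color_mode = "rgb"`.
#' @export
render_scribble <- function(params, seed, id = paste0(params$season_label, "_1")) {
  validate_season_style_params(params)
  side <- CANVAS_SIDE
  withr::with_seed(seed, {
    px <- array(rep(params$background_color, each = side * side),
                dim = c(side, side, 3))
    inked <- matrix(FALSE, side, side)
    n_max <- rint(params$stroke_count_range[1], params$stroke_count_range[2])
    use_cov <- !is.null(params$coverage_target)
    n_cap <- if (use_cov) params$stroke_count_range[2] else n_max
    n_strokes <- if (use_cov) n_cap else n_max
    weights <- vapply(params$palette, function(e) e$weight, numeric(1))
    k <- 0L
    while (k < n_strokes) {
      k <- k + 1L
      col_rgb <- params$palette[[
        sample.int(length(params$palette), 1, prob = weights)]]$rgb
      w <- rint(params$stroke_width_range[1], params$stroke_width_range[2])
      off <- disc_offsets(w)
      n_steps <- rint(40L, 110L)
      step <- 2
      x <- runif(1, 10, side - 10); y <- runif(1, 10, side - 10)
      theta <- runif(1, 0, 2 * pi)
      dth <- rnorm(n_steps, 0, params$curvature_scale)
      xs <- numeric(n_steps); ys <- numeric(n_steps)
      for (t in seq_len(n_steps)) {
        theta <- theta + dth[t]
        nx <- x + step * cos(theta); ny <- y + step * sin(theta)
        if (nx < 2 || nx > side - 1) { theta <- pi - theta; nx <- x + step * cos(theta) }
        if (ny < 2 || ny > side - 1) { theta <- -theta; ny <- y + step * sin(theta) }
        x <- min(max(nx, 1), side); y <- min(max(ny, 1), side)
        xs[t] <- x; ys[t] <- y
      }
      ci <- round(xs); ri <- round(ys)
      rr <- rep(ri, each = nrow(off)) + rep(off$dy, n_steps)
      cc <- rep(ci, each = nrow(off)) + rep(off$dx, n_steps)
      ok <- rr >= 1 & rr <= side & cc >= 1 & cc <= side
      lin <- unique((cc[ok] - 1L) * side + rr[ok])
      px[lin] <- col_rgb[1]
      px[lin + side * side] <- col_rgb[2]
      px[lin + 2L * side * side] <- col_rgb[3]
      inked[lin] <- TRUE
      if (use_cov && mean(inked) >= params$coverage_target) break
    }
    new_drawing_image(array(as.integer(px), dim(px)), params$season_label, id, "rgb")
  })
}

new_drawing_image <- function(pixels, label, id, color_mode) {
  structure(list(pixels = pixels, label = label, id = id,
                 color_mode = color_mode),
            class = "drawing_image")
}

#' @export
print.drawing_image <- function(x, ...) {
  cat(sprintf("<drawing_image> %s label=%s %s (%s)\n", x$id, x$label,
              paste(dim(x$pixels), collapse = "x"), x$color_mode))
  invisible(x)
}

#' Generate a labeled synthetic scribble dataset
#'
#' Renders `counts[s]` images per season with per-image seeds derived
#' deterministically (and order-independently) from the dataset seed, so the
#' whole dataset is bit-exactly reproducible from one integer.
#'
#' @param params_by_season Named list of [season_style_params()] (one entry
#'   per class), e.g. from [make_season_params()].
#' @param counts Named non-negative integer vector over the classes; defaults
#'   to the corpus counts [season_counts()].
#' @param seed Integer dataset seed.
#' @return A `drawing_dataset` tibble with columns `id`, `label`, `seed`,
#'   `pixels` (list of 224 x 224 x 3 integer arrays) and `color_mode`.
#' @export
generate_dataset <- function(params_by_season, counts = season_counts(), seed = 1L) {
  if (is.null(names(counts)) || !all(names(counts) %in% names(params_by_season)))
    stopf("counts must be named after entries of params_by_season")
  if (any(counts < 0)) stopf("counts must be non-negative")
  rows <- list()
  idx <- 0L
  for (s in names(counts)) {
    n <- counts[[s]]
    if (n == 0) next
    for (i in seq_len(n)) {
      idx <- idx + 1L
      im_seed <- derive_seed(seed, idx)
      id <- sprintf("%s_%05d", s, i)
      img <- render_scribble(params_by_season[[s]], im_seed, id)
      rows[[idx]] <- tibble::tibble(
        id = id, label = s, seed = im_seed,
        color_mode = "rgb", pixels = list(img$pixels))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(id = character(), label = character(),
                          seed = integer(), color_mode = character(),
                          pixels = list())
  attr(out, "dataset_seed") <- as.integer(seed)
  class(out) <- c("drawing_dataset", class(out))
  out
}

#' Class counts of a dataset
#' @param dataset A `drawing_dataset` (or any tibble with a `label` column).
#' @return Named integer vector of per-class counts.
#' @export
class_counts <- function(dataset) {
  tab <- table(dataset$label)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a dataset to disk as PNGs plus a manifest CSV
#'
#' @param dataset A `drawing_dataset`.
#' @param dir Output directory (created if missing).
#' @param preset Optional preset name recorded in the manifest.
#' @return Invisibly, the manifest tibble (id, filename, label, preset, seed).
#' @export
write_dataset <- function(dataset, dir, preset = NA_character_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fns <- file.path(dir, paste0(dataset$id, ".png"))
  for (i in seq_len(nrow(dataset)))
    png::writePNG(dataset$pixels[[i]] / 255, fns[i])
  manifest <- tibble::tibble(id = dataset$id, filename = basename(fns),
                             season = dataset$label, preset = preset,
                             seed = dataset$seed)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory holding `manifest.csv` and the PNGs.
#' @return A `drawing_dataset` tibble.
#' @export
read_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  px <- lapply(file.path(dir, manifest$filename), function(f) {
    a <- png::readPNG(f)
    array(as.integer(round(a * 255)), dim(a))
  })
  out <- tibble::tibble(id = manifest$id, label = manifest$season,
                        seed = manifest$seed, color_mode = "rgb", pixels = px)
  class(out) <- c("drawing_dataset", class(out))
  out
}
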