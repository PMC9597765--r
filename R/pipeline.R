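#' Configuration for a full probing study
#'
#' A flat, explicitly-seeded description of one end-to-end run: simulate ->
#' split -> train head -> probe activations (RGB and grayscale) -> probe Gram
#' matrices -> statistics -> report. Unknown fields are rejected so a typo can
#' never silently change a run.
#'
#' @param preset Generator preset, see [make_season_params()].
#' @param counts Named per-class image counts (default [season_counts()]).
#' @param train_fraction Fraction of images in the training split (the
#'   emulated corpus uses 907/1299, about 0.698).
#' @param weights_source Backbone weights, see [build_backbone()].
#' @param layers_content Layer ids probed with activations.
#' @param layers_gram Conv layer ids probed with Gram matrices.
#' @param color_modes Subset of `c("rgb", "gray")` for activation probes.
#' @param stats_layers Layers compared against the dummy baseline with the
#'   5x2cv paired t-test (re-extraction is needed, so keep this short).
#' @param scatter_layers Conv layers for the two-component Gram scatter.
#' @param n_folds Cross-validation folds for every probe (default 10; lower
#'   for small smoke-test corpora).
#' @param head Named list of [head_config()] overrides.
#' @param train_head Run the transfer-head stage (TRUE by default).
#' @param seed_dataset,seed_split,seed_training,seed_folds,seed_stats Integer
#'   seeds of each randomness source.
#' @param out_dir Output directory for artifacts and the stage cache.
#' @param write_images Also write every simulated image as PNG.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = "paperlike", counts = season_counts(),
                       train_fraction = 907 / 1299,
                       weights_source = "seeded_random",
                       layers_content = c("conv1", "conv4", "conv8", "conv12",
                                          "conv16", "FC1", "FC2"),
                       layers_gram = paste0("conv", c(1, 2, 4, 6, 8, 10, 12, 14, 16)),
                       color_modes = c("rgb", "gray"),
                       stats_layers = c("conv1", "conv8", "conv16"),
                       scatter_layers = c("conv1", "conv2"),
                       n_folds = 10L,
                       head = list(), train_head = TRUE,
                       seed_dataset = 1L, seed_split = 2L, seed_training = 3L,
                       seed_folds = 4L, seed_stats = 5L,
                       out_dir = tempfile("scribbleprobe_run_"),
                       write_images = FALSE) {
  cfg <- list(preset = preset, counts = as.list(counts),
              train_fraction = train_fraction,
              weights_source = weights_source,
              layers_content = layers_content, layers_gram = layers_gram,
              color_modes = color_modes, stats_layers = stats_layers,
              scatter_layers = scatter_layers, n_folds = as.integer(n_folds),
              head = head, train_head = train_head,
              seed_dataset = as.integer(seed_dataset),
              seed_split = as.integer(seed_split),
              seed_training = as.integer(seed_training),
              seed_folds = as.integer(seed_folds),
              seed_stats = as.integer(seed_stats),
              out_dir = out_dir, write_images = write_images)
  class(cfg) <- "run_config"
  cfg
}

#' Read and write run configurations as flat YAML
#'
#' Round-trips losslessly; unknown keys in the file are an error.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  raw$counts <- unlist(raw$counts)
  do.call(run_config, raw)
}

stage_cache <- function(out_dir, key, compute) {
  dir.create(file.path(out_dir, "cache"), showWarnings = FALSE, recursive = TRUE)
  f <- file.path(out_dir, "cache", paste0(key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  value <- compute()
  saveRDS(value, f)
  value
}

log_stage <- function(stage, key, t0) {
  message(sprintf("[scribbleprobe] stage=%s key=%s elapsed=%.1fs",
                  stage, substr(key, 1, 12),
                  as.numeric(Sys.time()) - t0))
}

#' Run the full probing study
#'
#' Orchestrates every stage with content-addressed caching (each stage's key
#' hashes its inputs plus the upstream key, so changing e.g. the dataset seed
#' invalidates all downstream caches) and writes all tables, figure CSV twins,
#' figures and a seed manifest under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("simulate", "prep", "train", "probe-content", "probe-style", "stats",
#'   "report")`; earlier stages a later stage depends on run (from cache) even
#'   if not listed.
#' @return Invisibly, a list with the dataset, split, head model, probe
#'   tibbles, stats tables and file paths.
#' @export
run_full_study <- function(config,
                           stages = c("simulate", "prep", "train",
                                      "probe-content", "probe-style",
                                      "stats", "report")) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  counts <- unlist(config$counts)

  key_sim <- rlang::hash(list("simulate", config$preset, counts,
                              config$seed_dataset))
  t0 <- as.numeric(Sys.time())
  dataset <- stage_cache(out, key_sim, function() {
    params <- make_season_params(config$preset)
    generate_dataset(params, counts, seed = config$seed_dataset)
  })
  log_stage("simulate", key_sim, t0)
  if ("simulate" %in% stages) {
    manifest <- tibble::tibble(id = dataset$id,
                               filename = paste0(dataset$id, ".png"),
                               season = dataset$label, preset = config$preset,
                               seed = dataset$seed)
    readr::write_csv(manifest, file.path(out, "dataset_manifest.csv"))
    if (config$write_images)
      write_dataset(dataset, file.path(out, "images"), preset = config$preset)
  }
  res$dataset <- dataset

  backbone <- build_backbone(config$weights_source, seed = config$seed_dataset)
  res$backbone <- backbone

  key_split <- rlang::hash(list("prep", key_sim, config$train_fraction,
                                config$seed_split))
  t0 <- as.numeric(Sys.time())
  n_train <- round(nrow(dataset) * config$train_fraction)
  split <- stage_cache(out, key_split, function() {
    split_train_val(dataset, n_train, nrow(dataset) - n_train,
                    seed = config$seed_split)
  })
  log_stage("prep", key_split, t0)
  if ("prep" %in% stages)
    readr::write_csv(split$split, file.path(out, "split_manifest.csv"))
  res$split <- split

  if (config$train_head && any(c("train", "report") %in% stages)) {
    key_train <- rlang::hash(list("train", key_split, config$weights_source,
                                  config$head, config$seed_training))
    t0 <- as.numeric(Sys.time())
    trained <- stage_cache(out, key_train, function() {
      hc <- do.call(head_config, modifyList(
        list(n_classes = length(unique(dataset$label)),
             seed = config$seed_training),
        config$head))
      model <- train_head(backbone, split$train, split$val, hc)
      ev <- evaluate_head(model, backbone, split$val)
      list(model = model, evaluation = ev)
    })
    log_stage("train", key_train, t0)
    readr::write_csv(trained$model$history, file.path(out, "head_history.csv"))
    conf_df <- tibble::as_tibble(as.table(unclass(trained$evaluation$confusion)))
    names(conf_df) <- c("true", "predicted", "count")
    readr::write_csv(conf_df, file.path(out, "confusion_matrix.csv"))
    jsonlite::write_json(
      list(val_accuracy = trained$evaluation$accuracy,
           dummy_baseline = unname(dummy_accuracy(split$val$label)),
           best_epoch = trained$model$best_epoch),
      file.path(out, "head_metrics.json"), auto_unbox = TRUE, digits = NA)
    res$head <- trained
  }

  content <- NULL
  if (any(c("probe-content", "stats", "report") %in% stages)) {
    key_content <- rlang::hash(list("probe-content", key_sim,
                                    config$weights_source,
                                    config$layers_content, config$color_modes,
                                    config$n_folds, config$seed_folds))
    t0 <- as.numeric(Sys.time())
    content <- stage_cache(out, key_content, function() {
      dplyr::bind_rows(lapply(config$color_modes, function(cm) {
        probe_layers(dataset, backbone, layers = config$layers_content,
                     color_mode = cm, n_folds = config$n_folds,
                     seed = config$seed_folds)
      }))
    })
    log_stage("probe-content", key_content, t0)
    res$content <- content
  }

  style <- NULL
  scatters <- list()
  if (any(c("probe-style", "stats", "report") %in% stages)) {
    key_style <- rlang::hash(list("probe-style", key_sim,
                                  config$weights_source, config$layers_gram,
                                  config$scatter_layers, config$n_folds,
                                  config$seed_folds))
    t0 <- as.numeric(Sys.time())
    style_bundle <- stage_cache(out, key_style, function() {
      sb <- list(probes = gram_probe_layers(dataset, backbone,
                                            layers = config$layers_gram,
                                            n_folds = config$n_folds,
                                            seed = config$seed_folds))
      sb$scatters <- lapply(config$scatter_layers, function(lid)
        gram_pca_scatter(dataset, backbone, lid))
      names(sb$scatters) <- config$scatter_layers
      sb
    })
    log_stage("probe-style", key_style, t0)
    style <- style_bundle$probes
    scatters <- style_bundle$scatters
    res$style <- style
    res$scatters <- scatters
  }

  if (any(c("probe-content", "probe-style", "report") %in% stages)) {
    folds_csv <- dplyr::bind_rows(
      if (!is.null(content)) tidy(content),
      if (!is.null(style)) tidy(style))
    readr::write_csv(folds_csv, file.path(out, "probe_folds.csv"))
    summary_csv <- dplyr::bind_rows(
      if (!is.null(content)) tibble::as_tibble(content)[
        , c("layer_id", "depth_index", "feature_type", "color_mode",
            "n_components", "mean_accuracy", "sd_accuracy")],
      if (!is.null(style)) tibble::as_tibble(style)[
        , c("layer_id", "depth_index", "feature_type", "color_mode",
            "n_components", "mean_accuracy", "sd_accuracy")])
    readr::write_csv(summary_csv, file.path(out, "probe_summary.csv"))
    for (lid in names(scatters))
      readr::write_csv(scatters[[lid]],
                       file.path(out, paste0("gram_scatter_", lid, ".csv")))
  }

  stats_tab <- NULL
  slopes <- NULL
  if (any(c("stats", "report") %in% stages)) {
    key_stats <- rlang::hash(list("stats", key_sim, config$weights_source,
                                  config$stats_layers, config$seed_stats))
    t0 <- as.numeric(Sys.time())
    stats_tab <- stage_cache(out, key_stats, function() {
      rows <- lapply(config$stats_layers, function(lid) {
        fm <- activation_feature_matrix(
          backbone, dataset, lid, subsample = lid %in% c("conv1", "conv2"))
        tst <- layer_dummy_test(fm$X, dataset$label, seed = config$seed_stats)
        tibble::tibble(comparison = "svm_vs_dummy", layer_id = lid,
                       t_statistic = tst$t_statistic, p_value = tst$p_value,
                       degenerate = tst$degenerate)
      })
      add_holm_column(dplyr::bind_rows(rows))
    })
    log_stage("stats", key_stats, t0)
    slope_rows <- list()
    if (!is.null(content)) {
      for (cm in unique(content$color_mode)) {
        sub <- content[content$color_mode == cm, ]
        if (nrow(sub) >= 3) {
          st_all <- slope_test(sub)
          slope_rows[[length(slope_rows) + 1]] <- tibble::tibble(
            series = paste0("activation_", cm), subset = "all_layers",
            slope = st_all$slope, p_value = st_all$p_value)
        }
        conv_sub <- sub[startsWith(sub$layer_id, "conv"), ]
        if (nrow(conv_sub) >= 3 && nrow(conv_sub) < nrow(sub)) {
          st_conv <- slope_test(conv_sub)
          slope_rows[[length(slope_rows) + 1]] <- tibble::tibble(
            series = paste0("activation_", cm), subset = "conv_only",
            slope = st_conv$slope, p_value = st_conv$p_value)
        }
      }
    }
    if (!is.null(style) && nrow(style) >= 3) {
      st <- slope_test(style)
      slope_rows[[length(slope_rows) + 1]] <- tibble::tibble(
        series = "gram_rgb", subset = "conv_only", slope = st$slope,
        p_value = st$p_value)
    }
    slopes <- dplyr::bind_rows(slope_rows)
    readr::write_csv(stats_tab, file.path(out, "stats_dummy_tests.csv"))
    readr::write_csv(slopes, file.path(out, "stats_slopes.csv"))
    res$stats <- stats_tab
    res$slopes <- slopes
  }

  if ("report" %in% stages) {
    if (!is.null(content)) {
      p <- plot_layer_accuracy(content, dummy = unname(dummy_accuracy(dataset$label)))
      ggplot2::ggsave(file.path(out, "fig_layer_accuracy_content.png"), p,
                      width = 7, height = 4, dpi = 120)
    }
    if (!is.null(style) && !is.null(content)) {
      both <- dplyr::bind_rows(tibble::as_tibble(style),
                               tibble::as_tibble(content[content$color_mode == "rgb", ]))
      p <- plot_layer_accuracy(both, dummy = unname(dummy_accuracy(dataset$label)))
      ggplot2::ggsave(file.path(out, "fig_gram_vs_activation.png"), p,
                      width = 7, height = 4, dpi = 120)
    }
    if (!is.null(res$head)) {
      p <- autoplot(res$head$evaluation$confusion)
      ggplot2::ggsave(file.path(out, "fig_confusion.png"), p,
                      width = 5, height = 4, dpi = 120)
    }
    for (lid in names(scatters)) {
      p <- plot_gram_scatter(scatters[[lid]])
      ggplot2::ggsave(file.path(out, paste0("fig_gram_scatter_", lid, ".png")),
                      p, width = 5, height = 4, dpi = 120)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("scribbleprobe")),
      r_version = R.version.string,
      config = unclass(config),
      config_hash = rlang::hash(unclass(config)))
    jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
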