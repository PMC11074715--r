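# End-to-end experiment orchestration from one config: phantom generation
# (or existing manifests) -> brain contour cropping -> threshold
# segmentation -> deterministic augmentation -> partitioning (single-dataset
# 80/20 or unseen-case 70/30) -> training -> prediction -> seven-metric
# report. One top-level seed derives every stage seed; rerunning a config
# reproduces the same partition and, for fixed weights, the same report.

#' Default run configuration
#'
#' Returns the full default config as a nested list; [run_experiment()]
#' merges a user config (list or YAML file) over these defaults.
#'
#' @return nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 0,
    out_dir = NULL,
    scenario = "single",          # "single" (80/20) or "unseen" (70/30)
    manifest = NULL,              # CSV path; unseen: list(train=, test=)
    phantoms = NULL,              # e.g. list(n_tumor=30, n_normal=30) or
                                  # list(train=list(...), test=list(...))
    preprocess = list(enabled = TRUE, threshold = 45, kernel_size = 5),
    segmentation = list(enabled = TRUE, alpha = 3, beta = -420, side = 144,
                        threshold = NULL, on_degenerate = "zero"),
    augmentation = list(plan = "none"),   # "none", "x8" or "x36"
    split = list(test_fraction = 0.2, val_fraction = 0.2, stratified = TRUE,
                 group_by_source = TRUE),
    model = list(width_multiplier = 1, frozen_conv = 10,
                 head_widths = c(512, 256, 64), dropout_rate = 0.5),
    train = list(learning_rate = 2e-5, max_epochs = 30, batch_size = 32,
                 patience = 5)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) && nm != "phantoms" &&
        nm != "manifest") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return config list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "contourtl_leakage")) stop(e)  # keep the condition class
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

preprocess_manifest <- function(manifest, cfg, out_dir, tag) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pp <- cfg$preprocess; sg <- cfg$segmentation
  paths <- character(nrow(manifest))
  thresholds <- rep(NA_real_, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    src <- manifest$path[i]
    img <- tryCatch(read_image(src), error = function(e) {
      stop(sprintf("cannot read '%s': %s", src, conditionMessage(e)), call. = FALSE)
    })
    if (isTRUE(pp$enabled)) {
      img <- tryCatch(
        extract_brain(img, threshold = pp$threshold,
                      kernel_size = pp$kernel_size),
        error = function(e) stop(sprintf("'%s': %s", src, conditionMessage(e)),
                                 call. = FALSE))
    }
    img <- to_grayscale(img)
    if (isTRUE(sg$enabled)) {
      res <- tryCatch(
        segment_pipeline(img, alpha = sg$alpha, beta = sg$beta,
                         side = sg$side, threshold = sg$threshold),
        contourtl_degenerate_histogram = function(e) {
          # a constant enhanced image has nothing above the window floor:
          # that is an empty segmentation, not a failure (typical for
          # lesion-free brains under the bright-end window)
          if (identical(sg$on_degenerate, "zero")) {
            list(image = matrix(0, sg$side, sg$side), threshold = NA_real_)
          } else {
            stop(sprintf("'%s': %s", src, conditionMessage(e)), call. = FALSE)
          }
        },
        error = function(e) stop(sprintf("'%s': %s", src, conditionMessage(e)),
                                 call. = FALSE))
      img <- res$image
      thresholds[i] <- res$threshold
    } else {
      img <- resize_image(img, sg$side)
    }
    dst <- file.path(out_dir, sprintf("%s_%s", tag, basename(src)))
    write_image(img, dst)
    paths[i] <- dst
  }
  out <- data.frame(path = paths, label = manifest$label,
                    source = manifest$path, stringsAsFactors = FALSE)
  utils::write.csv(data.frame(path = paths, threshold = thresholds),
                   file.path(out_dir, sprintf("%s_thresholds.csv", tag)),
                   row.names = FALSE)
  out
}

augment_stage <- function(manifest, plan_name, out_dir, tag) {
  if (is.null(plan_name) || plan_name == "none") return(manifest)
  k <- switch(plan_name, x8 = 8L, x36 = 36L,
              stop("unknown augmentation plan: ", plan_name, call. = FALSE))
  aug <- apply_plan(manifest[c("path", "label")], standard_plan(k),
                    file.path(out_dir, paste0("augmented_", tag)))
  if ("source" %in% names(manifest)) {
    # augmented rows trace back to the ORIGINAL source image, not the
    # intermediate processed file, so grouping prevents leakage end to end
    aug$source <- manifest$source[match(aug$source, manifest$path)]
  }
  aug
}

#' Run a full experiment from a configuration
#'
#' Executes the whole pipeline (see the package vignette): data intake or
#' phantom generation, brain cropping, segmentation, augmentation,
#' partitioning, training, prediction, evaluation. All artifacts (config
#' copy, manifests with a `split` column, per-image thresholds, training
#' history, model weights, metrics report) are written under
#' `config$out_dir`.
#'
#' @param config nested config list (merged over [default_run_config()]) or
#'   a YAML file path.
#' @return run report: list with `metrics` (seven-metric report),
#'   `confusion`, `partition` sizes, `history`, and `out_dir`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  unseen <- identical(config$scenario, "unseen")

  # ---- data intake ---------------------------------------------------------
  manifests <- stage("data", {
    if (!is.null(config$phantoms)) {
      ph <- config$phantoms
      ranges <- if (!is.null(ph$ranges)) do.call(modify_ranges, ph["ranges"]) else phantom_ranges()
      if (unseen) {
        list(train = generate_phantom_dataset(ph$train$n_tumor, ph$train$n_normal,
                                              file.path(out_dir, "phantoms_train"),
                                              seed = stage_seed(seed, "phantoms"),
                                              spec_ranges = ranges),
             test = generate_phantom_dataset(ph$test$n_tumor, ph$test$n_normal,
                                             file.path(out_dir, "phantoms_test"),
                                             seed = stage_seed(seed, "phantoms") + 1L,
                                             spec_ranges = ranges))
      } else {
        list(train = generate_phantom_dataset(ph$n_tumor, ph$n_normal,
                                              file.path(out_dir, "phantoms"),
                                              seed = stage_seed(seed, "phantoms"),
                                              spec_ranges = ranges))
      }
    } else if (!is.null(config$manifest)) {
      if (unseen) list(train = read_manifest(config$manifest$train),
                       test = read_manifest(config$manifest$test))
      else list(train = read_manifest(config$manifest))
    } else {
      stop("config must provide either `phantoms` or `manifest`", call. = FALSE)
    }
  })

  # ---- preprocessing + segmentation ---------------------------------------
  message("stage: preprocess + segment")
  proc <- stage("preprocess", {
    lapply(stats::setNames(names(manifests), names(manifests)), function(nm) {
      preprocess_manifest(manifests[[nm]], config,
                          file.path(out_dir, "processed"), nm)
    })
  })

  # ---- augmentation --------------------------------------------------------
  message("stage: augment (plan ", config$augmentation$plan, ")")
  aug <- stage("augment", {
    lapply(stats::setNames(names(proc), names(proc)), function(nm) {
      augment_stage(proc[[nm]], config$augmentation$plan, out_dir, nm)
    })
  })

  # ---- partition -----------------------------------------------------------
  message("stage: split (", config$scenario, ")")
  part <- stage("split", {
    sp <- config$split
    if (unseen) {
      build_unseen_scenario(aug$train, aug$test,
                            split_spec(test_fraction = 0,
                                       val_fraction = if (!is.null(sp$val_fraction_unseen))
                                         sp$val_fraction_unseen else 0.3,
                                       stratified = sp$stratified,
                                       group_by_source = sp$group_by_source,
                                       seed = stage_seed(seed, "split")))
    } else {
      split_dataset(aug$train,
                    split_spec(test_fraction = sp$test_fraction,
                               val_fraction = sp$val_fraction,
                               stratified = sp$stratified,
                               group_by_source = sp$group_by_source,
                               seed = stage_seed(seed, "split")))
    }
  })
  for (nm in c("train", "validation", "test")) {
    m <- part[[nm]]; m$split <- nm
    utils::write.csv(m, file.path(out_dir, paste0("split_", nm, ".csv")),
                     row.names = FALSE)
  }

  # ---- model + training ----------------------------------------------------
  message("stage: train")
  fitted <- stage("train", {
    mc <- config$model
    spec <- model_spec(input_side = config$segmentation$side,
                       frozen_conv = mc$frozen_conv,
                       head_widths = mc$head_widths,
                       dropout_rate = mc$dropout_rate,
                       width_multiplier = mc$width_multiplier)
    net <- build_contourtl_net(spec, seed = stage_seed(seed, "model"))
    tc <- config$train
    train_model(net, part,
                train_config(learning_rate = tc$learning_rate,
                             max_epochs = tc$max_epochs,
                             batch_size = tc$batch_size,
                             patience = tc$patience,
                             seed = stage_seed(seed, "train")))
  })

  # ---- evaluation ----------------------------------------------------------
  message("stage: evaluate")
  report <- stage("evaluate", {
    test_imgs <- lapply(part$test$path, read_image)
    probs <- predict(fitted, test_imgs)
    y <- as.integer(part$test$label)
    pred <- as.integer(probs[, 2] > probs[, 1])
    cm <- confusion(y, pred)
    mr <- metrics(cm)
    mr$roc_auc <- if (length(unique(y)) == 2L) roc_auc(y, probs[, 2]) else NA_real_
    list(metrics = mr, confusion = cm)
  })

  history_df <- fitted$history$epochs
  utils::write.csv(history_df, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  saveRDS(save_weights(fitted), file.path(out_dir, "weights.rds"))
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  yaml::write_yaml(list(package_version = as.character(utils::packageVersion("contourtl")),
                        seed = seed),
                   file.path(out_dir, "run_meta.yaml"))
  jsonlite::write_json(
    list(metrics = unclass(report$metrics),
         confusion = unclass(report$confusion),
         partition = list(train = nrow(part$train),
                          validation = nrow(part$validation),
                          test = nrow(part$test))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)

  list(metrics = report$metrics, confusion = report$confusion,
       partition = c(train = nrow(part$train),
                     validation = nrow(part$validation),
                     test = nrow(part$test)),
       history = fitted$history, model = fitted, out_dir = out_dir)
}

# allow configs to override individual phantom ranges
modify_ranges <- function(ranges) {
  base <- phantom_ranges()
  for (nm in names(ranges)) base[[nm]] <- as.numeric(ranges[[nm]])
  base
}
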