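# End-to-end orchestration: generate -> preprocess -> optimize ->
# train_seg -> segment -> train_cls -> grow -> classify -> evaluate.
# Every stage writes its artifacts and a manifest (config hash + seed)
# into its own subdirectory; a run is a pure function of (config, seed).

#' Pipeline run configuration
#'
#' @param stages ordered subset of `c("generate", "preprocess",
#'   "optimize", "train_seg", "segment", "train_cls", "grow",
#'   "classify", "evaluate")`.  Dependencies are checked up front:
#'   `segment` needs a model (`train_seg` or `optimize`+`train_seg`),
#'   `evaluate` needs predictions, `grow`/`classify` need `train_cls`.
#' @param out_dir output directory for artifacts (`NULL` = keep all
#'   results in memory only).
#' @param seed global seed; all stage seeds derive from it.
#' @param n_images number of synthetic images for the segmentation flow.
#' @param image_size square image size in pixels.
#' @param foreground_fraction lesion pixel fraction of generated images.
#' @param hair_count,impulse_noise_prob,speckle_variance artifact/noise
#'   settings passed to the generator.
#' @param class_ids integer class labels for the classification flow;
#'   the first `length(class_ids) - n_grow_classes` are used by
#'   `train_cls`, the rest arrive incrementally via `grow`.
#' @param n_grow_classes how many of `class_ids` arrive via `grow`.
#' @param n_per_class images generated per class.
#' @param split train/validation/test proportions (sums to 1).
#' @param preprocess_cfg a [preprocess_config()] (target size should
#'   match `image_size` for the segmentation flow).
#' @param optimizer_cfg an [optimizer_config()] for the architecture
#'   search.
#' @param fitness_train a [train_config()] used inside each fitness
#'   evaluation.
#' @param final_train a [train_config()] for the final segmentation
#'   model.
#' @param epsilon smoothing constant of the Jaccard fitness.
#' @param cnn_cfg an [adaptive_cnn_config()] for classifier nodes.
#' @param cls_train a [train_config()] for classifier training.
#' @param policy a [growth_policy()].
#' @param log_level `"info"` (one line per stage event) or `"quiet"`.
#' @return a validated `run_config`.
#' @export
run_config <- function(stages = c("generate", "preprocess", "optimize",
                                  "train_seg", "segment", "evaluate"),
                       out_dir = NULL, seed = 1L, n_images = 60L,
                       image_size = 64L, foreground_fraction = 0.2,
                       hair_count = 0L, impulse_noise_prob = 0,
                       speckle_variance = 0, class_ids = c(0L, 1L),
                       n_grow_classes = 0L, n_per_class = 20L,
                       split = c(0.8, 0.1, 0.1),
                       preprocess_cfg = NULL,
                       optimizer_cfg = optimizer_config(population_size = 5L,
                                                        iterations = 3L),
                       fitness_train = train_config(epochs = 5L,
                                                    batch_size = 4L,
                                                    max_images = 12L),
                       final_train = train_config(epochs = 5L,
                                                  batch_size = 4L),
                       epsilon = 1,
                       cnn_cfg = adaptive_cnn_config(),
                       cls_train = train_config(epochs = 8L, batch_size = 4L),
                       policy = growth_policy(),
                       log_level = c("info", "quiet")) {
  all_stages <- c("generate", "preprocess", "optimize", "train_seg",
                  "segment", "train_cls", "grow", "classify", "evaluate")
  lf_check(length(stages) >= 1 && all(stages %in% all_stages), "stages",
           paste("must be a subset of:", paste(all_stages, collapse = ", ")))
  lf_check(!is.unsorted(match(stages, all_stages)), "stages",
           "must respect the canonical stage order")
  needs <- list(segment = "train_seg", grow = "train_cls",
                classify = "train_cls")
  for (st in names(needs)) {
    if (st %in% stages && !needs[[st]] %in% stages) {
      lf_stop(sprintf("stage `%s` requires stage `%s`", st, needs[[st]]),
              class = "lesionforge_config_error")
    }
  }
  if ("evaluate" %in% stages &&
      !any(c("segment", "classify") %in% stages)) {
    lf_stop("stage `evaluate` requires predictions (`segment` or `classify`)",
            class = "lesionforge_config_error")
  }
  lf_check(abs(sum(split) - 1) < 1e-8 && length(split) == 3, "split",
           "must be three proportions summing to 1")
  if (is.null(preprocess_cfg)) {
    preprocess_cfg <- preprocess_config(target_height = image_size,
                                        target_width = image_size)
  }
  structure(
    list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
         n_images = as.integer(n_images), image_size = as.integer(image_size),
         foreground_fraction = foreground_fraction,
         hair_count = as.integer(hair_count),
         impulse_noise_prob = impulse_noise_prob,
         speckle_variance = speckle_variance,
         class_ids = as.integer(class_ids),
         n_grow_classes = as.integer(n_grow_classes),
         n_per_class = as.integer(n_per_class), split = split,
         preprocess_cfg = preprocess_cfg, optimizer_cfg = optimizer_cfg,
         fitness_train = fitness_train, final_train = final_train,
         epsilon = epsilon, cnn_cfg = cnn_cfg, cls_train = cls_train,
         policy = policy, log_level = match.arg(log_level)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; nested blocks
#' (`preprocess`, `optimizer`, `fitness_train`, `final_train`, `cnn`,
#' `cls_train`, `policy`) mirror the corresponding configuration
#' constructors.  `overrides` (name = value) take precedence over the
#' file, so command-line style overrides are possible.
#'
#' @param path YAML file path.
#' @param overrides named list overriding top-level fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  args <- list()
  plain <- c("stages", "out_dir", "seed", "n_images", "image_size",
             "foreground_fraction", "hair_count", "impulse_noise_prob",
             "speckle_variance", "class_ids", "n_grow_classes",
             "n_per_class", "split", "epsilon")
  for (k in plain) if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  blocks <- list(preprocess = "preprocess_cfg", optimizer = "optimizer_cfg",
                 fitness_train = "fitness_train", final_train = "final_train",
                 cnn = "cnn_cfg", cls_train = "cls_train", policy = "policy")
  ctors <- list(preprocess_cfg = preprocess_config,
                optimizer_cfg = optimizer_config,
                fitness_train = train_config, final_train = train_config,
                cnn_cfg = adaptive_cnn_config, cls_train = train_config,
                policy = growth_policy)
  for (k in names(blocks)) {
    if (!is.null(y[[k]])) {
      blk <- y[[k]]
      if (identical(k, "cnn") && !is.null(blk$conv_blocks)) {
        blk$conv_blocks <- lapply(blk$conv_blocks, unlist)
      }
      args[[blocks[[k]]]] <- do.call(ctors[[blocks[[k]]]], blk)
    }
  }
  for (k in names(overrides)) args[[k]] <- overrides[[k]]
  do.call(run_config, args)
}

pipeline_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info")) {
    message(sprintf("[lesionforge] %s", sprintf(fmt, ...)))
  }
}

config_hash <- function(cfg) {
  slim <- cfg
  slim$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage_dir <- function(cfg, stage) {
  if (is.null(cfg$out_dir)) return(NULL)
  d <- file.path(cfg$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_stage_manifest <- function(cfg, stage, extra = list()) {
  d <- stage_dir(cfg, stage)
  if (is.null(d)) return(invisible(NULL))
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     config_hash = config_hash(cfg)), extra)
  jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# deterministic train/val/test split indices
split_indices <- function(n, split, seed) {
  ord <- with_seed(derive_seed(seed, 421L), sample(n))
  n_train <- round(split[1] * n)
  n_val <- round(split[2] * n)
  list(train = ord[seq_len(n_train)],
       val = ord[n_train + seq_len(n_val)],
       test = ord[(n_train + n_val + 1):n])
}

#' Run the lesionforge pipeline
#'
#' Executes the configured stages in order.  The segmentation flow is
#' generate -> preprocess -> optimize (sparrow search over FCEDN
#' architectures) -> train_seg (final model) -> segment -> evaluate;
#' the classification flow adds train_cls / grow / classify over the
#' configured class labels.  Stage artifacts (PNGs, CSV/JSON tables,
#' manifests with the config hash and seed) are written under `out_dir`
#' when one is set.
#'
#' @param cfg a [run_config()].
#' @return a `lesionforge_run` report: per-stage outputs plus metric
#'   tables.
#' @export
run_pipeline <- function(cfg = run_config()) {
  lf_check(inherits(cfg, "run_config"), "cfg", "must be a run_config")
  state <- list(config = cfg, stages_run = character(0))
  for (stage in cfg$stages) {
    pipeline_log(cfg, "stage %s: start", stage)
    t0 <- Sys.time()
    state <- tryCatch(
      switch(stage,
        generate = stage_generate(state, cfg),
        preprocess = stage_preprocess(state, cfg),
        optimize = stage_optimize(state, cfg),
        train_seg = stage_train_seg(state, cfg),
        segment = stage_segment(state, cfg),
        train_cls = stage_train_cls(state, cfg),
        grow = stage_grow(state, cfg),
        classify = stage_classify(state, cfg),
        evaluate = stage_evaluate(state, cfg)
      ),
      error = function(e) {
        lf_stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
                class = "lesionforge_stage_error")
      }
    )
    state$stages_run <- c(state$stages_run, stage)
    pipeline_log(cfg, "stage %s: done (%.1f s)", stage,
                 as.numeric(Sys.time() - t0, units = "secs"))
  }
  structure(state, class = "lesionforge_run")
}

#' @export
print.lesionforge_run <- function(x, ...) {
  cat("lesionforge pipeline run\n")
  cat(" stages:", paste(x$stages_run, collapse = " -> "), "\n")
  if (!is.null(x$best_fitness)) {
    cat(sprintf(" best architecture fitness: %.4f\n", x$best_fitness))
  }
  if (!is.null(x$seg_metrics)) {
    m <- x$seg_metrics[x$seg_metrics$stat == "mean", ]
    cat(sprintf(" segmentation (test means): accuracy %.2f%%, JAC %.3f, DIC %.3f\n",
                m$accuracy, m$jaccard, m$dice))
  }
  if (!is.null(x$cls_metrics)) {
    cat(sprintf(" classification accuracy: %.2f%%\n", x$cls_metrics$accuracy))
  }
  invisible(x)
}

stage_generate <- function(state, cfg) {
  spec <- lesion_spec(
    cfg$image_size, cfg$image_size, cfg$foreground_fraction,
    hair_count = cfg$hair_count, impulse_noise_prob = cfg$impulse_noise_prob,
    speckle_variance = cfg$speckle_variance
  )
  state$images <- generate_dataset(cfg$n_images, spec,
                                   seed = derive_seed(cfg$seed, 1L))
  if (length(cfg$class_ids) >= 2 &&
      any(c("train_cls", "grow", "classify") %in% cfg$stages)) {
    state$class_images <- lapply(cfg$class_ids, function(cid) {
      cspec <- lesion_spec(cfg$image_size, cfg$image_size,
                           cfg$foreground_fraction, class_id = cid)
      generate_dataset(cfg$n_per_class, cspec,
                       seed = derive_seed(cfg$seed, 100L + cid))
    })
    names(state$class_images) <- as.character(cfg$class_ids)
  }
  d <- stage_dir(cfg, "generate")
  if (!is.null(d)) write_dataset(state$images, d)
  write_stage_manifest(cfg, "generate", list(n_images = length(state$images)))
  state
}

stage_preprocess <- function(state, cfg) {
  lf_check(!is.null(state$images), "stages", "preprocess requires generate")
  state$images <- lapply(state$images, preprocess, cfg = cfg$preprocess_cfg)
  d <- stage_dir(cfg, "preprocess")
  if (!is.null(d)) write_dataset(state$images, d)
  write_stage_manifest(cfg, "preprocess")
  state
}

pipeline_split <- function(state, cfg) {
  if (is.null(state$split)) {
    state$split <- split_indices(length(state$images), cfg$split, cfg$seed)
  }
  state
}

stage_optimize <- function(state, cfg) {
  lf_check(!is.null(state$images), "stages", "optimize requires generate")
  state <- pipeline_split(state, cfg)
  ctx <- fitness_context(
    state$images[state$split$train], state$images[state$split$val],
    train_cfg = cfg$fitness_train, epsilon = cfg$epsilon
  )
  layout <- default_layout()
  space <- fcedn_search_space(layout)
  ocfg <- cfg$optimizer_cfg
  ocfg$seed <- derive_seed(cfg$seed, 2L)
  fit <- spasa(function(x) evaluate_fitness(x, ctx, layout), space, ocfg)
  state$search <- fit
  state$best_fitness <- fit$best_fitness
  state$best_genes <- project_feasible(
    repair_genes(fit$best_position, space), layout, cfg$image_size
  )
  d <- stage_dir(cfg, "optimize")
  if (!is.null(d)) {
    trace_df <- data.frame(iteration = seq_along(fit$trace) - 1L,
                           best_fitness = fit$trace)
    write.csv(trace_df, file.path(d, "trace.csv"), row.names = FALSE)
    best_spec <- decode_network(state$best_genes, space, layout,
                                input_height = cfg$image_size,
                                input_width = cfg$image_size)
    jsonlite::write_json(best_spec, file.path(d, "best_network.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  write_stage_manifest(cfg, "optimize",
                       list(best_fitness = fit$best_fitness,
                            evaluations = fit$evaluations))
  state
}

stage_train_seg <- function(state, cfg) {
  lf_check(!is.null(state$images), "stages", "train_seg requires generate")
  state <- pipeline_split(state, cfg)
  spec <- if (!is.null(state$best_genes)) {
    decode_network(state$best_genes, input_height = cfg$image_size,
                   input_width = cfg$image_size)
  } else {
    default_fcedn_spec(cfg$image_size, cfg$image_size)
  }
  model <- build_network(spec, seed = derive_seed(cfg$seed, 3L),
                         eps = cfg$epsilon)
  state$seg_model <- train_network(model, state$images[state$split$train],
                                   cfg$final_train)
  d <- stage_dir(cfg, "train_seg")
  if (!is.null(d)) write_fcedn(state$seg_model, file.path(d, "model.json"))
  write_stage_manifest(cfg, "train_seg",
                       list(final_loss = tail(state$seg_model$history, 1)))
  state
}

stage_segment <- function(state, cfg) {
  lf_check(!is.null(state$seg_model), "stages", "segment requires train_seg")
  state <- pipeline_split(state, cfg)
  test <- state$images[state$split$test]
  state$pred_masks <- lapply(test, function(im) predict_mask(state$seg_model, im))
  d <- stage_dir(cfg, "segment")
  if (!is.null(d)) {
    for (i in seq_along(state$pred_masks)) {
      png::writePNG(state$pred_masks[[i]] * 1.0,
                    file.path(d, sprintf("pred%04d.png", i)))
      png::writePNG(test[[i]]$mask * 1.0,
                    file.path(d, sprintf("pred%04d_truth.png", i)))
    }
  }
  write_stage_manifest(cfg, "segment", list(n_test = length(test)))
  state
}

stage_train_cls <- function(state, cfg) {
  lf_check(!is.null(state$class_images), "stages",
           "train_cls requires generate with >= 2 class_ids")
  n_init <- length(state$class_images) - cfg$n_grow_classes
  lf_check(n_init >= 2, "n_grow_classes",
           "at least two classes must remain for initial training")
  init <- state$class_images[seq_len(n_init)]
  # hold out the last quarter of each class for evaluation
  state$cls_holdout <- lapply(state$class_images, function(imgs) {
    n_test <- max(1L, length(imgs) %/% 4)
    imgs[(length(imgs) - n_test + 1):length(imgs)]
  })
  train_set <- lapply(init, function(imgs) {
    n_test <- max(1L, length(imgs) %/% 4)
    imgs[seq_len(length(imgs) - n_test)]
  })
  cls_train <- cfg$cls_train
  cls_train$seed <- derive_seed(cfg$seed, 4L)
  state$tree <- tree_cnn(train_set, cfg$cnn_cfg, cls_train, cfg$policy)
  write_stage_manifest(cfg, "train_cls",
                       list(classes = tree_classes(state$tree)))
  state
}

stage_grow <- function(state, cfg) {
  lf_check(!is.null(state$tree), "stages", "grow requires train_cls")
  n_init <- length(state$class_images) - cfg$n_grow_classes
  if (cfg$n_grow_classes < 1) return(state)
  grow_set <- state$class_images[(n_init + 1):length(state$class_images)]
  grow_set <- lapply(grow_set, function(imgs) {
    n_test <- max(1L, length(imgs) %/% 4)
    imgs[seq_len(length(imgs) - n_test)]
  })
  for (lab in names(grow_set)) {
    state$tree <- grow_tree(state$tree,
                            stats::setNames(grow_set[lab], lab))
  }
  write_stage_manifest(cfg, "grow", list(classes = tree_classes(state$tree)))
  state
}

stage_classify <- function(state, cfg) {
  lf_check(!is.null(state$tree), "stages", "classify requires train_cls")
  present <- as.character(tree_classes(state$tree))
  holdout <- state$cls_holdout[present]
  truth <- rep(as.integer(present), vapply(holdout, length, 1L))
  preds <- unlist(lapply(holdout, function(imgs) {
    vapply(imgs, function(im) classify(state$tree, im), integer(1))
  }))
  state$cls_predictions <- data.frame(truth = truth, predicted = preds)
  d <- stage_dir(cfg, "classify")
  if (!is.null(d)) {
    write.csv(state$cls_predictions, file.path(d, "predictions.csv"),
              row.names = FALSE)
  }
  write_stage_manifest(cfg, "classify", list(n = length(preds)))
  state
}

stage_evaluate <- function(state, cfg) {
  d <- stage_dir(cfg, "evaluate")
  if (!is.null(state$pred_masks)) {
    state <- pipeline_split(state, cfg)
    truths <- lapply(state$images[state$split$test], function(im) im$mask)
    state$seg_metrics <- metric_table(state$pred_masks, truths)
    # all-background baseline on the same test masks
    zeros <- lapply(truths, function(m) m * 0L)
    state$baseline_metrics <- metric_table(zeros, truths)
    if (!is.null(d)) {
      write.csv(state$seg_metrics, file.path(d, "segmentation.csv"),
                row.names = FALSE)
      write.csv(state$baseline_metrics, file.path(d, "baseline.csv"),
                row.names = FALSE)
    }
  }
  if (!is.null(state$cls_predictions)) {
    p <- state$cls_predictions
    classes <- sort(unique(c(p$truth, p$predicted)))
    per_class <- lapply(classes, function(cl) {
      cc <- confusion((p$predicted == cl) * 1, (p$truth == cl) * 1)
      data.frame(
        class = cl, accuracy = accuracy(cc),
        sensitivity = if (cc$tp + cc$fn > 0) sensitivity(cc) else NA_real_,
        specificity = if (cc$tn + cc$fp > 0) specificity(cc) else NA_real_,
        precision = if (cc$tp + cc$fp > 0) precision(cc) else NA_real_,
        f1 = tryCatch(f1(cc), error = function(e) NA_real_),
        mcc = suppressWarnings(mcc(cc))
      )
    })
    state$cls_metrics <- list(
      accuracy = 100 * mean(p$predicted == p$truth),
      per_class = do.call(rbind, per_class)
    )
    if (!is.null(d)) {
      write.csv(state$cls_metrics$per_class,
                file.path(d, "classification.csv"), row.names = FALSE)
    }
  }
  if (!is.null(d)) {
    summary <- list(
      seg_mean_jaccard = if (!is.null(state$seg_metrics)) {
        state$seg_metrics$jaccard[state$seg_metrics$stat == "mean"]
      },
      baseline_mean_jaccard = if (!is.null(state$baseline_metrics)) {
        state$baseline_metrics$jaccard[state$baseline_metrics$stat == "mean"]
      },
      cls_accuracy = state$cls_metrics$accuracy
    )
    jsonlite::write_json(summary[!vapply(summary, is.null, TRUE)],
                         file.path(d, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_stage_manifest(cfg, "evaluate")
  state
}

#' Evaluate prediction masks stored on disk against ground truth
#'
#' Matches `<stem>.png` predictions to `<stem>.png` truths by file stem;
#' unmatched stems are listed in the result and skipped.
#'
#' @param predictions_dir directory of predicted binary mask PNGs.
#' @param truth_dir directory of ground-truth mask PNGs.
#' @param eps smoothing for Jaccard/Dice (default 0).
#' @return list with `metrics` (a [metric_table()]) and `unmatched`
#'   (stems present on one side only).
#' @export
evaluate_run <- function(predictions_dir, truth_dir, eps = 0) {
  stems <- function(d) {
    f <- list.files(d, pattern = "\\.png$")
    stats::setNames(file.path(d, f), sub("\\.png$", "", f))
  }
  p <- stems(predictions_dir); t <- stems(truth_dir)
  common <- intersect(names(p), names(t))
  unmatched <- c(setdiff(names(p), names(t)), setdiff(names(t), names(p)))
  lf_check(length(common) >= 1, "predictions_dir",
           "no matching file stems between predictions and truth")
  read_mask <- function(path) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    (m >= 0.5) * 1L
  }
  preds <- lapply(p[common], read_mask)
  truths <- lapply(t[common], read_mask)
  list(metrics = metric_table(preds, truths, eps = eps),
       unmatched = unmatched)
}
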