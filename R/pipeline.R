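#' Pipeline configuration
#'
#' One object tying the stage configurations together. A single `seed` fans
#' out deterministically to the split, augmentation, both branch
#' initializations and training.
#'
#' @param preprocess a [preprocess_config()] or `NULL` to skip enhancement
#'   (synthetic inputs are already uniform).
#' @param augment an [augment_config()]; `multiplier = 1` disables
#'   augmentation.
#' @param vnet_spec,unet_spec [model_spec()]s of the two branches.
#' @param train a [train_config()].
#' @param fusion a [fusion_config()].
#' @param test_fraction held-out fraction of the input pairs (default 0.2).
#' @param output_dir directory for checkpoints, masks and the report;
#'   `NULL` keeps everything in memory.
#' @param seed master seed.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(preprocess = NULL,
                            augment = augment_config(multiplier = 1L),
                            vnet_spec = model_spec("vnet2d"),
                            unet_spec = model_spec("unet_resnet2d"),
                            train = train_config(),
                            fusion = fusion_config(),
                            test_fraction = 0.2,
                            output_dir = NULL,
                            seed = 1L) {
  structure(list(preprocess = preprocess, augment = augment,
                 vnet_spec = vnet_spec, unet_spec = unet_spec,
                 train = train, fusion = fusion,
                 test_fraction = test_fraction, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

write_report <- function(report, dir) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(mean = lapply(report$mean, as.list),
                            pooled = lapply(report$pooled, as.list)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("| model | dice | jaccard | t_jaccard | accuracy | sensitivity | specificity |",
          "|---|---|---|---|---|---|---|")
  for (nm in names(report$mean)) {
    v <- report$mean[[nm]]
    md <- c(md, paste0("| ", nm, " | ",
                       paste(sprintf("%.4f", v[c("dice", "jaccard", "t_jaccard",
                                                 "accuracy", "sensitivity",
                                                 "specificity")]),
                             collapse = " | "), " |"))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(NULL)
}

#' Run the full two-branch segmentation pipeline
#'
#' Preprocesses (optionally), splits, augments the training set, trains the
#' V-Net and U-Net+ResNet branches with the configured loss, predicts on
#' the held-out test pairs, cleans each branch's masks of small connected
#' components, fuses the two predictions, and reports the overlap metrics
#' for each branch and the fused result.
#'
#' @param pairs list of `ImageMaskPair` (real or synthetic).
#' @param cfg a [pipeline_config()].
#' @return list with `report` (element `mean`: named metric vectors for
#'   `vnet2d`, `unet_resnet2d`, `fused`; element `pooled` likewise),
#'   `per_image` data.frames, `histories`, `models`, `split` and the fused
#'   `masks`.
#' @export
run_pipeline <- function(pairs, cfg = pipeline_config()) {
  stage <- "preprocess"
  res <- tryCatch({
    if (!is.null(cfg$preprocess)) pairs <- preprocess_dataset(pairs, cfg$preprocess)

    stage <- "split"
    split <- split_dataset(pairs, cfg$test_fraction, derive_seed(cfg$seed, 1L))

    stage <- "augment"
    aug_cfg <- cfg$augment; aug_cfg$seed <- derive_seed(cfg$seed, 2L)
    train_pairs <- augment_dataset(split$train, aug_cfg)

    stage <- "train_vnet2d"
    vspec <- cfg$vnet_spec; vspec$seed <- derive_seed(cfg$seed, 3L)
    tcfg <- cfg$train; tcfg$seed <- derive_seed(cfg$seed, 4L)
    vres <- train(build_vnet2d(vspec), train_pairs, tcfg)

    stage <- "train_unet_resnet2d"
    uspec <- cfg$unet_spec; uspec$seed <- derive_seed(cfg$seed, 5L)
    tcfg$seed <- derive_seed(cfg$seed, 6L)
    ures <- train(build_unet_resnet2d(uspec), train_pairs, tcfg)

    stage <- "predict"
    thr <- cfg$train$threshold
    va <- predict_masks(vres$model, split$test, thr)
    ua <- predict_masks(ures$model, split$test, thr)

    stage <- "fuse"
    vclean <- lapply(va, remove_small_components,
                     min_size = cfg$fusion$min_component_size,
                     connectivity = cfg$fusion$connectivity)
    uclean <- lapply(ua, remove_small_components,
                     min_size = cfg$fusion$min_component_size,
                     connectivity = cfg$fusion$connectivity)
    fused <- mapply(fuse_predictions, vclean, uclean,
                    MoreArgs = list(cfg = cfg$fusion), SIMPLIFY = FALSE)

    stage <- "evaluate"
    truths <- lapply(split$test, `[[`, "mask")
    ev_v <- evaluate_predictions(vclean, truths)
    ev_u <- evaluate_predictions(uclean, truths)
    ev_f <- evaluate_predictions(fused, truths)
    report <- list(
      mean = list(vnet2d = ev_v$mean, unet_resnet2d = ev_u$mean,
                  fused = ev_f$mean),
      pooled = list(vnet2d = ev_v$pooled, unet_resnet2d = ev_u$pooled,
                    fused = ev_f$pooled))

    if (!is.null(cfg$output_dir)) {
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      save_model(vres$model, file.path(cfg$output_dir, "vnet2d.rds"))
      save_model(ures$model, file.path(cfg$output_dir, "unet_resnet2d.rds"))
      write.csv(vres$history, file.path(cfg$output_dir, "history_vnet2d.csv"),
                row.names = FALSE)
      write.csv(ures$history, file.path(cfg$output_dir, "history_unet_resnet2d.csv"),
                row.names = FALSE)
      mask_dir <- file.path(cfg$output_dir, "masks")
      dir.create(mask_dir, showWarnings = FALSE)
      for (i in seq_along(fused)) {
        id <- split$test[[i]]$id
        save_mask(vclean[[i]], file.path(mask_dir, paste0(id, "_vnet2d.png")))
        save_mask(uclean[[i]], file.path(mask_dir, paste0(id, "_unet_resnet2d.png")))
        save_mask(fused[[i]], file.path(mask_dir, paste0(id, "_fused.png")))
      }
      write_report(report, cfg$output_dir)
    }

    list(report = report,
         per_image = list(vnet2d = ev_v$per_image, unet_resnet2d = ev_u$per_image,
                          fused = ev_f$per_image),
         histories = list(vnet2d = vres$history, unet_resnet2d = ures$history),
         models = list(vnet2d = vres$model, unet_resnet2d = ures$model),
         split = split,
         masks = list(vnet2d = vclean, unet_resnet2d = uclean, fused = fused))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
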