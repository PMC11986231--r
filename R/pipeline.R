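# Orchestration: configuration, cohort simulation to disk, cross-validated
# training, evaluation reports, and checkpointing. Every artifact records the
# seed and resolved-config hash that produced it, so any run is replayable
# from its manifest alone.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with the reference defaults
#' (augmentation ranges +/- 15 degrees and 0.8-1.2 scaling, imaging batch 16,
#' genomic batch 32, Adam lr 0.001 with weight decay 1e-5, 100 epochs,
#' early-stopping patience 10, validation split 0.2, k = 5 folds). Any subset
#' can be overridden by a YAML file with the same block structure
#' (`data`, `segmenter`, `gfam`, `fusion`, `loss`, `train`).
#'
#' @param path optional YAML file whose values override the defaults.
#' @return nested configuration list of class `hepafuse_config`.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(
    data = list(
      height = 64L, width = 64L, n_samples = 40L, n_markers = 200L,
      latent_rank = 8L, n_subtypes = 4L, cluster_separation = 6,
      marker_noise_sigma = 1, joint_rule = "joint_xor",
      radius_range = c(6, 14), boundary_irregularity = 0.15,
      tumor_contrast = 0.35, noise_sigma = 0.05
    ),
    segmenter = list(
      n_levels = 3L, base_channels = 16L, reduction_ratio = 4L,
      attention_alpha = 0.6, attention_beta = 0.4,
      attention_trainable = FALSE, hdfo_weights = NULL, epochs = 30L
    ),
    gfam = list(latent_dim = 16L, hidden = NULL, dropout = 0.3, epochs = 100L),
    fusion = list(d_f = 64L, epochs = 200L),
    loss = list(lambda_dice = 0.5, lambda_ce = 0.3, lambda_ssim = 0.2),
    train = list(
      epochs = 100L, imaging_batch = 16L, genomic_batch = 32L,
      lr = 1e-3, weight_decay = 1e-5, patience = 10L, val_split = 0.2,
      folds = 5L, early_stopping = TRUE, augment = FALSE,
      rotation_range = c(-15, 15), scale_range = c(0.8, 1.2)
    )
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  structure(cfg, class = c("hepafuse_config", "list"))
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

cohort_from_config <- function(cfg, seed) {
  ph <- phantom_spec(
    height = cfg$data$height, width = cfg$data$width, n_tumors = 1,
    radius_range = cfg$data$radius_range,
    boundary_irregularity = cfg$data$boundary_irregularity,
    tumor_contrast = cfg$data$tumor_contrast,
    noise_sigma = cfg$data$noise_sigma, seed = seed
  )
  co <- cohort_spec(
    n_samples = cfg$data$n_samples, n_markers = cfg$data$n_markers,
    latent_rank = cfg$data$latent_rank, n_subtypes = cfg$data$n_subtypes,
    cluster_separation = cfg$data$cluster_separation,
    marker_noise_sigma = cfg$data$marker_noise_sigma, seed = seed
  )
  generate_paired_cohort(ph, co, joint_rule = cfg$data$joint_rule)
}

#' Simulate a paired cohort to disk
#'
#' Writes one image and mask PNG per sample, the cohort-level genomic CSV
#' (`sample_id`, `subtype_label`, marker columns) and a JSON manifest
#' recording the resolved configuration, seed and config hash.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param force overwrite a non-empty directory (default FALSE: refuse).
#' @return (invisibly) the manifest list.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir, seed = 1L,
                         force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop_invalid("output directory %s is not empty (use force = TRUE)", out_dir)
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  cohort <- cohort_from_config(config, seed)
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    png::writePNG(s$image, file.path(out_dir, "images",
                                     sprintf("sample_%04d_image.png", i)))
    png::writePNG(s$mask, file.path(out_dir, "masks",
                                    sprintf("sample_%04d_mask.png", i)))
  }
  utils::write.csv(cohort$genomic, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = seed, config = unclass(config), config_hash = config_hash(config),
    n_samples = length(cohort$samples),
    joint_rule = cohort$joint_rule, n_classes = cohort$n_classes,
    labels = cohort$labels, morph_strata = cohort$morph_strata,
    genomic_clusters = cohort$genomic_clusters
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a simulated cohort back from disk
#'
#' @param dir a directory written by [run_simulate()].
#' @return a `paired_cohort` (images/masks from the PNGs, genomic rows from
#'   the CSV, labels and strata from the manifest).
#' @export
read_cohort_dir <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_invalid("no manifest.json in %s", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  genomic <- tibble::as_tibble(utils::read.csv(file.path(dir, "cohort.csv"),
                                               check.names = FALSE))
  gen <- as.matrix(genomic[, !(names(genomic) %in%
                                 c("sample_id", "subtype_label")), drop = FALSE])
  n <- mf$n_samples
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    img <- read_slice(file.path(dir, "images", sprintf("sample_%04d_image.png", i)))
    msk <- (read_slice(file.path(dir, "masks", sprintf("sample_%04d_mask.png", i))) >= 0.5) * 1
    samples[[i]] <- list(image = img, mask = msk, genomic_row = gen[i, ],
                         subtype_label = mf$labels[i],
                         morph_stratum = mf$morph_strata[i],
                         genomic_cluster = mf$genomic_clusters[i])
  }
  structure(list(
    samples = samples, genomic = genomic, genomic_matrix = gen,
    labels = mf$labels, morph_strata = mf$morph_strata,
    genomic_clusters = mf$genomic_clusters, n_classes = mf$n_classes,
    joint_rule = mf$joint_rule, manifest = mf
  ), class = "paired_cohort")
}

#' Deterministic stratified cross-validation folds
#'
#' Partition of `seq_along(labels)` into `k` folds, stratified by label so
#' small cohorts never produce label-empty folds; a pure function of
#' (labels, k, seed).
#'
#' @param labels label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), one per sample.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  if (k < 2) stop_invalid("need at least 2 folds")
  n <- length(labels)
  if (k > n) stop_invalid("more folds than samples")
  fold <- integer(n)
  withr::with_seed(seed, {
    for (lv in sort(unique(labels))) {
      ix <- sample(which(labels == lv))
      fold[ix] <- rep(seq_len(k), length.out = length(ix))
    }
  })
  fold
}

# fit all three stages on one training subset; returns models + features
fit_stages <- function(cohort, config, train_idx, seed, log_path = NULL,
                       validation_idx = NULL) {
  arrs <- cohort_image_array(cohort, train_idx)
  seg_cfg <- segmenter_config(
    n_levels = config$segmenter$n_levels,
    base_channels = config$segmenter$base_channels,
    reduction_ratio = config$segmenter$reduction_ratio,
    attention_alpha = config$segmenter$attention_alpha,
    attention_beta = config$segmenter$attention_beta,
    attention_trainable = config$segmenter$attention_trainable,
    hdfo_weights = config$segmenter$hdfo_weights
  )
  weights <- loss_weights(config$loss$lambda_dice, config$loss$lambda_ce,
                          config$loss$lambda_ssim)
  segmenter <- build_segmenter(seg_cfg, seed = seed)
  validation <- NULL
  if (config$train$early_stopping && !is.null(validation_idx) &&
      length(validation_idx) > 0) {
    va <- cohort_image_array(cohort, validation_idx)
    validation <- list(images = va$images, masks = va$masks)
  }
  augment <- if (isTRUE(config$train$augment)) {
    augmentation_spec(rotation_range = config$train$rotation_range,
                      scale_range = config$train$scale_range, seed = seed)
  } else {
    NULL
  }
  segmenter <- train_segmenter(
    segmenter, arrs$images, arrs$masks,
    epochs = config$segmenter$epochs,
    batch_size = config$train$imaging_batch,
    lr = config$train$lr, weight_decay = config$train$weight_decay,
    weights = weights, augment = augment, validation = validation,
    patience = if (config$train$early_stopping) config$train$patience else Inf,
    seed = seed, log_path = log_path
  )
  autoencoder <- build_autoencoder(
    m = ncol(cohort$genomic_matrix), k = config$gfam$latent_dim,
    hidden = config$gfam$hidden, dropout = config$gfam$dropout, seed = seed
  )
  autoencoder <- train_autoencoder(
    autoencoder, cohort$genomic_matrix[train_idx, , drop = FALSE],
    epochs = config$gfam$epochs, batch_size = config$train$genomic_batch,
    lr = config$train$lr, weight_decay = config$train$weight_decay, seed = seed
  )
  joint <- train_joint(cohort, segmenter, autoencoder, train_idx = train_idx,
                       d_f = config$fusion$d_f, epochs = config$fusion$epochs,
                       lr = config$train$lr,
                       weight_decay = config$train$weight_decay,
                       batch_size = config$train$genomic_batch, seed = seed)
  list(segmenter = segmenter, autoencoder = autoencoder, fusion = joint$model,
       img = joint$img, gen = joint$gen, weights = weights)
}

#' Cross-validated training of the full pipeline
#'
#' Stratified k-fold loop: per fold, the segmenter is trained with the hybrid
#' loss (with optional early stopping on the held-out fold's hybrid loss),
#' the genomic autoencoder on the training rows, and the fusion classifier on
#' the pooled imaging features + latent codes. Each fold's checkpoint (all
#' three models plus seed and config hash) is saved, and the fold is
#' evaluated on its held-out samples. A fold whose training aborts (e.g.
#' non-finite loss) is recorded as failed and the remaining folds continue.
#'
#' @param cohort a `paired_cohort` (or a directory written by
#'   [run_simulate()]).
#' @param config a [pipeline_config()].
#' @param out_dir directory for checkpoints, logs and reports.
#' @param seed integer seed; fold f uses `seed + f`.
#' @return object of class `hepafuse_cv`: per-fold reports, the aggregate
#'   report (mean over folds), fold assignment, and checkpoint paths.
#' @export
run_train <- function(cohort, config = pipeline_config(), out_dir, seed = 1L) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k <- config$train$folds
  fold <- make_folds(cohort$labels, k, seed)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    val_idx <- which(fold == f)
    train_idx <- which(fold != f)
    fseed <- seed + f
    log_path <- file.path(out_dir, sprintf("fold%02d_steps.jsonl", f))
    res <- tryCatch({
      fit <- fit_stages(cohort, config, train_idx, fseed, log_path = log_path,
                        validation_idx = val_idx)
      report <- evaluate_fit(fit, cohort, val_idx)
      ckpt <- file.path(out_dir, sprintf("fold%02d_checkpoint.rds", f))
      saveRDS(list(segmenter = fit$segmenter, autoencoder = fit$autoencoder,
                   fusion = fit$fusion, seed = fseed,
                   config = unclass(config), config_hash = config_hash(config)),
              ckpt)
      list(ok = TRUE, report = report, checkpoint = ckpt,
           val_hybrid_loss = evaluate_hybrid_loss(
             fit$segmenter, cohort_image_array(cohort, val_idx)$images,
             cohort_image_array(cohort, val_idx)$masks, fit$weights))
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    folds[[f]] <- res
  }
  ok <- vapply(folds, function(x) isTRUE(x$ok), logical(1))
  agg <- NULL
  if (any(ok)) {
    per_fold <- dplyr::bind_rows(lapply(which(ok), function(f) {
      dplyr::mutate(folds[[f]]$report$aggregate, fold = f)
    }))
    agg <- dplyr::summarise(per_fold, dplyr::across(
      dplyr::where(is.numeric) & !dplyr::matches("^fold$"),
      ~ mean(.x, na.rm = TRUE)))
  }
  out <- structure(list(folds = folds, fold_assignment = fold,
                        aggregate = agg, config_hash = config_hash(config),
                        seed = seed),
                   class = "hepafuse_cv")
  saveRDS(out, file.path(out_dir, "cv_result.rds"))
  out
}

# evaluate one fitted stage set on cohort indices
evaluate_fit <- function(fit, cohort, idx) {
  arrs <- cohort_image_array(cohort, idx)
  fw <- forward_segment(fit$segmenter, arrs$images)
  pred_masks <- (fw$prob >= 0.5) * 1
  per_sample <- dplyr::bind_rows(lapply(seq_along(idx), function(j) {
    tibble::tibble(
      sample_id = sprintf("S%04d", idx[j]),
      dice = dice_coefficient(pred_masks[, , j], arrs$masks[, , j]),
      ssim = ssim_global(fw$prob[, , j], arrs$masks[, , j]),
      pcp = proportion_correct_patches(pred_masks[, , j], arrs$masks[, , j])
    )
  }))
  pred <- predict_subtypes(fit$fusion, fit$img[idx, , drop = FALSE],
                           fit$gen[idx, , drop = FALSE])
  truth <- cohort$labels[idx]
  cls <- confusion_metrics(pred$predicted_subtype, truth,
                           levels = 0:(cohort$n_classes - 1L))
  overall <- cls[cls$class == "overall", ]
  aggregate <- tibble::tibble(
    dice = mean(per_sample$dice), ssim = mean(per_sample$ssim),
    pcp = mean(per_sample$pcp), accuracy = overall$accuracy,
    precision = overall$precision, recall = overall$recall,
    specificity = overall$specificity, f1 = overall$f1
  )
  list(per_sample = per_sample, classification = cls,
       predictions = dplyr::mutate(pred, truth = truth),
       aggregate = aggregate)
}

#' Evaluate a checkpoint on a cohort
#'
#' Recomputes the full metric suite (Dice, SSIM, PCP per sample; accuracy,
#' precision, recall, specificity, F1 for the subtype predictions) and
#' optionally writes the report as CSV + JSON.
#'
#' @param checkpoint a checkpoint path from [run_train()] or the checkpoint
#'   list itself.
#' @param cohort a `paired_cohort` or simulated-cohort directory.
#' @param idx sample indices to evaluate (default: all).
#' @param out_dir optional directory for `report_per_sample.csv`,
#'   `report_classification.csv` and `report.json`.
#' @return a `hepafuse_report`: list with `per_sample`, `classification`,
#'   `predictions`, `aggregate`, `config_hash`, `seed`.
#' @export
run_evaluate <- function(checkpoint, cohort, idx = NULL, out_dir = NULL) {
  if (is.character(checkpoint)) checkpoint <- readRDS(checkpoint)
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  stopifnot(inherits(cohort, "paired_cohort"))
  if (ncol(cohort$genomic_matrix) != checkpoint$autoencoder$m) {
    stop_invalid("checkpoint/cohort mismatch: marker count %d vs %d",
                 checkpoint$autoencoder$m, ncol(cohort$genomic_matrix))
  }
  idx <- idx %||% seq_along(cohort$samples)
  arrs <- cohort_image_array(cohort)
  img <- pool_image_features(forward_segment(checkpoint$segmenter, arrs$images))
  gen <- encode(checkpoint$autoencoder, cohort$genomic_matrix)
  fit <- list(segmenter = checkpoint$segmenter,
              autoencoder = checkpoint$autoencoder,
              fusion = checkpoint$fusion, img = img, gen = gen)
  rep <- evaluate_fit(fit, cohort, idx)
  rep$config_hash <- checkpoint$config_hash
  rep$seed <- checkpoint$seed
  class(rep) <- "hepafuse_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rep$per_sample,
                     file.path(out_dir, "report_per_sample.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$classification,
                     file.path(out_dir, "report_classification.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(aggregate = as.list(rep$aggregate), config_hash = rep$config_hash,
           seed = rep$seed),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.hepafuse_report <- function(x, ...) {
  cat("evaluation report (config", substr(x$config_hash %||% "", 1, 8), ")\n")
  print(x$aggregate)
  invisible(x)
}

#' @export
print.hepafuse_cv <- function(x, ...) {
  ok <- vapply(x$folds, function(f) isTRUE(f$ok), logical(1))
  cat(sprintf("cross-validated run: %d/%d folds succeeded\n",
              sum(ok), length(ok)))
  if (!is.null(x$aggregate)) print(x$aggregate)
  invisible(x)
}
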