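# Multimodal fusion: project pooled imaging features and latent genomic codes
# into a shared space, blend them with a trainable convex weight, refine the
# blend with a learned sigmoid feature gate, and classify subtypes with a
# softmax layer.

#' Pool per-sample imaging features
#'
#' Global average pooling of the attention-refined bottleneck feature map:
#' one feature vector per sample, dimension equal to the bottleneck channel
#' count.
#'
#' @param x the result of [forward_segment()] (uses its
#'   `bottleneck_features`), or a raw (H, W, C, N) feature array to pool.
#' @return n x d_img feature matrix.
#' @export
pool_image_features <- function(x) {
  if (is.list(x)) {
    if (is.null(x$bottleneck_features)) {
      stop_invalid("no bottleneck features present; run forward_segment() first")
    }
    return(x$bottleneck_features)
  }
  if (length(dim(x)) != 4L) stop_invalid("expected an (H, W, C, N) array")
  gap_numeric(x)
}

#' Project both modalities into a shared feature space
#'
#' Affine maps `F_img = A W_img + b_img` and `F_gen = G W_gen + b_gen`
#' landing in the same `d_f`-dimensional space; the source dimensions need
#' not agree.
#'
#' @param img n x d_img pooled imaging features.
#' @param gen n x d_gen latent genomic features.
#' @param params list with `Wimg` (d_img x d_f), `bimg`, `Wgen`
#'   (d_gen x d_f), `bgen`.
#' @return list with matrices `Fimg` and `Fgen`, both n x d_f.
#' @export
project_features <- function(img, gen, params) {
  img <- as.matrix(img); gen <- as.matrix(gen)
  if (nrow(img) != nrow(gen)) stop_invalid("modalities disagree on sample count")
  if (ncol(img) != nrow(params$Wimg) || ncol(gen) != nrow(params$Wgen)) {
    stop_invalid("projection dimensions do not match the feature matrices")
  }
  if (ncol(params$Wimg) != ncol(params$Wgen)) {
    stop_invalid("both projections must land in the same shared dimension")
  }
  list(Fimg = sweep(img %*% params$Wimg, 2L, params$bimg, "+"),
       Fgen = sweep(gen %*% params$Wgen, 2L, params$bgen, "+"))
}

#' Adaptive convex fusion of the projected modalities
#'
#' `F_fusion = alpha * F_img + (1 - alpha) * F_gen`. Values outside \[0, 1\]
#' are clamped with a warning (in the trainable model the weight is
#' sigmoid-parameterized, so it cannot leave the interval).
#'
#' @param proj list with `Fimg` and `Fgen` (from [project_features()]).
#' @param alpha fusion weight in \[0, 1\].
#' @return n x d_f fused feature matrix.
#' @export
fuse_features <- function(proj, alpha) {
  if (alpha < 0 || alpha > 1) {
    warning("fusion alpha clamped to [0, 1]", call. = FALSE)
    alpha <- min(max(alpha, 0), 1)
  }
  check_same_shape(proj$Fimg, proj$Fgen, "projected features")
  alpha * proj$Fimg + (1 - alpha) * proj$Fgen
}

#' Gated attention over fused features
#'
#' A learned sigmoid feature gate — the smallest mechanism that amplifies
#' informative components and suppresses noisy ones:
#' `F_attn = F_fusion * sigmoid(F_fusion W_a + b_a)` (element-wise product).
#'
#' @param f n x d_f fused features.
#' @param params list with `Wa` (d_f x d_f) and `ba` (length d_f).
#' @return n x d_f gated features; never larger in magnitude than the input.
#' @export
attend_fused <- function(f, params) {
  f <- as.matrix(f)
  check_finite(f, "fused features")
  gate <- stats::plogis(sweep(f %*% params$Wa, 2L, params$ba, "+"))
  f * gate
}

#' Softmax subtype classification
#'
#' `P = softmax(F_attn W_fc + b_fc)` row-wise; each row is a probability
#' distribution over the S subtypes.
#'
#' @param f n x d_f feature matrix.
#' @param Wfc d_f x S weights; `bfc` length-S bias.
#' @param bfc classifier bias.
#' @return n x S row-stochastic matrix.
#' @export
classify_subtypes <- function(f, Wfc, bfc) {
  f <- as.matrix(f)
  if (ncol(Wfc) < 2) stop_invalid("need at least 2 subtypes")
  z <- sweep(f %*% Wfc, 2L, bfc, "+")
  if (!all(is.finite(z))) stop("non-finite classifier logits")
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Build a fusion classifier
#'
#' @param d_img,d_gen source dimensions of the imaging and genomic features.
#' @param n_classes number of subtypes S (>= 2).
#' @param d_f shared feature dimension (default 64 at desk scale; 256
#'   reproduces the full-scale fusion width).
#' @param modality `"both"` (trainable fusion weight), `"image"` (weight
#'   frozen at 1) or `"genomic"` (frozen at 0) — the single-modality settings
#'   are the ablation baselines.
#' @param fusion_alpha_init initial fusion weight (default 0.5).
#' @param seed weight initialization seed.
#' @return an object of class `hepafuse_fusion`.
#' @export
build_fusion_model <- function(d_img, d_gen, n_classes, d_f = 64L,
                               modality = c("both", "image", "genomic"),
                               fusion_alpha_init = 0.5, seed = 1L) {
  modality <- match.arg(modality)
  if (n_classes < 2) stop_invalid("need at least 2 subtypes")
  if (fusion_alpha_init <= 0 || fusion_alpha_init >= 1) {
    stop_invalid("fusion_alpha_init must be inside (0, 1)")
  }
  withr::with_seed(seed, {
    md <- structure(list(
      d_img = as.integer(d_img), d_gen = as.integer(d_gen),
      d_f = as.integer(d_f), n_classes = as.integer(n_classes),
      modality = modality,
      proj_img = new_dense_layer(d_img, d_f),
      proj_gen = new_dense_layer(d_gen, d_f),
      gate = new_dense_layer(d_f, d_f, init_sd = sqrt(1 / d_f)),
      fc = new_dense_layer(d_f, n_classes, init_sd = sqrt(1 / d_f)),
      alpha_raw = if (modality == "both") {
        ag_param(stats::qlogis(fusion_alpha_init))
      } else {
        ag_const(if (modality == "image") Inf else -Inf)
      },
      seed = as.integer(seed), history = NULL
    ), class = "hepafuse_fusion")
    md$params <- collect_params(md[c("proj_img", "proj_gen", "gate", "fc",
                                     "alpha_raw")])
    md
  })
}

#' Current fusion weight of a model
#' @param model a `hepafuse_fusion`.
#' @export
fusion_alpha <- function(model) stats::plogis(ag_value(model$alpha_raw))

fusion_graph <- function(model, img, gen) {
  fi <- dense_forward(model$proj_img, ag_const(img))
  fg <- dense_forward(model$proj_gen, ag_const(gen))
  alpha <- ag_sigmoid(model$alpha_raw)
  ffus <- ag_add(ag_mul(alpha, fi),
                 ag_mul(ag_sub(ag_const(1), alpha), fg))
  gate <- ag_sigmoid(dense_forward(model$gate, ffus))
  fattn <- ag_mul(ffus, gate)
  list(logits = dense_forward(model$fc, fattn), alpha = alpha)
}

check_fusion_inputs <- function(model, img, gen) {
  img <- as.matrix(img); gen <- as.matrix(gen)
  if (nrow(img) != nrow(gen)) stop_invalid("modalities disagree on sample count")
  if (ncol(img) != model$d_img) stop_invalid("expected %d imaging features",
                                             model$d_img)
  if (ncol(gen) != model$d_gen) stop_invalid("expected %d genomic features",
                                             model$d_gen)
  list(img = img, gen = gen)
}

#' Train the fusion classifier
#'
#' Minimizes the softmax cross-entropy of the subtype labels with Adam. The
#' fusion weight's trajectory is recorded per epoch.
#'
#' @param model a [build_fusion_model()].
#' @param img n x d_img pooled imaging features.
#' @param gen n x d_gen latent genomic features.
#' @param labels 0-based integer subtype labels.
#' @param epochs,batch_size,lr,weight_decay Adam training settings.
#' @param seed RNG seed for shuffling.
#' @return the trained model with `$history` (tibble: epoch, ce, alpha).
#' @export
train_fusion <- function(model, img, gen, labels, epochs = 200,
                         batch_size = 32L, lr = 1e-3, weight_decay = 1e-5,
                         seed = 1L) {
  stopifnot(inherits(model, "hepafuse_fusion"))
  io <- check_fusion_inputs(model, img, gen)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= model$n_classes)) {
    stop_invalid("labels must lie in [0, %d)", model$n_classes)
  }
  n <- nrow(io$img)
  opt <- new_adam(model$params, lr = lr, weight_decay = weight_decay)
  hist <- list()
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fw <- fusion_graph(model, io$img[idx, , drop = FALSE],
                           io$gen[idx, , drop = FALSE])
        loss <- ag_softmax_ce(fw$logits, labels[idx])
        ag_backward(loss)
        adam_step(opt)
        tot <- tot + loss$value
        nb <- nb + 1L
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, ce = tot / nb,
                                   alpha = fusion_alpha(model))
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Predict subtype probabilities
#'
#' @inheritParams train_fusion
#' @return a tibble with `sample` index, one `prob_<s>` column per subtype,
#'   and `predicted_subtype` (0-based argmax).
#' @export
predict_subtypes <- function(model, img, gen) {
  io <- check_fusion_inputs(model, img, gen)
  fw <- fusion_graph(model, io$img, io$gen)
  z <- fw$logits$value
  z <- z - apply(z, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- sprintf("prob_%d", seq_len(model$n_classes) - 1L)
  out <- tibble::as_tibble(p)
  out$sample <- seq_len(nrow(p))
  out$predicted_subtype <- max.col(p) - 1L
  out[, c("sample", colnames(p), "predicted_subtype")]
}

#' Train segmenter-, autoencoder- and fusion stages on a paired cohort
#'
#' Two-stage protocol: the segmenter and the genomic autoencoder are
#' pretrained (or passed in already trained), per-sample imaging features are
#' pooled from the attention-refined bottleneck, genomic rows are encoded to
#' the latent space, and the fusion classifier is trained on the requested
#' sample subset.
#'
#' @param cohort a [generate_paired_cohort()] result.
#' @param segmenter a trained [build_segmenter()] model.
#' @param autoencoder a trained [build_autoencoder()] model.
#' @param train_idx sample indices to train the classifier on (default all).
#' @param modality passed to [build_fusion_model()].
#' @param d_f shared feature dimension.
#' @param epochs,lr,weight_decay,batch_size fusion training settings.
#' @param seed RNG seed.
#' @return list with the fitted `model`, the full-cohort `img` and `gen`
#'   feature matrices, and `train_idx`.
#' @export
train_joint <- function(cohort, segmenter, autoencoder, train_idx = NULL,
                        modality = "both", d_f = 64L, epochs = 200,
                        lr = 1e-3, weight_decay = 1e-5, batch_size = 32L,
                        seed = 1L) {
  stopifnot(inherits(cohort, "paired_cohort"))
  train_idx <- train_idx %||% seq_along(cohort$samples)
  arrs <- cohort_image_array(cohort)
  img <- pool_image_features(forward_segment(segmenter, arrs$images))
  gen <- encode(autoencoder, cohort$genomic_matrix)
  model <- build_fusion_model(ncol(img), ncol(gen), cohort$n_classes,
                              d_f = d_f, modality = modality, seed = seed)
  model <- train_fusion(model, img[train_idx, , drop = FALSE],
                        gen[train_idx, , drop = FALSE],
                        cohort$labels[train_idx], epochs = epochs,
                        batch_size = batch_size, lr = lr,
                        weight_decay = weight_decay, seed = seed)
  list(model = model, img = img, gen = gen, train_idx = train_idx)
}

#' @method tidy hepafuse_fusion
#' @export
tidy.hepafuse_fusion <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), ce = numeric(),
                                alpha = numeric())
}

#' @method glance hepafuse_fusion
#' @export
glance.hepafuse_fusion <- function(x, ...) {
  tibble::tibble(
    d_img = x$d_img, d_gen = x$d_gen, d_f = x$d_f, n_classes = x$n_classes,
    modality = x$modality, fusion_alpha = fusion_alpha(x),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_ce = if (is.null(x$history)) NA_real_ else
      x$history$ce[nrow(x$history)]
  )
}

#' @export
print.hepafuse_fusion <- function(x, ...) {
  cat(sprintf(
    "fusion classifier: %d + %d -> %d -> %d classes (%s, alpha = %.3f)\n",
    x$d_img, x$d_gen, x$d_f, x$n_classes, x$modality, fusion_alpha(x)))
  invisible(x)
}
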