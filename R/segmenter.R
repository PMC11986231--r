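# The attention-guided convolutional segmenter (AG-CNN): an encoder-decoder
# backbone with a spatial attention module (SAM) and channel attention module
# (CAM) at the bottleneck and each decoder level, a sigmoid segmentation head,
# and optional SSIM-based depth supervision of per-depth projections (HDFO).

#' Segmenter configuration
#'
#' @param n_levels number of resolution levels of the U-shaped backbone
#'   (default 3: two encoder levels plus bottleneck).
#' @param base_channels channels at the finest level; doubled per level
#'   (default 16).
#' @param reduction_ratio bottleneck reduction of the channel attention MLP;
#'   `C / reduction_ratio` must be >= 1 at every attention site (default 4).
#' @param attention_alpha,attention_beta non-negative mixing weights of the
#'   spatial and channel attention maps in the combined attention
#'   (defaults 0.6 / 0.4). Distinct from the fusion module's `fusion_alpha`.
#' @param attention_trainable make the mixing weights trainable instead of
#'   fixed (default `FALSE`).
#' @param hdfo_weights per-depth weights of the SSIM depth-supervision
#'   penalty, ordered coarse to fine; `NULL` (default) disables the auxiliary
#'   term, reducing training exactly to the hybrid loss.
#' @return an object of class `segmenter_config`.
#' @export
segmenter_config <- function(n_levels = 3, base_channels = 16,
                             reduction_ratio = 4,
                             attention_alpha = 0.6, attention_beta = 0.4,
                             attention_trainable = FALSE,
                             hdfo_weights = NULL) {
  if (n_levels < 2) stop_invalid("need at least 2 levels")
  if (attention_alpha < 0 || attention_beta < 0) {
    stop_invalid("attention mixing weights must be non-negative")
  }
  if (base_channels < reduction_ratio) {
    stop_invalid("base_channels must be >= reduction_ratio")
  }
  if (!is.null(hdfo_weights)) {
    if (length(hdfo_weights) != n_levels || any(hdfo_weights < 0)) {
      stop_invalid("hdfo_weights must be %d non-negative values", n_levels)
    }
  }
  structure(list(
    n_levels = as.integer(n_levels), base_channels = as.integer(base_channels),
    reduction_ratio = as.integer(reduction_ratio),
    attention_alpha = attention_alpha, attention_beta = attention_beta,
    attention_trainable = attention_trainable,
    hdfo_weights = hdfo_weights
  ), class = "segmenter_config")
}

new_attention_block <- function(C, config) {
  hidden <- max(1L, C %/% config$reduction_ratio)
  W1 <- new_dense_layer(C, hidden)
  # small positive bias keeps the narrow ReLU bottleneck active at init
  W1$b$value[] <- 0.1
  list(
    C = C,
    f1 = new_conv_layer(1L, 1L, C, 1L),
    f2 = new_conv_layer(1L, 1L, C, 1L),
    W1 = W1,
    W2 = new_dense_layer(hidden, C)
  )
}

#' Build an attention-guided segmenter
#'
#' Constructs the U-shaped backbone: per encoder level one 3x3 convolution +
#' batch normalization + ReLU followed by 2x2 max-pooling; a bottleneck
#' convolution; per decoder level nearest-neighbour upsampling, skip
#' concatenation and a 3x3 convolution block. A SAM+CAM attention block
#' refines the bottleneck and every decoder level; a terminal 1x1 convolution
#' with sigmoid produces the soft mask, and per-depth 1x1 projection heads
#' expose the feature pyramid for SSIM depth supervision.
#'
#' @param config a [segmenter_config()].
#' @param in_channels input image channels (default 1, grayscale).
#' @param seed seed for weight initialization.
#' @return an object of class `hepafuse_segmenter`.
#' @export
build_segmenter <- function(config = segmenter_config(), in_channels = 1L,
                            seed = 1L) {
  stopifnot(inherits(config, "segmenter_config"))
  withr::with_seed(seed, {
    L <- config$n_levels
    ch <- config$base_channels * 2L^(seq_len(L) - 1L)
    enc <- vector("list", L)
    cin <- in_channels
    for (l in seq_len(L)) {
      enc[[l]] <- list(conv = new_conv_layer(3L, 3L, cin, ch[l]),
                       bn = new_batchnorm(ch[l]))
      cin <- ch[l]
    }
    att <- list()
    att[[L]] <- new_attention_block(ch[L], config)  # bottleneck
    dec <- vector("list", L)
    for (l in rev(seq_len(L - 1L))) {
      cin_dec <- ch[l + 1L] + ch[l]  # upsampled coarser + skip
      dec[[l]] <- list(conv = new_conv_layer(3L, 3L, cin_dec, ch[l]),
                       bn = new_batchnorm(ch[l]))
      att[[l]] <- new_attention_block(ch[l], config)
    }
    aux <- lapply(seq_len(L), function(l) new_conv_layer(1L, 1L, ch[l], 1L))
    head <- new_conv_layer(1L, 1L, ch[1L], 1L)
    mix <- if (config$attention_trainable) {
      list(alpha = ag_param(config$attention_alpha),
           beta = ag_param(config$attention_beta))
    } else {
      list(alpha = ag_const(config$attention_alpha),
           beta = ag_const(config$attention_beta))
    }
    model <- structure(list(
      config = config, in_channels = as.integer(in_channels),
      channels = ch, enc = enc, dec = dec, att = att, aux = aux,
      head = head, mix = mix, seed = as.integer(seed)
    ), class = "hepafuse_segmenter")
    model$params <- collect_params(model[c("enc", "dec", "att", "aux",
                                           "head", "mix")])
    model
  })
}

# graph form of one SAM+CAM attention block applied to feature node x
attention_graph <- function(block, x, mix) {
  d <- dim(x$value)
  as_map <- ag_sigmoid(ag_mul(conv_forward(block$f1, x),
                              conv_forward(block$f2, x)))
  ac_vec <- ag_sigmoid(dense_forward(block$W2,
                                     ag_relu(dense_forward(block$W1, ag_gap(x)))))
  a_final <- ag_add(ag_mul(mix$alpha, ag_bcast_spatial(as_map, d[3])),
                    ag_mul(mix$beta, ag_bcast_channel(ac_vec, d[1], d[2])))
  list(refined = ag_mul(x, a_final), a_final = a_final,
       spatial = as_map, channel = ac_vec)
}

# full forward graph; x is an ag node of shape (H, W, Cin, N)
segmenter_graph <- function(model, x, training = FALSE) {
  L <- model$config$n_levels
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    h <- ag_relu(batchnorm_forward(model$enc[[l]]$bn,
                                   conv_forward(model$enc[[l]]$conv, h),
                                   training))
    skips[[l]] <- h
    if (l < L) h <- ag_maxpool2(h)
  }
  att_b <- attention_graph(model$att[[L]], h, model$mix)
  h <- att_b$refined
  depth_nodes <- vector("list", L)   # coarse -> fine
  depth_nodes[[1L]] <- h
  for (l in rev(seq_len(L - 1L))) {
    h <- ag_concat_c(ag_upsample2(h), skips[[l]])
    h <- ag_relu(batchnorm_forward(model$dec[[l]]$bn,
                                   conv_forward(model$dec[[l]]$conv, h),
                                   training))
    h <- attention_graph(model$att[[l]], h, model$mix)$refined
    depth_nodes[[L - l + 1L]] <- h
  }
  logits <- conv_forward(model$head, h)
  # per-depth single-channel projections, upsampled to full resolution
  aux_logits <- lapply(seq_len(L), function(k) {
    l <- L - k + 1L  # level index of depth k (k = 1 is coarsest)
    a <- conv_forward(model$aux[[l]], depth_nodes[[k]])
    times <- l - 1L
    while (times > 0L) {
      a <- ag_upsample2(a)
      times <- times - 1L
    }
    a
  })
  list(logits = logits, prob = ag_sigmoid(logits), aux_logits = aux_logits,
       bottleneck = att_b$refined)
}

validate_segmenter_input <- function(model, images) {
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1, 1))
  if (length(dim(images)) == 3L) {
    d <- dim(images)
    images <- array(images, dim = c(d[1], d[2], 1, d[3]))
  }
  d <- dim(images)
  div <- 2L^(model$config$n_levels - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop_invalid("input %d x %d not divisible by %d (2^(n_levels-1))",
                 d[1], d[2], div)
  }
  if (d[3] != model$in_channels) stop_invalid("channel mismatch")
  images
}

#' Forward pass of the segmenter
#'
#' Evaluation-mode forward pass (batch statistics frozen, no dropout):
#' returns the soft tumor masks and the depth feature set used for SSIM depth
#' supervision and imaging-feature pooling.
#'
#' @param model a [build_segmenter()] model.
#' @param images an H x W matrix, H x W x N array, or (H, W, C, N) array.
#'   Spatial dimensions must be divisible by `2^(n_levels - 1)`.
#' @param batch_size evaluation batch size (memory bound only).
#' @return a list with `prob` (H x W x N soft masks in (0, 1)), `depthset`
#'   (class `depth_feature_set`: per-depth sigmoid projections at full
#'   resolution, ordered coarse to fine), and `bottleneck_features`
#'   (N x C matrix of globally average-pooled attention-refined bottleneck
#'   features).
#' @export
forward_segment <- function(model, images, batch_size = 32L) {
  stopifnot(inherits(model, "hepafuse_segmenter"))
  x <- validate_segmenter_input(model, images)
  d <- dim(x)
  L <- model$config$n_levels
  prob <- array(0, dim = c(d[1], d[2], d[4]))
  projections <- lapply(seq_len(L), function(k) array(0, dim = c(d[1], d[2], d[4])))
  feats <- NULL
  for (start in seq(1L, d[4], by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, d[4])
    g <- segmenter_graph(model, ag_const(x[, , , idx, drop = FALSE]),
                         training = FALSE)
    prob[, , idx] <- g$prob$value[, , 1L, ]
    for (k in seq_len(L)) {
      projections[[k]][, , idx] <- stats::plogis(g$aux_logits[[k]]$value[, , 1L, ])
    }
    fb <- gap_numeric(g$bottleneck$value)
    feats <- rbind(feats, fb)
  }
  list(prob = prob,
       depthset = structure(list(projections = projections,
                                 weights = model$config$hdfo_weights),
                            class = "depth_feature_set"),
       bottleneck_features = feats)
}

gap_numeric <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

#' Predict binary tumor masks
#'
#' @inheritParams forward_segment
#' @param threshold probability cut for binarization (default 0.5).
#' @return binary H x W x N array.
#' @export
predict_mask <- function(model, images, threshold = 0.5, batch_size = 32L) {
  (forward_segment(model, images, batch_size)$prob >= threshold) * 1
}

# ---- functional attention operations (numeric, single sample) ---------------

#' Spatial attention map
#'
#' Numeric form of the SAM on a single feature map: two 1x1 convolutions
#' `f1`, `f2` map the C channels to one plane each; their element-wise
#' product is squashed by the logistic function,
#' `As = sigmoid(f1(X) * f2(X))`. Entries are strictly inside (0, 1).
#'
#' @param x H x W x C feature array.
#' @param params list with `w1`, `b1`, `w2`, `b2`: each `w` a length-C
#'   weight vector of the corresponding 1x1 convolution, each `b` a scalar
#'   bias.
#' @return H x W matrix in (0, 1).
#' @export
spatial_attention <- function(x, params) {
  x <- feature_array(x)
  d <- dim(x)
  if (length(params$w1) != d[3] || length(params$w2) != d[3]) {
    stop_invalid("1x1 kernel length must equal channel count %d", d[3])
  }
  xm <- matrix(x, d[1] * d[2], d[3])
  f1 <- xm %*% params$w1 + params$b1
  f2 <- xm %*% params$w2 + params$b2
  matrix(stats::plogis(f1 * f2), d[1], d[2])
}

#' Channel attention vector
#'
#' Numeric form of the CAM on a single feature map: global average pooling
#' per channel, a bottleneck dense layer with ReLU, an expansion dense layer,
#' and a logistic squash: `Ac = sigmoid(W2 . relu(W1 . GAP(X)))`.
#'
#' @param x H x W x C feature array.
#' @param params list with `W1` (C x C/r), `b1`, `W2` (C/r x C), `b2`.
#' @param reduction_ratio declared reduction; `C / reduction_ratio` must be
#'   >= 1 and match `ncol(W1)`.
#' @return length-C vector in (0, 1).
#' @export
channel_attention <- function(x, params, reduction_ratio = 4) {
  x <- feature_array(x)
  C <- dim(x)[3]
  hidden <- C %/% reduction_ratio
  if (hidden < 1) stop_invalid("C / reduction_ratio must be >= 1")
  if (nrow(params$W1) != C || ncol(params$W1) != hidden) {
    stop_invalid("W1 must be %d x %d", C, hidden)
  }
  gap <- colMeans(matrix(x, prod(dim(x)[1:2]), C))
  hid <- pmax(as.numeric(gap %*% params$W1) + params$b1, 0)
  as.numeric(stats::plogis(as.numeric(hid %*% params$W2) + params$b2))
}

#' Combined attention map
#'
#' Broadcasts the spatial map over channels and the channel vector over
#' pixels, then mixes them linearly:
#' `A_final[i,j,c] = alpha * As[i,j] + beta * Ac[c]`. When
#' `alpha + beta = 1` and both inputs lie in (0, 1), so does the result.
#'
#' @param a_s H x W spatial attention map.
#' @param a_c length-C channel attention vector.
#' @param alpha,beta non-negative mixing weights (defaults 0.6 / 0.4).
#' @return H x W x C array.
#' @export
combine_attention <- function(a_s, a_c, alpha = 0.6, beta = 0.4) {
  if (alpha < 0 || beta < 0) stop_invalid("mixing weights must be non-negative")
  a_s <- as.matrix(a_s)
  out <- array(rep(alpha * a_s, length(a_c)),
               dim = c(nrow(a_s), ncol(a_s), length(a_c)))
  sweep(out, 3L, beta * a_c, "+")
}

#' Attention-refined features
#'
#' Element-wise modulation of a feature map by its combined attention:
#' `X * A_final`. With attention entries in \[0, 1\] this is a contraction.
#'
#' @param x H x W x C feature array.
#' @param a attention array of the same shape.
#' @return refined feature array.
#' @export
refine_features <- function(x, a) {
  x <- feature_array(x); a <- feature_array(a)
  check_same_shape(x, a, "features and attention")
  x * a
}

feature_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop_invalid("expected an H x W x C array")
  check_finite(x, "feature map")
  x
}

# ---- HDFO -------------------------------------------------------------------

#' SSIM depth-supervision terms
#'
#' For each depth of the feature pyramid, compares the depth's single-channel
#' projection (upsampled to ground-truth resolution) against the binary mask
#' with the global-statistics SSIM, and accumulates the auxiliary penalty
#' `sum_d w_d * (1 - SSIM_d)` that training adds to the hybrid loss.
#' All-zero weights disable the term exactly.
#'
#' @param depthset a `depth_feature_set` from [forward_segment()], or a plain
#'   list of H x W x N projection arrays ordered coarse to fine.
#' @param g binary ground-truth masks, H x W (single) or H x W x N.
#' @param weights per-depth non-negative weights; default uniform `1/D`.
#' @return a list with `per_depth` (tibble: depth, weight, mean SSIM) and
#'   `aux_loss` (scalar).
#' @export
hdfo_terms <- function(depthset, g, weights = NULL) {
  projections <- if (inherits(depthset, "depth_feature_set")) {
    depthset$projections
  } else {
    depthset
  }
  D <- length(projections)
  weights <- weights %||%
    (if (inherits(depthset, "depth_feature_set") && !is.null(depthset$weights))
       depthset$weights else rep(1 / D, D))
  if (length(weights) != D || any(weights < 0)) {
    stop_invalid("need %d non-negative depth weights", D)
  }
  if (length(dim(g)) == 2L) g <- array(g, dim = c(dim(g), 1L))
  ssims <- vapply(projections, function(pd) {
    if (length(dim(pd)) == 2L) pd <- array(pd, dim = c(dim(pd), 1L))
    check_same_shape(pd, g, "projection and ground truth")
    mean(vapply(seq_len(dim(g)[3]), function(i) {
      ssim_global(pd[, , i], g[, , i])
    }, numeric(1)))
  }, numeric(1))
  list(
    per_depth = tibble::tibble(depth = seq_len(D), weight = weights,
                               ssim = ssims),
    aux_loss = sum(weights * (1 - ssims))
  )
}

# graph-side mean-over-samples global SSIM between a (H,W,1,N) node and a
# constant mask array of the same shape
ag_ssim_mean <- function(p, g_arr, K1 = 0.01, K2 = 0.03, L = 1) {
  c1 <- (K1 * L)^2
  c2 <- (K2 * L)^2
  per <- prod(dim(g_arr)[1:3])
  gm <- matrix(g_arr, per, dim(g_arr)[4])
  mu_g <- colMeans(gm)
  var_g <- colMeans(gm^2) - mu_g^2
  g_node <- ag_const(g_arr)
  mu_p <- ag_sw_mean(p)
  m_pg <- ag_sw_mean(ag_mul(p, g_node))
  m_p2 <- ag_sw_mean(ag_square(p))
  var_p <- ag_sub(m_p2, ag_square(mu_p))
  cov_pg <- ag_sub(m_pg, ag_mul(mu_p, ag_const(mu_g)))
  num <- ag_mul(ag_add(ag_mul(ag_const(2 * mu_g), mu_p), ag_const(c1)),
                ag_add(ag_mul(ag_const(2), cov_pg), ag_const(c2)))
  den <- ag_mul(ag_add(ag_add(ag_square(mu_p), ag_const(mu_g^2)), ag_const(c1)),
                ag_add(ag_add(var_p, ag_const(var_g)), ag_const(c2)))
  ag_mean(ag_div(num, den))
}

# graph-side hybrid loss; returns nodes for the components and total
hybrid_loss_graph <- function(logits, prob, g_arr, weights, hdfo_weights,
                              aux_logits, smooth = 1e-6) {
  g_node <- ag_const(g_arr)
  inter <- ag_sum(ag_mul(prob, g_node))
  dice <- ag_sub(ag_const(1),
                 ag_div(ag_add(ag_mul(ag_const(2), inter), ag_const(smooth)),
                        ag_add(ag_add(ag_sum(prob), ag_const(sum(g_arr))),
                               ag_const(smooth))))
  ce <- ag_bce_logits(logits, g_arr)
  ssim <- ag_sub(ag_const(1), ag_ssim_mean(prob, g_arr))
  total <- ag_add(ag_add(ag_mul(ag_const(weights$dice), dice),
                         ag_mul(ag_const(weights$ce), ce)),
                  ag_mul(ag_const(weights$ssim), ssim))
  if (!is.null(hdfo_weights) && any(hdfo_weights > 0)) {
    for (k in seq_along(aux_logits)) {
      if (hdfo_weights[k] > 0) {
        sd_k <- ag_sub(ag_const(1),
                       ag_ssim_mean(ag_sigmoid(aux_logits[[k]]), g_arr))
        total <- ag_add(total, ag_mul(ag_const(hdfo_weights[k]), sd_k))
      }
    }
  }
  list(total = total, dice = dice, ce = ce, ssim = ssim)
}

#' Train the segmenter with the hybrid loss
#'
#' Minimizes `lambda_dice * L_Dice + lambda_ce * L_CE + lambda_ssim * L_SSIM`
#' (plus the optional SSIM depth-supervision penalty configured in the model)
#' with Adam. Per-epoch mean component losses are recorded; when a validation
#' set is supplied, early stopping monitors the validation hybrid loss with
#' the given patience.
#'
#' @param model a [build_segmenter()] model (updated in place and returned).
#' @param images training images, H x W x N array.
#' @param masks binary masks, H x W x N array.
#' @param epochs maximum epochs.
#' @param batch_size minibatch size (default 16).
#' @param lr,weight_decay Adam settings (defaults 1e-3, 1e-5).
#' @param weights a [loss_weights()].
#' @param augment optional [augmentation_spec()] applied to each training
#'   pair with a per-(epoch, sample) derived seed.
#' @param validation optional `list(images =, masks =)` for early stopping.
#' @param patience epochs without validation improvement before stopping
#'   (default `Inf`; ignored without a validation set).
#' @param seed RNG seed for shuffling (and augmentation draws).
#' @param log_path optional JSONL file receiving one line per step with the
#'   loss breakdown.
#' @param init_head_prior calibrate the segmentation head's bias to the
#'   training masks' foreground fraction before the first update (default
#'   TRUE). Tumor pixels are a small minority of each slice, so starting the
#'   head at the class prior instead of probability 0.5 removes the early
#'   epochs otherwise spent re-learning the base rate.
#' @return the model, with `$history` (tibble: epoch, dice, ce, ssim, total,
#'   val_total) attached.
#' @export
train_segmenter <- function(model, images, masks, epochs = 30,
                            batch_size = 16L, lr = 1e-3, weight_decay = 1e-5,
                            weights = loss_weights(), augment = NULL,
                            validation = NULL, patience = Inf, seed = 1L,
                            log_path = NULL, init_head_prior = TRUE) {
  stopifnot(inherits(model, "hepafuse_segmenter"))
  x <- validate_segmenter_input(model, images)
  if (length(dim(masks)) == 2L) masks <- array(masks, dim = c(dim(masks), 1L))
  n <- dim(x)[4]
  stopifnot(dim(masks)[3] == n)
  if (isTRUE(init_head_prior) && is.null(model$history)) {
    prior <- min(max(mean(masks), 1e-3), 1 - 1e-3)
    model$head$b$value[] <- stats::qlogis(prior)
  }
  opt <- new_adam(model$params, lr = lr, weight_decay = weight_decay)
  hist <- list()
  best <- Inf
  wait <- 0L
  step <- 0L
  if (!is.null(log_path)) file.create(log_path)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      comp <- c(dice = 0, ce = 0, ssim = 0, total = 0)
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        gb <- masks[, , idx, drop = FALSE]
        if (!is.null(augment)) {
          for (k in seq_along(idx)) {
            d <- draw_augmentation(augmentation_spec(
              rotation_range = augment$rotation_range,
              scale_range = augment$scale_range,
              flip_horizontal = augment$flip_horizontal,
              flip_vertical = augment$flip_vertical,
              seed = augment$seed + 1000L * ep + idx[k]))
            a <- apply_augmentation(xb[, , 1L, k], gb[, , k],
                                    d$rotation, d$scale, d$flip_h, d$flip_v)
            xb[, , 1L, k] <- a$image
            gb[, , k] <- a$mask
          }
        }
        g4 <- array(gb, dim = c(dim(gb)[1:2], 1L, length(idx)))
        fw <- segmenter_graph(model, ag_const(xb), training = TRUE)
        ls <- hybrid_loss_graph(fw$logits, fw$prob, g4, weights,
                                model$config$hdfo_weights, fw$aux_logits)
        ag_backward(ls$total)
        adam_step(opt)
        step <- step + 1L
        vals <- c(dice = ls$dice$value, ce = ls$ce$value,
                  ssim = ls$ssim$value, total = ls$total$value)
        comp <- comp + vals
        nb <- nb + 1L
        if (!is.null(log_path)) {
          cat(jsonlite::toJSON(c(list(step = step), as.list(vals)),
                               auto_unbox = TRUE, digits = NA),
              "\n", sep = "", file = log_path, append = TRUE)
        }
      }
      comp <- comp / nb
      val_total <- NA_real_
      if (!is.null(validation)) {
        val_total <- evaluate_hybrid_loss(model, validation$images,
                                          validation$masks, weights)
        if (val_total < best - 1e-9) {
          best <- val_total
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, dice = comp["dice"],
                                   ce = comp["ce"], ssim = comp["ssim"],
                                   total = comp["total"],
                                   val_total = val_total)
      if (!is.null(validation) && wait >= patience) break
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model
}

# evaluation-mode mean hybrid loss over a set
evaluate_hybrid_loss <- function(model, images, masks, weights = loss_weights(),
                                 batch_size = 32L) {
  fw <- forward_segment(model, images, batch_size = batch_size)
  if (length(dim(masks)) == 2L) masks <- array(masks, dim = c(dim(masks), 1L))
  n <- dim(masks)[3]
  mean(vapply(seq_len(n), function(i) {
    hybrid_loss(fw$prob[, , i], masks[, , i], weights)$total
  }, numeric(1)))
}

#' @export
print.hepafuse_segmenter <- function(x, ...) {
  cat(sprintf(
    "attention-guided segmenter: %d levels, channels %s, alpha/beta %.2f/%.2f\n",
    x$config$n_levels, paste(x$channels, collapse = "/"),
    x$config$attention_alpha, x$config$attention_beta))
  cat(sprintf("  %d parameter tensors (%d values)\n", length(x$params),
              sum(vapply(x$params, function(p) length(p$value), numeric(1)))))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, final hybrid loss %.4f\n",
                nrow(x$history), x$history$total[nrow(x$history)]))
  }
  invisible(x)
}
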