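# Genomic feature analysis: a fully connected autoencoder compresses the
# samples x markers matrix to a latent code, the code is clustered to reveal
# subtypes, and markers are ranked by a transparent saliency score. The
# marker-ranking saliency is this package's own documented convention and
# should not be read as a canonical selection method.

#' Build a genomic autoencoder
#'
#' Four fully connected layers: encoder `m -> hidden -> k` (ReLU activations,
#' dropout after the hidden layer during training) and decoder
#' `k -> hidden -> m` (ReLU hidden, linear output). The latent width `k`
#' must be strictly smaller than `m`.
#'
#' @param m input dimensionality (number of markers, >= 2).
#' @param k latent dimensionality (default 128 at full scale; tests and the
#'   synthetic benchmarks use smaller values).
#' @param hidden hidden width; default the rounded geometric mean of `m`
#'   and `k`.
#' @param dropout dropout rate on the encoder hidden layer (default 0.3).
#' @param seed weight initialization seed.
#' @return an object of class `hepafuse_autoencoder`.
#' @export
build_autoencoder <- function(m, k = 128L, hidden = NULL, dropout = 0.3,
                              seed = 1L) {
  if (m < 2) stop_invalid("need at least 2 markers")
  if (k < 1 || k >= m) stop_invalid("latent dim k must satisfy 1 <= k < m")
  if (dropout < 0 || dropout >= 1) stop_invalid("dropout must be in [0, 1)")
  hidden <- as.integer(hidden %||% round(sqrt(as.numeric(m) * k)))
  withr::with_seed(seed, {
    st <- structure(list(
      m = as.integer(m), k = as.integer(k), hidden = hidden, dropout = dropout,
      enc1 = new_dense_layer(m, hidden), enc2 = new_dense_layer(hidden, k),
      dec1 = new_dense_layer(k, hidden), dec2 = new_dense_layer(hidden, m),
      center = NULL, scale = NULL, seed = as.integer(seed), history = NULL
    ), class = "hepafuse_autoencoder")
    st$params <- collect_params(st[c("enc1", "enc2", "dec1", "dec2")])
    st
  })
}

#' Number of trainable parameters of an autoencoder
#' @param state a `hepafuse_autoencoder`.
#' @export
n_params <- function(state) {
  sum(vapply(state$params, function(p) length(p$value), numeric(1)))
}

autoencoder_graph <- function(state, x_node, training = FALSE) {
  h <- ag_relu(dense_forward(state$enc1, x_node))
  h <- ag_dropout(h, state$dropout, training)
  z <- ag_relu(dense_forward(state$enc2, h))
  hd <- ag_relu(dense_forward(state$dec1, z))
  xhat <- dense_forward(state$dec2, hd)  # linear output
  list(z = z, xhat = xhat)
}

# extract the numeric genomic matrix from a tibble (sample_id/subtype_label
# columns dropped) or pass a plain matrix through
genomic_matrix <- function(x) {
  if (is.data.frame(x)) {
    keep <- !(names(x) %in% c("sample_id", "subtype_label"))
    x <- as.matrix(x[, keep, drop = FALSE])
  }
  x <- as.matrix(x)
  check_finite(x, "genomic matrix")
  if (ncol(x) < 2) stop_invalid("genomic matrix needs >= 2 markers")
  x
}

standardize_columns <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

#' Train the genomic autoencoder
#'
#' Columns are standardized (mean 0, unit variance; statistics stored on the
#' model for later encoding and de-standardization), then the mean per-sample
#' squared reconstruction error is minimized with Adam. The loss history
#' records the epoch-mean reconstruction loss on the standardized scale.
#'
#' @param state a [build_autoencoder()] model.
#' @param x genomic data: an n x m matrix or a cohort tibble with
#'   `sample_id` / `subtype_label` columns (dropped automatically).
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param lr,weight_decay Adam settings (defaults 1e-3, 1e-5).
#' @param standardize standardize columns first (default TRUE).
#' @param seed RNG seed (shuffling and dropout masks).
#' @return the trained state with `$history` (tibble: epoch, recon) attached.
#' @export
train_autoencoder <- function(state, x, epochs = 100, batch_size = 32L,
                              lr = 1e-3, weight_decay = 1e-5,
                              standardize = TRUE, seed = 1L) {
  stopifnot(inherits(state, "hepafuse_autoencoder"))
  x <- genomic_matrix(x)
  if (ncol(x) != state$m) stop_invalid("expected %d markers, got %d",
                                       state$m, ncol(x))
  if (standardize) {
    state$center <- colMeans(x)
    sds <- apply(x, 2L, stats::sd)
    state$scale <- ifelse(sds > 0, sds, 1)
    x <- standardize_columns(x, state$center, state$scale)
  } else {
    state$center <- rep(0, state$m)
    state$scale <- rep(1, state$m)
  }
  n <- nrow(x)
  opt <- new_adam(state$params, lr = lr, weight_decay = weight_decay)
  hist <- numeric(epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        fw <- autoencoder_graph(state, ag_const(xb), training = TRUE)
        res <- ag_sub(fw$xhat, ag_const(xb))
        loss <- ag_mul(ag_mean(ag_square(res)), ag_const(state$m))
        if (!is.finite(loss$value)) {
          stop("non-finite reconstruction loss at epoch ", ep,
               " (step loss = ", loss$value, ")")
        }
        ag_backward(loss)
        adam_step(opt)
        tot <- tot + loss$value
        nb <- nb + 1L
      }
      hist[ep] <- tot / nb
    }
  })
  state$history <- tibble::tibble(epoch = seq_len(epochs), recon = hist)
  state
}

#' Encode samples into the latent space
#'
#' Deterministic forward pass of the encoder (dropout disabled); input
#' columns are standardized with the statistics stored at training time.
#'
#' @param state a trained (or initialized) `hepafuse_autoencoder`.
#' @param x n x m matrix or cohort tibble.
#' @return n x k latent matrix.
#' @export
encode <- function(state, x) {
  stopifnot(inherits(state, "hepafuse_autoencoder"))
  x <- genomic_matrix(x)
  if (ncol(x) != state$m) stop_invalid("expected %d markers, got %d",
                                       state$m, ncol(x))
  if (!is.null(state$center)) {
    x <- standardize_columns(x, state$center, state$scale)
  }
  autoencoder_graph(state, ag_const(x), training = FALSE)$z$value
}

#' Reconstruct samples through the autoencoder
#'
#' @inheritParams encode
#' @param destandardize return the reconstruction on the original marker
#'   scale (default) or the standardized training scale.
#' @return n x m reconstruction.
#' @export
reconstruct <- function(state, x, destandardize = TRUE) {
  stopifnot(inherits(state, "hepafuse_autoencoder"))
  x <- genomic_matrix(x)
  xs <- if (!is.null(state$center)) {
    standardize_columns(x, state$center, state$scale)
  } else {
    x
  }
  xhat <- autoencoder_graph(state, ag_const(xs), training = FALSE)$xhat$value
  if (destandardize && !is.null(state$center)) {
    xhat <- sweep(sweep(xhat, 2L, state$scale, "*"), 2L, state$center, "+")
  }
  xhat
}

#' Cluster the latent representation
#'
#' k-means on the latent rows with a fixed seed and multiple restarts.
#'
#' @param z n x k latent matrix.
#' @param n_clusters number of clusters (>= 2, <= n).
#' @param seed RNG seed.
#' @param n_init random restarts (default 10).
#' @return integer cluster labels in `0:(n_clusters - 1)`.
#' @export
cluster_latent <- function(z, n_clusters, seed = 1L, n_init = 10L) {
  z <- as.matrix(z)
  if (n_clusters < 2) stop_invalid("n_clusters must be >= 2")
  if (nrow(z) < n_clusters) stop_invalid("fewer samples than clusters")
  if (nrow(z) == n_clusters) return(seq_len(n_clusters) - 1L)
  withr::with_seed(seed, {
    km <- stats::kmeans(z, centers = n_clusters, nstart = n_init,
                        iter.max = 100L)
  })
  as.integer(km$cluster - 1L)
}

# one-way F statistic of y against integer groups, vectorized over columns
column_f_stats <- function(y, groups) {
  y <- as.matrix(y)
  n <- nrow(y)
  gs <- split(seq_len(n), groups)
  k <- length(gs)
  if (k < 2 || n - k < 1) return(rep(0, ncol(y)))
  gmeans <- vapply(gs, function(ix) colMeans(y[ix, , drop = FALSE]),
                   numeric(ncol(y)))
  gmeans <- matrix(gmeans, ncol(y), k)
  overall <- colMeans(y)
  sizes <- lengths(gs)
  ss_b <- as.numeric((gmeans - overall)^2 %*% sizes)
  ss_w <- vapply(seq_len(ncol(y)), function(j) {
    sum(vapply(seq_len(k), function(g) {
      sum((y[gs[[g]], j] - gmeans[j, g])^2)
    }, numeric(1)))
  }, numeric(1))
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (n - k)
  ifelse(ms_w > 0, ms_b / ms_w, 0)
}

#' Rank markers by cluster-separating saliency
#'
#' A transparent, non-canonical saliency score: each latent dimension is
#' weighted by its one-way F statistic across the cluster labels
#' (normalized), and each marker scores the F-weighted sum of the absolute
#' correlations between its column and the latent dimensions. Markers that
#' co-vary with the latent directions that separate the clusters rank first.
#' Constant marker columns score 0 and are flagged.
#'
#' @param x n x m genomic matrix or cohort tibble.
#' @param z n x k latent matrix (e.g. from [encode()]).
#' @param labels integer cluster labels (e.g. from [cluster_latent()]).
#' @return a tibble (`marker`, `score`, `rank`, `constant`) ordered by
#'   non-increasing score; every input marker appears exactly once.
#' @export
rank_markers <- function(x, z, labels) {
  x <- genomic_matrix(x)
  z <- as.matrix(z)
  if (nrow(x) != nrow(z) || nrow(x) != length(labels)) {
    stop_invalid("x, z and labels must agree on the number of samples")
  }
  fstat <- column_f_stats(z, labels)
  w <- if (sum(fstat) > 0) fstat / sum(fstat) else rep(1 / ncol(z), ncol(z))
  sds <- apply(x, 2L, stats::sd)
  constant <- sds == 0
  scores <- numeric(ncol(x))
  if (any(!constant)) {
    # constant latent dimensions (dead ReLU units) yield NA correlations,
    # zeroed below; silence the sd-zero warning they provoke
    cors <- abs(suppressWarnings(stats::cor(x[, !constant, drop = FALSE], z)))
    cors[is.na(cors)] <- 0
    scores[!constant] <- as.numeric(cors %*% w)
  }
  nm <- colnames(x) %||% sprintf("marker_%03d", seq_len(ncol(x)))
  tb <- tibble::tibble(marker = nm, score = scores, constant = constant)
  tb <- dplyr::arrange(tb, dplyr::desc(.data$score))
  tb$rank <- seq_len(nrow(tb))
  tb[, c("marker", "score", "rank", "constant")]
}

#' @method tidy hepafuse_autoencoder
#' @export
tidy.hepafuse_autoencoder <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), recon = numeric())
}

#' @method glance hepafuse_autoencoder
#' @export
glance.hepafuse_autoencoder <- function(x, ...) {
  tibble::tibble(
    m = x$m, k = x$k, hidden = x$hidden, dropout = x$dropout,
    n_params = n_params(x),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_recon = if (is.null(x$history)) NA_real_ else
      x$history$recon[nrow(x$history)]
  )
}

#' @export
print.hepafuse_autoencoder <- function(x, ...) {
  cat(sprintf("genomic autoencoder: %d -> %d -> %d -> %d -> %d (dropout %.2f)\n",
              x$m, x$hidden, x$k, x$hidden, x$m, x$dropout))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, reconstruction loss %.4f\n",
                nrow(x$history), x$history$recon[nrow(x$history)]))
  }
  invisible(x)
}
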