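# ggplot2 visualizations of training histories and latent structure.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot hepafuse_segmenter
#' @export
autoplot.hepafuse_segmenter <- function(object, ...) {
  if (is.null(object$history)) stop_invalid("model has no training history")
  long <- tidyr_pivot(object$history[, c("epoch", "dice", "ce", "ssim", "total")])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "hybrid segmentation loss components") +
    ggplot2::theme_minimal()
}

# minimal wide-to-long without requiring tidyr at run time
tidyr_pivot <- function(df) {
  comps <- setdiff(names(df), "epoch")
  dplyr::bind_rows(lapply(comps, function(cp) {
    tibble::tibble(epoch = df$epoch, component = cp, value = df[[cp]])
  }))
}

#' @method autoplot hepafuse_autoencoder
#' @export
autoplot.hepafuse_autoencoder <- function(object, ...) {
  if (is.null(object$history)) stop_invalid("model has no training history")
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$recon)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "reconstruction loss",
                  title = "autoencoder training") +
    ggplot2::theme_minimal()
}

#' @method autoplot hepafuse_fusion
#' @export
autoplot.hepafuse_fusion <- function(object, ...) {
  if (is.null(object$history)) stop_invalid("model has no training history")
  long <- tidyr_pivot(object$history[, c("epoch", "ce", "alpha")])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "fusion training: cross-entropy and fusion weight") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a latent representation
#'
#' Projects the latent rows onto their first two principal components and
#' colours them by label — the usual first look at planted or discovered
#' subtype structure.
#'
#' @param z n x k latent matrix.
#' @param labels grouping labels (cluster or subtype), length n.
#' @return a ggplot object.
#' @export
plot_latent <- function(z, labels) {
  z <- as.matrix(z)
  pc <- stats::prcomp(z, rank. = 2L)
  df <- tibble::tibble(pc1 = pc$x[, 1],
                       pc2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0,
                       label = factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2", title = "latent space") +
    ggplot2::theme_minimal()
}
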