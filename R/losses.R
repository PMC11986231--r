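# The hybrid training objective: soft Dice, pixel-wise cross-entropy, SSIM
# loss, their weighted combination, and the autoencoder reconstruction loss.
# These are the numeric (evaluation) forms; the trainers rebuild the same
# quantities on the autodiff tape so that a single definition is tested from
# two routes.

#' Soft Dice loss
#'
#' `1 - (2 * sum(P*G) + smooth) / (sum(P) + sum(G) + smooth)`. With a binary
#' `p` and `smooth = 0` this is exactly one minus the Dice coefficient; the
#' soft form (probabilities in `p`) is what gradient training uses, and the
#' small default smoothing keeps empty-mask batches defined.
#'
#' @param p soft or binary predicted mask, entries in \[0, 1\].
#' @param g binary ground-truth mask.
#' @param smooth additive smoothing (default 1e-6; 0 reproduces the exact
#'   overlap formula).
#' @export
dice_loss <- function(p, g, smooth = 1e-6) {
  check_same_shape(p, g, "Dice-loss inputs")
  if (any(p < 0) || any(g < 0)) stop_invalid("mask entries must be non-negative")
  if (any(p > 1)) stop_invalid("predicted mask entries must be <= 1")
  1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
}

#' Pixel-wise binary cross-entropy
#'
#' Mean over pixels of `-[G log P + (1-G) log(1-P)]`, with predictions clipped
#' to `[eps, 1-eps]` before the logs.
#'
#' @param p predicted probabilities in \[0, 1\].
#' @param g binary ground truth.
#' @param eps clipping constant (default 1e-7).
#' @export
cross_entropy_loss <- function(p, g, eps = 1e-7) {
  check_same_shape(p, g, "cross-entropy inputs")
  if (length(p) == 0L) stop_invalid("empty pixel field")
  check_binary(g, "ground truth")
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

#' Structural similarity loss
#'
#' `1 - ssim_global(p, g)`; lies in \[0, 2\].
#' @inheritParams ssim_global
#' @export
ssim_loss <- function(p, g, K1 = 0.01, K2 = 0.03, L = 1) {
  1 - ssim_global(p, g, K1 = K1, K2 = K2, L = L)
}

#' Weights of the hybrid segmentation objective
#'
#' @param lambda_dice,lambda_ce,lambda_ssim non-negative weights of the Dice,
#'   cross-entropy and SSIM components. Defaults (0.5, 0.3, 0.2).
#' @export
loss_weights <- function(lambda_dice = 0.5, lambda_ce = 0.3, lambda_ssim = 0.2) {
  w <- c(dice = lambda_dice, ce = lambda_ce, ssim = lambda_ssim)
  if (any(w < 0)) stop_invalid("loss weights must be non-negative")
  if (all(w == 0)) stop_invalid("at least one loss weight must be positive")
  structure(as.list(w), class = "hepafuse_loss_weights")
}

#' Hybrid segmentation loss with its breakdown
#'
#' Computes the three components once and combines them as
#' `lambda_dice * L_Dice + lambda_ce * L_CE + lambda_ssim * L_SSIM`.
#'
#' @param p soft predicted mask in \[0, 1\].
#' @param g binary ground-truth mask.
#' @param weights a [loss_weights()] object.
#' @param smooth Dice smoothing passed to [dice_loss()].
#' @param eps clipping constant passed to [cross_entropy_loss()].
#' @return an object of class `loss_breakdown`: a list with `dice`, `ce`,
#'   `ssim`, `total` and the weights used. `tidy()` turns it into a one-row
#'   tibble.
#' @export
hybrid_loss <- function(p, g, weights = loss_weights(), smooth = 1e-6,
                        eps = 1e-7) {
  if (!inherits(weights, "hepafuse_loss_weights")) {
    stop_invalid("weights must be created with loss_weights()")
  }
  ld <- dice_loss(p, g, smooth = smooth)
  lc <- cross_entropy_loss(p, g, eps = eps)
  ls <- ssim_loss(p, g)
  structure(
    list(dice = ld, ce = lc, ssim = ls,
         total = weights$dice * ld + weights$ce * lc + weights$ssim * ls,
         weights = weights),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "hybrid loss: %.6f  (dice %.6f x %.2f, ce %.6f x %.2f, ssim %.6f x %.2f)\n",
    x$total, x$dice, x$weights$dice, x$ce, x$weights$ce, x$ssim, x$weights$ssim))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy loss_breakdown
#' @export
tidy.loss_breakdown <- function(x, ...) {
  tibble::tibble(
    component = c("dice", "ce", "ssim", "total"),
    value = c(x$dice, x$ce, x$ssim, x$total),
    weight = c(x$weights$dice, x$weights$ce, x$weights$ssim, NA_real_)
  )
}

#' Autoencoder reconstruction loss
#'
#' Mean over samples of the squared Euclidean norm of the per-sample residual
#' (summed over markers, not averaged): `mean_i ||x_i - xhat_i||^2`.
#'
#' @param x,xhat n x m matrices (original and reconstruction).
#' @export
reconstruction_loss <- function(x, xhat) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  check_same_shape(x, xhat, "reconstruction inputs")
  mean(rowSums((x - xhat)^2))
}
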