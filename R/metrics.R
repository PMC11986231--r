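# Evaluation metrics: global-statistics SSIM, Dice overlap, confusion-matrix
# metrics, and the proportion of correct patches (PCP).

#' Structural similarity from global image statistics
#'
#' Computes the structural similarity index between two grids from their
#' global means, variances and covariance,
#' \deqn{SSIM(P,G) = \frac{(2\mu_P\mu_G + C_1)(2\sigma_{PG} + C_2)}
#'                        {(\mu_P^2+\mu_G^2+C_1)(\sigma_P^2+\sigma_G^2+C_2)}}
#' with stabilizers \eqn{C_1=(K_1 L)^2} and \eqn{C_2=(K_2 L)^2}. This is the
#' single whole-image form (one set of statistics for the full grid), which is
#' what the segmenter's structural loss and depth supervision use; the sliding
#' window variant common in image-quality work is available via
#' `window_size`. Variances and the covariance are population moments
#' (denominator `n`).
#'
#' @param p,g numeric grids of identical shape.
#' @param K1,K2 stabilizer constants, defaults 0.01 and 0.03.
#' @param L dynamic range of the inputs; defaults to 1 because all compared
#'   grids here live in \[0, 1\].
#' @param window_size `NULL` (default) for the global form, or a tile size in
#'   pixels: the grids are cut into non-overlapping `window_size`-square tiles
#'   (padding with zeros) and the tile-wise global SSIM values are averaged.
#' @return a scalar in \[-1, 1\].
#' @export
#' @examples
#' ssim_global(matrix(0.5, 4, 4), matrix(0.5, 4, 4))
ssim_global <- function(p, g, K1 = 0.01, K2 = 0.03, L = 1, window_size = NULL) {
  p <- as.array(p); g <- as.array(g)
  check_same_shape(p, g, "SSIM inputs")
  check_finite(p, "p"); check_finite(g, "g")
  if (L <= 0) stop_invalid("dynamic range L must be positive")
  if (!is.null(window_size)) {
    tiles_p <- tile_grid(as.matrix(p), window_size)
    tiles_g <- tile_grid(as.matrix(g), window_size)
    return(mean(vapply(seq_along(tiles_p), function(i) {
      ssim_global(tiles_p[[i]], tiles_g[[i]], K1, K2, L)
    }, numeric(1))))
  }
  c1 <- (K1 * L)^2
  c2 <- (K2 * L)^2
  n <- length(p)
  mu_p <- mean(p); mu_g <- mean(g)
  var_p <- mean((p - mu_p)^2)
  var_g <- mean((g - mu_g)^2)
  cov_pg <- mean((p - mu_p) * (g - mu_g))
  ((2 * mu_p * mu_g + c1) * (2 * cov_pg + c2)) /
    ((mu_p^2 + mu_g^2 + c1) * (var_p + var_g + c2))
}

#' Dice similarity coefficient between binary masks
#'
#' \eqn{DSC = 2|P \cap G| / (|P| + |G|)}. Two empty masks agree that there is
#' no tumor, so empty-vs-empty returns 1; empty-vs-nonempty returns 0.
#'
#' @param p,g binary grids of identical shape.
#' @return a scalar in \[0, 1\].
#' @export
dice_coefficient <- function(p, g) {
  check_same_shape(p, g, "Dice inputs")
  check_binary(p, "predicted mask"); check_binary(g, "ground-truth mask")
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p * g) / denom
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 per class
#' (one-vs-rest) plus an `"overall"` row (micro accuracy, macro means of the
#' others). Ratios with a zero denominator are reported as 0 and flagged in
#' the `undefined` column.
#'
#' @param predicted,truth label vectors of equal length.
#' @param levels the label set; defaults to the union of observed labels.
#' @return a tibble with columns `class`, `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`, `undefined`.
#' @export
confusion_metrics <- function(predicted, truth, levels = NULL) {
  if (length(predicted) != length(truth)) {
    stop_invalid("predicted and truth must have equal length")
  }
  if (length(truth) < 1L) stop_invalid("need at least one sample")
  lev <- levels %||% sort(unique(c(predicted, truth)))
  if (!all(predicted %in% lev) || !all(truth %in% lev)) {
    stop_invalid("labels outside the declared level set")
  }
  n <- length(truth)
  safe <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  rows <- purrr::map(lev, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    tn <- sum(predicted != cl & truth != cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    pr <- safe(tp, tp + fp)
    rc <- safe(tp, tp + fn)
    sp <- safe(tn, tn + fp)
    f1 <- safe(2 * pr[1] * rc[1], pr[1] + rc[1])
    tibble::tibble(
      class = as.character(cl),
      accuracy = (tp + tn) / n,
      precision = pr[1], recall = rc[1], specificity = sp[1], f1 = f1[1],
      undefined = any(c(pr[2], rc[2], sp[2], f1[2]) > 0)
    )
  })
  per_class <- dplyr::bind_rows(rows)
  overall <- tibble::tibble(
    class = "overall",
    accuracy = mean(predicted == truth),
    precision = mean(per_class$precision),
    recall = mean(per_class$recall),
    specificity = mean(per_class$specificity),
    f1 = mean(per_class$f1),
    undefined = any(per_class$undefined)
  )
  dplyr::bind_rows(per_class, overall)
}

# cut a matrix into non-overlapping size x size tiles, zero-padding the edges
tile_grid <- function(x, size) {
  if (size < 1L) stop_invalid("patch size must be >= 1")
  H <- nrow(x); W <- ncol(x)
  Hp <- ceiling(H / size) * size
  Wp <- ceiling(W / size) * size
  if (Hp != H || Wp != W) {
    xp <- matrix(0, Hp, Wp)
    xp[seq_len(H), seq_len(W)] <- x
    x <- xp
  }
  out <- list()
  for (j in seq_len(Wp / size)) {
    for (i in seq_len(Hp / size)) {
      out[[length(out) + 1L]] <-
        x[(i - 1) * size + seq_len(size), (j - 1) * size + seq_len(size)]
    }
  }
  out
}

#' Proportion of correct patches
#'
#' Tiles both masks into non-overlapping square patches (zero-padded at the
#' edges) and counts a patch as correct when the fraction of pixels on which
#' prediction and ground truth agree reaches `correctness_threshold`. The
#' patch size and threshold have no published definition, so the defaults
#' (16 px, 0.9) are this package's documented convention.
#'
#' @param p,g binary grids of identical shape.
#' @param patch_size tile edge in pixels (default 16).
#' @param correctness_threshold required pixel-agreement fraction in (0, 1\]
#'   (default 0.9).
#' @return fraction of correct patches in \[0, 1\].
#' @export
proportion_correct_patches <- function(p, g, patch_size = 16,
                                       correctness_threshold = 0.9) {
  p <- as.matrix(p); g <- as.matrix(g)
  check_same_shape(p, g, "PCP inputs")
  check_binary(p, "predicted mask"); check_binary(g, "ground-truth mask")
  if (correctness_threshold <= 0 || correctness_threshold > 1) {
    stop_invalid("correctness_threshold must be in (0, 1]")
  }
  tp <- tile_grid(p, patch_size)
  tg <- tile_grid(g, patch_size)
  ok <- vapply(seq_along(tp), function(i) {
    mean(tp[[i]] == tg[[i]]) >= correctness_threshold
  }, logical(1))
  mean(ok)
}
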