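# Independent brute-force oracles used to cross-check the package's numeric
# paths. These are deliberately written in the most literal way possible
# (explicit loops, direct formula substitution) and share no code with the
# implementation.

# quadruple-loop 2-D convolution of a single channel pair, zero padding
oracle_conv2d_1ch <- function(x, w, b = 0, pad = 0) {
  kh <- nrow(w); kw <- ncol(w)
  H <- nrow(x); W <- ncol(x)
  Ho <- H + 2 * pad - kh + 1
  Wo <- W + 2 * pad - kw + 1
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) {
    for (j in seq_len(Wo)) {
      acc <- 0
      for (m in seq_len(kh)) {
        for (n in seq_len(kw)) {
          ii <- i + m - 1 - pad
          jj <- j + n - 1 - pad
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
            acc <- acc + x[ii, jj] * w[m, n]
          }
        }
      }
      out[i, j] <- acc + b
    }
  }
  out
}

# direct substitution into the global-statistics structural similarity
oracle_ssim <- function(p, g, K1 = 0.01, K2 = 0.03, L = 1) {
  p <- as.numeric(p)
  g <- as.numeric(g)
  n <- length(p)
  mp <- sum(p) / n
  mg <- sum(g) / n
  vp <- sum((p - mp)^2) / n
  vg <- sum((g - mg)^2) / n
  cpg <- sum((p - mp) * (g - mg)) / n
  c1 <- (K1 * L)^2
  c2 <- (K2 * L)^2
  ((2 * mp * mg + c1) * (2 * cpg + c2)) /
    ((mp^2 + mg^2 + c1) * (vp + vg + c2))
}

# per-pixel summation cross-entropy
oracle_cross_entropy <- function(p, g, eps = 1e-7) {
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  g <- as.numeric(g)
  total <- 0
  for (i in seq_along(p)) {
    total <- total - (g[i] * log(p[i]) + (1 - g[i]) * log(1 - p[i]))
  }
  total / length(p)
}

# exhaustive confusion-table counting for one positive class
oracle_confusion <- function(predicted, truth, positive) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    if (predicted[i] == positive && truth[i] == positive) tp <- tp + 1
    if (predicted[i] != positive && truth[i] != positive) tn <- tn + 1
    if (predicted[i] == positive && truth[i] != positive) fp <- fp + 1
    if (predicted[i] != positive && truth[i] == positive) fn <- fn + 1
  }
  n <- length(truth)
  list(accuracy = (tp + tn) / n, precision = tp / (tp + fp),
       recall = tp / (tp + fn), specificity = tn / (tn + fp),
       f1 = 2 * tp / (2 * tp + fp + fn))
}

# brute-force rasterizer: count pixel centers inside an axis-aligned disk
oracle_disk_area <- function(h, w, cy, cx, radius) {
  count <- 0
  for (i in 0:(h - 1)) {
    for (j in 0:(w - 1)) {
      if ((i - cy)^2 + (j - cx)^2 <= radius^2) count <- count + 1
    }
  }
  count
}

# small deterministic phantom training set shared by segmenter tests
make_phantom_batch <- function(n, size = 32, seed0 = 500) {
  imgs <- array(0, dim = c(size, size, n))
  msks <- array(0, dim = c(size, size, n))
  for (i in seq_len(n)) {
    ph <- generate_phantom(phantom_spec(height = size, width = size,
                                        radius_range = c(4, 7),
                                        seed = seed0 + i))
    imgs[, , i] <- ph$image
    msks[, , i] <- ph$mask
  }
  list(images = imgs, masks = msks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
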