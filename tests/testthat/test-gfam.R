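test_that("autoencoder parameter count matches the closed form", {
  ae <- build_autoencoder(m = 500, k = 128, seed = 1)
  h <- ae$hidden
  expected <- (500 * h + h) + (h * 128 + 128) + (128 * h + h) + (h * 500 + 500)
  expect_equal(n_params(ae), expected)
  expect_equal(h, round(sqrt(500 * 128)))
})

test_that("latent width must compress strictly", {
  expect_silent(ae <- build_autoencoder(m = 10, k = 9))
  expect_error(build_autoencoder(m = 10, k = 10),
               class = "hepafuse_validation_error")
  expect_error(build_autoencoder(m = 10, k = 0),
               class = "hepafuse_validation_error")
})

test_that("training reduces reconstruction loss and is seed-reproducible", {
  co <- generate_genomic_cohort(cohort_spec(n_samples = 60, n_markers = 40,
                                            latent_rank = 4, n_subtypes = 4,
                                            seed = 2))
  run <- function() {
    ae <- build_autoencoder(m = 40, k = 8, seed = 2)
    train_autoencoder(ae, co$matrix, epochs = 30, batch_size = 16, seed = 2)
  }
  ae <- run()
  expect_lt(ae$history$recon[30], ae$history$recon[1])
  expect_identical(ae$history, run()$history)
})

test_that("encoding is deterministic with the promised shape", {
  co <- generate_genomic_cohort(cohort_spec(n_samples = 20, n_markers = 30,
                                            latent_rank = 3, n_subtypes = 2,
                                            seed = 3))
  ae <- build_autoencoder(m = 30, k = 5, seed = 3)
  ae <- train_autoencoder(ae, co$matrix, epochs = 10, seed = 3)
  z <- encode(ae, co$matrix)
  expect_equal(dim(z), c(20, 5))
  # duplicated rows encode identically
  x2 <- co$matrix[c(1, 1, 2), ]
  z2 <- encode(ae, x2)
  expect_identical(z2[1, ], z2[2, ])
  expect_error(encode(ae, co$matrix[, 1:10]),
               class = "hepafuse_validation_error")
  # tibble input with id columns is accepted
  z3 <- encode(ae, co$x)
  expect_equal(z3, z, ignore_attr = TRUE)
})

test_that("autoencoder approaches the best linear rank-k reconstruction", {
  co <- generate_genomic_cohort(cohort_spec(n_samples = 150, n_markers = 60,
                                            latent_rank = 4, n_subtypes = 4,
                                            seed = 4))
  k <- 8
  # reconstruction-fidelity check: dropout off so the comparison against the
  # unregularized linear optimum is like-for-like
  ae <- build_autoencoder(m = 60, k = k, dropout = 0, seed = 4)
  ae <- train_autoencoder(ae, co$matrix, epochs = 1000, batch_size = 32,
                          seed = 4)
  xs <- scale(co$matrix)
  sv <- svd(xs, nu = k, nv = k)
  pca_floor <- reconstruction_loss(xs, sv$u %*% diag(sv$d[1:k]) %*% t(sv$v))
  ae_loss <- reconstruction_loss(xs, reconstruct(ae, co$matrix,
                                                 destandardize = FALSE))
  expect_lte(ae_loss, 1.5 * pca_floor)
})

test_that("de-standardized reconstructions preserve column statistics", {
  co <- generate_genomic_cohort(cohort_spec(n_samples = 120, n_markers = 40,
                                            latent_rank = 3, n_subtypes = 4,
                                            marker_noise_sigma = 0, seed = 5))
  ae <- build_autoencoder(m = 40, k = 6, dropout = 0, seed = 5)
  ae <- train_autoencoder(ae, co$matrix, epochs = 400, batch_size = 32,
                          seed = 5)
  xhat <- reconstruct(ae, co$matrix)
  mu_rel <- abs(colMeans(xhat) - colMeans(co$matrix)) /
    pmax(apply(co$matrix, 2, stats::sd), 1e-9)
  v_rel <- abs(apply(xhat, 2, stats::var) - apply(co$matrix, 2, stats::var)) /
    pmax(apply(co$matrix, 2, stats::var), 1e-9)
  expect_lt(mean(mu_rel), 0.05)
  expect_lt(mean(v_rel), 0.05)
})

test_that("latent clustering recovers planted structure", {
  # two samples, two clusters: one per cluster
  z0 <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  expect_equal(sort(cluster_latent(z0, 2, seed = 1)), c(0, 1))
  expect_error(cluster_latent(z0, 1), class = "hepafuse_validation_error")
  expect_error(cluster_latent(z0, 3), class = "hepafuse_validation_error")
  # noiseless planted clusters are recovered exactly
  co <- generate_genomic_cohort(cohort_spec(n_samples = 30, n_markers = 30,
                                            latent_rank = 3, n_subtypes = 3,
                                            marker_noise_sigma = 0, seed = 6))
  ae <- build_autoencoder(m = 30, k = 4, seed = 6)
  ae <- train_autoencoder(ae, co$matrix, epochs = 40, seed = 6)
  cl <- cluster_latent(encode(ae, co$matrix), 3, seed = 6)
  expect_equal(mclust::adjustedRandIndex(cl, co$labels), 1)
})

test_that("cluster recovery improves with separation", {
  ari_at <- function(sep) {
    co <- generate_genomic_cohort(cohort_spec(
      n_samples = 90, n_markers = 40, latent_rank = 4, n_subtypes = 3,
      cluster_separation = sep, seed = 7))
    ae <- build_autoencoder(m = 40, k = 6, seed = 7)
    ae <- train_autoencoder(ae, co$matrix, epochs = 60, seed = 7)
    cl <- cluster_latent(encode(ae, co$matrix), 3, seed = 7)
    mclust::adjustedRandIndex(cl, co$labels)
  }
  aris <- vapply(c(0.5, 2, 6), ari_at, numeric(1))
  expect_true(all(diff(aris) >= 0))
  expect_gt(aris[3], aris[1])
})

test_that("marker ranking puts the cluster indicator first", {
  set.seed(8)
  n <- 60
  labels <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 4] <- labels  # a marker equal to the cluster indicator
  colnames(x) <- sprintf("m%02d", 1:10)
  z <- cbind(labels + rnorm(n, sd = 0.05), rnorm(n))
  rk <- rank_markers(x, z, labels)
  expect_equal(rk$marker[1], "m04")
  expect_equal(nrow(rk), 10)
  expect_setequal(rk$marker, colnames(x))
  expect_true(all(diff(rk$score) <= 1e-12))
})

test_that("pure-noise markers look like their permutation null", {
  set.seed(9)
  n <- 80
  labels <- rep(0:2, length.out = n)
  z <- cbind(labels + rnorm(n, sd = 0.2), rnorm(n), rnorm(n))
  x <- matrix(rnorm(n * 6), n, 6)  # all markers pure noise
  colnames(x) <- sprintf("m%d", 1:6)
  obs <- rank_markers(x, z, labels)$score
  null_scores <- replicate(1000, {
    xp <- x[sample(n), , drop = FALSE]
    max(rank_markers(xp, z, labels)$score)
  })
  # observed max score is not extreme under the permutation null
  expect_gt(mean(null_scores >= max(obs)), 0.05)
})

test_that("constant markers score zero and are flagged", {
  set.seed(10)
  labels <- rep(0:1, 10)
  x <- cbind(const = rep(1, 20), sig = labels + rnorm(20, sd = 0.1))
  z <- matrix(labels + rnorm(20, sd = 0.1), 20, 1)
  rk <- rank_markers(x, z, labels)
  expect_equal(rk$score[rk$marker == "const"], 0)
  expect_true(rk$constant[rk$marker == "const"])
  expect_equal(rk$marker[1], "sig")
})

test_that("tidy and glance summarize the fitted autoencoder", {
  co <- generate_genomic_cohort(cohort_spec(n_samples = 20, n_markers = 15,
                                            latent_rank = 2, n_subtypes = 2,
                                            seed = 11))
  ae <- build_autoencoder(m = 15, k = 3, seed = 11)
  ae <- train_autoencoder(ae, co$matrix, epochs = 5, seed = 11)
  td <- tidy(ae)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  gl <- glance(ae)
  expect_equal(gl$final_recon, td$recon[5])
  expect_equal(gl$k, 3)
})
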