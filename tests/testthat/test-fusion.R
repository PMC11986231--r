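test_that("image feature pooling is the per-channel spatial mean", {
  x <- array(0, dim = c(4, 4, 2, 3))
  x[, , 1, ] <- 2.5
  x[, , 2, ] <- -1
  pooled <- pool_image_features(x)
  expect_equal(pooled, matrix(c(2.5, -1), 3, 2, byrow = TRUE))
  expect_error(pool_image_features(list(prob = 1)),
               class = "hepafuse_validation_error")
  # pooling commutes with horizontal flipping of the feature map
  set.seed(1)
  y <- array(rnorm(4 * 4 * 2 * 2), dim = c(4, 4, 2, 2))
  expect_equal(pool_image_features(y),
               pool_image_features(y[, 4:1, , , drop = FALSE]))
})

test_that("projection is the stated affine map", {
  set.seed(2)
  img <- matrix(rnorm(12), 3, 4)
  gen <- matrix(rnorm(6), 3, 2)
  params <- list(Wimg = matrix(0, 4, 5), bimg = rep(0, 5),
                 Wgen = matrix(0, 2, 5), bgen = rep(0, 5))
  pr <- project_features(img, gen, params)
  expect_equal(pr$Fimg, matrix(0, 3, 5))
  # identity-like square projection passes features through
  p2 <- list(Wimg = diag(4), bimg = rep(0, 4), Wgen = diag(2) %x% c(1, 0),
             bgen = rep(0, 4))
  p2$Wgen <- matrix(0, 2, 4); p2$Wgen[1, 1] <- 1; p2$Wgen[2, 2] <- 1
  pr2 <- project_features(img, gen, p2)
  expect_equal(pr2$Fimg, img, ignore_attr = TRUE)
  # random fixed parameters match a direct matrix product
  p3 <- list(Wimg = matrix(rnorm(20), 4, 5), bimg = rnorm(5),
             Wgen = matrix(rnorm(10), 2, 5), bgen = rnorm(5))
  pr3 <- project_features(img, gen, p3)
  expect_equal(pr3$Fgen, sweep(gen %*% p3$Wgen, 2, p3$bgen, "+"))
  expect_error(project_features(img[, 1:2], gen, p3),
               class = "hepafuse_validation_error")
})

test_that("fusion is the convex combination with clamping", {
  proj <- list(Fimg = matrix(2, 1, 2), Fgen = matrix(0, 1, 2))
  expect_equal(fuse_features(proj, 1), proj$Fimg)
  expect_equal(fuse_features(proj, 0), proj$Fgen)
  expect_equal(fuse_features(proj, 0.5), matrix(1, 1, 2))
  expect_warning(out <- fuse_features(proj, 1.2), "clamped")
  expect_equal(out, proj$Fimg)
})

test_that("the sigmoid gate amplifies and suppresses as its saturation dictates", {
  set.seed(3)
  f <- matrix(rnorm(8), 2, 4)
  open_gate <- list(Wa = matrix(0, 4, 4), ba = rep(50, 4))
  expect_equal(attend_fused(f, open_gate), f, tolerance = 1e-9)
  closed <- list(Wa = matrix(0, 4, 4), ba = rep(-50, 4))
  expect_equal(attend_fused(f, closed), matrix(0, 2, 4), tolerance = 1e-9)
  # small fixed example against element-wise computation
  params <- list(Wa = diag(4), ba = rep(0.5, 4))
  got <- attend_fused(f, params)
  want <- f * stats::plogis(f %*% diag(4) + 0.5)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(abs(got) <= abs(f)))
})

test_that("softmax classification yields row-stochastic probabilities", {
  f <- matrix(rnorm(12), 3, 4)
  p <- classify_subtypes(f, matrix(0, 4, 4), rep(0, 4))
  expect_equal(p, matrix(0.25, 3, 4), ignore_attr = TRUE)
  p2 <- classify_subtypes(matrix(1, 1, 1), matrix(c(1, 0), 1, 2), c(0, 0))
  expect_equal(as.numeric(p2), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-9)
  set.seed(4)
  p3 <- classify_subtypes(matrix(rnorm(30, sd = 4), 10, 3),
                          matrix(rnorm(9), 3, 3), rnorm(3))
  expect_equal(rowSums(p3), rep(1, 10), tolerance = 1e-6)
  expect_true(all(p3 > 0 & p3 < 1))
})

test_that("fusion predictions are permutation-equivariant over samples", {
  set.seed(5)
  md <- build_fusion_model(4, 3, 2, d_f = 6, seed = 5)
  img <- matrix(rnorm(40), 10, 4)
  gen <- matrix(rnorm(30), 10, 3)
  p <- predict_subtypes(md, img, gen)
  perm <- sample(10)
  pp <- predict_subtypes(md, img[perm, ], gen[perm, ])
  expect_equal(pp$prob_0, p$prob_0[perm], tolerance = 1e-12)
})

test_that("with the weight frozen at 1 the genomic branch is inert", {
  set.seed(6)
  md <- build_fusion_model(4, 3, 2, d_f = 6, modality = "image", seed = 6)
  img <- matrix(rnorm(40), 10, 4)
  p1 <- predict_subtypes(md, img, matrix(rnorm(30), 10, 3))
  p2 <- predict_subtypes(md, img, matrix(rnorm(30, 100, 50), 10, 3))
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(fusion_alpha(md), 1)
  md0 <- build_fusion_model(4, 3, 2, d_f = 6, modality = "genomic", seed = 6)
  expect_equal(fusion_alpha(md0), 0)
})

test_that("an untrained classifier sits at prior-level accuracy", {
  set.seed(7)
  n <- 400
  labels <- rep(0:1, n / 2)
  md <- build_fusion_model(4, 3, 2, d_f = 8, seed = 7)
  p <- predict_subtypes(md, matrix(rnorm(n * 4), n, 4),
                        matrix(rnorm(n * 3), n, 3))
  acc <- mean(p$predicted_subtype == labels)
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("fusion training learns and records the weight trajectory", {
  set.seed(8)
  n <- 60
  labels <- rep(0:1, n / 2)
  img <- matrix(rnorm(n * 3), n, 3) + labels * 2  # informative image branch
  gen <- matrix(rnorm(n * 2), n, 2)               # pure noise genomic branch
  md <- build_fusion_model(3, 2, 2, d_f = 8, seed = 8)
  md <- train_fusion(md, img, gen, labels, epochs = 300, seed = 8)
  expect_lt(md$history$ce[300], md$history$ce[1])
  a <- fusion_alpha(md)
  expect_true(a > 0 && a < 1)
  # with only the image informative, the weight drifts upward
  expect_gt(a, md$history$alpha[1] - 0.05)
  p <- predict_subtypes(md, img, gen)
  expect_gt(mean(p$predicted_subtype == labels), 0.9)
  gl <- glance(md)
  expect_equal(gl$modality, "both")
  expect_equal(gl$fusion_alpha, a)
  expect_error(train_fusion(md, img, gen, labels + 5),
               class = "hepafuse_validation_error")
})

test_that("row-stochasticity holds after every training step", {
  set.seed(9)
  n <- 24
  labels <- rep(0:2, n / 3)
  img <- matrix(rnorm(n * 3), n, 3)
  gen <- matrix(rnorm(n * 2), n, 2)
  md <- build_fusion_model(3, 2, 3, d_f = 4, seed = 9)
  for (ep in 1:5) {
    md <- train_fusion(md, img, gen, labels, epochs = 1, batch_size = 8,
                       seed = ep)
    p <- predict_subtypes(md, img, gen)
    expect_equal(rowSums(as.matrix(p[, c("prob_0", "prob_1", "prob_2")])),
                 rep(1, n), tolerance = 1e-6)
  }
})
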