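test_that("spatial attention at zero input and zero bias is exactly 0.5", {
  x <- array(0, dim = c(3, 3, 2))
  params <- list(w1 = c(1, -1), b1 = 0, w2 = c(0.5, 2), b2 = 0)
  as_map <- spatial_attention(x, params)
  expect_equal(as_map, matrix(0.5, 3, 3))
})

test_that("spatial attention stays strictly inside (0, 1)", {
  set.seed(1)
  for (i in 1:5) {
    x <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
    params <- list(w1 = rnorm(3), b1 = rnorm(1), w2 = rnorm(3), b2 = rnorm(1))
    as_map <- spatial_attention(x, params)
    expect_true(all(as_map > 0 & as_map < 1))
  }
  expect_error(spatial_attention(x, list(w1 = rnorm(2), b1 = 0,
                                         w2 = rnorm(2), b2 = 0)),
               class = "hepafuse_validation_error")
})

test_that("spatial attention matches a scalar-by-scalar evaluation", {
  # fixed 2x2x2 feature map with hand-set unit weights
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8), dim = c(2, 2, 2))
  params <- list(w1 = c(1, 1), b1 = 0, w2 = c(1, -1), b2 = 0.5)
  out <- spatial_attention(x, params)
  for (i in 1:2) {
    for (j in 1:2) {
      f1 <- x[i, j, 1] * 1 + x[i, j, 2] * 1 + 0
      f2 <- x[i, j, 1] * 1 + x[i, j, 2] * (-1) + 0.5
      expect_equal(out[i, j], 1 / (1 + exp(-f1 * f2)))
    }
  }
})

test_that("channel attention reproduces the GAP -> MLP -> sigmoid form", {
  # all-zero input with zero biases gives 0.5 per channel
  x0 <- array(0, dim = c(3, 3, 4))
  params0 <- list(W1 = matrix(rnorm(4), 4, 1), b1 = 0,
                  W2 = matrix(rnorm(4), 1, 4), b2 = rep(0, 4))
  expect_equal(channel_attention(x0, params0, reduction_ratio = 4), rep(0.5, 4))

  # a constant channel pools to exactly its value; identity MLP passes it on
  x <- array(0, dim = c(2, 2, 2))
  x[, , 1] <- 0.3
  x[, , 2] <- -1.2
  params <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  ac <- channel_attention(x, params, reduction_ratio = 1)
  expect_equal(ac, stats::plogis(c(max(0.3, 0), max(-1.2, 0))))
  expect_true(all(ac > 0 & ac < 1))
  expect_error(channel_attention(x, params, reduction_ratio = 4),
               class = "hepafuse_validation_error")
})

test_that("combined attention is the broadcast weighted sum", {
  a_s <- matrix(1, 2, 2)
  expect_equal(combine_attention(a_s, c(0, 0), 0.6, 0.4),
               array(0.6, dim = c(2, 2, 2)))
  expect_equal(combine_attention(a_s, c(1, 1), 0.55, 0.45),
               array(1, dim = c(2, 2, 2)))
  # alpha = 1 reduces to the spatial map broadcast over channels
  a_s2 <- matrix(runif(4), 2, 2)
  out <- combine_attention(a_s2, c(0.9, 0.1), 1, 0)
  expect_equal(out[, , 1], a_s2)
  expect_equal(out[, , 2], a_s2)
  # element-wise: A[i,j,c] = alpha As[i,j] + beta Ac[c]
  out2 <- combine_attention(a_s2, c(0.9, 0.1), 0.6, 0.4)
  expect_equal(out2[1, 2, 2], 0.6 * a_s2[1, 2] + 0.4 * 0.1)
  expect_error(combine_attention(a_s, c(1, 1), -0.1, 0.4),
               class = "hepafuse_validation_error")
})

test_that("convex attention mixtures stay inside (0, 1)", {
  set.seed(2)
  for (i in 1:10) {
    a_s <- matrix(runif(9, 1e-3, 1 - 1e-3), 3, 3)
    a_c <- runif(4, 1e-3, 1 - 1e-3)
    alpha <- runif(1)
    out <- combine_attention(a_s, a_c, alpha, 1 - alpha)
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("feature refinement is an element-wise gate", {
  x <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  expect_equal(refine_features(x, array(1, dim = dim(x))), x)
  expect_equal(refine_features(x, array(0, dim = dim(x))),
               array(0, dim = dim(x)))
  a <- array(runif(12), dim = dim(x))
  expect_true(all(abs(refine_features(x, a)) <= abs(x)))
  expect_error(refine_features(x, array(1, dim = c(2, 2, 2))),
               class = "hepafuse_validation_error")
})

test_that("the backbone convolution agrees with a quadruple-loop oracle", {
  set.seed(3)
  x <- matrix(rnorm(25), 5, 5)
  w <- matrix(rnorm(9), 3, 3)
  b <- 0.7
  for (pad in c(0L, 1L)) {
    got <- hepafuse:::cpp_conv2d_forward(
      array(x, dim = c(5, 5, 1, 1)),
      array(w, dim = c(3, 3, 1, 1)), b, pad)
    want <- oracle_conv2d_1ch(x, w, b, pad)
    expect_equal(array(got, dim = dim(got))[, , 1, 1], want, tolerance = 1e-6)
  }
  # multi-channel case: sum of per-channel convolutions
  x2 <- array(rnorm(50), dim = c(5, 5, 2, 1))
  w2 <- array(rnorm(18), dim = c(3, 3, 2, 1))
  got <- hepafuse:::cpp_conv2d_forward(x2, w2, 0, 1L)
  want <- oracle_conv2d_1ch(x2[, , 1, 1], w2[, , 1, 1], 0, 1) +
    oracle_conv2d_1ch(x2[, , 2, 1], w2[, , 2, 1], 0, 1)
  expect_equal(got[, , 1, 1], want, tolerance = 1e-6)
})

test_that("forward_segment obeys its output contracts", {
  cfg <- segmenter_config(n_levels = 2, base_channels = 8)
  model <- build_segmenter(cfg, seed = 9)
  batch <- make_phantom_batch(3, size = 16)
  out <- forward_segment(model, batch$images)
  expect_equal(dim(out$prob), c(16, 16, 3))
  expect_true(all(out$prob > 0 & out$prob < 1))
  expect_length(out$depthset$projections, 2)
  expect_equal(dim(out$bottleneck_features), c(3, 16))
  # deterministic in eval mode
  out2 <- forward_segment(model, batch$images)
  expect_identical(out$prob, out2$prob)
  # shape must divide 2^(n_levels - 1)
  model3 <- build_segmenter(segmenter_config(n_levels = 3), seed = 1)
  expect_error(forward_segment(model3, array(0.5, dim = c(18, 18, 1))),
               class = "hepafuse_validation_error")
})

test_that("every parameter receives gradient on a random batch", {
  model <- build_segmenter(segmenter_config(n_levels = 3, base_channels = 16,
                                            hdfo_weights = c(1, 1, 1) / 3),
                           seed = 4)
  set.seed(4)
  x <- array(runif(16 * 16 * 4), dim = c(16, 16, 1, 4))
  g <- array((array(runif(16 * 16 * 4), dim = c(16, 16, 4)) > 0.7) * 1,
             dim = c(16, 16, 1, 4))
  fw <- hepafuse:::segmenter_graph(model, hepafuse:::ag_const(x),
                                   training = TRUE)
  loss <- hepafuse:::hybrid_loss_graph(fw$logits, fw$prob, g, loss_weights(),
                                       model$config$hdfo_weights,
                                       fw$aux_logits)$total
  hepafuse:::ag_backward(loss)
  sizes <- vapply(model$params, function(p) max(abs(p$grad)), numeric(1))
  expect_true(all(is.finite(sizes)))
  expect_true(all(sizes > 0))
})

test_that("forward_segment is equivariant to horizontal flip under symmetric kernels", {
  model <- build_segmenter(segmenter_config(n_levels = 2, base_channels = 8),
                           seed = 11)
  # symmetrize every 3x3 kernel left-right; 1x1 kernels are trivially symmetric
  walk <- function(o) {
    if (is.list(o) && !is.null(o$w) && hepafuse:::is_ag(o$w)) {
      d <- dim(o$w$value)
      if (d[2] == 3) o$w$value <- (o$w$value + o$w$value[, 3:1, , , drop = FALSE]) / 2
    } else if (is.list(o)) lapply(o, walk)
    invisible(NULL)
  }
  walk(model[c("enc", "dec", "att", "aux", "head")])
  batch <- make_phantom_batch(2, size = 16)
  p <- forward_segment(model, batch$images)$prob
  flipped <- batch$images[, 16:1, , drop = FALSE]
  pf <- forward_segment(model, flipped)$prob
  expect_equal(pf[, 16:1, ], p, tolerance = 1e-10)
})

test_that("training reduces the hybrid loss on a small phantom set", {
  batch <- make_phantom_batch(16, size = 32)
  model <- build_segmenter(segmenter_config(n_levels = 2, base_channels = 8),
                           seed = 5)
  model <- train_segmenter(model, batch$images, batch$masks, epochs = 4,
                           batch_size = 8, seed = 5)
  expect_lt(model$history$total[4], model$history$total[1])
  expect_true(all(is.finite(model$history$total)))
})

test_that("training is reproducible under a fixed seed", {
  batch <- make_phantom_batch(8, size = 16)
  run <- function() {
    m <- build_segmenter(segmenter_config(n_levels = 2, base_channels = 8),
                         seed = 6)
    m <- train_segmenter(m, batch$images, batch$masks, epochs = 2,
                         batch_size = 4, seed = 6)
    m$history
  }
  expect_identical(run(), run())
})
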