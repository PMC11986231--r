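test_that("phantom with no tumors is pure textured background", {
  ph <- generate_phantom(phantom_spec(n_tumors = 0, seed = 3))
  expect_true(all(ph$mask == 0))
  expect_true(all(ph$image >= 0 & ph$image <= 1))
  expect_gt(stats::sd(ph$image), 0)
})

test_that("phantom generation is a pure function of (spec, seed)", {
  spec <- phantom_spec(n_tumors = 2, seed = 17)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_phantom(phantom_spec(n_tumors = 2, seed = 18))
  expect_false(identical(a$image, c$image))
})

test_that("smooth circular lesion area matches the analytic disk", {
  # radius fixed at 10 px, no eccentricity or boundary perturbation
  spec <- phantom_spec(height = 64, width = 64, radius_range = c(10, 10),
                       eccentricity_range = c(0, 0), boundary_irregularity = 0,
                       seed = 5)
  ph <- generate_phantom(spec)
  area <- sum(ph$mask)
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.05)
  # and against the brute-force rasterizer at the same center
  for (s in 1:5) {
    ph <- generate_phantom(phantom_spec(height = 64, width = 64,
                                        radius_range = c(10, 10),
                                        eccentricity_range = c(0, 0),
                                        boundary_irregularity = 0, seed = s))
    expect_lt(abs(sum(ph$mask) - pi * 100) / (pi * 100), 0.05)
  }
})

test_that("degenerate phantom specs are rejected", {
  expect_error(phantom_spec(height = 16, width = 16, radius_range = c(2, 10)),
               class = "hepafuse_validation_error")
  expect_error(phantom_spec(radius_range = c(9, 6)),
               class = "hepafuse_validation_error")
  expect_error(phantom_spec(eccentricity_range = c(0, 1)),
               class = "hepafuse_validation_error")
})

test_that("noiseless cohort rows are identical within a subtype", {
  co <- generate_genomic_cohort(cohort_spec(n_samples = 12, n_markers = 30,
                                            latent_rank = 3, n_subtypes = 3,
                                            marker_noise_sigma = 0, seed = 2))
  for (s in 0:2) {
    rows <- co$matrix[co$labels == s, , drop = FALSE]
    expect_true(all(abs(sweep(rows, 2, rows[1, ])) < 1e-12))
  }
  expect_gt(sum(abs(co$matrix[co$labels == 0, ][1, ] -
                      co$matrix[co$labels == 1, ][1, ])), 1)
})

test_that("empirical rank of the noiseless matrix equals the latent rank", {
  # needs at least as many subtypes as latent dimensions for full rank
  co <- generate_genomic_cohort(cohort_spec(n_samples = 40, n_markers = 25,
                                            latent_rank = 4, n_subtypes = 5,
                                            marker_noise_sigma = 0, seed = 9))
  sv <- svd(co$matrix)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 4)
})

test_that("cohort generation is deterministic and balanced", {
  spec <- cohort_spec(n_samples = 10, n_markers = 20, latent_rank = 3,
                      n_subtypes = 3, seed = 4)
  a <- generate_genomic_cohort(spec)
  b <- generate_genomic_cohort(spec)
  expect_identical(a$matrix, b$matrix)
  counts <- table(a$labels)
  expect_lte(max(counts) - min(counts), 1)
  expect_error(cohort_spec(n_samples = 2, n_subtypes = 5, n_markers = 10,
                           latent_rank = 2),
               class = "hepafuse_validation_error")
  expect_error(cohort_spec(n_markers = 10, latent_rank = 10),
               class = "hepafuse_validation_error")
})

test_that("latent silhouette grows with cluster separation", {
  sil_for <- function(sep) {
    co <- generate_genomic_cohort(cohort_spec(
      n_samples = 60, n_markers = 40, latent_rank = 4, n_subtypes = 3,
      cluster_separation = sep, marker_noise_sigma = 1, seed = 21))
    # silhouette in the latent factor geometry: project data onto the
    # centroid subspace via SVD scores
    sc <- svd(scale(co$matrix, scale = FALSE))$u[, 1:4]
    d <- as.matrix(stats::dist(sc))
    sil <- vapply(seq_len(nrow(sc)), function(i) {
      own <- mean(d[i, co$labels == co$labels[i] &
                      seq_along(co$labels) != i])
      other <- min(vapply(setdiff(unique(co$labels), co$labels[i]),
                          function(s) mean(d[i, co$labels == s]), numeric(1)))
      (other - own) / max(own, other)
    }, numeric(1))
    mean(sil)
  }
  sils <- vapply(c(1, 2.5, 6), sil_for, numeric(1))
  expect_true(all(diff(sils) > 0))
})

test_that("joint_xor truth table has the designed ceilings", {
  # enumerate the rule over the full (M, C) grid
  M <- rep(0:1, each = 4)
  C <- rep(0:3, 2)
  lab <- hepafuse:::joint_rule_label("joint_xor", M, C)
  expect_equal(sum(lab), 4)  # balanced
  # joint knowledge determines the label exactly
  expect_equal(length(unique(paste(M, C, lab))), 8)
  # best single-modality accuracy: 0.75 from either side
  best_m <- sum(vapply(0:1, function(v) max(table(lab[M == v])), numeric(1))) / 8
  best_c <- sum(vapply(0:3, function(v) max(table(lab[C == v])), numeric(1))) / 8
  expect_equal(best_m, 0.75)
  expect_equal(best_c, 0.75)
})

test_that("paired cohorts respect the labeling rule and balance", {
  ph <- phantom_spec(height = 32, width = 32, radius_range = c(3, 9), seed = 2)
  co <- cohort_spec(n_samples = 16, n_markers = 20, latent_rank = 3,
                    n_subtypes = 4, seed = 2)
  pc <- generate_paired_cohort(ph, co, joint_rule = "joint_xor")
  expect_equal(length(pc$samples), 16)
  relab <- hepafuse:::joint_rule_label("joint_xor", pc$morph_strata,
                                       pc$genomic_clusters)
  expect_equal(pc$labels, relab)
  expect_lte(abs(sum(pc$labels == 0) - sum(pc$labels == 1)), 1)

  co2 <- cohort_spec(n_samples = 4, n_markers = 20, latent_rank = 3,
                     n_subtypes = 2, seed = 2)
  pc2 <- generate_paired_cohort(ph, co2, joint_rule = "image_only")
  expect_equal(sort(pc2$labels), c(0, 0, 1, 1))
  expect_equal(pc2$labels, pc2$morph_strata)

  pc3 <- generate_paired_cohort(ph, co2, joint_rule = "genomic_only")
  expect_equal(pc3$labels, pc3$genomic_clusters)

  expect_error(generate_paired_cohort(ph, co2, joint_rule = "joint_xor"),
               class = "hepafuse_validation_error")
  expect_error(generate_paired_cohort(ph, co, joint_rule = "nope"))
})

test_that("image-only labels track the tumor size stratum", {
  ph <- phantom_spec(height = 48, width = 48, radius_range = c(4, 13), seed = 6)
  co <- cohort_spec(n_samples = 12, n_markers = 20, latent_rank = 3,
                    n_subtypes = 2, seed = 6)
  pc <- generate_paired_cohort(ph, co, joint_rule = "image_only")
  areas <- vapply(pc$samples, function(s) sum(s$mask), numeric(1))
  expect_gt(min(areas[pc$labels == 1]), max(areas[pc$labels == 0]))
})
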