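# Synthetic paired imaging-genomic cohorts with planted subtype structure.
# Phantoms emulate tomographic slices: a smoothed random-field background plus
# one or more blob lesions with controllable size, eccentricity and boundary
# irregularity. Genomic cohorts follow a low-rank latent factor model whose
# subtype centroids are separated by a controllable multiple of the marker
# noise. Every generator is a pure function of (spec, seed).

#' Specification of a synthetic phantom slice
#'
#' @param height,width image size in pixels (default 64 x 64, the desk-scale
#'   stand-in for full-resolution tomographic slices).
#' @param n_tumors number of lesions (>= 0).
#' @param radius_range lesion radius range in pixels, `c(lo, hi)`.
#' @param eccentricity_range axis-ratio eccentricity range in \[0, 1).
#' @param boundary_irregularity amplitude of the radial sinusoid perturbation
#'   of the lesion boundary, as a fraction of the radius (0 = smooth ellipse).
#' @param tumor_contrast intensity offset added inside the lesion (positive =
#'   bright lesion) before clipping to \[0, 1\].
#' @param background_texture_scale correlation length (pixels) of the smoothed
#'   random-field background texture.
#' @param noise_sigma standard deviation of the additive Gaussian pixel noise.
#' @param seed integer seed; the same spec and seed give bit-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64, n_tumors = 1,
                         radius_range = c(6, 14),
                         eccentricity_range = c(0, 0.4),
                         boundary_irregularity = 0.15,
                         tumor_contrast = 0.35,
                         background_texture_scale = 8,
                         noise_sigma = 0.05,
                         seed = 1L) {
  if (height < 1 || width < 1) stop_invalid("image dimensions must be >= 1")
  if (n_tumors < 0) stop_invalid("n_tumors must be >= 0")
  check_range(radius_range[1], radius_range[2], "radius")
  check_range(eccentricity_range[1], eccentricity_range[2], "eccentricity")
  if (eccentricity_range[2] >= 1 || eccentricity_range[1] < 0) {
    stop_invalid("eccentricity must lie in [0, 1)")
  }
  if (2 * radius_range[2] >= min(height, width)) {
    stop_invalid("largest radius (%g px) does not fit a %d x %d image",
                 radius_range[2], height, width)
  }
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_tumors = as.integer(n_tumors), radius_range = radius_range,
    eccentricity_range = eccentricity_range,
    boundary_irregularity = boundary_irregularity,
    tumor_contrast = tumor_contrast,
    background_texture_scale = background_texture_scale,
    noise_sigma = noise_sigma, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# smoothed white noise background via separable box-blur passes
smooth_field <- function(h, w, scale) {
  x <- matrix(stats::rnorm(h * w), h, w)
  if (scale <= 1) return(x)
  k <- max(3L, 2L * as.integer(scale %/% 2L) + 1L)
  box <- function(m) {
    cs <- apply(m, 2, function(col) {
      n <- length(col)
      padded <- c(rep(col[1], k %/% 2), col, rep(col[n], k %/% 2))
      as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))[
        (k %/% 2 + 1):(k %/% 2 + n)]
    })
    cs
  }
  x <- box(x)       # columns
  t(box(t(x)))      # rows
}

# rasterize one irregular ellipse: pixel centers with polar radius below the
# perturbed boundary are inside. 0-based pixel coordinates, origin top-left.
raster_blob <- function(h, w, cy, cx, radius, ecc, irregularity, phases, harmonics,
                        amps, theta0) {
  ys <- matrix(seq_len(h) - 1, h, w)
  xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  dy <- ys - cy
  dx <- xs - cx
  # rotate into the ellipse frame
  ry <- cos(theta0) * dy - sin(theta0) * dx
  rx <- sin(theta0) * dy + cos(theta0) * dx
  b_axis <- radius * sqrt(1 - ecc^2)
  r_ell <- sqrt((rx / radius)^2 + (ry / b_axis)^2)  # 1 on the smooth boundary
  if (irregularity > 0 && length(harmonics)) {
    ang <- atan2(ry, rx)
    pert <- rep(0, length(ang))
    for (i in seq_along(harmonics)) {
      pert <- pert + amps[i] * sin(harmonics[i] * ang + phases[i])
    }
    boundary <- 1 + irregularity * matrix(pert, h, w)
  } else {
    boundary <- 1
  }
  r_ell <= boundary
}

#' Generate a phantom image and its ground-truth mask
#'
#' The image is a textured background (smoothed Gaussian random field mapped
#' to mid-grey) plus `tumor_contrast` inside the lesion mask plus additive
#' Gaussian noise, clipped to \[0, 1\]. The mask is the union of the lesion
#' interiors.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `image` (H x W matrix in \[0, 1\]) and `mask`
#'   (binary H x W matrix).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("spec must be a phantom_spec")
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    bg <- smooth_field(h, w, spec$background_texture_scale)
    bg <- 0.45 + 0.1 * bg / max(stats::sd(bg), 1e-12)
    mask <- matrix(0, h, w)
    if (spec$n_tumors > 0) {
      for (t in seq_len(spec$n_tumors)) {
        radius <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
        ecc <- stats::runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
        # keep the lesion inside the frame; on tight frames fall back to the
        # central pixel rather than sampling an empty interval
        margin <- radius + 2
        cy <- if (margin <= h - 1 - margin) {
          stats::runif(1, margin, h - 1 - margin)
        } else {
          stats::runif(1)  # keep the RNG stream aligned
          (h - 1) / 2
        }
        cx <- if (margin <= w - 1 - margin) {
          stats::runif(1, margin, w - 1 - margin)
        } else {
          stats::runif(1)
          (w - 1) / 2
        }
        theta0 <- stats::runif(1, 0, pi)
        nh <- sample(2:4, 1)
        harmonics <- sample(2:6, nh)
        phases <- stats::runif(nh, 0, 2 * pi)
        amps <- stats::runif(nh)
        amps <- amps / sum(amps)
        inside <- raster_blob(h, w, cy, cx, radius, ecc,
                              spec$boundary_irregularity,
                              phases, harmonics, amps, theta0)
        mask[inside] <- 1
      }
    }
    img <- bg + spec$tumor_contrast * mask
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
    }
    list(image = pmin(pmax(img, 0), 1), mask = mask)
  })
}

#' Specification of a synthetic genomic cohort
#'
#' Samples are drawn from a low-rank latent factor model: each sample's latent
#' row is exactly its subtype centroid (an r-dimensional point), mapped to
#' marker space through a fixed dense loading matrix with i.i.d. standard
#' normal entries, plus i.i.d. Gaussian marker noise. All within-subtype
#' variance therefore comes from the marker noise; `cluster_separation` is
#' the pairwise centroid distance in latent units, and with unit-variance
#' loadings it is also the scale of the per-marker subtype signal relative
#' to `marker_noise_sigma`.
#'
#' @param n_samples number of samples.
#' @param n_markers number of molecular markers (m).
#' @param latent_rank rank r of the factor model (< n_markers).
#' @param n_subtypes number of planted subtypes (>= 2); labels are balanced
#'   within one sample by round-robin assignment.
#' @param cluster_separation pairwise centroid distance in latent units
#'   (default 6, i.e. six marker-noise standard deviations — well-separated
#'   molecular subtypes).
#' @param marker_noise_sigma marker noise standard deviation (default 1).
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 120, n_markers = 200, latent_rank = 8,
                        n_subtypes = 3, cluster_separation = 6,
                        marker_noise_sigma = 1, seed = 1L) {
  if (latent_rank >= n_markers) stop_invalid("latent_rank must be < n_markers")
  if (n_subtypes < 2) stop_invalid("n_subtypes must be >= 2")
  if (n_subtypes > n_samples) stop_invalid("more subtypes than samples")
  if (cluster_separation < 0 || marker_noise_sigma < 0) {
    stop_invalid("separation and noise must be non-negative")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_markers = as.integer(n_markers),
    latent_rank = as.integer(latent_rank), n_subtypes = as.integer(n_subtypes),
    cluster_separation = cluster_separation,
    marker_noise_sigma = marker_noise_sigma, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# S centroids in R^r with all pairwise distances equal to `sep`: a regular
# simplex scaled to edge length sep, embedded in the first min(S, r) coords.
simplex_centroids <- function(S, r, sep) {
  if (S > r + 1) {
    # no equidistant configuration exists; fall back to random directions
    # scaled so the *minimum* pairwise distance is sep
    C <- matrix(stats::rnorm(S * r), S, r)
    d <- as.matrix(stats::dist(C))
    diag(d) <- Inf
    C * (sep / min(d))
  } else {
    C <- diag(1, S)[, seq_len(min(S, r)), drop = FALSE]  # S unit vectors
    C <- C - matrix(colMeans(C), S, min(S, r), byrow = TRUE)
    C <- C * (sep / sqrt(2))  # edge of identity simplex is sqrt(2)
    cbind(C, matrix(0, S, r - ncol(C)))
  }
}

# balanced round-robin subtype labels 0..S-1
round_robin_labels <- function(n, S) rep(seq_len(S) - 1L, length.out = n)

#' Generate a synthetic genomic cohort with planted subtypes
#'
#' @param spec a [cohort_spec()].
#' @return a list with `x` (a tibble: `sample_id`, `subtype_label`, and
#'   `n_markers` marker columns), `matrix` (the raw n x m numeric matrix),
#'   `labels` (0-based integer subtype labels) and `centroids`.
#' @export
generate_genomic_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_invalid("spec must be a cohort_spec")
  withr::with_seed(spec$seed, {
    n <- spec$n_samples; m <- spec$n_markers; r <- spec$latent_rank
    S <- spec$n_subtypes
    centroids <- simplex_centroids(S, r, spec$cluster_separation)
    labels <- round_robin_labels(n, S)
    Z <- centroids[labels + 1L, , drop = FALSE]
    # dense i.i.d. N(0,1) loadings: every marker loads on all latent factors,
    # as co-expressed marker modules do, so the planted structure dominates
    # the per-marker noise
    L <- matrix(stats::rnorm(m * r), m, r)
    X <- Z %*% t(L)
    if (spec$marker_noise_sigma > 0) {
      X <- X + matrix(stats::rnorm(n * m, sd = spec$marker_noise_sigma), n, m)
    }
    colnames(X) <- sprintf("marker_%03d", seq_len(m))
    tb <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)),
                     subtype_label = labels),
      tibble::as_tibble(X)
    )
    list(x = tb, matrix = X, labels = labels, centroids = centroids)
  })
}

# truth table of the joint labeling rules. M = morphology stratum (0 = small
# lesion, 1 = large), C = genomic cluster. joint_xor needs 4 genomic clusters
# and gives: label = M when C in {0,1}, 0 when C = 2, 1 when C = 3 — joint
# accuracy 1.0, either-modality ceiling exactly 0.75, balanced labels.
joint_rule_label <- function(rule, M, C) {
  switch(rule,
    image_only = M,
    genomic_only = C,
    joint_xor = ifelse(C <= 1L, M, ifelse(C == 2L, 0L, 1L)),
    stop_invalid("unknown joint_rule '%s'", rule)
  )
}

#' Generate a paired imaging-genomic cohort
#'
#' Produces one phantom image + mask per sample together with a genomic
#' cohort, and assigns each sample a subtype label through `joint_rule`:
#'
#' * `"image_only"`: the label is the binary tumor-size stratum (small vs
#'   large lesion radius).
#' * `"genomic_only"`: the label is the planted genomic cluster.
#' * `"joint_xor"`: with 4 genomic clusters `C` and binary size stratum `M`,
#'   the label is `M` for `C` in \{0, 1\}, `0` for `C = 2`, `1` for `C = 3`.
#'   Neither modality alone determines the label (each has a designed ceiling
#'   of 0.75 accuracy) while both together determine it exactly — the
#'   property the fusion benchmark exploits.
#'
#' Strata are assigned round-robin over the (M, C) grid, so labels are
#' balanced. The size strata draw radii from the lower third (stratum 0) and
#' upper third (stratum 1) of `phantom$radius_range`.
#'
#' @param phantom a [phantom_spec()] template (its `n_tumors` is forced to 1).
#' @param cohort a [cohort_spec()]; for `joint_xor` its `n_subtypes` must be 4.
#' @param joint_rule one of `"image_only"`, `"genomic_only"`, `"joint_xor"`.
#' @return a list of class `paired_cohort`: `samples` (list of per-sample
#'   lists with `image`, `mask`, `genomic_row`, `subtype_label`,
#'   `morph_stratum`, `genomic_cluster`), `genomic` (tibble), `labels`,
#'   `n_classes`, and the specs.
#' @export
generate_paired_cohort <- function(phantom, cohort,
                                   joint_rule = c("joint_xor", "image_only",
                                                  "genomic_only")) {
  joint_rule <- match.arg(joint_rule)
  if (!inherits(phantom, "phantom_spec")) stop_invalid("phantom must be a phantom_spec")
  if (!inherits(cohort, "cohort_spec")) stop_invalid("cohort must be a cohort_spec")
  if (cohort$n_samples < 1) stop_invalid("need at least one sample")
  if (joint_rule == "joint_xor" && cohort$n_subtypes != 4L) {
    stop_invalid("joint_xor requires 4 genomic clusters (cohort n_subtypes = 4)")
  }
  n <- cohort$n_samples
  S_gen <- cohort$n_subtypes
  # round-robin over the (M, C) grid keeps every stratum combination balanced
  combo <- (seq_len(n) - 1L) %% (2L * S_gen)
  M <- combo %/% S_gen
  C <- combo %% S_gen
  withr::with_seed(cohort$seed, {
    perm <- sample.int(n)
  })
  M <- M[perm]; C <- C[perm]

  # genomic rows: same factor model as generate_genomic_cohort but with
  # cluster assignments C
  gen <- withr::with_seed(cohort$seed + 1L, {
    r <- cohort$latent_rank; m <- cohort$n_markers
    centroids <- simplex_centroids(S_gen, r, cohort$cluster_separation)
    L <- matrix(stats::rnorm(m * r), m, r)
    X <- centroids[C + 1L, , drop = FALSE] %*% t(L)
    if (cohort$marker_noise_sigma > 0) {
      X <- X + matrix(stats::rnorm(n * m, sd = cohort$marker_noise_sigma), n, m)
    }
    colnames(X) <- sprintf("marker_%03d", seq_len(m))
    X
  })

  labels <- joint_rule_label(joint_rule, M, C)
  rr <- phantom$radius_range
  third <- (rr[2] - rr[1]) / 3
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    ri <- if (M[i] == 0L) c(rr[1], rr[1] + third) else c(rr[2] - third, rr[2])
    ps <- phantom_spec(
      height = phantom$height, width = phantom$width, n_tumors = 1,
      radius_range = ri, eccentricity_range = phantom$eccentricity_range,
      boundary_irregularity = phantom$boundary_irregularity,
      tumor_contrast = phantom$tumor_contrast,
      background_texture_scale = phantom$background_texture_scale,
      noise_sigma = phantom$noise_sigma, seed = phantom$seed + i
    )
    ph <- generate_phantom(ps)
    samples[[i]] <- list(
      image = ph$image, mask = ph$mask, genomic_row = gen[i, ],
      subtype_label = labels[i], morph_stratum = M[i], genomic_cluster = C[i]
    )
  }
  genomic_tb <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)),
                   subtype_label = labels),
    tibble::as_tibble(gen)
  )
  structure(list(
    samples = samples, genomic = genomic_tb, genomic_matrix = gen,
    labels = labels, morph_strata = M, genomic_clusters = C,
    n_classes = length(unique(joint_rule_label(joint_rule,
                                               rep(0:1, each = S_gen),
                                               rep(0:(S_gen - 1L), 2L)))),
    joint_rule = joint_rule, phantom_spec = phantom, cohort_spec = cohort
  ), class = "paired_cohort")
}

#' Stack a paired cohort's images and masks into arrays
#'
#' @param cohort a `paired_cohort`.
#' @param idx sample indices (default all).
#' @return list with `images` ((H, W, 1, N) array, the segmenter's input
#'   layout) and `masks` ((H, W, N) binary array).
#' @export
cohort_image_array <- function(cohort, idx = NULL) {
  idx <- idx %||% seq_along(cohort$samples)
  h <- nrow(cohort$samples[[1]]$image)
  w <- ncol(cohort$samples[[1]]$image)
  x <- array(0, dim = c(h, w, 1, length(idx)))
  g <- array(0, dim = c(h, w, length(idx)))
  for (k in seq_along(idx)) {
    x[, , 1, k] <- cohort$samples[[idx[k]]]$image
    g[, , k] <- cohort$samples[[idx[k]]]$mask
  }
  list(images = x, masks = g)
}
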