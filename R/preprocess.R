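# Intensity normalization and paired geometric augmentation.

#' Min-max intensity normalization
#'
#' Rescales a slice to \[0, 1\] as `(X - Xmin) / (Xmax - Xmin)`. A constant
#' slice (the formula's undefined case) maps to all zeros with a warning
#' rather than an error, so batch pipelines survive blank slices.
#'
#' @param image numeric matrix (H x W) with finite entries.
#' @return matrix of the same shape with entries in \[0, 1\]; for non-constant
#'   input the minimum is exactly 0 and the maximum exactly 1.
#' @export
#' @examples
#' normalize_intensity(matrix(c(0, 5, 10, 20), 2, 2, byrow = TRUE))
normalize_intensity <- function(image) {
  image <- as.matrix(image)
  check_finite(image, "image")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: normalization returns all zeros", call. = FALSE)
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Specification of a random paired augmentation
#'
#' Holds the draw ranges of the train-time augmentation: rotation uniform in
#' `rotation_range` degrees (default +/- 15), isotropic scaling uniform in
#' `scale_range` (default 0.8-1.2), and independent coin-flip horizontal /
#' vertical flips where enabled.
#'
#' @param rotation_range degrees, `c(lo, hi)`.
#' @param scale_range scale factor range, `c(lo, hi)`.
#' @param flip_horizontal,flip_vertical whether each flip may be drawn.
#' @param seed integer seed for the draw.
#' @export
augmentation_spec <- function(rotation_range = c(-15, 15),
                              scale_range = c(0.8, 1.2),
                              flip_horizontal = TRUE, flip_vertical = TRUE,
                              seed = 1L) {
  check_range(rotation_range[1], rotation_range[2], "rotation")
  check_range(scale_range[1], scale_range[2], "scale")
  if (scale_range[1] <= 0) stop_invalid("scale must be positive")
  structure(list(rotation_range = rotation_range, scale_range = scale_range,
                 flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical, seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' @rdname augmentation_spec
#' @param spec an `augmentation_spec`.
#' @return `draw_augmentation()`: a list with the drawn `rotation`, `scale`,
#'   `flip_h`, `flip_v`.
#' @export
draw_augmentation <- function(spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  withr::with_seed(spec$seed, {
    list(
      rotation = stats::runif(1, spec$rotation_range[1], spec$rotation_range[2]),
      scale = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
      flip_h = spec$flip_horizontal && stats::runif(1) < 0.5,
      flip_v = spec$flip_vertical && stats::runif(1) < 0.5
    )
  })
}

# inverse-map resampling shared by image (bilinear) and mask (nearest).
# Transform order is rotate, then scale, then flip (innermost first), all
# about the image center; out-of-range samples fill with 0 (the normalized
# background floor). 0-based pixel coordinates.
resample_affine <- function(x, rotation, scale, flip_h, flip_v, bilinear) {
  h <- nrow(x); w <- ncol(x)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  yo <- matrix(seq_len(h) - 1, h, w) - cy
  xo <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - cx
  # invert flips (involutions), then scale, then rotation
  if (flip_h) xo <- -xo
  if (flip_v) yo <- -yo
  yo <- yo / scale
  xo <- xo / scale
  th <- -rotation * pi / 180  # inverse rotation
  ys <- cos(th) * yo - sin(th) * xo + cy
  xs <- sin(th) * yo + cos(th) * xo + cx
  out <- matrix(0, h, w)
  if (bilinear) {
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    for (dy in 0:1) {
      for (dx in 0:1) {
        yy <- y0 + dy; xx <- x0 + dx
        wgt <- (if (dy == 0) 1 - fy else fy) * (if (dx == 0) 1 - fx else fx)
        ok <- yy >= 0 & yy < h & xx >= 0 & xx < w & wgt > 0
        if (any(ok)) {
          out[ok] <- out[ok] + wgt[ok] * x[cbind(yy[ok] + 1, xx[ok] + 1)]
        }
      }
    }
  } else {
    yy <- round(ys); xx <- round(xs)
    ok <- yy >= 0 & yy < h & xx >= 0 & xx < w
    out[ok] <- x[cbind(yy[ok] + 1, xx[ok] + 1)]
  }
  out
}

#' Apply one geometric augmentation identically to an image and its mask
#'
#' Applies rotation, then scaling, then flips (innermost transform first),
#' all about the image center, with output cropped/padded to the input shape.
#' The image is resampled bilinearly and re-clipped to \[0, 1\]; the mask is
#' resampled by nearest neighbour and re-binarized at 0.5, so it stays
#' strictly binary. Out-of-frame regions fill with 0.
#'
#' @param image normalized H x W matrix in \[0, 1\].
#' @param mask binary H x W matrix of the same shape.
#' @param rotation degrees counter-clockwise.
#' @param scale isotropic scale factor (> 0).
#' @param flip_h,flip_v horizontal / vertical flip.
#' @return list with transformed `image` and `mask`.
#' @export
apply_augmentation <- function(image, mask, rotation = 0, scale = 1,
                               flip_h = FALSE, flip_v = FALSE) {
  image <- as.matrix(image); mask <- as.matrix(mask)
  check_same_shape(image, mask, "image and mask")
  check_binary(mask)
  if (scale <= 0) stop_invalid("scale must be positive")
  img <- resample_affine(image, rotation, scale, flip_h, flip_v, bilinear = TRUE)
  msk <- resample_affine(mask, rotation, scale, flip_h, flip_v, bilinear = FALSE)
  list(image = pmin(pmax(img, 0), 1), mask = (msk >= 0.5) * 1)
}

#' @rdname apply_augmentation
#' @param spec an [augmentation_spec()]; the transform parameters are drawn
#'   from it deterministically (same spec + seed, same draw).
#' @export
augment_pair <- function(image, mask, spec) {
  d <- draw_augmentation(spec)
  apply_augmentation(image, mask, rotation = d$rotation, scale = d$scale,
                     flip_h = d$flip_h, flip_v = d$flip_v)
}

#' Read a 2-D slice from disk
#'
#' Supports PNG (via \pkg{png}; RGB(A) images are converted to grayscale by
#' channel averaging) and NIfTI `.nii`/`.nii.gz` (via \pkg{RNifti}; the volume
#' must be a single slice, i.e. 2-D or with singleton trailing dimensions).
#' DICOM input is not supported by this build — no DICOM reader is among the
#' package's dependencies; convert such slices to PNG or NIfTI first.
#'
#' @param path file path.
#' @return numeric H x W matrix of raw intensities.
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE], c(1, 2), mean)
    return(as.matrix(x))
  }
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    x <- drop(as.array(RNifti::readNifti(path)))
    if (length(dim(x)) != 2L) {
      stop_invalid("NIfTI volume at %s is not a single 2-D slice", path)
    }
    return(matrix(as.numeric(x), nrow(x), ncol(x)))
  }
  if (grepl("\\.dcm$", lower)) {
    stop_invalid("DICOM is not supported; convert %s to PNG or NIfTI", path)
  }
  stop_invalid("unrecognized image format: %s", path)
}
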