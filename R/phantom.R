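#' Phantom generator configuration
#'
#' Settings for the synthetic ultrasound-phantom generator. Each phantom is
#' a single bright organ region with an asymmetric, irregular star-convex
#' contour, blurred boundary, multiplicative speckle noise and a smooth
#' intensity-inhomogeneity field, on a darker background — together with
#' the exact binary ground-truth mask.
#'
#' @param size integer `(H, W)` image size (default `c(64, 64)`).
#' @param contour_harmonics integer >= 2: radial perturbation terms
#'   `2..contour_harmonics` shaping the irregular contour.
#' @param boundary_blur_sigma Gaussian blur of the rendered boundary, in
#'   pixels.
#' @param speckle_strength standard deviation of the unit-mean
#'   multiplicative (gamma) speckle field; 0 disables speckle.
#' @param inhomogeneity_strength amplitude of the smooth multiplicative
#'   intensity field; 0 disables it.
#' @param area_fraction_range `(lo, hi)` bounds on the organ's area
#'   fraction of the frame.
#' @param seed integer seed; identical seed and config give a bitwise
#'   identical sample.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(size = c(64L, 64L), contour_harmonics = 5L,
                           boundary_blur_sigma = 1.2,
                           speckle_strength = 0.25,
                           inhomogeneity_strength = 0.3,
                           area_fraction_range = c(0.08, 0.35),
                           seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 16),
            contour_harmonics >= 2,
            boundary_blur_sigma >= 0, speckle_strength >= 0,
            inhomogeneity_strength >= 0,
            length(area_fraction_range) == 2L,
            area_fraction_range[1] > 0, area_fraction_range[2] < 1,
            area_fraction_range[1] < area_fraction_range[2])
  structure(list(size = as.integer(size),
                 contour_harmonics = as.integer(contour_harmonics),
                 boundary_blur_sigma = boundary_blur_sigma,
                 speckle_strength = speckle_strength,
                 inhomogeneity_strength = inhomogeneity_strength,
                 area_fraction_range = area_fraction_range,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Image/mask sample pair
#'
#' @param image `H x W` numeric matrix in `[0, 1]`.
#' @param mask `H x W` binary (0/1) matrix, or `NULL` (image-only,
#'   prediction mode).
#' @return An object of class `sample_pair`.
#' @export
sample_pair <- function(image, mask = NULL) {
  stopifnot(is.matrix(image))
  if (!is.null(mask)) {
    if (!identical(dim(image), dim(mask)))
      stop("image shape (", paste(dim(image), collapse = " x "),
           ") does not match mask shape (",
           paste(dim(mask), collapse = " x "), ")")
    if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
    storage.mode(mask) <- "double"
  }
  structure(list(image = image, mask = mask), class = "sample_pair")
}

#' Generate one synthetic phantom
#'
#' Draws a random star-convex contour
#' `r(theta) = r0 * (1 + sum_j a_j * sin(j * theta + phi_j))` around a
#' random interior centre, rasterises the exact binary mask, and renders
#' the image as two intensity levels smoothed by `boundary_blur_sigma`,
#' multiplied by unit-mean gamma speckle and a smooth inhomogeneity field,
#' clipped to `[0, 1]`. Resamples the contour until the organ fits the
#' frame and its area fraction lies in `area_fraction_range`.
#'
#' @param cfg a [phantom_config()].
#' @return A [sample_pair()] with exact ground-truth mask.
#' @examples
#' s <- generate_phantom(phantom_config(seed = 7))
#' mean(s$mask)    # area fraction
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  H <- cfg$size[1]; W <- cfg$size[2]
  lo <- cfg$area_fraction_range[1]; hi <- cfg$area_fraction_range[2]
  yy <- matrix(seq_len(H) - 1, H, W)
  xx <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  mask <- NULL
  for (try in seq_len(50L)) {
    cx <- runif(1, 0.38, 0.62) * (W - 1)
    cy <- runif(1, 0.38, 0.62) * (H - 1)
    af <- runif(1, lo, hi)
    r0 <- sqrt(af * H * W / pi)
    js <- 2:cfg$contour_harmonics
    aj <- runif(length(js), 0, 0.24) * 2 / js
    ph <- runif(length(js), 0, 2 * pi)
    # keep the radius positive and the contour inside the frame
    if (sum(aj) > 0.45) next
    margin <- min(cx, cy, W - 1 - cx, H - 1 - cy) - 1
    if (r0 * (1 + sum(aj)) > margin) next
    th <- atan2(yy - cy, xx - cx)
    r <- sqrt((xx - cx)^2 + (yy - cy)^2)
    rb <- r0 * (1 + Reduce(`+`, Map(function(a, j, p) a * sin(j * th + p),
                                    aj, js, ph)))
    m <- (r <= rb) * 1
    frac <- mean(m)
    if (frac >= lo && frac <= hi) { mask <- m; break }
  }
  if (is.null(mask)) stop("phantom does not fit")
  organ <- runif(1, 0.55, 0.75)
  bg <- runif(1, 0.15, 0.30)
  img <- bg + (organ - bg) * mask
  if (cfg$boundary_blur_sigma > 0)
    img <- gauss_blur2(img, cfg$boundary_blur_sigma)
  if (cfg$inhomogeneity_strength > 0) {
    coarse <- matrix(rnorm(16, 1, cfg$inhomogeneity_strength), 4, 4)
    img <- img * pmax(resize_bilinear(coarse, H, W), 0)
  }
  if (cfg$speckle_strength > 0) {
    sh <- 1 / cfg$speckle_strength^2
    img <- img * matrix(rgamma(H * W, shape = sh, rate = sh), H, W)
  }
  img <- pmin(pmax(img, 0), 1)
  sample_pair(img, mask)
}

#' Generate a seeded phantom dataset
#'
#' Sample `i` uses seed `seed + i - 1` with otherwise identical settings,
#' so any prefix of the dataset is reproducible.
#'
#' @param n number of samples.
#' @param cfg a [phantom_config()]; its `seed` is the base seed.
#' @return A list of [sample_pair()]s.
#' @export
generate_phantoms <- function(n, cfg = phantom_config()) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    ci <- cfg; ci$seed <- cfg$seed + i - 1L
    generate_phantom(ci)
  })
}

# separable Gaussian blur via banded row/column operators; kernel rows are
# renormalised at the borders (no wrap-around)
gauss_blur2 <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  band <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - rad):(i + rad)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- g[ok] / sum(g[ok])
    }
    K
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# pixel-centre-aligned resize; edge-replicating
resize_axis_weights <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src); w <- src - i0
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- i0[i] + 1
    A[i, a] <- A[i, a] + (1 - w[i])
    A[i, min(a + 1, n_in)] <- A[i, min(a + 1, n_in)] + w[i]
  }
  A
}

resize_bilinear <- function(m, H, W) {
  if (nrow(m) == H && ncol(m) == W) return(m)
  resize_axis_weights(H, nrow(m)) %*% m %*% t(resize_axis_weights(W, ncol(m)))
}

resize_nearest <- function(m, H, W) {
  if (nrow(m) == H && ncol(m) == W) return(m)
  ri <- pmin(pmax(floor((seq_len(H) - 0.5) * nrow(m) / H) + 1, 1), nrow(m))
  ci <- pmin(pmax(floor((seq_len(W) - 0.5) * ncol(m) / W) + 1, 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Per-channel normalization
#'
#' Centres and scales each channel to zero mean and unit standard
#' deviation (population SD). A constant channel maps to all zeros.
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @return Normalized array of the same shape.
#' @export
normalize_image <- function(image) {
  if (length(image) == 0L) stop("empty input")
  x <- as_cube(image)
  for (c in seq_len(dim(x)[3])) {
    v <- x[, , c]
    s <- sqrt(mean((v - mean(v))^2))
    x[, , c] <- if (s < 1e-12) 0 * v else (v - mean(v)) / s
  }
  restore_dims(x, image)
}

#' Augmentation configuration
#'
#' One jointly sampled transform per call of [augment_sample()]: a random
#' translation of up to `max_translation_fraction` of each axis, a random
#' crop of `crop_fraction` of the frame resized back to the original size,
#' and a horizontal flip with probability `hflip_probability`. The image is
#' resampled bilinearly, the mask with nearest neighbour (staying binary).
#'
#' @param max_translation_fraction maximum shift per axis as a fraction of
#'   its extent (default 0.1).
#' @param crop_fraction side fraction of the random crop (default 0.9;
#'   1 disables cropping).
#' @param hflip_probability probability of a horizontal flip (default 0.5).
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(max_translation_fraction = 0.1,
                                crop_fraction = 0.9,
                                hflip_probability = 0.5) {
  stopifnot(max_translation_fraction >= 0, max_translation_fraction <= 1,
            crop_fraction > 0, crop_fraction <= 1,
            hflip_probability >= 0, hflip_probability <= 1)
  structure(list(max_translation_fraction = max_translation_fraction,
                 crop_fraction = crop_fraction,
                 hflip_probability = hflip_probability),
            class = "augmentation_config")
}

shift_matrix <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Augment an image/mask pair
#'
#' Applies one random transform (translation, crop-and-resize, horizontal
#' flip) identically to image and mask; draws come from R's RNG, so seed
#' with `set.seed()` for reproducibility.
#'
#' @param s a [sample_pair()].
#' @param cfg an [augmentation_config()].
#' @return The transformed [sample_pair()]; shapes are unchanged and the
#'   mask stays binary.
#' @export
augment_sample <- function(s, cfg = augmentation_config()) {
  stopifnot(inherits(s, "sample_pair"), inherits(cfg, "augmentation_config"))
  img <- s$image; msk <- s$mask
  H <- nrow(img); W <- ncol(img)
  if (cfg$max_translation_fraction > 0) {
    dy <- round(runif(1, -1, 1) * cfg$max_translation_fraction * H)
    dx <- round(runif(1, -1, 1) * cfg$max_translation_fraction * W)
    if (dy != 0 || dx != 0) {
      img <- shift_matrix(img, dy, dx)
      if (!is.null(msk)) msk <- shift_matrix(msk, dy, dx)
    }
  }
  if (cfg$crop_fraction < 1) {
    ch <- max(1L, round(cfg$crop_fraction * H))
    cw <- max(1L, round(cfg$crop_fraction * W))
    y0 <- sample.int(H - ch + 1L, 1L)
    x0 <- sample.int(W - cw + 1L, 1L)
    img <- resize_bilinear(img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L),
                               drop = FALSE], H, W)
    if (!is.null(msk))
      msk <- resize_nearest(msk[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L),
                                drop = FALSE], H, W)
  }
  if (cfg$hflip_probability > 0 && runif(1) < cfg$hflip_probability) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(msk)) msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  sample_pair(pmin(pmax(img, 0), 1), msk)
}

#' Save and load image/mask sample pairs
#'
#' Images are written as 8-bit grayscale PNG, masks as 8-bit PNG with
#' values 0 and 255 (white = organ). On read, PNG and TIFF images are
#' accepted; a missing mask path loads an image-only pair (prediction
#' mode). The round trip is lossless for 8-bit data.
#'
#' @param s a [sample_pair()].
#' @param image_path path of the image PNG.
#' @param mask_path path of the mask PNG (`NULL` to skip).
#' @return `save_sample` the paths, invisibly; `load_sample` a
#'   [sample_pair()].
#' @export
save_sample <- function(s, image_path, mask_path = NULL) {
  stopifnot(inherits(s, "sample_pair"))
  png::writePNG(round(pmin(pmax(s$image, 0), 1) * 255) / 255, image_path)
  if (!is.null(mask_path)) {
    if (is.null(s$mask)) stop("sample has no mask to save")
    png::writePNG(s$mask, mask_path)
  }
  invisible(c(image = image_path, mask = mask_path))
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname save_sample
#' @export
load_sample <- function(image_path, mask_path = NULL) {
  img <- read_gray(image_path)
  if (is.null(mask_path)) return(sample_pair(img))
  msk <- read_gray(mask_path)
  if (!identical(dim(img), dim(msk)))
    stop("image shape (", paste(dim(img), collapse = " x "),
         ") does not match mask shape (", paste(dim(msk), collapse = " x "), ")")
  if (!all(msk %in% c(0, 1)))
    stop("non-binary mask file: ", mask_path)
  sample_pair(img, msk)
}

#' Split a dataset into train/validation/test
#'
#' Seed-reproducible disjoint exhaustive partition with largest-remainder
#' rounding of the split sizes. The default fractions are the exact
#' proportions of a 780/123/154 split of 1057 cases.
#'
#' @param n number of samples (or a list, whose length is used).
#' @param fractions length-3 positive fractions summing to 1.
#' @param seed integer seed for the random assignment.
#' @return A list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(780, 123, 154) / 1057, seed = 1L) {
  if (is.list(n)) n <- length(n)
  stopifnot(n >= 3, length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  q <- n * fractions
  sizes <- floor(q)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(q - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  if (any(sizes == 0)) stop("a split would be empty at n = ", n)
  set.seed(seed)
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(sizes[1])]),
       val = sort(idx[sizes[1] + seq_len(sizes[2])]),
       test = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}
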