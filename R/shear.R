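#' Shear transform specification
#'
#' Defines a 2-D shear transform by direction and shear factor. The factor
#' can be given directly (e.g. `0.3`) or through the dyadic parameterisation
#' `k / 2^n_dir` with integer `k`, `|k| <= 2^n_dir`, in which case
#' `|factor| <= 1`.
#'
#' A horizontal shear maps a point `(x, y)` (x = column, y = row, 0-based)
#' to `(x + factor * y, y)`; a vertical shear maps it to
#' `(x, y + factor * x)`. The inverse transform negates the factor.
#'
#' @param direction `"horizontal"` or `"vertical"`.
#' @param factor shear factor, set directly. Exactly one of `factor` or the
#'   pair `k`, `n_dir` must be supplied.
#' @param k integer numerator of the dyadic factor `k / 2^n_dir`.
#' @param n_dir non-negative integer direction parameter.
#' @param interp resampling used by [apply_shear()]: `"bilinear"`
#'   (differentiable, used inside the network) or `"nearest"` (exact pixel
#'   relocation).
#' @param canvas `"lossless"` expands the output canvas so no content is
#'   lost; `"fixed"` keeps the input frame and discards out-of-frame content.
#' @return An object of class `shear_spec`.
#' @examples
#' sp <- shear_spec("horizontal", factor = 0.3)
#' shear_matrix(sp)
#' @export
shear_spec <- function(direction = c("horizontal", "vertical"),
                       factor = NULL, k = NULL, n_dir = NULL,
                       interp = c("bilinear", "nearest"),
                       canvas = c("lossless", "fixed")) {
  direction <- match.arg(direction)
  interp <- match.arg(interp)
  canvas <- match.arg(canvas)
  if (is.null(factor)) {
    if (is.null(k) || is.null(n_dir))
      stop("supply either `factor` or both `k` and `n_dir`")
    if (n_dir < 0 || n_dir != round(n_dir))
      stop("`n_dir` must be a non-negative integer")
    if (k != round(k)) stop("`k` must be an integer")
    if (abs(k) > 2^n_dir)
      stop("|k| must not exceed 2^n_dir (got k = ", k,
           ", 2^n_dir = ", 2^n_dir, ")")
    factor <- k / 2^n_dir
  } else {
    if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor))
      stop("`factor` must be a single finite number")
  }
  structure(
    list(direction = direction, factor = factor, k = k, n_dir = n_dir,
         interp = interp, canvas = canvas),
    class = "shear_spec")
}

#' @export
print.shear_spec <- function(x, ...) {
  cat(sprintf("shear_spec: %s, factor %g, %s interpolation, %s canvas\n",
              x$direction, x$factor, x$interp, x$canvas))
  invisible(x)
}

#' Shear matrix and its inverse
#'
#' Returns the 2x2 shear matrix applied as a row-vector product
#' `(x, y) %*% S`. For a horizontal shear `S = [[1, 0], [factor, 1]]`
#' (so `x' = x + factor * y`); for a vertical shear
#' `S = [[1, factor], [0, 1]]` (so `y' = y + factor * x`).
#' The inverse matrix is the same matrix with the factor negated;
#' their product is exactly the identity.
#'
#' @param spec a [shear_spec()].
#' @return A 2x2 numeric matrix.
#' @export
shear_matrix <- function(spec) {
  stopifnot(inherits(spec, "shear_spec"))
  f <- spec$factor
  if (spec$direction == "horizontal")
    matrix(c(1, f, 0, 1), 2, 2)   # columns: (1, factor), (0, 1)
  else
    matrix(c(1, 0, f, 1), 2, 2)
}

#' @rdname shear_matrix
#' @export
inverse_shear_matrix <- function(spec) {
  spec$factor <- -spec$factor
  shear_matrix(spec)
}

#' Apply a shear transform to coordinate points
#'
#' @param points an `n x 2` matrix (or length-2 vector) of `(x, y)` points.
#' @param spec a [shear_spec()].
#' @param inverse apply the inverse transform instead.
#' @return An `n x 2` matrix of transformed points.
#' @export
shear_points <- function(points, spec, inverse = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  m <- if (inverse) inverse_shear_matrix(spec) else shear_matrix(spec)
  points %*% m
}

# canvas geometry: the forward map sends x to x + f*y (+ shift to keep all
# source content at non-negative coordinates); lossless widens the sheared
# axis by ceil(|f| * (extent of the other axis - 1))
shear_geometry_of <- function(spec, H, W) {
  f <- spec$factor
  if (spec$direction == "horizontal") {
    grow <- ceiling(abs(f) * (H - 1))
    shift <- if (f < 0) abs(f) * (H - 1) else 0
    if (spec$canvas == "lossless")
      list(shift = shift, out_len = W + grow, axis_len = W)
    else
      list(shift = 0, out_len = W, axis_len = W)
  } else {
    grow <- ceiling(abs(f) * (W - 1))
    shift <- if (f < 0) abs(f) * (W - 1) else 0
    if (spec$canvas == "lossless")
      list(shift = shift, out_len = H + grow, axis_len = H)
    else
      list(shift = 0, out_len = H, axis_len = H)
  }
}

as_cube <- function(img) {
  if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
}

restore_dims <- function(out, img) {
  if (is.matrix(img)) out[, , 1L] else out
}

#' Shear-warp an image or feature map
#'
#' Resamples each channel of `img` under the shear coordinate map of `spec`.
#' With `canvas = "lossless"` the sheared axis is widened so no content is
#' lost; with `"fixed"` the frame is kept and content may leave it.
#' Out-of-source samples are zero. With nearest-neighbour interpolation the
#' warp is an exact per-row (per-column) pixel relocation, so
#' `apply_inverse_shear(apply_shear(x))` restores `x` bitwise.
#'
#' @param img an `H x W` matrix or `H x W x C` array.
#' @param spec a [shear_spec()].
#' @return The warped map, same number of channels as the input.
#' @seealso [apply_inverse_shear()]
#' @export
apply_shear <- function(img, spec) {
  stopifnot(inherits(spec, "shear_spec"))
  if (length(img) == 0L) stop("empty input")
  x <- as_cube(img)
  g <- shear_geometry_of(spec, dim(x)[1], dim(x)[2])
  out <- shear_warp(x, spec$factor, spec$direction == "horizontal",
                    g$shift, g$out_len,
                    if (spec$interp == "nearest") 0L else 1L)
  restore_dims(out, img)
}

#' Invert a shear warp
#'
#' Resamples under the negated-factor map and crops or zero-pads the result
#' to `target_shape`. Applied to the output of [apply_shear()] with the same
#' spec and the original shape as target, it restores the original image
#' (exactly for nearest interpolation with a lossless canvas).
#'
#' @param img a warped `H x W` matrix or `H x W x C` array.
#' @param spec the [shear_spec()] used for the forward warp.
#' @param target_shape integer `(H, W)` of the restored image.
#' @return The restored map.
#' @export
apply_inverse_shear <- function(img, spec, target_shape) {
  stopifnot(inherits(spec, "shear_spec"))
  if (length(img) == 0L) stop("empty input")
  if (length(target_shape) != 2L || any(target_shape <= 0))
    stop("`target_shape` must be two positive integers")
  x <- as_cube(img)
  H <- as.integer(target_shape[1]); W <- as.integer(target_shape[2])
  # forward-warp geometry is defined by the *original* shape; for a
  # horizontal shear the row count is unchanged by the warp (and vice versa)
  if (spec$direction == "horizontal") {
    g <- shear_geometry_of(spec, dim(x)[1], W)
    out <- shear_warp(x, -spec$factor, TRUE, -g$shift, W,
                      if (spec$interp == "nearest") 0L else 1L)
    out <- crop_pad_rows(out, H)
  } else {
    g <- shear_geometry_of(spec, H, dim(x)[2])
    out <- shear_warp(x, -spec$factor, FALSE, -g$shift, H,
                      if (spec$interp == "nearest") 0L else 1L)
    out <- crop_pad_cols(out, W)
  }
  restore_dims(out, img)
}

crop_pad_rows <- function(x, H) {
  h <- dim(x)[1]
  if (h == H) return(x)
  out <- array(0, c(H, dim(x)[2], dim(x)[3]))
  n <- min(h, H)
  out[seq_len(n), , ] <- x[seq_len(n), , , drop = FALSE]
  out
}

crop_pad_cols <- function(x, W) {
  w <- dim(x)[2]
  if (w == W) return(x)
  out <- array(0, c(dim(x)[1], W, dim(x)[3]))
  n <- min(w, W)
  out[, seq_len(n), ] <- x[, seq_len(n), , drop = FALSE]
  out
}
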