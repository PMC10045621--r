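#' The 3x3 receptive-field grid
#'
#' The nine integer tap offsets of a 3x3, dilation-1 kernel in row-major
#' order `(-1,-1), (-1,0), ..., (1,1)`, as `(dy, dx)` pairs.
#'
#' @return A 9 x 2 integer matrix with columns `dy`, `dx`.
#' @export
kernel_grid3 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))[, c("dy", "dx")]
  storage.mode(g) <- "integer"
  rownames(g) <- NULL
  g
}

check_weights <- function(x, w) {
  d <- dim(w)
  if (length(d) != 4L || d[1] != 3L || d[2] != 3L)
    stop("`w` must be a 3 x 3 x in_channels x out_channels array")
  if (d[3] != dim(x)[3])
    stop("channel mismatch: input has ", dim(x)[3],
         " channels but weights expect ", d[3])
  d
}

# 3x3xCinxCout array -> (9*Cin x Cout) matrix with rows ordered
# r = ci*9 + t, t = (dy+1)*3 + (dx+1)
weights_to_mat <- function(w) {
  d <- dim(w)
  m <- aperm(w, c(2, 1, 3, 4))       # (dx, dy, ci, co): dx fastest
  dim(m) <- c(9L * d[3], d[4])
  m
}

mat_to_weights <- function(m, cin, cout) {
  w <- m
  dim(w) <- c(3L, 3L, cin, cout)
  aperm(w, c(2, 1, 3, 4))
}

#' Reference 3x3 convolution (direct loop)
#'
#' Computes `y(p) = sum_n w(n) * x(p + tap_n)` by an explicit loop over
#' output positions and kernel taps, with stride 1 and zero padding 1
#' (same-size output). This is the plain-convolution reference the
#' deformable convolution reduces to at zero offsets; it is deliberately a
#' direct transcription of the weighted-sum definition and is not used on
#' the training path.
#'
#' @param x an `H x W x Cin` array (or `H x W` matrix).
#' @param w a `3 x 3 x Cin x Cout` weight array, indexed `w[dy+2, dx+2, ci, co]`.
#' @param bias optional length-`Cout` bias vector.
#' @return An `H x W x Cout` array.
#' @export
conv2d_reference <- function(x, w, bias = NULL) {
  x <- as_cube(x)
  d <- check_weights(x, w)
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- d[3]; cout <- d[4]
  if (is.null(bias)) bias <- numeric(cout)
  y <- array(0, c(H, W, cout))
  taps <- kernel_grid3()
  for (co in seq_len(cout)) {
    acc <- matrix(bias[co], H, W)
    for (ci in seq_len(cin)) {
      for (t in seq_len(9L)) {
        dy <- taps[t, 1]; dx <- taps[t, 2]
        wv <- w[dy + 2L, dx + 2L, ci, co]
        if (wv == 0) next
        for (xo in seq_len(W)) {
          xs <- xo + dx
          if (xs < 1L || xs > W) next
          for (yo in seq_len(H)) {
            ys <- yo + dy
            if (ys >= 1L && ys <= H)
              acc[yo, xo] <- acc[yo, xo] + wv * x[ys, xs, ci]
          }
        }
      }
    }
    y[, , co] <- acc
  }
  y
}

#' Bilinear sampling with zero padding
#'
#' Samples channel `channel` of `x` at real-valued points `(x_coord,
#' y_coord)` (0-based, x = column) by 4-neighbour bilinear weighting.
#' Samples outside the array read as zero; integer lattice points return the
#' stored value exactly.
#'
#' @param x an `H x W x C` array or `H x W` matrix.
#' @param x_coord,y_coord numeric vectors of sampling coordinates.
#' @param channel 1-based channel index.
#' @return A numeric vector of sampled values.
#' @export
bilinear_sample <- function(x, x_coord, y_coord, channel = 1L) {
  x <- as_cube(x)
  stopifnot(length(x_coord) == length(y_coord),
            channel >= 1L, channel <= dim(x)[3])
  bilinear_sample_cpp(x, as.numeric(x_coord), as.numeric(y_coord),
                      as.integer(channel) - 1L)
}

#' Deformable 3x3 convolution
#'
#' Computes `y(p) = sum_n w(n) * x(p + tap_n + offset_n(p))`: each of the
#' nine kernel taps is displaced per output position by a learned 2-D
#' offset, and the displaced (generally fractional) sampling positions are
#' evaluated by bilinear interpolation with zero padding. Offsets are
#' shared across input channels. With a zero offset field the operation
#' equals the plain convolution [conv2d_reference()].
#'
#' @param x an `H x W x Cin` array (or `H x W` matrix).
#' @param w a `3 x 3 x Cin x Cout` weight array.
#' @param offsets an `H x W x 18` array; slice `2t - 1` holds the
#'   x-displacement of tap `t` (row-major tap order), slice `2t` its
#'   y-displacement.
#' @param bias optional length-`Cout` bias.
#' @return An `H x W x Cout` array.
#' @export
deformable_conv <- function(x, w, offsets, bias = NULL) {
  x <- as_cube(x)
  d <- check_weights(x, w)
  H <- dim(x)[1]; W <- dim(x)[2]
  od <- dim(offsets)
  if (length(od) != 3L || od[1] != H || od[2] != W || od[3] != 18L)
    stop("offset field shape mismatch: expected ", H, " x ", W,
         " x 18, got ", paste(od, collapse = " x "))
  if (is.null(bias)) bias <- numeric(d[4])
  deform3x3_fwd(x, weights_to_mat(w), bias, offsets)
}

#' Offset-predictor convolution
#'
#' The deformable convolution obtains its offset field from the same input
#' feature map through a trainable 3x3 same-padding convolution with
#' `2 * 9 = 18` output channels. Inside the network each deformable
#' convolution owns one such predictor; its weights and biases start at
#' zero so training begins from plain-convolution behaviour.
#'
#' @param x an `H x W x Cin` array (or `H x W` matrix).
#' @param w a `3 x 3 x Cin x 18` weight array (zeros at initialisation).
#' @param bias length-18 bias vector.
#' @return An `H x W x 18` offset field.
#' @export
offset_predictor <- function(x, w, bias = NULL) {
  x <- as_cube(x)
  d <- check_weights(x, w)
  if (d[4] != 18L) stop("offset predictor must have 18 output channels")
  if (is.null(bias)) bias <- numeric(18L)
  conv3x3_fwd(x, weights_to_mat(w), bias)
}
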