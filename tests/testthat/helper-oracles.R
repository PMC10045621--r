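# Independent reference implementations used as test oracles. These are
# deliberately written as direct transcriptions of the defining formulas
# (forward splatting, closed-form bilinear weights, explicit loops) and
# share no code with the package's compute path.

# closed-form bilinear interpolation with zero padding, 0-based (x, y)
oracle_bilinear <- function(x, px, py, ci = 1L) {
  x <- if (is.matrix(x)) array(x, c(dim(x), 1)) else x
  H <- dim(x)[1]; W <- dim(x)[2]
  g <- function(yy, xx)
    if (yy >= 0 && yy < H && xx >= 0 && xx < W) x[yy + 1, xx + 1, ci] else 0
  x0 <- floor(px); y0 <- floor(py)
  wx <- px - x0; wy <- py - y0
  (1 - wx) * (1 - wy) * g(y0, x0) + wx * (1 - wy) * g(y0, x0 + 1) +
    (1 - wx) * wy * g(y0 + 1, x0) + wx * wy * g(y0 + 1, x0 + 1)
}

# triple-loop deformable convolution calling the closed-form bilinear oracle
oracle_deform_conv <- function(x, w, off, bias = NULL) {
  x <- if (is.matrix(x)) array(x, c(dim(x), 1)) else x
  H <- dim(x)[1]; W <- dim(x)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  if (is.null(bias)) bias <- numeric(cout)
  taps <- kernel_grid3()
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) for (xo in 0:(W - 1)) for (yo in 0:(H - 1)) {
    acc <- bias[co]
    for (t in 1:9) for (ci in seq_len(cin)) {
      px <- xo + taps[t, 2] + off[yo + 1, xo + 1, 2 * t - 1]
      py <- yo + taps[t, 1] + off[yo + 1, xo + 1, 2 * t]
      acc <- acc + w[taps[t, 1] + 2, taps[t, 2] + 2, ci, co] *
        oracle_bilinear(x, px, py, ci)
    }
    y[yo + 1, xo + 1, co] <- acc
  }
  y
}

# forward-splatting nearest-neighbour shear on a lossless canvas: each
# source pixel is placed at its transformed coordinate, rounded to the
# lattice (per-row/column shift, ties away from zero)
oracle_shear_nearest <- function(img, factor, direction) {
  H <- nrow(img); W <- ncol(img)
  rnd <- function(v) sign(v) * floor(abs(v) + 0.5)
  if (direction == "horizontal") {
    s0 <- if (factor < 0) abs(factor) * (H - 1) else 0
    out <- matrix(0, H, W + ceiling(abs(factor) * (H - 1)))
    for (y in 0:(H - 1)) {
      shift <- rnd(factor * y + s0)
      for (x in 0:(W - 1)) out[y + 1, x + shift + 1] <- img[y + 1, x + 1]
    }
  } else {
    s0 <- if (factor < 0) abs(factor) * (W - 1) else 0
    out <- matrix(0, H + ceiling(abs(factor) * (W - 1)), W)
    for (x in 0:(W - 1)) {
      shift <- rnd(factor * x + s0)
      for (y in 0:(H - 1)) out[y + shift + 1, x + 1] <- img[y + 1, x + 1]
    }
  }
  out
}

# 4-connected reachability: grow from one foreground seed through
# 4-neighbour dilation restricted to the mask; single-component iff the
# grown region covers the mask
mask_is_single_4connected <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[idx[1, 1], idx[1, 2]] <- TRUE
  H <- nrow(m); W <- ncol(m)
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-H, ]
    grown[-H, ] <- grown[-H, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -W]
    grown[, -W] <- grown[, -W] | reach[, -1]
    grown <- grown & (m > 0)
    if (identical(grown, reach)) break
    reach <- grown
  }
  all(reach[m > 0])
}

# tiny deterministic phantom sets for training tests
make_phantoms <- function(n, seed, size = c(64L, 64L)) {
  generate_phantoms(n, phantom_config(size = size, seed = seed))
}

random_mask <- function(H, W, p = 0.3) matrix(rbinom(H * W, 1, p), H, W)
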