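test_that("reference convolution satisfies the weighted-sum definition", {
  # constant input, all-ones weights: interior output is 9c
  x <- matrix(2.5, 5, 5)
  w <- array(1, c(3, 3, 1, 1))
  y <- conv2d_reference(x, w)
  expect_equal(y[3, 3, 1], 9 * 2.5)
  expect_equal(y[2:4, 2:4, 1], matrix(9 * 2.5, 3, 3))

  # identity kernel: weight 1 at the centre tap only
  wi <- array(0, c(3, 3, 1, 1)); wi[2, 2, 1, 1] <- 1
  xr <- matrix(runif(25), 5, 5)
  expect_equal(conv2d_reference(xr, wi)[, , 1], xr)

  # channel mismatch is rejected
  expect_error(conv2d_reference(xr, array(1, c(3, 3, 2, 1))),
               "channel mismatch")
})

test_that("bilinear sampling matches the closed form", {
  x <- matrix(runif(16), 4, 4)
  # integer lattice points return stored values
  expect_equal(bilinear_sample(x, 2, 3), x[4, 3])
  # midway between pixels valued 0 and 1 gives 0.5
  m <- matrix(c(0, 0, 1, 1), 2, 2)   # columns x=0 -> 0, x=1 -> 1
  expect_equal(bilinear_sample(m, 0.5, 0), 0.5)
  # hand-evaluated 2x2 case at (0.25, 0.75)
  v <- matrix(c(0.2, 0.9, 0.4, 0.1), 2, 2)  # v[y+1, x+1]
  hand <- 0.75 * 0.25 * v[1, 1] + 0.25 * 0.25 * v[1, 2] +
          0.75 * 0.75 * v[2, 1] + 0.25 * 0.75 * v[2, 2]
  expect_equal(bilinear_sample(v, 0.25, 0.75), hand)
  expect_equal(bilinear_sample(v, 0.25, 0.75), oracle_bilinear(v, 0.25, 0.75))
  # out-of-bounds reads are zero-padded
  expect_equal(bilinear_sample(v, -1, -1), 0)
  expect_equal(bilinear_sample(v, -0.5, 0), 0.5 * v[1, 1])
})

test_that("deformable convolution reduces to the reference at zero offsets", {
  set.seed(21)
  x <- array(runif(5 * 5 * 2), c(5, 5, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  expect_lt(max(abs(deformable_conv(x, w, array(0, c(5, 5, 18)), b) -
                    conv2d_reference(x, w, b))), 1e-12)
})

test_that("integer offsets keep interior outputs of a constant input at 9c", {
  x <- matrix(1.7, 8, 8)
  w <- array(1, c(3, 3, 1, 1))
  off <- array(0, c(8, 8, 18))
  off[, , seq(1, 18, 2)] <- 1   # shift every tap one column right
  y <- deformable_conv(x, w, off)
  expect_equal(y[3:6, 3:5, 1], matrix(9 * 1.7, 4, 3))
})

test_that("offset shape mismatch names expected and actual shapes", {
  x <- matrix(runif(16), 4, 4)
  w <- array(rnorm(9), c(3, 3, 1, 1))
  expect_error(deformable_conv(x, w, array(0, c(4, 4, 9))),
               "expected 4 x 4 x 18, got 4 x 4 x 9")
})

test_that("offset predictor is a same-shape convolution, zero at initialisation", {
  x <- array(runif(6 * 6 * 2), c(6, 6, 2))
  w0 <- array(0, c(3, 3, 2, 18))
  off <- offset_predictor(x, w0)
  expect_equal(dim(off), c(6L, 6L, 18L))
  expect_true(all(off == 0))
  # with generic weights it agrees with the loop reference
  set.seed(4)
  w <- array(rnorm(3 * 3 * 2 * 18, sd = 0.1), c(3, 3, 2, 18))
  b <- rnorm(18, sd = 0.1)
  expect_equal(offset_predictor(x, w, b), conv2d_reference(x, w, b),
               tolerance = 1e-12)
})

test_that("deformable convolution gradients match central finite differences", {
  set.seed(33)
  x <- array(runif(4 * 4 * 2), c(4, 4, 2))
  w <- array(rnorm(3 * 3 * 2 * 2, sd = 0.5), c(3, 3, 2, 2))
  wm <- shearseg:::weights_to_mat(w)
  b <- rnorm(2)
  off <- array(runif(4 * 4 * 18, -0.8, 0.8), c(4, 4, 18))
  gy <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  loss <- function(xx, wwm, oo)
    sum(shearseg:::deform3x3_fwd(xx, wwm, b, oo) * gy)
  g <- shearseg:::deform3x3_bwd(x, wm, off, gy)
  eps <- 1e-6
  relerr <- function(a, b) abs(a - b) / pmax(1e-6, abs(a) + abs(b))

  for (k in sample(length(off), 12)) {
    o2 <- off; o2[k] <- off[k] + eps
    o3 <- off; o3[k] <- off[k] - eps
    fd <- (loss(x, wm, o2) - loss(x, wm, o3)) / (2 * eps)
    expect_lt(relerr(fd, g$goff[k]), 1e-3)
  }
  for (k in sample(length(x), 8)) {
    x2 <- x; x2[k] <- x[k] + eps
    x3 <- x; x3[k] <- x[k] - eps
    fd <- (loss(x2, wm, off) - loss(x3, wm, off)) / (2 * eps)
    expect_lt(relerr(fd, g$gx[k]), 1e-3)
  }
  for (k in sample(length(wm), 8)) {
    w2 <- wm; w2[k] <- wm[k] + eps
    w3 <- wm; w3[k] <- wm[k] - eps
    fd <- (loss(x, w2, off) - loss(x, w3, off)) / (2 * eps)
    expect_lt(relerr(fd, g$gw[k]), 1e-3)
  }
})

test_that("offset-predictor weights receive nonzero gradients through a block", {
  set.seed(55)
  cfg <- model_config("du_net", depth = 1, base_width = 2)
  m <- build_model(cfg, seed = 9)
  # break the zero-offset symmetry so predictor gradients are generic
  for (nm in grep("\\.ow$", names(m$params), value = TRUE))
    m$params[[nm]] <- matrix(rnorm(length(m$params[[nm]]), sd = 0.05),
                             nrow(m$params[[nm]]))
  x <- matrix(runif(16), 4, 4)
  gt <- matrix(rbinom(16, 1, 0.5), 4, 4)
  fw <- model_forward(m, x, keep_cache = TRUE)
  ce <- shearseg:::ce_from_logits(fw$logits, gt, "softmax2")
  g <- model_backward(m, fw$cache, ce$glogits)
  ow_norms <- vapply(grep("\\.ow$", names(g), value = TRUE),
                     function(nm) sum(abs(g[[nm]])), numeric(1))
  expect_true(all(ow_norms > 0))
})
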