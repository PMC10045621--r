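test_that("blocks have the contracted output shape and reduce across variants", {
  sp0 <- shear_spec("horizontal", factor = 0)
  bd <- build_block(block_config(1, 16, variant = "shear_deform", shear = sp0),
                    seed = 2)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- forward_block(bd, x)
  expect_equal(dim(y), c(32L, 32L, 16L))

  # factor-0 shear + zero-initialised offsets reproduce the plain block
  bp <- build_block(block_config(1, 16, variant = "plain"), seed = 99)
  bp$params[["blk.conv1.w"]] <- bd$params[["blk.conv1.w"]]
  bp$params[["blk.conv1.b"]] <- bd$params[["blk.conv1.b"]]
  bp$params[["blk.conv2.w"]] <- bd$params[["blk.conv2.w"]]
  bp$params[["blk.conv2.b"]] <- bd$params[["blk.conv2.b"]]
  expect_equal(forward_block(bp, x), y, tolerance = 1e-12)

  # a nonzero shear factor changes the result
  bs <- build_block(block_config(1, 16, variant = "shear_deform",
                                 shear = shear_spec("horizontal", factor = 0.3)),
                    seed = 2)
  expect_gt(max(abs(forward_block(bs, x) - y)), 1e-6)
})

test_that("the model emits a valid per-pixel probability field", {
  m <- build_model(model_config("dsu_net", depth = 4, base_width = 4), seed = 1)
  x <- matrix(runif(64 * 64), 64, 64)
  out <- model_forward(m, x)
  expect_equal(dim(out$prob), c(64L, 64L, 2L))
  expect_true(all(out$prob >= 0))
  expect_lt(max(abs(out$prob[, , 1] + out$prob[, , 2] - 1)), 1e-6)
})

test_that("input sizes not divisible by 2^depth are rejected with advice", {
  m <- build_model(model_config("unet", depth = 4, base_width = 2), seed = 1)
  expect_error(model_forward(m, matrix(0, 60, 64)), "divisible.*pad")
})

test_that("unet parameter count equals the textbook closed form", {
  b <- 16L; d <- 4L
  m <- build_model(model_config("unet", depth = d, base_width = b), seed = 1)
  # independent enumeration of the same-padding U-Net with 2x2
  # transposed-conv upsampling, biases included, 1 input channel, 2 classes
  conv <- function(cin, cout) 9 * cin * cout + cout
  widths <- b * 2^(0:d)
  total <- 0
  cin <- 1
  for (i in 1:d) {
    total <- total + conv(cin, widths[i]) + conv(widths[i], widths[i])
    cin <- widths[i]
  }
  total <- total + conv(widths[d], widths[d + 1]) +
    conv(widths[d + 1], widths[d + 1])
  for (i in d:1) {
    cup <- widths[i + 1]
    total <- total + (4 * cup * widths[i] + widths[i])        # upsample
    total <- total + conv(2 * widths[i], widths[i]) +
      conv(widths[i], widths[i])
  }
  total <- total + (b * 2 + 2)                                # 1x1 head
  expect_identical(n_params(m), as.integer(total))
})

test_that("reduction ladder: dsu_net(factor 0) = du_net(zero offsets) = unet", {
  sp0 <- shear_spec("horizontal", factor = 0)
  md <- build_model(model_config("dsu_net", depth = 2, base_width = 4,
                                 shear = sp0), seed = 3)
  mdu <- copy_shared_weights(
    build_model(model_config("du_net", depth = 2, base_width = 4), seed = 77), md)
  mu <- copy_shared_weights(
    build_model(model_config("unet", depth = 2, base_width = 4), seed = 78), md)
  x <- matrix(runif(32 * 32), 32, 32)
  ld <- model_forward(md, x)$logits
  expect_lt(max(abs(model_forward(mdu, x)$logits - ld)), 1e-5)
  expect_lt(max(abs(model_forward(mu, x)$logits - ld)), 1e-5)
})

test_that("encoder and decoder stages mirror in width and count", {
  cfg <- model_config("unet", depth = 3, base_width = 8)
  m <- build_model(cfg, seed = 1)
  for (i in 1:3) {
    enc_w <- ncol(m$params[[paste0("enc", i, ".conv2.w")]])
    dec_w <- ncol(m$params[[paste0("dec", i, ".conv2.w")]])
    expect_identical(enc_w, dec_w)
  }
  expect_identical(ncol(m$params[["bottleneck.conv2.w"]]), 64L)
})

test_that("one forward+backward pass produces nonzero conv gradients everywhere", {
  m <- build_model(model_config("dsu_net", depth = 2, base_width = 2), seed = 7)
  x <- matrix(runif(16 * 16), 16, 16)
  gt <- matrix(rbinom(256, 1, 0.4), 16, 16)
  fw <- model_forward(m, x, keep_cache = TRUE)
  ce <- shearseg:::ce_from_logits(fw$logits, gt, "softmax2")
  g <- model_backward(m, fw$cache, ce$glogits)
  expect_setequal(names(g), names(m$params))
  wnorms <- vapply(grep("\\.conv[12]\\.w$", names(g), value = TRUE),
                   function(nm) sum(abs(g[[nm]])), numeric(1))
  expect_true(all(wnorms > 0))
})

test_that("sigmoid head yields a single foreground-probability channel", {
  m <- build_model(model_config("unet", depth = 2, base_width = 4,
                                head = "sigmoid1"), seed = 2)
  x <- matrix(runif(16 * 16), 16, 16)
  out <- model_forward(m, x)
  expect_equal(dim(out$prob), c(16L, 16L, 1L))
  expect_true(all(out$prob > 0 & out$prob < 1))
  mask <- binarize(out$prob)
  expect_true(all(mask %in% c(0, 1)))
})
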