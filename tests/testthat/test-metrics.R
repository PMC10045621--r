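test_that("dice and jaccard match their printed-formula substitutions", {
  gt <- matrix(0, 4, 4); gt[1, 1:4] <- 1          # |GT| = 4
  sr <- matrix(0, 4, 4); sr[1, 3:4] <- 1; sr[2, 1:2] <- 1  # |SR| = 4, overlap 2
  expect_identical(dice(gt, sr), 0.5)             # 2*2 / (4 + 4)
  expect_identical(jaccard(gt, sr), 2 / 6)        # 2 / (4 + 4 - 2)

  m <- random_mask(6, 6)
  expect_identical(dice(m, m), 1)
  expect_identical(jaccard(m, m), 1)
  a <- matrix(0, 3, 3); a[1, 1] <- 1
  b <- matrix(0, 3, 3); b[3, 3] <- 1
  expect_identical(dice(a, b), 0)
  e <- matrix(0, 3, 3)
  expect_identical(dice(e, e), 1)                 # vacuous agreement
  expect_identical(jaccard(e, e), 1)
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "shape mismatch")
  expect_error(jaccard(matrix(0, 2, 2), matrix(0, 3, 3)), "shape mismatch")
})

test_that("metrics agree with set arithmetic on 200 random mask pairs", {
  set.seed(99)
  for (i in 1:200) {
    H <- sample(2:12, 1); W <- sample(2:12, 1)
    gt <- random_mask(H, W, runif(1, 0, 0.7))
    sr <- random_mask(H, W, runif(1, 0, 0.7))
    A <- which(gt == 1); B <- which(sr == 1)
    inter <- length(intersect(A, B)); uni <- length(union(A, B))
    d_oracle <- if (length(A) + length(B) == 0) 1
                else 2 * inter / (length(A) + length(B))
    j_oracle <- if (uni == 0) 1 else inter / uni
    d <- dice(gt, sr); j <- jaccard(gt, sr)
    expect_equal(d, d_oracle)
    expect_equal(j, j_oracle)
    expect_true(d >= 0 && d <= 1 && j >= 0 && j <= 1)
    expect_lte(j, d + 1e-15)
    expect_lt(abs(j - d / (2 - d)), 1e-12)        # J = D / (2 - D)
  }
})

test_that("soft dice extends the hard dice to probability maps", {
  gt <- random_mask(8, 8, 0.4)
  expect_identical(soft_dice(gt, gt), dice(gt, gt))
  sr <- random_mask(8, 8, 0.4)
  expect_identical(soft_dice(sr, gt), dice(gt, sr))
  # constant probability 0.5: closed form 2*0.5*A / (0.5*N + A)
  A <- sum(gt); N <- length(gt)
  expect_equal(soft_dice(matrix(0.5, 8, 8), gt), 2 * 0.5 * A / (0.5 * N + A))
  # loop oracle on random probability maps
  set.seed(31)
  for (i in 1:20) {
    p <- matrix(runif(64), 8, 8)
    num <- 0; dl <- 0
    for (k in 1:64) { num <- num + p[k] * gt[k]; dl <- dl + p[k] + gt[k] }
    expect_equal(soft_dice(p, gt), 2 * num / dl)
  }
  expect_error(soft_dice(matrix(1.5, 8, 8), gt), "\\[0, 1\\]")
  # soft dice converges to hard dice as probabilities sharpen
  sharp <- function(t) 1 / (1 + exp(-t * (gt - 0.5)))
  expect_equal(soft_dice(sharp(200), gt), dice(gt, gt), tolerance = 1e-6)
})

test_that("binary cross entropy matches its closed forms and a loop oracle", {
  gt <- random_mask(6, 6, 0.5)
  perfect <- array(0, c(6, 6, 2))
  perfect[, , 2] <- gt; perfect[, , 1] <- 1 - gt
  expect_lt(bce_loss(perfect, gt), 1e-6)
  expect_equal(bce_loss(matrix(0.5, 6, 6), gt), log(2))
  set.seed(8)
  for (i in 1:20) {
    p <- matrix(runif(36, 0.01, 0.99), 6, 6)
    acc <- 0
    for (k in 1:36) acc <- acc - (gt[k] * log(p[k]) + (1 - gt[k]) * log(1 - p[k]))
    expect_equal(bce_loss(p, gt), acc / 36)
  }
  # the 2-channel softmax form gives the same value as its foreground channel
  p2 <- array(0, c(6, 6, 2)); p1 <- matrix(runif(36, 0.01, 0.99), 6, 6)
  p2[, , 2] <- p1; p2[, , 1] <- 1 - p1
  expect_equal(bce_loss(p2, gt), bce_loss(p1, gt))
})

test_that("binarization follows the threshold and argmax tie rules", {
  expect_identical(binarize(matrix(c(0.49, 0.51), 1, 2)),
                   matrix(c(0, 1), 1, 2))
  expect_identical(binarize(matrix(0.5, 2, 2)), matrix(0, 2, 2))  # tie -> bg
  set.seed(3)
  pr <- array(runif(32), c(4, 4, 2))
  expected <- (apply(pr, c(1, 2), which.max) == 2) * 1
  # which.max breaks ties low, matching ties-to-background
  expect_identical(binarize(pr), expected)
})

test_that("evaluation reports per-image metrics and their unweighted means", {
  samples <- make_phantoms(4, seed = 60, size = c(32L, 32L))
  m <- build_model(model_config("unet", depth = 2, base_width = 2), seed = 5)
  rep <- evaluate_model(m, samples)
  expect_s3_class(rep, "metrics_report")
  expect_identical(nrow(rep$per_image), 4L)
  manual <- vapply(seq_along(samples), function(i) {
    pred <- binarize(model_forward(m, normalize_image(samples[[i]]$image))$prob)
    c(dice(samples[[i]]$mask, pred), jaccard(samples[[i]]$mask, pred))
  }, numeric(2))
  expect_equal(rep$per_image$dice, manual[1, ])
  expect_equal(rep$mean_dice, mean(manual[1, ]))
  expect_equal(rep$mean_jaccard, mean(manual[2, ]))
  expect_error(evaluate_model(m, list()), "empty dataset")

  # a constant-background predictor scores zero on nonempty masks
  m$params[["head.w"]][] <- 0
  m$params[["head.b"]] <- c(10, -10)
  rep0 <- evaluate_model(m, samples)
  expect_identical(rep0$mean_dice, 0)
  expect_identical(rep0$mean_jaccard, 0)
})
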