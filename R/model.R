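#' Block configuration
#'
#' A block is the unit the encoder and decoder are built from: two 3x3
#' convolution units, each followed by a ReLU. The `variant` selects what
#' each convolution unit is:
#' \describe{
#'   \item{`plain`}{an ordinary 3x3 convolution (vanilla U-Net block).}
#'   \item{`shear_only`}{shear transform, 3x3 convolution, inverse shear.}
#'   \item{`deform_only`}{deformable convolution with its own offset predictor.}
#'   \item{`shear_deform`}{shear transform, deformable convolution, inverse
#'     shear — the full composite block.}
#' }
#'
#' @param in_channels,out_channels positive integer channel counts.
#' @param variant block variant, see above.
#' @param shear a [shear_spec()] (default horizontal, factor 0.3, bilinear,
#'   lossless canvas) used by the shear variants.
#' @return An object of class `block_config`.
#' @export
block_config <- function(in_channels, out_channels,
                         variant = c("shear_deform", "plain", "shear_only",
                                     "deform_only"),
                         shear = shear_spec("horizontal", factor = 0.3)) {
  variant <- match.arg(variant)
  stopifnot(in_channels >= 1, out_channels >= 1,
            inherits(shear, "shear_spec"))
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 variant = variant, shear = shear),
            class = "block_config")
}

#' Model configuration
#'
#' Architecture settings for the encoder-decoder. The model `variant` maps
#' every block of the network to a block variant, giving the ablation
#' ladder: `unet` (plain), `st_unet` (shear only), `du_net` (deformable
#' only), `dsu_net` (shear + deformable).
#'
#' @param variant model variant, see above.
#' @param depth number of 2x2 pooling stages (default 4).
#' @param base_width channel width of the first encoder stage (default 64;
#'   widths double at each stage).
#' @param in_channels input channels (grayscale images: 1).
#' @param head `"softmax2"`: 1x1 convolution to 2 channels plus per-pixel
#'   softmax; `"sigmoid1"`: 1x1 convolution to 1 channel plus sigmoid.
#' @param shear the [shear_spec()] shared by all blocks.
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("dsu_net", "unet", "st_unet", "du_net"),
                         depth = 4L, base_width = 64L, in_channels = 1L,
                         head = c("softmax2", "sigmoid1"),
                         shear = shear_spec("horizontal", factor = 0.3)) {
  variant <- match.arg(variant)
  head <- match.arg(head)
  stopifnot(depth >= 1, base_width >= 1, in_channels >= 1,
            inherits(shear, "shear_spec"))
  structure(list(variant = variant, depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 head = head, shear = shear),
            class = "model_config")
}

block_variant_of <- function(model_variant) {
  switch(model_variant,
         unet = "plain", st_unet = "shear_only",
         du_net = "deform_only", dsu_net = "shear_deform")
}

uses_shear <- function(variant) variant %in% c("shear_only", "shear_deform")
uses_deform <- function(variant) variant %in% c("deform_only", "shear_deform")

# ---------------------------------------------------------------------------
# parameter initialisation (He-normal for convs, zeros for offset predictors)
# ---------------------------------------------------------------------------

init_conv <- function(cin, cout) {
  matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), 9 * cin, cout)
}

init_block_params <- function(params, prefix, cin, cout, variant) {
  chans <- c(cin, cout)
  for (j in 1:2) {
    cj <- chans[j]
    params[[paste0(prefix, ".conv", j, ".w")]] <- init_conv(cj, cout)
    params[[paste0(prefix, ".conv", j, ".b")]] <- numeric(cout)
    if (uses_deform(variant)) {
      params[[paste0(prefix, ".conv", j, ".ow")]] <- matrix(0, 9 * cj, 18)
      params[[paste0(prefix, ".conv", j, ".ob")]] <- numeric(18)
    }
  }
  params
}

#' Build a convolution block
#'
#' Constructs a single block (two convolution units with ReLU) with freshly
#' initialised parameters. Mainly useful for inspecting the composite
#' operation in isolation; [build_model()] assembles whole networks from
#' these blocks.
#'
#' @param cfg a [block_config()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `ds_block`; call it on an `H x W x Cin` input
#'   via [forward_block()] or `predict()`.
#' @export
build_block <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "block_config"))
  set.seed(seed)
  params <- init_block_params(list(), "blk", cfg$in_channels,
                              cfg$out_channels, cfg$variant)
  structure(list(config = cfg, params = params), class = "ds_block")
}

#' Run a block forward
#'
#' @param block a [build_block()] result.
#' @param x an `H x W x Cin` array (or `H x W` matrix).
#' @return An `H x W x Cout` array.
#' @export
forward_block <- function(block, x) {
  stopifnot(inherits(block, "ds_block"))
  x <- as_cube(x)
  if (dim(x)[3] != block$config$in_channels)
    stop("input has ", dim(x)[3], " channels, block expects ",
         block$config$in_channels)
  block_fwd(block$params, "blk", x, block$config$variant,
            block$config$shear, keep_cache = FALSE)$out
}

#' @export
predict.ds_block <- function(object, x, ...) forward_block(object, x)

# one convolution unit: [shear ->] (deform | plain) conv [-> inverse shear]
convunit_fwd <- function(params, name, x, variant, shear, keep_cache) {
  H <- dim(x)[1]; W <- dim(x)[2]
  xs <- if (uses_shear(variant)) apply_shear_cube(x, shear) else x
  w <- params[[paste0(name, ".w")]]
  b <- params[[paste0(name, ".b")]]
  if (uses_deform(variant)) {
    off <- conv3x3_fwd(xs, params[[paste0(name, ".ow")]],
                       params[[paste0(name, ".ob")]])
    z <- deform3x3_fwd(xs, w, b, off)
  } else {
    off <- NULL
    z <- conv3x3_fwd(xs, w, b)
  }
  if (uses_shear(variant))
    z <- apply_inverse_shear_cube(z, shear, c(H, W))
  a <- relu_fwd(z)
  cache <- if (keep_cache)
    list(x = x, xs = xs, off = off, mask = z > 0, H = H, W = W) else NULL
  list(out = a, cache = cache)
}

convunit_bwd <- function(params, name, cache, variant, shear, ga) {
  gz <- ga * cache$mask
  grads <- list()
  if (uses_shear(variant))
    gz <- inverse_shear_adjoint_cube(gz, shear, dim(cache$xs)[1:2],
                                     c(cache$H, cache$W))
  w <- params[[paste0(name, ".w")]]
  if (uses_deform(variant)) {
    r <- deform3x3_bwd(cache$xs, w, cache$off, gz)
    grads[[paste0(name, ".w")]] <- r$gw
    grads[[paste0(name, ".b")]] <- r$gb
    ro <- conv3x3_bwd(cache$xs, params[[paste0(name, ".ow")]], r$goff)
    grads[[paste0(name, ".ow")]] <- ro$gw
    grads[[paste0(name, ".ob")]] <- ro$gb
    gxs <- r$gx + ro$gx
  } else {
    r <- conv3x3_bwd(cache$xs, w, gz)
    grads[[paste0(name, ".w")]] <- r$gw
    grads[[paste0(name, ".b")]] <- r$gb
    gxs <- r$gx
  }
  gx <- if (uses_shear(variant))
    shear_adjoint_cube(gxs, shear, c(cache$H, cache$W)) else gxs
  list(gx = gx, grads = grads)
}

block_fwd <- function(params, prefix, x, variant, shear, keep_cache) {
  u1 <- convunit_fwd(params, paste0(prefix, ".conv1"), x, variant, shear,
                     keep_cache)
  u2 <- convunit_fwd(params, paste0(prefix, ".conv2"), u1$out, variant,
                     shear, keep_cache)
  list(out = u2$out,
       cache = if (keep_cache) list(u1 = u1$cache, u2 = u2$cache) else NULL)
}

block_bwd <- function(params, prefix, cache, variant, shear, ga) {
  b2 <- convunit_bwd(params, paste0(prefix, ".conv2"), cache$u2, variant,
                     shear, ga)
  b1 <- convunit_bwd(params, paste0(prefix, ".conv1"), cache$u1, variant,
                     shear, b2$gx)
  list(gx = b1$gx, grads = c(b1$grads, b2$grads))
}

# shear plumbing on cubes (network path: bilinear + lossless canvas)
apply_shear_cube <- function(x, spec) {
  g <- shear_geometry_of(spec, dim(x)[1], dim(x)[2])
  shear_warp(x, spec$factor, spec$direction == "horizontal", g$shift,
             g$out_len, if (spec$interp == "nearest") 0L else 1L)
}

apply_inverse_shear_cube <- function(z, spec, target) {
  H <- target[1]; W <- target[2]
  interp <- if (spec$interp == "nearest") 0L else 1L
  if (spec$direction == "horizontal") {
    g <- shear_geometry_of(spec, H, W)
    shear_warp(z, -spec$factor, TRUE, -g$shift, W, interp)
  } else {
    g <- shear_geometry_of(spec, H, W)
    shear_warp(z, -spec$factor, FALSE, -g$shift, H, interp)
  }
}

# adjoint of apply_inverse_shear_cube (gradient back onto the sheared canvas)
inverse_shear_adjoint_cube <- function(gz, spec, sheared_dims, target) {
  H <- target[1]; W <- target[2]
  interp <- if (spec$interp == "nearest") 0L else 1L
  g <- shear_geometry_of(spec, H, W)
  if (spec$direction == "horizontal")
    shear_warp_adjoint(gz, -spec$factor, TRUE, -g$shift,
                       sheared_dims[1], sheared_dims[2], interp)
  else
    shear_warp_adjoint(gz, -spec$factor, FALSE, -g$shift,
                       sheared_dims[1], sheared_dims[2], interp)
}

# adjoint of apply_shear_cube (gradient back onto the original frame)
shear_adjoint_cube <- function(gxs, spec, orig) {
  H <- orig[1]; W <- orig[2]
  g <- shear_geometry_of(spec, H, W)
  shear_warp_adjoint(gxs, spec$factor, spec$direction == "horizontal",
                     g$shift, H, W,
                     if (spec$interp == "nearest") 0L else 1L)
}

relu_fwd <- function(z) { z[z < 0] <- 0; z }

# ---------------------------------------------------------------------------
# whole model
# ---------------------------------------------------------------------------

#' Build the encoder-decoder segmentation model
#'
#' Assembles the U-Net-style network: `depth` encoder stages of (block,
#' 2x2 max-pool) with channel widths doubling from `base_width`, a
#' bottleneck block, and `depth` decoder stages of (2x2 transposed-convolution
#' upsampling, skip concatenation with the same-level encoder features,
#' block), finished by a 1x1 convolution head with per-pixel softmax (or
#' sigmoid). The model `variant` selects the block type everywhere
#' (ablation ladder `unet`, `st_unet`, `du_net`, `dsu_net`).
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `dsunet_model` holding the configuration and
#'   a named list of parameter arrays.
#' @examples
#' m <- build_model(model_config("unet", base_width = 4, depth = 2))
#' x <- matrix(runif(32 * 32), 32, 32)
#' p <- predict(m, x)            # 32 x 32 x 2 probability field
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(seed)
  bv <- block_variant_of(cfg$variant)
  params <- list()
  widths <- cfg$base_width * 2^(0:(cfg$depth))
  cin <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    params <- init_block_params(params, paste0("enc", i), cin, widths[i], bv)
    cin <- widths[i]
  }
  params <- init_block_params(params, "bottleneck", cin,
                              widths[cfg$depth + 1], bv)
  for (i in rev(seq_len(cfg$depth))) {
    cup_in <- if (i == cfg$depth) widths[cfg$depth + 1] else widths[i + 1]
    cout <- widths[i]
    params[[paste0("up", i, ".w")]] <-
      matrix(rnorm(cup_in * 4 * cout, sd = sqrt(2 / cup_in)), cup_in, 4 * cout)
    params[[paste0("up", i, ".b")]] <- numeric(cout)
    params <- init_block_params(params, paste0("dec", i), 2L * cout, cout, bv)
  }
  nhead <- if (cfg$head == "softmax2") 2L else 1L
  params[["head.w"]] <- matrix(rnorm(cfg$base_width * nhead,
                                     sd = sqrt(2 / cfg$base_width)),
                               cfg$base_width, nhead)
  params[["head.b"]] <- numeric(nhead)
  structure(list(config = cfg, params = params), class = "dsunet_model")
}

#' @export
print.dsunet_model <- function(x, ...) {
  cat(sprintf(
    "dsunet_model: variant %s, depth %d, base width %d, %s head, %d parameters\n",
    x$config$variant, x$config$depth, x$config$base_width, x$config$head,
    n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a [build_model()] result.
#' @return Integer parameter count.
#' @export
n_params <- function(model) sum(vapply(model$params, length, integer(1)))

#' Copy shared weights between models
#'
#' Copies every parameter whose name and shape match from `from` into `to`.
#' Used to compare ablation variants under identical weights (e.g. the
#' reduction of the full block to a plain convolution at shear factor 0 and
#' zero offsets).
#'
#' @param to,from models from [build_model()].
#' @return `to` with the shared parameters replaced.
#' @export
copy_shared_weights <- function(to, from) {
  for (nm in intersect(names(to$params), names(from$params)))
    if (identical(dim(to$params[[nm]]), dim(from$params[[nm]])) &&
        length(to$params[[nm]]) == length(from$params[[nm]]))
      to$params[[nm]] <- from$params[[nm]]
  to
}

#' Model forward pass
#'
#' @param model a [build_model()] result.
#' @param x input image: `H x W` matrix or `H x W x in_channels` array with
#'   `H`, `W` divisible by `2^depth`.
#' @param keep_cache keep intermediate activations for a backward pass
#'   (training use).
#' @return A list with `prob` (per-pixel class probabilities, `H x W x 2`
#'   for the softmax head), `logits`, and (if requested) `cache`.
#' @export
model_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  x <- as_cube(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H %% 2^cfg$depth != 0 || W %% 2^cfg$depth != 0)
    stop("input spatial dims (", H, " x ", W, ") must be divisible by 2^depth = ",
         2^cfg$depth, "; pad the image first")
  bv <- block_variant_of(cfg$variant)
  sh <- cfg$shear
  p <- model$params
  skips <- list(); caches <- list()
  h <- x
  for (i in seq_len(cfg$depth)) {
    bf <- block_fwd(p, paste0("enc", i), h, bv, sh, keep_cache)
    skips[[i]] <- bf$out
    if (keep_cache) caches[[paste0("enc", i)]] <- bf$cache
    mp <- maxpool2_fwd(bf$out)
    if (keep_cache) caches[[paste0("pool", i)]] <- mp$arg
    h <- mp$y
  }
  bf <- block_fwd(p, "bottleneck", h, bv, sh, keep_cache)
  if (keep_cache) caches[["bottleneck"]] <- bf$cache
  h <- bf$out
  for (i in rev(seq_len(cfg$depth))) {
    if (keep_cache) caches[[paste0("upin", i)]] <- h
    up <- tconv2_fwd(h, p[[paste0("up", i, ".w")]], p[[paste0("up", i, ".b")]])
    cat_in <- abind3(skips[[i]], up)
    bf <- block_fwd(p, paste0("dec", i), cat_in, bv, sh, keep_cache)
    if (keep_cache) caches[[paste0("dec", i)]] <- bf$cache
    h <- bf$out
  }
  if (keep_cache) caches[["headin"]] <- h
  logits <- conv1x1_fwd(h, p[["head.w"]], p[["head.b"]])
  prob <- if (cfg$head == "softmax2") softmax2(logits)
          else sigmoid_arr(logits)
  list(prob = prob, logits = logits,
       cache = if (keep_cache) caches else NULL)
}

#' Model backward pass
#'
#' Backpropagates a gradient with respect to the logits through the whole
#' network.
#'
#' @param model a [build_model()] result.
#' @param cache the cache returned by [model_forward()] with
#'   `keep_cache = TRUE`.
#' @param glogits gradient of the scalar loss w.r.t. the logits.
#' @return A named list of parameter gradients (same names as
#'   `model$params`).
#' @export
model_backward <- function(model, cache, glogits) {
  cfg <- model$config
  bv <- block_variant_of(cfg$variant)
  sh <- cfg$shear
  p <- model$params
  grads <- list()
  r <- conv1x1_bwd(cache[["headin"]], p[["head.w"]], glogits)
  grads[["head.w"]] <- r$gw; grads[["head.b"]] <- r$gb
  gh <- r$gx
  gskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    bb <- block_bwd(p, paste0("dec", i), cache[[paste0("dec", i)]], bv, sh, gh)
    grads <- c(grads, bb$grads)
    cs <- dim(cache[[paste0("enc", i)]]$u2$mask)[3]  # skip channels
    gskip <- bb$gx[, , seq_len(cs), drop = FALSE]
    gup <- bb$gx[, , -seq_len(cs), drop = FALSE]
    rt <- tconv2_bwd(cache[[paste0("upin", i)]], p[[paste0("up", i, ".w")]], gup)
    grads[[paste0("up", i, ".w")]] <- rt$gw
    grads[[paste0("up", i, ".b")]] <- rt$gb
    gskips[[i]] <- gskip
    gh <- rt$gx
  }
  bb <- block_bwd(p, "bottleneck", cache[["bottleneck"]], bv, sh, gh)
  grads <- c(grads, bb$grads)
  gh <- bb$gx
  for (i in rev(seq_len(cfg$depth))) {
    gpool <- maxpool2_bwd(gh, cache[[paste0("pool", i)]])
    gout <- gpool + gskips[[i]]
    bb <- block_bwd(p, paste0("enc", i), cache[[paste0("enc", i)]], bv, sh, gout)
    grads <- c(grads, bb$grads)
    gh <- bb$gx
  }
  grads
}

#' Predict segmentation probabilities
#'
#' @param object a [build_model()] result.
#' @param x input image (`H x W` matrix or `H x W x C` array).
#' @param type `"prob"` for the probability field, `"mask"` for the
#'   binarized mask.
#' @param ... unused.
#' @return Probability array or binary `H x W` mask.
#' @export
predict.dsunet_model <- function(object, x, type = c("prob", "mask"), ...) {
  type <- match.arg(type)
  out <- model_forward(object, x)
  if (type == "prob") out$prob else binarize(out$prob)
}

# ---- small array helpers ---------------------------------------------------

abind3 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

conv1x1_fwd <- function(x, w, b) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  ym <- xm %*% w
  ym <- sweep(ym, 2, b, "+")
  array(ym, c(d[1], d[2], ncol(w)))
}

conv1x1_bwd <- function(x, w, gy) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  gym <- matrix(gy, d[1] * d[2], ncol(w))
  list(gx = array(gym %*% t(w), d),
       gw = t(xm) %*% gym,
       gb = colSums(gym))
}

softmax2 <- function(logits) {
  m <- pmax(logits[, , 1], logits[, , 2])
  e1 <- exp(logits[, , 1] - m); e2 <- exp(logits[, , 2] - m)
  s <- e1 + e2
  out <- logits
  out[, , 1] <- e1 / s; out[, , 2] <- e2 / s
  out
}

sigmoid_arr <- function(z) 1 / (1 + exp(-z))
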