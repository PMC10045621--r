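#' Training configuration
#'
#' Optimization settings. The defaults are the study settings: Adam with
#' learning rate 0.001, 80 epochs, batch size 8.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs number of passes over the training set (default 80).
#' @param batch_size samples per optimization step (default 8).
#' @param optimizer only `"Adam"` is supported (betas 0.9/0.999,
#'   epsilon 1e-8).
#' @param seed integer seed controlling initial shuffling, augmentation
#'   draws and any other randomness of the loop.
#' @param checkpoint_dir if non-`NULL`, the best checkpoint (`best.rds`)
#'   and a line-oriented `train.log` are written there.
#' @param device `"cpu"` (the only backend).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 80L, batch_size = 8L,
                         optimizer = "Adam", seed = 1L,
                         checkpoint_dir = NULL, device = "cpu") {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            identical(optimizer, "Adam"), device %in% c("cpu", "accelerator"))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
                 device = device),
            class = "train_config")
}

# cross entropy from logits + gradient (numerically stable)
ce_from_logits <- function(logits, gt, head) {
  if (head == "softmax2") {
    m <- pmax(logits[, , 1], logits[, , 2])
    lse <- m + log(exp(logits[, , 1] - m) + exp(logits[, , 2] - m))
    zt <- gt * logits[, , 2] + (1 - gt) * logits[, , 1]
    loss <- mean(lse - zt)
    p2 <- exp(logits[, , 2] - lse)
    n <- length(gt)
    g <- logits
    g[, , 2] <- (p2 - gt) / n
    g[, , 1] <- ((1 - p2) - (1 - gt)) / n
    list(loss = loss, glogits = g)
  } else {
    z <- logits[, , 1]
    loss <- mean(pmax(z, 0) - z * gt + log1p(exp(-abs(z))))
    p <- 1 / (1 + exp(-z))
    g <- logits
    g[, , 1] <- (p - gt) / length(gt)
    list(loss = loss, glogits = g)
  }
}

zero_like <- function(params) lapply(params, function(p) p * 0)

#' Train a segmentation model
#'
#' Mini-batch Adam on per-pixel cross entropy (binary cross entropy for
#' this two-class problem). Images are per-channel normalized before the
#' forward pass. Per-epoch training loss and validation Dice are logged;
#' the checkpoint with the best validation Dice is retained (the final
#' epoch if no validation set is given). Fully reproducible for a fixed
#' seed.
#'
#' @param model a [build_model()] result.
#' @param train_data non-empty list of [sample_pair()]s with masks.
#' @param val_data optional validation list.
#' @param cfg a [train_config()].
#' @param augment optional [augmentation_config()] applied to each training
#'   sample each epoch.
#' @param verbose print one line per epoch.
#' @return An object of class `train_result`: list with `model` (best
#'   checkpoint), `final_model`, `history` (data frame `epoch`, `loss`,
#'   `val_dice`), `best_epoch`.
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        cfg = train_config(), augment = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "dsunet_model"), inherits(cfg, "train_config"))
  if (length(train_data) == 0L) stop("empty training set")
  set.seed(cfg$seed)
  head <- model$config$head
  mstate <- zero_like(model$params)
  vstate <- zero_like(model$params)
  tstep <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_dice = numeric())
  best <- list(dice = -Inf, params = model$params, epoch = 0L)
  logfile <- NULL
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(cfg$checkpoint_dir, "train.log")
    cat(sprintf("[%s] start: %d train / %d val, lr %g, batch %d, %d epochs\n",
                format(Sys.time()), length(train_data), length(val_data),
                cfg$learning_rate, cfg$batch_size, cfg$epochs),
        file = logfile)
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(train_data))
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      ids <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      gacc <- NULL
      bloss <- 0
      for (i in ids) {
        s <- train_data[[i]]
        if (!is.null(augment)) s <- augment_sample(s, augment)
        x <- normalize_image(s$image)
        fw <- model_forward(model, x, keep_cache = TRUE)
        ce <- ce_from_logits(fw$logits, s$mask, head)
        bloss <- bloss + ce$loss
        g <- model_backward(model, fw$cache, ce$glogits)
        gacc <- if (is.null(gacc)) g
                else Map(`+`, gacc, g[names(gacc)])
      }
      k <- length(ids)
      tstep <- tstep + 1L
      for (nm in names(model$params)) {
        gn <- gacc[[nm]] / k
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gn
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gn * gn
        mhat <- mstate[[nm]] / (1 - b1^tstep)
        vhat <- vstate[[nm]] / (1 - b2^tstep)
        model$params[[nm]] <- model$params[[nm]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      epoch_loss <- epoch_loss + bloss / k
      nb <- nb + 1L
    }
    epoch_loss <- epoch_loss / nb
    vd <- NA_real_
    if (!is.null(val_data) && length(val_data) > 0) {
      vd <- evaluate_model(model, val_data)$mean_dice
      if (vd > best$dice)
        best <- list(dice = vd, params = model$params, epoch = epoch)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss,
                                val_dice = vd))
    line <- sprintf("epoch %d: loss %.5f val_dice %s", epoch, epoch_loss,
                    ifelse(is.na(vd), "NA", sprintf("%.4f", vd)))
    if (verbose) message(line)
    if (!is.null(logfile))
      cat(sprintf("[%s] %s\n", format(Sys.time()), line),
          file = logfile, append = TRUE)
  }
  final_model <- model
  if (is.finite(best$dice)) model$params <- best$params
  else best$epoch <- cfg$epochs
  result <- structure(list(model = model, final_model = final_model,
                           history = history, best_epoch = best$epoch),
                      class = "train_result")
  if (!is.null(cfg$checkpoint_dir))
    save_checkpoint(model, file.path(cfg$checkpoint_dir, "best.rds"))
  result
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("train_result: %d epochs, final loss %.5f, best epoch %d\n",
              nrow(x$history), tail(x$history$loss, 1), x$best_epoch))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files holding the model configuration and parameter
#' arrays.
#'
#' @param model a [build_model()] result.
#' @param path `.rds` file path.
#' @return `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dsunet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dsunet_model")) stop("not a model checkpoint: ", path)
  model
}
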