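as_mask <- function(m) {
  if (inherits(m, "sample_pair")) m <- m$mask
  m
}

check_same_shape <- function(gt, sr) {
  if (!identical(dim(gt), dim(sr)))
    stop("shape mismatch: ", paste(dim(gt), collapse = " x "), " vs ",
         paste(dim(sr), collapse = " x "))
}

#' Dice coefficient
#'
#' Overlap similarity between a ground-truth mask `GT` and a segmentation
#' result `SR`: `2|GT n SR| / (|GT| + |SR|)`. Two empty masks are in
#' vacuous agreement and score 1.
#'
#' @param gt,sr binary masks of equal shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(gt, sr) {
  gt <- as_mask(gt); sr <- as_mask(sr)
  check_same_shape(gt, sr)
  a <- sum(gt); b <- sum(sr)
  if (a + b == 0) return(1)
  2 * sum(gt * sr) / (a + b)
}

#' Jaccard coefficient (intersection over union)
#'
#' `|GT n SR| / (|GT| + |SR| - |GT n SR|)`. Two empty masks score 1.
#' For hard masks `J = D / (2 - D)` where `D` is the [dice()] coefficient.
#'
#' @param gt,sr binary masks of equal shape.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(gt, sr) {
  gt <- as_mask(gt); sr <- as_mask(sr)
  check_same_shape(gt, sr)
  i <- sum(gt * sr)
  u <- sum(gt) + sum(sr) - i
  if (u == 0) return(1)
  i / u
}

#' Soft (differentiable) Dice coefficient
#'
#' Approximates the intersection by the dot product of the probability map
#' with the label: `2 * sum(prob * gt) / (sum(prob) + sum(gt))`. Equals the
#' hard [dice()] when `prob` is binary.
#'
#' @param prob probability map in `[0, 1]`, same shape as `gt`.
#' @param gt binary mask.
#' @return A number in `[0, 1]`.
#' @export
soft_dice <- function(prob, gt) {
  gt <- as_mask(gt)
  check_same_shape(gt, prob)
  if (any(prob < 0 | prob > 1)) stop("prob must lie in [0, 1]")
  s <- sum(prob) + sum(gt)
  if (s == 0) return(1)
  2 * sum(prob * gt) / s
}

#' Mean per-pixel binary cross entropy
#'
#' For a foreground-probability map `p` and binary target `y`:
#' `mean(-(y * log p + (1 - y) * log(1 - p)))`. A two-channel softmax
#' output may be passed directly; its foreground channel (slice 2) is used,
#' which makes the value identical to two-class cross entropy.
#'
#' @param pred probability map (`H x W`, `H x W x 1` or `H x W x 2`).
#' @param gt binary mask.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(pred, gt) {
  gt <- as_mask(gt)
  p <- fg_prob(pred)
  check_same_shape(gt, p)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(gt * log(p) + (1 - gt) * log(1 - p)))
}

fg_prob <- function(pred) {
  d <- dim(pred)
  if (length(d) == 3L) {
    if (d[3] == 2L) pred[, , 2] else pred[, , 1]
  } else pred
}

#' Binarize a probability map
#'
#' Two-channel softmax output: per-pixel argmax with ties going to the
#' background. Single-channel sigmoid output: threshold at 0.5, with an
#' exact 0.5 mapping to background.
#'
#' @param prob probability map (`H x W`, `H x W x 1` or `H x W x 2`).
#' @return A binary `H x W` mask (0 background, 1 organ).
#' @export
binarize <- function(prob) {
  d <- dim(prob)
  if (length(d) == 3L && d[3] == 2L)
    (prob[, , 2] > prob[, , 1]) * 1
  else
    (fg_prob(prob) > 0.5) * 1
}

#' Evaluate a model on a dataset
#'
#' Runs the model on every sample, binarizes the predictions, and reports
#' per-image hard Dice and Jaccard with unweighted means.
#'
#' @param model a [build_model()] result (trained or not).
#' @param dataset a list of [sample_pair()]s with masks.
#' @param normalize normalize each image before the forward pass (must
#'   match how the model was trained).
#' @return An object of class `metrics_report`: list with `per_image`
#'   (data frame `id`, `dice`, `jaccard`), `mean_dice`, `mean_jaccard`.
#' @export
evaluate_model <- function(model, dataset, normalize = TRUE) {
  if (length(dataset) == 0L) stop("empty dataset")
  rows <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    x <- if (normalize) normalize_image(s$image) else s$image
    pred <- binarize(model_forward(model, x)$prob)
    data.frame(id = i, dice = dice(s$mask, pred),
               jaccard = jaccard(s$mask, pred))
  })
  per_image <- do.call(rbind, rows)
  structure(list(per_image = per_image,
                 mean_dice = mean(per_image$dice),
                 mean_jaccard = mean(per_image$jaccard)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %d images, mean Dice %.4f, mean Jaccard %.4f\n",
              nrow(x$per_image), x$mean_dice, x$mean_jaccard))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Per-image metrics as CSV (`id`, `dice`, `jaccard`) and the summary as
#' JSON.
#'
#' @param report a [evaluate_model()] result.
#' @param dir output directory (created if missing).
#' @return The file paths, invisibly.
#' @export
write_metrics <- function(report, dir) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "metrics.csv")
  js <- file.path(dir, "metrics.json")
  write.csv(report$per_image, csv, row.names = FALSE)
  jsonlite::write_json(list(n = nrow(report$per_image),
                            mean_dice = report$mean_dice,
                            mean_jaccard = report$mean_jaccard),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
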