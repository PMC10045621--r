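#' Default run configuration
#'
#' The run configuration is a nested list with sections `phantom`,
#' `augment`, `model`, `train` and `paths`, serialized as a single YAML
#' file. [load_run_config()] merges a user file over these defaults and
#' rejects unknown keys; commands write a fully resolved copy next to
#' their outputs so every run can be repeated from it.
#'
#' @return A nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    phantom = list(size = c(64L, 64L), contour_harmonics = 5L,
                   boundary_blur_sigma = 1.2, speckle_strength = 0.25,
                   inhomogeneity_strength = 0.3,
                   area_fraction_range = c(0.08, 0.35), seed = 1L),
    augment = list(enabled = FALSE, max_translation_fraction = 0.1,
                   crop_fraction = 0.9, hflip_probability = 0.5),
    model = list(variant = "dsu_net", depth = 4L, base_width = 64L,
                 in_channels = 1L, head = "softmax2",
                 shear_direction = "horizontal", shear_factor = 0.3),
    train = list(learning_rate = 0.001, epochs = 80L, batch_size = 8L,
                 optimizer = "Adam", seed = 1L),
    paths = list(data_dir = NULL, out_dir = NULL, checkpoint = NULL)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    else
      defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load and resolve a run configuration
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides optional nested list applied after the file (e.g. from
#'   command-line flags).
#' @return The resolved configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

#' Write a resolved configuration
#'
#' @param cfg a configuration list.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

phantom_config_from <- function(cfg) {
  p <- cfg$phantom
  phantom_config(size = as.integer(p$size),
                 contour_harmonics = p$contour_harmonics,
                 boundary_blur_sigma = p$boundary_blur_sigma,
                 speckle_strength = p$speckle_strength,
                 inhomogeneity_strength = p$inhomogeneity_strength,
                 area_fraction_range = p$area_fraction_range,
                 seed = p$seed)
}

model_config_from <- function(cfg) {
  m <- cfg$model
  model_config(variant = m$variant, depth = m$depth,
               base_width = m$base_width, in_channels = m$in_channels,
               head = m$head,
               shear = shear_spec(m$shear_direction,
                                  factor = m$shear_factor))
}

train_config_from <- function(cfg, checkpoint_dir = NULL) {
  t <- cfg$train
  train_config(learning_rate = t$learning_rate, epochs = t$epochs,
               batch_size = t$batch_size, optimizer = t$optimizer,
               seed = t$seed, checkpoint_dir = checkpoint_dir)
}
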