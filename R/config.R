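#' Default run configuration
#'
#' The single nested configuration that drives every pipeline stage:
#' `synth` (dataset sizes + [synth_config()] knobs), `model`
#' ([model_config()] knobs), `train` ([train_config()] knobs incl. loss
#' weights), `eval` (test-set size and operating points), `finetune`
#' (Dice-only epochs; 0 disables), plus the global `seed` and `out_dir`.
#' Per-stage seeds are derived deterministically from the global seed.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "cadpair_run",
    verbose = FALSE,
    synth = list(n_train_pairs = 128L, n_val_pairs = 32L, image_size = 32L,
                 sphere_count = c(2L, 4L), radius = c(1.8, 3.5),
                 bbox_halfwidth = 4, attenuation = c(0.02, 0.07),
                 blend_ratio = c(0.3, 1.0), label_threshold = 0.01,
                 nodule_polarity = "bright", noise_sd = 0.02,
                 rib_freq = 5, rib_amp = 0.05),
    model = list(levels = 3L, base_channels = 8L, residual = TRUE,
                 use_bottleneck_dense = FALSE),
    train = list(epochs = 20L, batch_size = 8L, learning_rate = 1e-3,
                 w_dice = 1, w_necmos = 1, w_nac = 1, epsilon = 1),
    eval = list(n_test_pairs = 32L, iou_min = 0.1, fp_rate = 0.2,
                specificity = 0.8),
    finetune = list(epochs = 0L)
  )
}

#' Smoke-test run configuration
#'
#' A minutes-scale preset of the full pipeline (16 pairs, 2 epochs,
#' 32 px) for end-to-end checks; the default configuration is the
#' desk-scale benchmark.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return A `run_config`.
#' @export
smoke_run_config <- function(out_dir = "cadpair_smoke", seed = 1L) {
  as_run_config(list(seed = seed, out_dir = out_dir,
                     synth = list(n_train_pairs = 12L, n_val_pairs = 4L),
                     train = list(epochs = 2L),
                     eval = list(n_test_pairs = 8L)))
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key: '", full, "'")
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key '", full, "' must be a mapping")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration file
#'
#' Reads a YAML file, fills every missing key with its default, and
#' rejects unknown keys by name. An empty or minimal file (e.g. only
#' `seed`) is valid.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  as_run_config(user)
}

#' Coerce a (partial) list into a validated run configuration
#' @param user Partial named list of overrides.
#' @return A `run_config` list with all defaults filled.
#' @export
as_run_config <- function(user = list()) {
  cfg <- merge_config(default_run_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' 32-bit FNV-1a over the deparsed canonical form; used to stamp every
#' artifact (manifest, checkpoint, report) so a report can be traced back
#' to the exact configuration that produced it.
#'
#' @param config Any R object (typically a `run_config`).
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  s <- paste(deparse(unclass(config), control = "exact"), collapse = "\n")
  bytes <- utf8ToInt(s)
  # FNV-1a in 16-bit halves: R has no unsigned 32-bit integers and doubles
  # cannot hold the full 32x24-bit product exactly
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- ((lo * p) %% 4294967296 + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage seeds, kept well below 2^31
  offsets <- c(synth = 1L, test = 2L, train = 3L, finetune = 4L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

synth_config_from <- function(cfg) {
  s <- cfg$synth
  synth_config(image_size = s$image_size, sphere_count = s$sphere_count,
               radius = s$radius, bbox_halfwidth = s$bbox_halfwidth,
               attenuation = s$attenuation, blend_ratio = s$blend_ratio,
               label_threshold = s$label_threshold,
               nodule_polarity = s$nodule_polarity, noise_sd = s$noise_sd,
               rib_freq = s$rib_freq, rib_amp = s$rib_amp)
}

model_config_from <- function(cfg) {
  m <- cfg$model
  model_config(levels = m$levels, base_channels = m$base_channels,
               input_size = cfg$synth$image_size, residual = m$residual,
               use_bottleneck_dense = m$use_bottleneck_dense)
}

train_config_from <- function(cfg) {
  t <- cfg$train
  train_config(epochs = t$epochs, batch_size = t$batch_size,
               learning_rate = t$learning_rate,
               weights = loss_weights(t$w_dice, t$w_necmos, t$w_nac,
                                      t$epsilon),
               seed = stage_seed(cfg$seed, "train"), iou_min = cfg$eval$iou_min,
               verbose = isTRUE(cfg$verbose))
}
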