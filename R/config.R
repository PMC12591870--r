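#' Training hyper-parameters for the detection architectures
#'
#' Carries the training schedule used for the cutter-slot/tumor detectors:
#' SGD with momentum at an initial learning rate of 0.01, batch size 64, up
#' to 333 epochs with early stopping after 55 epochs without validation
#' improvement. The momentum value is the family-standard default (0.937),
#' exposed here because the schedule itself does not pin it.
#'
#' @param optimizer One of `"SGD"`, `"Adam"`, `"AdamW"`, `"NAdam"`.
#' @param learning_rate Initial learning rate (> 0).
#' @param momentum SGD momentum.
#' @param batch_size Images per step.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience, epochs (< `epochs`).
#' @param seed Integer seed.
#' @return A list with class `"training_config"`.
#' @export
training_config <- function(optimizer = "SGD", learning_rate = 0.01,
                            momentum = 0.937, batch_size = 64,
                            epochs = 333, patience = 55, seed = 0L) {
  optimizer <- match.arg(optimizer, c("SGD", "Adam", "AdamW", "NAdam"))
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            patience >= 1, patience < epochs)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Data-augmentation settings for detector training
#'
#' The augmentation recipe used for ultrasound frames: colour (HSV) gains,
#' random erasing, horizontal flips, mosaic composition and mild scaling;
#' rotation is disabled because probe orientation is meaningful.
#'
#' @param crop_fraction Random crop fraction.
#' @param degrees Rotation range, degrees.
#' @param erasing Random-erasing probability.
#' @param fliplr Horizontal-flip probability.
#' @param hsv_h,hsv_s,hsv_v HSV hue/saturation/value gains.
#' @param mosaic Mosaic probability.
#' @param scale Scaling gain.
#' @return A list with class `"augmentation_config"`.
#' @export
augmentation_config <- function(crop_fraction = 1, degrees = 0, erasing = 0.4,
                                fliplr = 0.5, hsv_h = 0.015, hsv_s = 0.7,
                                hsv_v = 0.4, mosaic = 0.5, scale = 0.2) {
  probs <- c(erasing = erasing, fliplr = fliplr, mosaic = mosaic)
  if (any(probs < 0 | probs > 1)) {
    stop("augmentation probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(crop_fraction = crop_fraction, degrees = degrees,
                 erasing = erasing, fliplr = fliplr, hsv_h = hsv_h,
                 hsv_s = hsv_s, hsv_v = hsv_v, mosaic = mosaic, scale = scale),
            class = "augmentation_config")
}

#' Full run configuration
#'
#' @param training A [training_config()].
#' @param augmentation An [augmentation_config()].
#' @param decision A [decision_config()].
#' @return A list with class `"rotoloc_config"`.
#' @export
rotoloc_config <- function(training = training_config(),
                           augmentation = augmentation_config(),
                           decision = decision_config()) {
  structure(list(training = training, augmentation = augmentation,
                 decision = decision),
            class = "rotoloc_config")
}

config_sections <- c("training", "augmentation", "decision")

#' Load a YAML run configuration
#'
#' Merges, in order: package defaults, the YAML file, then explicit
#' overrides. Configuration keys live under the sections `training`,
#' `augmentation` and `decision`. Unknown keys are rejected with the closest
#' valid key named; values must match the type of the default.
#'
#' @param path YAML file (optional; defaults only when `NULL`).
#' @param overrides Named nested list applied last, e.g.
#'   `list(training = list(batch_size = 32))`.
#' @return A [rotoloc_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- rotoloc_config()
  apply_layer <- function(cfg, layer, origin) {
    bad_sections <- setdiff(names(layer), config_sections)
    if (length(bad_sections)) {
      stop(sprintf("config error (%s): unknown section '%s'; valid: %s",
                   origin, bad_sections[1],
                   paste(config_sections, collapse = ", ")), call. = FALSE)
    }
    for (sec in names(layer)) {
      vals <- layer[[sec]]
      valid <- names(cfg[[sec]])
      for (key in names(vals)) {
        if (!key %in% valid) {
          near <- valid[which.min(utils::adist(key, valid))]
          stop(sprintf(
            "config error (%s): unknown key '%s' in section '%s'; did you mean '%s'? valid keys: %s",
            origin, key, sec, near, paste(valid, collapse = ", ")),
            call. = FALSE)
        }
        old <- cfg[[sec]][[key]]
        new <- vals[[key]]
        if (is.numeric(old) && !is.numeric(new)) {
          stop(sprintf("config error (%s): key '%s' must be numeric", origin, key),
               call. = FALSE)
        }
        if (is.character(old) && !is.character(new)) {
          stop(sprintf("config error (%s): key '%s' must be character", origin, key),
               call. = FALSE)
        }
        if (is.logical(old) && !is.logical(new)) {
          stop(sprintf("config error (%s): key '%s' must be logical", origin, key),
               call. = FALSE)
        }
        cfg[[sec]][[key]] <- if (is.integer(old)) as.integer(new) else new
      }
      # re-validate through the constructor
      cfg[[sec]] <- switch(sec,
        training = do.call(training_config, unclass(cfg[[sec]])),
        augmentation = do.call(augmentation_config, unclass(cfg[[sec]])),
        decision = do.call(decision_config, unclass(cfg[[sec]]))
      )
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config error: no such file: ", path,
                                 call. = FALSE)
    file_cfg <- yaml::read_yaml(path)
    if (length(file_cfg)) cfg <- apply_layer(cfg, file_cfg, path)
  }
  if (length(overrides)) cfg <- apply_layer(cfg, overrides, "overrides")
  cfg
}

#' Write a configuration as YAML
#'
#' `load_config(write_config(cfg, path))` reproduces `cfg`.
#'
#' @param cfg A [rotoloc_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "rotoloc_config"))
  yaml::write_yaml(lapply(cfg, unclass), path)
  invisible(path)
}

#' Train a detection architecture (not provided)
#'
#' rotoloc implements architecture planning, complexity accounting, the
#' activation decision logic, metrics and simulation — not gradient-based
#' network training, which needs a GPU deep-learning runtime. Datasets
#' written by [write_yolo_dataset()] and configurations written by
#' [write_config()] are laid out so the standard trainer of this detector
#' family can consume them directly; checkpoints trained elsewhere can be
#' evaluated with [detection_report()] on exported predictions.
#'
#' @param manifest A [write_yolo_dataset()] manifest.
#' @param arch Architecture name (see [arch_names()]).
#' @param cfg A [training_config()].
#' @return Never returns; always raises a `rotoloc_no_backend_error`.
#' @export
train <- function(manifest, arch = "yolov11n_plus", cfg = training_config()) {
  stop(rlang::error_cnd(
    class = "rotoloc_no_backend_error",
    message = paste(
      "gradient-based training of the detection architectures is outside",
      "rotoloc's scope (it requires a GPU deep-learning runtime).",
      "Export the dataset with write_yolo_dataset() and the configuration",
      "with write_config() and train with the detector family's standard",
      "trainer; evaluate resulting predictions with detection_report()."
    )
  ))
}
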