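# Model-interface contract: every attribution method and metric in the
# package talks to a classifier only through a `classifier_handle`, so the
# whole pipeline is model-agnostic. A handle wraps
#   * predict_scores(image)  -> per-class real-valued scores (logits),
#   * predict_probs(image)   -> per-class probabilities (softmax of scores
#                               unless the model defines them directly),
#   * gradient(image, target)             [optional capability],
#   * features(image, layer, target, ...) [optional capability],
#   * deeplift(image, baseline, target)   [optional, for models built from
#                                          supported primitive layers].
# Class indices are 0-based (disease grades 0..4) throughout the user API.

#' Input specification for a classifier
#'
#' Describes the tensor contract a classifier expects: spatial size, channel
#' count, intensity range and number of classes. The defaults mirror the
#' standard fundus-grading setup: 224 x 224 RGB in \[0, 1\] with five grades.
#'
#' @param height,width Image size in pixels.
#' @param channels Number of channels (3 = RGB).
#' @param value_range Closed intensity interval, `c(lower, upper)`.
#' @param num_classes Number of output classes.
#' @return An object of class `input_spec`.
#' @export
input_spec <- function(height = 224L, width = 224L, channels = 3L,
                       value_range = c(0, 1), num_classes = 5L) {
  stopifnot(height > 0, width > 0, channels > 0, num_classes > 0,
            length(value_range) == 2, value_range[1] < value_range[2])
  structure(list(height = as.integer(height), width = as.integer(width),
                 channels = as.integer(channels),
                 value_range = as.numeric(value_range),
                 num_classes = as.integer(num_classes)),
            class = "input_spec")
}

#' Wrap a classifier in the model-interface contract
#'
#' @param identity Free-text model name.
#' @param spec An [input_spec()].
#' @param predict_scores Function `image -> numeric(num_classes)` of
#'   real-valued class scores. Must be deterministic (inference mode).
#' @param predict_probs Optional function `image -> probabilities`; defaults
#'   to the softmax of `predict_scores`.
#' @param gradient Optional function `(image, target) -> array` giving the
#'   gradient of the target-class score w.r.t. every input intensity. Its
#'   presence grants the `differentiable` capability.
#' @param features Optional function
#'   `(image, layer, target, with_gradients) -> list(maps, grads)` returning a
#'   stack of 2-D activation maps (`h x w x C` array) and, when requested, the
#'   gradient of the target score w.r.t. each activation. Grants the
#'   `exposes_feature_maps` capability.
#' @param layers Character vector of feature-layer ids; the first entry is the
#'   default (conventionally the last convolutional stage).
#' @param deeplift Optional function `(image, baseline, target) -> array` of
#'   DeepLIFT-Rescale contributions, available for models built from supported
#'   primitive layers.
#' @return An object of class `classifier_handle`.
#' @export
classifier_handle <- function(identity, spec, predict_scores,
                              predict_probs = NULL, gradient = NULL,
                              features = NULL, layers = character(),
                              deeplift = NULL) {
  stopifnot(inherits(spec, "input_spec"), is.function(predict_scores))
  if (is.null(predict_probs)) {
    predict_probs <- function(image) softmax(predict_scores(image))
  }
  structure(list(
    identity = as.character(identity),
    spec = spec,
    capabilities = c(differentiable = !is.null(gradient),
                     exposes_feature_maps = !is.null(features)),
    predict_scores = predict_scores,
    predict_probs = predict_probs,
    gradient = gradient,
    features = features,
    layers = layers,
    deeplift = deeplift
  ), class = "classifier_handle")
}

#' @export
print.classifier_handle <- function(x, ...) {
  caps <- names(x$capabilities)[x$capabilities]
  cat(sprintf("<classifier_handle> %s\n  input: %dx%dx%d, %d classes\n  capabilities: %s\n",
              x$identity, x$spec$height, x$spec$width, x$spec$channels,
              x$spec$num_classes,
              if (length(caps)) paste(caps, collapse = ", ") else "(none)"))
  invisible(x)
}

# validate an image against a handle's input spec
check_image <- function(handle, image) {
  spec <- handle$spec
  d <- dim(image)
  if (is.null(d) || length(d) != 3 ||
      !all(d == c(spec$height, spec$width, spec$channels))) {
    stop(sprintf("input-contract error: image shape (%s) does not match spec %dx%dx%d",
                 paste(d, collapse = "x"), spec$height, spec$width,
                 spec$channels), call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop("input-contract error: image contains non-finite values", call. = FALSE)
  }
  invisible(TRUE)
}

check_target <- function(handle, target) {
  if (length(target) != 1 || target < 0 || target >= handle$spec$num_classes ||
      target != floor(target)) {
    stop(sprintf("input-contract error: target class %s not in [0, %d)",
                 format(target), handle$spec$num_classes), call. = FALSE)
  }
  invisible(TRUE)
}

#' Class probabilities for an image
#'
#' @param handle A [classifier_handle()].
#' @param image Image array matching the handle's spec.
#' @return Numeric vector of `num_classes` probabilities (classes 0..K-1 in
#'   positions 1..K).
#' @export
predict_probabilities <- function(handle, image) {
  stopifnot(inherits(handle, "classifier_handle"))
  check_image(handle, image)
  p <- handle$predict_probs(image)
  if (!all(is.finite(p)) || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("model-fault error: probabilities are not a valid distribution",
         call. = FALSE)
  }
  pmax(p, 0)
}

#' Target-class scores (logits) for an image
#' @inheritParams predict_probabilities
#' @return Numeric vector of `num_classes` real-valued scores.
#' @export
predict_scores <- function(handle, image) {
  stopifnot(inherits(handle, "classifier_handle"))
  check_image(handle, image)
  s <- handle$predict_scores(image)
  if (!all(is.finite(s))) stop("model-fault error: non-finite scores", call. = FALSE)
  s
}

#' Model confidence in a target class
#'
#' Softmax probability of the target class, the quantity tracked by
#' perturbation curves.
#'
#' @inheritParams predict_probabilities
#' @param target 0-based class index (grade).
#' @return Probability in \[0, 1\].
#' @export
predict_confidence <- function(handle, image, target) {
  check_target(handle, target)
  predict_probabilities(handle, image)[target + 1L]
}

#' Gradient of the target-class score w.r.t. the input
#'
#' @inheritParams predict_confidence
#' @return Array of the same shape as `image`.
#' @export
input_gradient <- function(handle, image, target) {
  stopifnot(inherits(handle, "classifier_handle"))
  if (!isTRUE(handle$capabilities[["differentiable"]])) {
    stop("capability error: handle '", handle$identity,
         "' is not differentiable", call. = FALSE)
  }
  check_image(handle, image)
  check_target(handle, target)
  g <- handle$gradient(image, target)
  if (!all(is.finite(g))) stop("model-fault error: non-finite gradient", call. = FALSE)
  if (!identical(dim(g), dim(image))) {
    stop("model-fault error: gradient shape mismatch", call. = FALSE)
  }
  g
}

#' Convolutional feature maps (and optionally their gradients)
#'
#' @inheritParams predict_confidence
#' @param layer Layer id; `NULL` selects the handle's default (last
#'   convolutional stage).
#' @param target 0-based class index, required when `with_gradients = TRUE`.
#' @param with_gradients If `TRUE`, also return the gradient of the target
#'   score w.r.t. each activation.
#' @return List with `maps` (`h x w x C` array) and, when requested, `grads`
#'   of the same shape.
#' @export
feature_maps <- function(handle, image, layer = NULL, target = NULL,
                         with_gradients = FALSE) {
  stopifnot(inherits(handle, "classifier_handle"))
  if (!isTRUE(handle$capabilities[["exposes_feature_maps"]])) {
    stop("capability error: handle '", handle$identity,
         "' does not expose feature maps", call. = FALSE)
  }
  check_image(handle, image)
  if (is.null(layer)) {
    layer <- if (length(handle$layers)) handle$layers[[1]] else NULL
  } else if (length(handle$layers) && !layer %in% handle$layers) {
    stop("configuration error: unknown layer id '", layer, "'", call. = FALSE)
  }
  if (with_gradients) check_target(handle, target)
  fm <- handle$features(image, layer = layer, target = target,
                        with_gradients = with_gradients)
  stopifnot(length(dim(fm$maps)) == 3)
  fm
}

#' DeepLIFT contributions from a handle, if supported
#' @keywords internal
handle_deeplift <- function(handle, image, baseline, target) {
  if (is.null(handle$deeplift)) {
    stop("capability error: handle '", handle$identity,
         "' is not built from supported primitive layers (DeepLIFT unavailable)",
         call. = FALSE)
  }
  handle$deeplift(image, baseline, target)
}
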