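# Attribution methods. Each returns a `saliency_map`: the signed per-channel
# attribution grid `raw` plus the nonnegative 2-D aggregate `map2d` used by
# all downstream metrics (per-pixel sum of |raw| over channels, so negative
# evidence stays visible). Gradient-based methods attribute the target-class
# score; reference-based methods (IG, SHAP, DeepLIFT) measure contributions
# against a baseline image, by default all-black.

#' Attribution configuration
#'
#' @param baseline `"black"` (all intensities at the lower bound of the value
#'   range) or an explicit baseline image array; SHAP also accepts a list of
#'   baseline images.
#' @param ig_steps Number of Riemann-midpoint steps for Integrated Gradients.
#' @param sg_samples Number of noisy samples for SmoothGrad.
#' @param sg_sigma SmoothGrad noise standard deviation, as a fraction of the
#'   intensity span. Noisy inputs are not clipped to the valid range.
#' @param shap_samples Number of path samples for expected-gradients SHAP.
#' @param rng_seed Seed making the stochastic methods reproducible.
#' @return An object of class `attribution_config`.
#' @export
attribution_config <- function(baseline = "black", ig_steps = 32L,
                               sg_samples = 25L, sg_sigma = 0.15,
                               shap_samples = 64L, rng_seed = 1L) {
  stopifnot(ig_steps >= 1, sg_samples >= 1, shap_samples >= 1, sg_sigma >= 0)
  structure(list(baseline = baseline, ig_steps = as.integer(ig_steps),
                 sg_samples = as.integer(sg_samples), sg_sigma = sg_sigma,
                 shap_samples = as.integer(shap_samples),
                 rng_seed = as.integer(rng_seed)),
            class = "attribution_config")
}

new_saliency_map <- function(raw, method, target) {
  structure(list(raw = raw, map2d = aggregate_channels(raw),
                 method = method, target = as.integer(target)),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %s, target class %d, %dx%d, mass %.4g\n",
              x$method, x$target, nrow(x$map2d), ncol(x$map2d), sum(x$map2d)))
  invisible(x)
}

#' Collapse a signed attribution grid to a nonnegative 2-D map
#'
#' `map2d[p] = sum over channels of |raw[p, c]|`.
#'
#' @param raw Signed `h x w x c` attribution array (a plain matrix is treated
#'   as single-channel).
#' @return Nonnegative `h x w` matrix.
#' @export
aggregate_channels <- function(raw) {
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  stopifnot(length(dim(raw)) == 3)
  if (!all(is.finite(raw))) {
    stop("numeric error: non-finite attribution values", call. = FALSE)
  }
  out <- 0
  for (ch in seq_len(dim(raw)[3])) out <- out + abs(raw[, , ch])
  out
}

# resolve a baseline policy to an image array; list -> list of images
resolve_baseline <- function(baseline, handle) {
  spec <- handle$spec
  make_black <- function() {
    array(spec$value_range[1], c(spec$height, spec$width, spec$channels))
  }
  if (is.character(baseline)) {
    if (!identical(baseline, "black")) {
      stop("config error: unknown baseline policy '", baseline, "'",
           call. = FALSE)
    }
    return(make_black())
  }
  if (is.list(baseline)) {
    if (!length(baseline)) stop("config error: empty baseline set", call. = FALSE)
    lapply(baseline, function(b) { check_image(handle, b); b })
  } else {
    check_image(handle, baseline)
    baseline
  }
}

#' Vanilla gradient saliency
#'
#' The raw attribution is the gradient of the target-class score with respect
#' to every input intensity.
#'
#' @param handle A differentiable [classifier_handle()].
#' @param image Image array matching the handle's spec.
#' @param target 0-based class index.
#' @return A `saliency_map`.
#' @export
vanilla_gradient <- function(handle, image, target) {
  new_saliency_map(input_gradient(handle, image, target), "gradient", target)
}

#' SmoothGrad saliency
#'
#' Mean gradient over `sg_samples` Gaussian-noised copies of the input
#' (noise sd = `sg_sigma` x intensity span, not clipped to the valid range).
#' Deterministic given `config$rng_seed`. With `sg_sigma = 0` every sample
#' equals the input, so the result is exactly the vanilla gradient.
#'
#' @inheritParams vanilla_gradient
#' @param config An [attribution_config()].
#' @return A `saliency_map`.
#' @export
smoothgrad <- function(handle, image, target, config = attribution_config()) {
  if (config$sg_samples < 1) stop("config error: sg_samples < 1", call. = FALSE)
  span <- diff(handle$spec$value_range)
  if (config$sg_sigma == 0) {
    g <- input_gradient(handle, image, target)
    return(new_saliency_map(g, "smoothgrad", target))
  }
  sd <- config$sg_sigma * span
  acc <- with_seed(config$rng_seed, {
    a <- 0
    for (s in seq_len(config$sg_samples)) {
      noisy <- image + array(stats::rnorm(length(image), sd = sd), dim(image))
      a <- a + handle_gradient_unchecked(handle, noisy, target)
    }
    a
  })
  new_saliency_map(acc / config$sg_samples, "smoothgrad", target)
}

# gradient without the in-range check (SmoothGrad samples may leave the valid
# intensity range by design)
handle_gradient_unchecked <- function(handle, image, target) {
  if (!isTRUE(handle$capabilities[["differentiable"]])) {
    stop("capability error: handle '", handle$identity,
         "' is not differentiable", call. = FALSE)
  }
  handle$gradient(image, target)
}

#' Integrated Gradients
#'
#' Accumulates gradients along the straight-line path from the baseline to
#' the input: `raw_i = (x_i - b_i) * mean_k grad_i(b + a_k (x - b))` with
#' `a_k` at the midpoints of `ig_steps` equal subintervals (midpoint Riemann
#' rule). Satisfies the completeness axiom up to quadrature error.
#'
#' @inheritParams smoothgrad
#' @return A `saliency_map`.
#' @export
integrated_gradients <- function(handle, image, target,
                                 config = attribution_config()) {
  b <- resolve_baseline(config$baseline, handle)
  if (is.list(b)) b <- b[[1]]
  if (!identical(dim(b), dim(image))) {
    stop("config error: baseline shape mismatch", call. = FALSE)
  }
  diff <- image - b
  acc <- 0
  for (k in seq_len(config$ig_steps)) {
    alpha <- (k - 0.5) / config$ig_steps
    acc <- acc + handle_gradient_unchecked(handle, b + alpha * diff, target)
  }
  new_saliency_map(diff * acc / config$ig_steps, "integrated_gradients", target)
}

#' Expected-gradients SHAP attribution
#'
#' Monte-Carlo Shapley-value estimator along interpolation paths:
#' `raw_i = mean over samples of (x_i - b_i) * grad_i(b + a (x - b))` with the
#' baseline `b` drawn from the baseline set and `a ~ Uniform(0, 1)`.
#' Deterministic given `config$rng_seed`.
#'
#' @inheritParams smoothgrad
#' @return A `saliency_map`.
#' @export
shap_attribution <- function(handle, image, target,
                             config = attribution_config()) {
  bset <- resolve_baseline(config$baseline, handle)
  if (!is.list(bset)) bset <- list(bset)
  if (!length(bset)) stop("config error: empty baseline set", call. = FALSE)
  acc <- with_seed(config$rng_seed, {
    a <- 0
    for (s in seq_len(config$shap_samples)) {
      b <- bset[[sample.int(length(bset), 1L)]]
      alpha <- stats::runif(1)
      diff <- image - b
      a <- a + diff * handle_gradient_unchecked(handle, b + alpha * diff, target)
    }
    a
  })
  new_saliency_map(acc / config$shap_samples, "shap", target)
}

#' DeepLIFT attributions (Rescale rule)
#'
#' Backward multiplier propagation with the Rescale rule for nonlinearities:
#' a ReLU's multiplier is delta-activation / delta-input when the input
#' difference exceeds a small guard, otherwise the local gradient. Satisfies
#' summation-to-delta: attributions sum to `f(x) - f(baseline)` (f = target
#' score). Requires a handle built from supported primitive layers.
#'
#' @inheritParams smoothgrad
#' @return A `saliency_map`.
#' @export
deeplift_rescale <- function(handle, image, target,
                             config = attribution_config()) {
  b <- resolve_baseline(config$baseline, handle)
  if (is.list(b)) b <- b[[1]]
  if (!identical(dim(b), dim(image))) {
    stop("config error: baseline shape mismatch", call. = FALSE)
  }
  check_image(handle, image)
  check_target(handle, target)
  raw <- handle_deeplift(handle, image, b, target)
  new_saliency_map(raw, "deeplift", target)
}

# method registry used by the batch evaluator and the CLI
attribution_methods <- function() {
  c("gradient", "smoothgrad", "integrated_gradients", "shap", "deeplift",
    "gradcam_pp", "scorecam")
}

#' Compute a saliency map by method name
#'
#' Dispatches to one of the seven implemented methods.
#'
#' @inheritParams smoothgrad
#' @param method One of `"gradient"`, `"smoothgrad"`,
#'   `"integrated_gradients"`, `"shap"`, `"deeplift"`, `"gradcam_pp"`,
#'   `"scorecam"`.
#' @param layer CAM feature layer id (`NULL` = handle default).
#' @return A `saliency_map`.
#' @export
compute_saliency <- function(handle, image, target, method,
                             config = attribution_config(), layer = NULL) {
  method <- match.arg(method, attribution_methods())
  switch(method,
    gradient = vanilla_gradient(handle, image, target),
    smoothgrad = smoothgrad(handle, image, target, config),
    integrated_gradients = integrated_gradients(handle, image, target, config),
    shap = shap_attribution(handle, image, target, config),
    deeplift = deeplift_rescale(handle, image, target, config),
    gradcam_pp = gradcam_pp(handle, image, target, layer),
    scorecam = scorecam(handle, image, target, layer))
}
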