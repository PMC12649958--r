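# Class-activation-map methods. Both operate on the activation stack of a
# convolutional stage and return a nonnegative map bilinearly upsampled to
# the input grid; `raw` is that single-channel map.

#' Grad-CAM++ saliency
#'
#' Per-map weights from the closed-form Grad-CAM++ combination of the first,
#' second and third powers of the activation gradients:
#' `alpha = g^2 / (2 g^2 + sum(A) g^3 + eps)` (stabilized denominator),
#' `w_k = sum_ij alpha_ij * ReLU(g_ij)`; the map is the ReLU of the weighted
#' activation sum, bilinearly upsampled to the input size. If every weight is
#' zero (e.g. a constant-output model) the all-zero map is returned.
#'
#' @param handle A [classifier_handle()] exposing feature maps and gradients.
#' @param image Image array matching the handle's spec.
#' @param target 0-based class index.
#' @param layer Feature layer id (`NULL` = handle default, the last
#'   convolutional stage).
#' @param eps Denominator stabilizer.
#' @return A `saliency_map` whose `map2d` is the upsampled CAM.
#' @export
gradcam_pp <- function(handle, image, target, layer = NULL, eps = 1e-8) {
  fm <- feature_maps(handle, image, layer = layer, target = target,
                     with_gradients = TRUE)
  A <- fm$maps; G <- fm$grads
  nmap <- dim(A)[3]
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(nmap)) {
    Ak <- A[, , k]; g <- G[, , k]
    g2 <- g * g; g3 <- g2 * g
    denom <- 2 * g2 + sum(Ak) * g3
    alpha <- ifelse(abs(denom) > 0, g2 / (denom + eps), 0)
    wk <- sum(alpha * pmax(g, 0))
    cam <- cam + wk * Ak
  }
  cam <- pmax(cam, 0)
  up <- bilinear_upsample(cam, handle$spec$height, handle$spec$width)
  new_saliency_map(array(up, c(dim(up), 1L)), "gradcam_pp", target)
}

#' ScoreCAM saliency
#'
#' Gradient-free CAM: each activation map is min-max normalized, upsampled to
#' the input size and used as an elementwise mask on the image; the weight of
#' map `k` is the softmax (over maps) of the increase in target-class score
#' of the masked image relative to the all-black baseline. The final map is
#' the ReLU of the weighted sum of upsampled normalized maps. Runs entirely
#' through forward passes, so it works on handles without the gradient
#' capability.
#'
#' Constant activation maps carry no spatial structure: they keep their
#' softmax weight (from the unmasked-baseline score) but contribute a zero
#' map. An all-zero activation stack yields the all-zero map.
#'
#' @inheritParams gradcam_pp
#' @return A `saliency_map` whose `map2d` is the upsampled CAM.
#' @export
scorecam <- function(handle, image, target, layer = NULL) {
  fm <- feature_maps(handle, image, layer = layer, with_gradients = FALSE)
  A <- fm$maps
  check_target(handle, target)
  nmap <- dim(A)[3]
  h <- handle$spec$height; w <- handle$spec$width
  black <- array(handle$spec$value_range[1],
                 c(h, w, handle$spec$channels))
  base_score <- predict_scores(handle, black)[target + 1L]
  ups <- vector("list", nmap)
  increases <- numeric(nmap)
  for (k in seq_len(nmap)) {
    Ak <- A[, , k]
    rng <- range(Ak)
    if (rng[2] > rng[1]) {
      norm <- (Ak - rng[1]) / (rng[2] - rng[1])
      up <- bilinear_upsample(norm, h, w)
    } else {
      up <- matrix(0, h, w)  # constant map: no spatial structure
    }
    ups[[k]] <- up
    masked <- image
    for (ch in seq_len(handle$spec$channels)) {
      masked[, , ch] <- image[, , ch] * up
    }
    increases[k] <- predict_scores(handle, masked)[target + 1L] - base_score
  }
  wts <- softmax(increases)
  cam <- 0
  for (k in seq_len(nmap)) cam <- cam + wts[k] * ups[[k]]
  cam <- pmax(cam, 0)
  new_saliency_map(array(cam, c(dim(cam), 1L)), "scorecam", target)
}
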