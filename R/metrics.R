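# Quantitative saliency evaluation: min-max normalization, conversion to a
# pixel distribution, Shannon entropy (bits), the pixel-flipping perturbation
# protocol with AOPC, percentile binarization, and the Recall / Dice overlap
# metrics against ground-truth lesion masks.

#' Min-max normalize a saliency map to \[0, 1\]
#'
#' `(I_i - min I) / (max I - min I)` over all pixels. A constant map is
#' degenerate: a constant 0.5 map is returned with attribute
#' `degenerate = TRUE` (after sum-normalization it yields the uniform
#' distribution). The operation is idempotent.
#'
#' @param map2d Finite numeric matrix.
#' @return Matrix with values in \[0, 1\].
#' @export
normalize_minmax <- function(map2d) {
  stopifnot(is.matrix(map2d), all(is.finite(map2d)))
  rng <- range(map2d)
  if (rng[2] > rng[1]) {
    (map2d - rng[1]) / (rng[2] - rng[1])
  } else {
    out <- matrix(0.5, nrow(map2d), ncol(map2d))
    attr(out, "degenerate") <- TRUE
    out
  }
}

#' Convert a nonnegative map to a pixel probability distribution
#'
#' `p_i = value_i / sum(values)`. A zero-sum map is degenerate and yields the
#' uniform distribution with attribute `degenerate = TRUE`.
#'
#' @param map2d Nonnegative numeric matrix (typically min-max normalized).
#' @return Object of class `saliency_distribution`: list with `p` (matrix
#'   summing to 1) and `n` (pixel count).
#' @export
to_distribution <- function(map2d) {
  stopifnot(is.matrix(map2d))
  if (any(map2d < 0)) {
    stop("contract error: negative values in saliency map", call. = FALSE)
  }
  total <- sum(map2d)
  degenerate <- FALSE
  if (total > 0) {
    p <- map2d / total
  } else {
    p <- matrix(1 / length(map2d), nrow(map2d), ncol(map2d))
    degenerate <- TRUE
  }
  structure(list(p = p, n = length(map2d), degenerate = degenerate),
            class = "saliency_distribution")
}

#' Shannon entropy of a saliency distribution, in bits
#'
#' `H = -sum p_i log2 p_i` with `0 log 0 := 0`; bounded by `log2(n)`, which a
#' uniform distribution attains exactly.
#'
#' @param dist A [to_distribution()] result (a plain nonnegative matrix is
#'   converted first).
#' @return Entropy in bits.
#' @export
entropy <- function(dist) {
  if (!inherits(dist, "saliency_distribution")) dist <- to_distribution(dist)
  p <- dist$p[dist$p > 0]
  -sum(p * log2(p))
}

#' Saliency entropy of a raw map (full convention)
#'
#' Convenience composition: min-max normalize, sum-normalize, entropy in
#' bits. This is the convention under which a uniform 224 x 224 map attains
#' `log2(50176) ~= 15.615` bits.
#'
#' @param map2d Numeric matrix.
#' @return Entropy in bits.
#' @export
saliency_entropy <- function(map2d) {
  entropy(to_distribution(normalize_minmax(map2d)))
}

#' Perturbation curve (pixel flipping, most-relevant-first)
#'
#' Ranks all pixels by saliency from highest to lowest (ties broken by stable
#' row-major order) and cumulatively masks the top `ceiling(r * n)` pixels at
#' each perturbation ratio `r = 0, step, 2*step, ..., 1`, replacing them with
#' `mask_value` on all channels. Records the target-class confidence at every
#' ratio; ratio 0 holds the unperturbed confidence.
#'
#' @param handle A [classifier_handle()].
#' @param image Image array matching the handle's spec.
#' @param map2d Saliency matrix aligned with the image grid.
#' @param target 0-based class index.
#' @param step Ratio increment; must divide 1 within rounding (default 0.02,
#'   i.e. K = 50 masking steps, 51 curve points).
#' @param mask_value Replacement intensity (default 0, black).
#' @return Object of class `perturbation_curve`: list with `ratios`,
#'   `confidences` and `K`.
#' @export
perturbation_curve <- function(handle, image, map2d, target, step = 0.02,
                               mask_value = 0) {
  stopifnot(is.matrix(map2d))
  if (!(step > 0 && step <= 1)) stop("config error: step outside (0, 1]", call. = FALSE)
  K <- round(1 / step)
  if (abs(K * step - 1) > 1e-9) {
    stop("config error: step must divide 1 within rounding", call. = FALSE)
  }
  d <- dim(image)
  if (!all(dim(map2d) == d[1:2])) {
    stop("input-contract error: saliency map not aligned with image", call. = FALSE)
  }
  n <- length(map2d)
  ord <- rowmajor_order_desc(map2d)
  confidences <- numeric(K + 1)
  confidences[1] <- predict_confidence(handle, image, target)
  perturbed <- image
  masked_so_far <- 0L
  w <- ncol(map2d)
  for (k in seq_len(K)) {
    m_k <- min(as.integer(ceiling(k * step * n)), n)
    if (m_k > masked_so_far) {
      idx <- ord[(masked_so_far + 1L):m_k]
      rc <- rowmajor_to_rc(idx, w)
      for (ch in seq_len(d[3])) {
        perturbed[cbind(rc, ch)] <- mask_value
      }
      masked_so_far <- m_k
    }
    confidences[k + 1] <- predict_confidence(handle, perturbed, target)
  }
  structure(list(ratios = seq(0, 1, by = step)[seq_len(K + 1)],
                 confidences = confidences, K = K),
            class = "perturbation_curve")
}

#' Area Over the Perturbation Curve
#'
#' `AOPC = (1/K) sum_{k=1..K} (f(x) - f(x^(k)))`: the mean confidence drop
#' over the K nonzero masking steps. Higher values mean the saliency map
#' identifies more decision-critical pixels.
#'
#' @param curve A [perturbation_curve()].
#' @return Dimensionless score in \[-1, 1\].
#' @export
aopc <- function(curve) {
  stopifnot(inherits(curve, "perturbation_curve"))
  if (curve$K < 1) stop("contract error: curve has no perturbation steps", call. = FALSE)
  mean(curve$confidences[1] - curve$confidences[-1])
}

#' Binarize a saliency map at a percentile threshold
#'
#' The threshold is the `percentile` quantile of all pixel values
#' (linear-interpolation quantile); pixels strictly greater than the
#' threshold form the highlight region, so the default 0.9 retains (up to
#' ties) the top 10% of responses. A constant map retains nothing, with a
#' warning.
#'
#' @param map2d Finite numeric matrix (typically normalized).
#' @param percentile Quantile in (0, 1); default 0.9.
#' @return Object of class `binarized_map`: list with logical `highlight`,
#'   `threshold_value` and `percentile`.
#' @export
binarize_top_percentile <- function(map2d, percentile = 0.9) {
  stopifnot(is.matrix(map2d), all(is.finite(map2d)),
            percentile > 0, percentile < 1)
  thr <- unname(stats::quantile(map2d, probs = percentile, type = 7))
  highlight <- map2d > thr
  if (!any(highlight)) {
    warning("binarize_top_percentile: empty highlight (constant map?)")
  }
  structure(list(highlight = highlight, threshold_value = thr,
                 percentile = percentile),
            class = "binarized_map")
}

as_binary_matrix <- function(x) {
  if (inherits(x, "binarized_map")) x <- x$highlight
  stopifnot(is.matrix(x))
  x > 0
}

#' Recall of a highlight region against a ground-truth mask
#'
#' `Recall = TP / (TP + FN)` where TP counts truth pixels that are
#' highlighted and FN truth pixels that are not. Undefined for an empty
#' truth mask (grade-0 convention): returns `NA` with a warning, so callers
#' can skip the metric.
#'
#' @param highlight A [binarize_top_percentile()] result or binary matrix.
#' @param truth Binary ground-truth mask of the same shape.
#' @return Fraction in \[0, 1\], or `NA` for an empty truth mask.
#' @export
overlap_recall <- function(highlight, truth) {
  a <- as_binary_matrix(highlight); b <- as_binary_matrix(truth)
  stopifnot(all(dim(a) == dim(b)))
  if (!any(b)) {
    warning("recall undefined: empty ground-truth mask")
    return(NA_real_)
  }
  sum(a & b) / sum(b)
}

#' Dice coefficient between a highlight region and a ground-truth mask
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)`. Undefined when both sets are
#' empty: returns `NA` with a warning.
#'
#' @inheritParams overlap_recall
#' @return Fraction in \[0, 1\], or `NA` when both sets are empty.
#' @export
overlap_dice <- function(highlight, truth) {
  a <- as_binary_matrix(highlight); b <- as_binary_matrix(truth)
  stopifnot(all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("dice undefined: both sets empty")
    return(NA_real_)
  }
  2 * sum(a & b) / denom
}

#' Evaluate saliency quality for a batch of images
#'
#' For every (image, method) pair: computes the saliency map, its entropy
#' (full convention), the AOPC of its perturbation curve, and Recall / Dice
#' of the 0.9-percentile highlight against the union lesion mask. Recall and
#' Dice are `NA` for images with an empty mask (grade-0 convention). Failures
#' of individual rows are recorded (`error` column) and the batch continues.
#'
#' @param handle A [classifier_handle()].
#' @param images List of image arrays.
#' @param labels Integer vector of 0-based grade labels (used as the
#'   attribution target for each image).
#' @param masks List of binary union lesion masks (or `NULL` entries for
#'   grade-0 images).
#' @param methods Character vector of method names (see
#'   [compute_saliency()]).
#' @param config An [attribution_config()].
#' @param step,mask_value,percentile Metric settings, see
#'   [perturbation_curve()] and [binarize_top_percentile()].
#' @param layer CAM feature layer id.
#' @return Data frame with one row per (image, method): `model`, `image`,
#'   `label`, `method`, `entropy`, `aopc`, `recall`, `dice`, `error`.
#' @export
evaluate_batch <- function(handle, images, labels, masks = NULL,
                           methods = c("gradient", "smoothgrad",
                                       "integrated_gradients", "shap",
                                       "deeplift"),
                           config = attribution_config(), step = 0.02,
                           mask_value = 0, percentile = 0.9, layer = NULL) {
  stopifnot(length(images) == length(labels))
  if (is.null(masks)) masks <- vector("list", length(images))
  rows <- list()
  for (i in seq_along(images)) {
    for (m in methods) {
      rec <- data.frame(model = handle$identity, image = i,
                        label = as.integer(labels[[i]]), method = m,
                        entropy = NA_real_, aopc = NA_real_,
                        recall = NA_real_, dice = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        sal <- compute_saliency(handle, images[[i]], labels[[i]], m,
                                config = config, layer = layer)
        rec$entropy <- saliency_entropy(sal$map2d)
        curve <- perturbation_curve(handle, images[[i]], sal$map2d,
                                    labels[[i]], step = step,
                                    mask_value = mask_value)
        rec$aopc <- aopc(curve)
        truth <- masks[[i]]
        if (!is.null(truth) && any(truth > 0)) {
          bin <- suppressWarnings(
            binarize_top_percentile(normalize_minmax(sal$map2d), percentile))
          rec$recall <- overlap_recall(bin, truth)
          rec$dice <- overlap_dice(bin, truth)
        }
        rec
      }, error = function(e) {
        rec$error <- conditionMessage(e)
        rec
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Per-grade summary in the evaluation-report layout
#'
#' Averages per-image metrics over images for each (model, label) cell,
#' excluding the methods listed in `exclude_methods` (by default the two CAM
#' methods, whose perturbation curves are unstable and which the quality
#' tables omit).
#'
#' @param records Data frame from [evaluate_batch()].
#' @param exclude_methods Methods dropped from the quality summary.
#' @return Data frame with columns `Model`, `Label`, `Entropy`, `Recall`,
#'   `Dice`, `AOPC_Score` (NaN-free: all-NA cells stay `NA`).
#' @export
summarize_records <- function(records,
                              exclude_methods = c("gradcam_pp", "scorecam")) {
  keep <- records[!(records$method %in% exclude_methods) &
                    is.na(records$error), , drop = FALSE]
  if (!nrow(keep)) return(data.frame())
  agg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(keep, list(keep$model, keep$label),
                                     drop = TRUE), function(g) {
    data.frame(Model = g$model[1], Label = g$label[1],
               Entropy = agg(g$entropy), Recall = agg(g$recall),
               Dice = agg(g$dice), AOPC_Score = agg(g$aopc),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$Label, out$Model), , drop = FALSE]
}
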