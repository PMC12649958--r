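# Lesion extraction, blending and the insertion trend experiment. Polygon
# annotations are lists of (row, col) vertices in continuous 0-based pixel
# coordinates; the centre of pixel (i, j) sits at (i + 0.5, j + 0.5).
# Rasterization uses the even-odd rule on pixel centres.

LESION_CLASSES <- c("hard_exudate", "hemorrhage", "microaneurysm",
                    "soft_exudate")

#' Polygon lesion annotation
#'
#' @param vertices Numeric matrix (>= 3 rows) of (row, col) vertices in
#'   0-based pixel coordinates.
#' @param lesion_class One of `"hard_exudate"`, `"hemorrhage"`,
#'   `"microaneurysm"`, `"soft_exudate"`.
#' @return Object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(vertices, lesion_class) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  lesion_class <- match.arg(lesion_class, LESION_CLASSES)
  structure(list(vertices = vertices, lesion_class = lesion_class),
            class = "polygon_annotation")
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel belongs to the mask when its centre lies inside the polygon under
#' the even-odd (crossing-number) rule. A degenerate (zero-area) polygon
#' yields an empty mask with a warning.
#'
#' @param ann A [polygon_annotation()] (or bare vertex matrix).
#' @param shape Integer `c(height, width)` of the target image.
#' @return Logical `height x width` matrix.
#' @export
polygon_to_mask <- function(ann, shape) {
  v <- if (inherits(ann, "polygon_annotation")) ann$vertices else as.matrix(ann)
  stopifnot(length(shape) >= 2)
  h <- shape[1]; w <- shape[2]
  if (any(v[, 1] < 0 | v[, 1] > h | v[, 2] < 0 | v[, 2] > w)) {
    stop("annotation error: polygon vertices outside image bounds", call. = FALSE)
  }
  mask <- matrix(FALSE, h, w)
  r0 <- max(1L, floor(min(v[, 1])) ); r1 <- min(h, ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2])) ); c1 <- min(w, ceiling(max(v[, 2])))
  if (r1 < r0 || c1 < c0) return(mask)
  rows <- r0:r1; cols <- c0:c1
  py <- rows - 0.5  # pixel-centre row coordinate (0-based + 0.5 = index - 0.5)
  px <- cols - 0.5
  ny <- length(py); nx <- length(px)
  inside <- matrix(FALSE, ny, nx)
  n <- nrow(v)
  yc <- matrix(rep(py, nx), ny, nx)
  xc <- matrix(rep(px, each = ny), ny, nx)
  for (e in seq_len(n)) {
    a <- v[e, ]; b <- v[if (e == n) 1L else e + 1L, ]
    if (a[1] == b[1]) next  # horizontal edge: no crossing
    crosses <- (a[1] > yc) != (b[1] > yc)
    xint <- a[2] + (yc - a[1]) / (b[1] - a[1]) * (b[2] - a[2])
    inside <- xor(inside, crosses & (xc < xint))
  }
  mask[rows, cols] <- inside
  if (!any(mask)) warning("polygon_to_mask: empty mask (degenerate polygon?)")
  mask
}

#' Extract a feathered lesion patch from an annotated image
#'
#' Crops the polygon's bounding box (padded by the feather support) and
#' builds a soft alpha mask: the rasterized polygon blurred by a finite
#' Gaussian kernel, so alpha is exactly 0 on the patch border and 1 deep
#' inside large polygons.
#'
#' @param image Source image array.
#' @param ann A [polygon_annotation()].
#' @param feather_radius Gaussian feather radius in pixels.
#' @return Object of class `lesion_patch`: list with `pixels`
#'   (`ph x pw x c`), `alpha` (`ph x pw` in \[0, 1\], 0 on the border),
#'   `lesion_class` and `source` (bounding-box provenance, 0-based).
#' @export
extract_patch <- function(image, ann, feather_radius = 2L) {
  stopifnot(inherits(ann, "polygon_annotation"))
  d <- dim(image)
  mask_full <- polygon_to_mask(ann, d[1:2])
  pad <- as.integer(feather_radius) + 1L
  rr <- range(which(rowSums(mask_full) > 0))
  cc <- range(which(colSums(mask_full) > 0))
  r0 <- max(1L, rr[1] - pad); r1 <- min(d[1], rr[2] + pad)
  c0 <- max(1L, cc[1] - pad); c1 <- min(d[2], cc[2] + pad)
  sub_mask <- mask_full[r0:r1, c0:c1]
  alpha <- blur_gaussian(sub_mask * 1, radius = feather_radius,
                         sigma = feather_radius / 2)
  alpha <- pmin(alpha, 1)
  # force an exactly-zero border ring so compositing is local
  alpha[1, ] <- 0; alpha[nrow(alpha), ] <- 0
  alpha[, 1] <- 0; alpha[, ncol(alpha)] <- 0
  structure(list(pixels = image[r0:r1, c0:c1, , drop = FALSE],
                 alpha = alpha, lesion_class = ann$lesion_class,
                 source = list(bbox = c(r0, c0, r1, c1) - 1L)),
            class = "lesion_patch")
}

# alpha-composite a patch onto an image, top-left corner at (r, c) (1-based);
# returns the image plus the binary support mask (alpha > 0.5, the patch core)
blend_patch <- function(image, patch, r, c) {
  ph <- nrow(patch$alpha); pw <- ncol(patch$alpha)
  rows <- r:(r + ph - 1L); cols <- c:(c + pw - 1L)
  a <- patch$alpha
  for (ch in seq_len(dim(image)[3])) {
    image[rows, cols, ch] <- (1 - a) * image[rows, cols, ch] +
      a * patch$pixels[, , ch]
  }
  core_local <- a > 0.5
  if (!any(core_local)) core_local <- a >= max(a)  # tiny patch: keep >= 1 px
  core <- matrix(FALSE, dim(image)[1], dim(image)[2])
  core[rows, cols] <- core_local
  support <- matrix(FALSE, dim(image)[1], dim(image)[2])
  support[rows, cols] <- a > 0
  list(image = image, core = core, support = support)
}

#' Lesion mask set
#'
#' Per-class binary masks, their union, and the placement log of synthesized
#' lesions (0-based centres).
#'
#' @param class_masks Named list of binary matrices, names in the lesion
#'   vocabulary.
#' @param placements Data frame with columns `row`, `col`, `class`
#'   (0-based centres), or `NULL`.
#' @return Object of class `lesion_mask_set` with elements `classes`,
#'   `union`, `placements`.
#' @export
lesion_mask_set <- function(class_masks, placements = NULL) {
  stopifnot(is.list(class_masks), length(class_masks) >= 1)
  bad <- setdiff(names(class_masks), LESION_CLASSES)
  if (length(bad)) {
    stop("parse error: unknown lesion class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  u <- Reduce(`|`, lapply(class_masks, function(m) m > 0))
  if (is.null(placements)) {
    placements <- data.frame(row = numeric(), col = numeric(),
                             class = character(), stringsAsFactors = FALSE)
  }
  structure(list(classes = class_masks, union = u, placements = placements),
            class = "lesion_mask_set")
}

#' Compose lesion-insertion sequences
#'
#' For each requested count, alpha-blends that many lesion patches (drawn
#' round-robin from the pool) onto the lesion-free base image at seeded
#' random non-overlapping positions inside the circular field of view,
#' avoiding an optic-disc exclusion zone. Outside the (feather) supports of
#' the placed lesions, each composed image equals the base exactly.
#'
#' @param base Lesion-free image array.
#' @param patches List of [extract_patch()] results (one lesion class per
#'   call is typical, mirroring the insertion experiments).
#' @param counts Integer vector of lesion counts, one composed image per
#'   entry (e.g. `c(14, 12, 10, 8, 6)` for microaneurysms or
#'   `c(13, 11, 9, 7, 5)` for hemorrhages).
#' @param seed Integer seed; the full sequence is a deterministic function of
#'   it.
#' @param fov_center,fov_radius Field-of-view circle in 0-based pixel
#'   coordinates; defaults to the centred circle of radius 0.47 x min side.
#' @param exclusion_center,exclusion_radius Optional optic-disc exclusion
#'   zone (`NULL` disables it).
#' @param max_tries Rejection-sampling budget per lesion.
#' @return List with one element per count: `list(image, masks)` where
#'   `masks` is a [lesion_mask_set()] whose placement log has exactly the
#'   requested count.
#' @export
compose_sequence <- function(base, patches, counts, seed = 1L,
                             fov_center = NULL, fov_radius = NULL,
                             exclusion_center = NULL, exclusion_radius = 18,
                             max_tries = 200L) {
  stopifnot(length(dim(base)) == 3, length(patches) >= 1, all(counts >= 1))
  h <- dim(base)[1]; w <- dim(base)[2]
  if (is.null(fov_center)) fov_center <- c(h, w) / 2
  if (is.null(fov_radius)) fov_radius <- 0.47 * min(h, w)
  out <- vector("list", length(counts))
  for (ci in seq_along(counts)) {
    cnt <- counts[[ci]]
    res <- with_seed(seed * 10000L + ci, {
      img <- base
      placed_support <- matrix(FALSE, h, w)
      class_masks <- stats::setNames(
        lapply(unique(vapply(patches, `[[`, "", "lesion_class")),
               function(cl) matrix(FALSE, h, w)),
        unique(vapply(patches, `[[`, "", "lesion_class")))
      log <- data.frame(row = numeric(), col = numeric(), class = character(),
                        stringsAsFactors = FALSE)
      for (j in seq_len(cnt)) {
        patch <- patches[[(j - 1L) %% length(patches) + 1L]]
        ph <- nrow(patch$alpha); pw <- ncol(patch$alpha)
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          # uniform in the FoV disc (shrunk by the patch half-diagonal)
          margin <- sqrt(ph^2 + pw^2) / 2
          rad <- (fov_radius - margin) * sqrt(stats::runif(1))
          ang <- stats::runif(1, 0, 2 * pi)
          cy <- fov_center[1] + rad * sin(ang)
          cx <- fov_center[2] + rad * cos(ang)
          r <- as.integer(round(cy - ph / 2)) + 1L
          c <- as.integer(round(cx - pw / 2)) + 1L
          if (r < 1 || c < 1 || r + ph - 1L > h || c + pw - 1L > w) next
          if (!is.null(exclusion_center)) {
            if (sqrt((cy - exclusion_center[1])^2 +
                     (cx - exclusion_center[2])^2) <
                exclusion_radius + margin) next
          }
          cand <- matrix(FALSE, h, w)
          cand[r:(r + ph - 1L), c:(c + pw - 1L)] <- patch$alpha > 0
          if (any(cand & placed_support)) next
          bl <- blend_patch(img, patch, r, c)
          img <- bl$image
          placed_support <- placed_support | bl$support
          cls <- patch$lesion_class
          class_masks[[cls]] <- class_masks[[cls]] | bl$core
          # log the core pixel nearest the patch centre (inside the mask)
          core_idx <- which(bl$core, arr.ind = TRUE)
          dctr <- (core_idx[, 1] - (r + ph / 2))^2 + (core_idx[, 2] - (c + pw / 2))^2
          ctr <- core_idx[which.min(dctr), ]
          log <- rbind(log, data.frame(row = ctr[1] - 1L, col = ctr[2] - 1L,
                                       class = cls, stringsAsFactors = FALSE))
          ok <- TRUE
          break
        }
        if (!ok) {
          stop("composition error: could not place lesion ", j, " of ", cnt,
               " after ", max_tries, " tries", call. = FALSE)
        }
      }
      list(image = img, masks = lesion_mask_set(class_masks, log))
    })
    out[[ci]] <- res
  }
  out
}

#' Fraction of saliency mass inside (dilated) lesion masks
#'
#' Sum-normalizes the saliency map and measures the probability mass falling
#' inside the union lesion mask dilated by `margin` pixels. A quantitative
#' surrogate for the qualitative trend claim that model attention
#' concentrates on inserted lesions; a uniform map scores
#' `dilated-area / n`.
#'
#' @param saliency A `saliency_map` or nonnegative matrix.
#' @param masks A [lesion_mask_set()] or binary union mask.
#' @param margin Dilation radius in pixels (default 5).
#' @return Fraction in \[0, 1\]; `NA` with a warning for an empty mask.
#' @export
trend_overlap_score <- function(saliency, masks, margin = 5) {
  map2d <- if (inherits(saliency, "saliency_map")) saliency$map2d else saliency
  u <- if (inherits(masks, "lesion_mask_set")) masks$union else masks > 0
  stopifnot(all(dim(map2d) == dim(u)))
  if (!any(u)) {
    warning("trend_overlap_score undefined: empty lesion mask")
    return(NA_real_)
  }
  dist <- to_distribution(map2d)
  sum(dist$p[dilate_disc(u, margin)])
}

#' Run the lesion-insertion trend experiment
#'
#' Composes one image per requested count, computes the ScoreCAM map for each
#' (for the supplied target class, conventionally the diseased grade the
#' detector responds to) and its [trend_overlap_score()], together with the
#' uniform-saliency baseline for the same mask.
#'
#' @param handle A [classifier_handle()] exposing feature maps.
#' @param base Lesion-free base image.
#' @param patches Lesion patch pool (see [compose_sequence()]).
#' @param counts Integer vector of insertion counts.
#' @param target 0-based class for ScoreCAM.
#' @param seed Seed for the composition.
#' @param margin Mask dilation margin for the overlap score.
#' @param ... Passed to [compose_sequence()].
#' @return Data frame with one row per count: `count`, `overlap`,
#'   `uniform_baseline`; the composed images, masks and maps are attached as
#'   attribute `"artifacts"` (a list of `list(image, masks, saliency)`).
#' @export
run_trend_analysis <- function(handle, base, patches, counts, target = 2L,
                               seed = 1L, margin = 5, ...) {
  composed <- compose_sequence(base, patches, counts, seed = seed, ...)
  rows <- vector("list", length(composed))
  artifacts <- vector("list", length(composed))
  for (i in seq_along(composed)) {
    img <- composed[[i]]$image
    masks <- composed[[i]]$masks
    sal <- scorecam(handle, img, target)
    ov <- trend_overlap_score(sal, masks, margin = margin)
    dil <- dilate_disc(masks$union, margin)
    rows[[i]] <- data.frame(count = counts[[i]], overlap = ov,
                            uniform_baseline = sum(dil) / length(dil))
    artifacts[[i]] <- list(image = img, masks = masks, saliency = sal)
  }
  out <- do.call(rbind, rows)
  attr(out, "artifacts") <- artifacts
  out
}
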