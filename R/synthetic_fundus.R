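# Synthetic fundus scenes with exact lesion masks. The scenes are stylized,
# not photorealistic: a circular field of view with a radial color gradient
# and smooth texture, a bright optic disc, dark curved vessel-like
# structures, and spot lesions of two classes (microaneurysms: small dark
# discs; hemorrhages: larger dark blotches). Everything is a deterministic
# function of (spec, seed), and lesion masks exactly cover the rendered
# lesion supports.

#' Specification of a synthetic fundus scene
#'
#' @param size Image side in pixels (square).
#' @param fov_radius_frac Field-of-view radius as a fraction of the side.
#' @param n_vessels Number of vessel arcs.
#' @param n_microaneurysm,n_hemorrhage Lesion counts per class.
#' @param ma_radius,hem_radius Radius ranges in pixels (microaneurysm: small
#'   dark disc, 2-5 px; hemorrhage: dark blotch, 4-10 px).
#' @param seed Integer seed; scene generation is pure in (spec, seed).
#' @return Object of class `fundus_scene_spec`.
#' @export
fundus_scene_spec <- function(size = 224L, fov_radius_frac = 0.47,
                              n_vessels = 6L, n_microaneurysm = 0L,
                              n_hemorrhage = 0L, ma_radius = c(2, 5),
                              hem_radius = c(4, 10), seed = 1L) {
  stopifnot(size >= 32, fov_radius_frac > 0, n_microaneurysm >= 0,
            n_hemorrhage >= 0, all(ma_radius > 0), all(hem_radius > 0))
  structure(list(size = as.integer(size), fov_radius_frac = fov_radius_frac,
                 n_vessels = as.integer(n_vessels),
                 n_microaneurysm = as.integer(n_microaneurysm),
                 n_hemorrhage = as.integer(n_hemorrhage),
                 ma_radius = ma_radius, hem_radius = hem_radius,
                 seed = as.integer(seed)),
            class = "fundus_scene_spec")
}

# documented grade surrogate (simplified ICDR-style count rule):
# no lesions -> 0; microaneurysms only -> 1; both classes present:
# < 4 hemorrhages -> 2, < 8 -> 3, else 4.
grade_from_counts <- function(n_ma, n_hem) {
  if (n_ma == 0 && n_hem == 0) return(0L)
  if (n_hem == 0) return(1L)
  if (n_hem < 4) return(2L)
  if (n_hem < 8) return(3L)
  4L
}

# lesion-free scene (background + optic disc + vessels), deterministic
render_base_scene <- function(spec) {
  n <- spec$size
  R <- spec$fov_radius_frac * n
  ctr <- c(n / 2, n / 2)
  yy <- matrix(seq_len(n) - 0.5, n, n)
  xx <- t(yy)
  d2 <- (yy - ctr[1])^2 + (xx - ctr[2])^2
  fov <- d2 <= R^2
  shade <- 1 - 0.35 * pmin(d2 / R^2, 1)
  # smooth seeded texture: coarse noise grid, bilinearly upsampled
  tex <- with_seed(spec$seed * 7L + 11L, {
    g <- matrix(stats::runif(64, -1, 1), 8, 8)
    bilinear_upsample(g, n, n)
  })
  shade <- shade * (1 + 0.06 * tex)
  base_col <- c(0.82, 0.46, 0.24)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- base_col[ch] * shade * fov
  # optic disc: bright ellipse right of centre
  od_ctr <- c(0.48 * n, 0.74 * n)
  od_r <- 0.085 * n
  od <- ((yy - od_ctr[1])^2 / (1.15 * od_r)^2 +
           (xx - od_ctr[2])^2 / od_r^2) <= 1
  od_col <- c(0.97, 0.85, 0.55)
  for (ch in 1:3) {
    img[, , ch][od & fov] <- 0.25 * img[, , ch][od & fov] + 0.75 * od_col[ch]
  }
  # vessels: quadratic arcs from the optic disc with tapering width
  vessel_col <- c(0.45, 0.13, 0.10)
  vmask <- matrix(FALSE, n, n)
  with_seed(spec$seed * 7L + 23L, {
    for (v in seq_len(spec$n_vessels)) {
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.55, 0.95) * R
      p0 <- od_ctr
      p2 <- od_ctr + len * c(sin(ang), cos(ang))
      mid <- (p0 + p2) / 2 +
        stats::runif(2, -0.18, 0.18) * len
      for (t in seq(0, 1, length.out = 140)) {
        p <- (1 - t)^2 * p0 + 2 * t * (1 - t) * mid + t^2 * p2
        if ((p[1] - ctr[1])^2 + (p[2] - ctr[2])^2 > (0.96 * R)^2) break
        wdt <- max(0.8, (1 - t) * 0.012 * n)
        r0 <- max(1L, floor(p[1] - wdt)); r1 <- min(n, ceiling(p[1] + wdt + 1))
        c0 <- max(1L, floor(p[2] - wdt)); c1 <- min(n, ceiling(p[2] + wdt + 1))
        sub <- (yy[r0:r1, c0:c1] - p[1])^2 + (xx[r0:r1, c0:c1] - p[2])^2 <= wdt^2
        vmask[r0:r1, c0:c1] <- vmask[r0:r1, c0:c1] | sub
      }
    }
  })
  vmask <- vmask & fov
  for (ch in 1:3) {
    img[, , ch][vmask] <- 0.35 * img[, , ch][vmask] + 0.65 * vessel_col[ch]
  }
  list(image = img, fov = fov, yy = yy, xx = xx, ctr = ctr, R = R,
       od_ctr = od_ctr, od_r = od_r)
}

#' Generate a synthetic fundus scene with exact lesion masks
#'
#' Renders the lesion-free scene for the spec's seed, then places the
#' requested numbers of microaneurysms and hemorrhages at seeded random,
#' non-overlapping positions inside the field of view (outside the optic
#' disc). Lesion masks exactly cover the rendered lesion supports, and the
#' grade label follows a documented count rule (no lesions: 0;
#' microaneurysms only: 1; both classes: 2-4 by hemorrhage count).
#'
#' @param spec A [fundus_scene_spec()].
#' @return List with `image` (`size x size x 3` in \[0, 1\]), `masks`
#'   (a [lesion_mask_set()] with the placement log), `grade` (integer 0-4)
#'   and `spec`.
#' @export
generate_fundus <- function(spec) {
  stopifnot(inherits(spec, "fundus_scene_spec"))
  sc <- render_base_scene(spec)
  n <- spec$size
  img <- sc$image
  ma_mask <- matrix(FALSE, n, n)
  hem_mask <- matrix(FALSE, n, n)
  placements <- data.frame(row = numeric(), col = numeric(),
                           class = character(), stringsAsFactors = FALSE)
  all_supports <- matrix(FALSE, n, n)
  lesion_plan <- c(rep("hemorrhage", spec$n_hemorrhage),
                   rep("microaneurysm", spec$n_microaneurysm))
  if (length(lesion_plan)) {
    res <- with_seed(spec$seed * 7L + 41L, {
      for (cls in lesion_plan) {
        rr <- if (cls == "microaneurysm") spec$ma_radius else spec$hem_radius
        col <- if (cls == "microaneurysm") c(0.30, 0.05, 0.05) else c(0.36, 0.07, 0.07)
        placedok <- FALSE
        for (try in seq_len(300L)) {
          # cap lesion radii at 8 % of the scene side so small scenes work;
          # shrink on repeated rejections so dense plans stay placeable
          hi <- min(rr[2], 0.08 * n)
          lo <- min(rr[1], hi)
          rad <- max(1.5, stats::runif(1, lo, hi) * 0.97^(try - 1))
          axis_ratio <- if (cls == "hemorrhage") stats::runif(1, 0.55, 1) else 1
          theta <- stats::runif(1, 0, pi)
          prad <- (sc$R - rad - 3) * sqrt(stats::runif(1))
          pang <- stats::runif(1, 0, 2 * pi)
          cy <- sc$ctr[1] + prad * sin(pang)
          cx <- sc$ctr[2] + prad * cos(pang)
          # keep clear of the optic disc
          if (sqrt((cy - sc$od_ctr[1])^2 + (cx - sc$od_ctr[2])^2) <
              1.3 * sc$od_r + rad) next
          r0 <- max(1L, floor(cy - rad - 1)); r1 <- min(n, ceiling(cy + rad + 1))
          c0 <- max(1L, floor(cx - rad - 1)); c1 <- min(n, ceiling(cx + rad + 1))
          dy <- sc$yy[r0:r1, c0:c1] - cy
          dx <- sc$xx[r0:r1, c0:c1] - cx
          u <- cos(theta) * dy + sin(theta) * dx
          v <- -sin(theta) * dy + cos(theta) * dx
          shape <- (u / rad)^2 + (v / (rad * axis_ratio))^2 <= 1
          if (!any(shape)) next
          cand <- matrix(FALSE, n, n)
          cand[r0:r1, c0:c1] <- shape
          sep <- dilate_disc(cand, 2)  # 2 px separation between lesions
          if (any(sep & all_supports)) next
          for (ch in 1:3) {
            layer <- img[, , ch]
            layer[cand] <- 0.15 * layer[cand] + 0.85 * col[ch]
            img[, , ch] <- layer
          }
          if (cls == "microaneurysm") ma_mask <- ma_mask | cand
          else hem_mask <- hem_mask | cand
          all_supports <- all_supports | sep
          placements <- rbind(placements,
                              data.frame(row = cy - 0.5, col = cx - 0.5,
                                         class = cls, stringsAsFactors = FALSE))
          placedok <- TRUE
          break
        }
        if (!placedok) {
          stop("generation error: could not place a ", cls,
               " lesion without overlap", call. = FALSE)
        }
      }
      NULL
    })
  }
  class_masks <- list(microaneurysm = ma_mask, hemorrhage = hem_mask)
  masks <- lesion_mask_set(class_masks, placements)
  list(image = img, masks = masks,
       grade = grade_from_counts(spec$n_microaneurysm, spec$n_hemorrhage),
       spec = spec)
}

#' Generate a graded synthetic test set
#'
#' Produces `n_per_grade` scenes for each grade 0-4 with lesion counts drawn
#' from grade-consistent ranges (grade 0: none; grade 1: microaneurysms only;
#' grades 2-4: both classes with increasing hemorrhage counts, following the
#' same count rule as [generate_fundus()]).
#'
#' @param n_per_grade Scenes per grade.
#' @param size Image side in pixels.
#' @param seed Master seed.
#' @return List with `images`, `labels`, `masks` (union masks), `scenes`
#'   (full generation results).
#' @export
generate_grade_dataset <- function(n_per_grade = 5L, size = 224L, seed = 1L) {
  images <- list(); labels <- integer(); masks <- list(); scenes <- list()
  idx <- 0L
  for (grade in 0:4) {
    for (j in seq_len(n_per_grade)) {
      idx <- idx + 1L
      cnts <- with_seed(seed * 100000L + grade * 1000L + j, {
        switch(as.character(grade),
          "0" = c(0L, 0L),
          "1" = c(sample(1:4, 1), 0L),
          "2" = c(sample(2:5, 1), sample(1:3, 1)),
          "3" = c(sample(4:8, 1), sample(4:7, 1)),
          "4" = c(sample(6:10, 1), sample(8:11, 1)))
      })
      spec <- fundus_scene_spec(size = size, n_microaneurysm = cnts[1],
                                n_hemorrhage = cnts[2],
                                seed = seed * 100L + idx)
      sc <- generate_fundus(spec)
      stopifnot(sc$grade == grade)
      images[[idx]] <- sc$image
      labels[idx] <- sc$grade
      masks[[idx]] <- sc$masks$union
      scenes[[idx]] <- sc
    }
  }
  list(images = images, labels = labels, masks = masks, scenes = scenes)
}
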