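# Small numeric helpers shared across modules. Image arrays are numeric
# [height, width, channels] with intensities in [0, 1]; 2-D maps are plain
# matrices [height, width]. User-facing pixel coordinates are 0-based
# (row, col) with the centre of pixel (i, j) at (i + 0.5, j + 0.5).

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations do not disturb the global random stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Numerically stable softmax
#' @param x Numeric vector of scores.
#' @return Probabilities summing to 1.
#' @keywords internal
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Bilinear upsampling of a 2-D map
#'
#' Resizes a matrix to a target spatial size with bilinear interpolation,
#' using the half-pixel-centre convention (output pixel centres are mapped
#' back into the source grid; borders are clamped).
#'
#' @param m Numeric matrix.
#' @param out_h,out_w Target number of rows / columns.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
bilinear_upsample <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m), out_h >= 1, out_w >= 1)
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  sy <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h - 1)
  x0 <- pmin(pmax(floor(sx), 0), w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(sy - y0, 0), 1)
  fx <- pmin(pmax(sx - x0, 0), 1)
  wy0 <- (1 - fy); wy1 <- fy
  wx0 <- (1 - fx); wx1 <- fx
  outer(wy0, wx0) * m[y0 + 1, x0 + 1, drop = FALSE] +
    outer(wy0, wx1) * m[y0 + 1, x1 + 1, drop = FALSE] +
    outer(wy1, wx0) * m[y1 + 1, x0 + 1, drop = FALSE] +
    outer(wy1, wx1) * m[y1 + 1, x1 + 1, drop = FALSE]
}

#' Separable Gaussian blur with a finite kernel
#'
#' Blurs a matrix with a discrete Gaussian of the given radius (kernel width
#' `2 * radius + 1`, zero-padded borders). The kernel is normalized, so a
#' region of ones larger than the kernel support stays exactly 1.
#'
#' @param m Numeric matrix.
#' @param radius Kernel radius in pixels.
#' @param sigma Gaussian standard deviation; default `radius / 2`.
#' @return Blurred matrix of the same shape.
#' @export
blur_gaussian <- function(m, radius = 2, sigma = radius / 2) {
  stopifnot(is.matrix(m), radius >= 0)
  if (radius == 0) return(m)
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  pad <- radius
  mp <- matrix(0, h + 2 * pad, w + 2 * pad)
  mp[pad + seq_len(h), pad + seq_len(w)] <- m
  tmp <- matrix(0, h, w + 2 * pad)
  for (d in seq_along(k)) {
    tmp <- tmp + k[d] * mp[(d - 1) + seq_len(h), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (d in seq_along(k)) {
    out <- out + k[d] * tmp[, (d - 1) + seq_len(w), drop = FALSE]
  }
  out
}

#' Binary dilation by a disc
#'
#' @param mask Logical or 0/1 matrix.
#' @param radius Disc radius in pixels; 0 returns the mask unchanged.
#' @return Logical matrix.
#' @export
dilate_disc <- function(mask, radius = 5) {
  m <- mask > 0
  if (radius <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  r <- as.integer(ceiling(radius))
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy * dy + dx * dx > radius * radius) next
      rs <- max(1, 1 - dy):min(h, h - dy)
      cs <- max(1, 1 - dx):min(w, w - dx)
      out[rs, cs] <- out[rs, cs] | m[rs + dy, cs + dx]
    }
  }
  out
}

#' Cosine similarity between two maps
#' @param a,b Numeric matrices or vectors of equal length.
#' @return Cosine of the angle between the flattened maps; NA if either is 0.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# luminance of an [h, w, 3] image array (Rec. 601 weights)
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# row-major flattening helpers: index (r, c), 1-based, maps to (r-1)*W + c
rowmajor_order_desc <- function(m) {
  v <- as.vector(t(m))
  # radix sort is stable: ties keep row-major order
  order(v, decreasing = TRUE, method = "radix")
}

rowmajor_to_rc <- function(idx, w) {
  cbind(row = (idx - 1L) %/% w + 1L, col = (idx - 1L) %% w + 1L)
}
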