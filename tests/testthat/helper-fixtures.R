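# Shared fixtures: small specs, seeded images, independent oracles.

spec_small <- function(n = 8L, channels = 3L) {
  input_spec(n, n, channels, num_classes = 5L)
}

rand_image <- function(n = 8L, seed = 1L, channels = 3L) {
  withr::with_seed(seed, array(stats::runif(n * n * channels),
                               c(n, n, channels)))
}

# independent central-finite-difference oracle over every input entry
finite_diff_gradient <- function(handle, image, target, h = 1e-4) {
  g <- array(0, dim(image))
  for (i in seq_along(image)) {
    xp <- image; xp[i] <- xp[i] + h
    xm <- image; xm[i] <- xm[i] - h
    g[i] <- (predict_scores(handle, xp)[target + 1L] -
               predict_scores(handle, xm)[target + 1L]) / (2 * h)
  }
  g
}

# brute-force even-odd point-in-polygon oracle on pixel centres
brute_polygon_mask <- function(vertices, shape) {
  inside_pt <- function(py, px) {
    n <- nrow(vertices); cnt <- 0L
    for (e in seq_len(n)) {
      a <- vertices[e, ]; b <- vertices[if (e == n) 1L else e + 1L, ]
      if (a[1] == b[1]) next
      if ((a[1] > py) != (b[1] > py)) {
        xint <- a[2] + (py - a[1]) / (b[1] - a[1]) * (b[2] - a[2])
        if (px < xint) cnt <- cnt + 1L
      }
    }
    cnt %% 2L == 1L
  }
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      m[r, c] <- inside_pt(r - 0.5, c - 0.5)
    }
  }
  m
}

# a constant-output differentiable model (zero weights, fixed bias scores)
make_constant_model <- function(spec, scores = c(0.2, 0.4, 0.1, 0.15, 0.15)) {
  n <- spec$height * spec$width * spec$channels
  net <- fundusXAI:::seqnet(list(
    fundusXAI:::layer_flatten(name = "flatten"),
    fundusXAI:::layer_dense(matrix(0, n, spec$num_classes), log(scores),
                            name = "fc")), spec)
  fundusXAI:::handle_from_seqnet(net, "constant", feature_layers = character())
}

# small donor + patch pool used by lesion-composition tests
make_patch_pool <- function(size = 224L, seed = 11L, n_per_class = 2L) {
  donor <- generate_fundus(fundus_scene_spec(
    size = size, n_microaneurysm = 4L, n_hemorrhage = 3L, seed = seed))
  pl <- donor$masks$placements
  mk <- function(row, col, r, cls) {
    extract_patch(donor$image, polygon_annotation(
      rbind(c(row - r, col - r), c(row - r, col + r),
            c(row + r, col + r), c(row + r, col - r)), cls))
  }
  ma <- lapply(utils::head(which(pl$class == "microaneurysm"), n_per_class),
               function(i) mk(pl$row[i], pl$col[i], 6, "microaneurysm"))
  hem <- lapply(utils::head(which(pl$class == "hemorrhage"), n_per_class),
                function(i) mk(pl$row[i], pl$col[i], 9, "hemorrhage"))
  list(microaneurysm = ma, hemorrhage = hem, donor = donor)
}
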