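# Fixture classifiers with known decision structure. These stand in for
# trained grading networks so that every attribution method and metric can be
# checked against a closed form or an independent oracle:
#   * region_fraction  - confidence is the mean intensity inside a planted
#                        region; the analytic oracle for perturbation / AOPC.
#   * intensity_linear - softmax over per-class linear functionals with known
#                        weights; the oracle for gradient / IG / DeepLIFT.
#   * tiny_cnn         - a 2-conv-layer network (seeded or trained weights)
#                        exposing feature maps; host for the CAM methods.

#' Construct a planted fixture classifier
#'
#' @param kind One of `"region_fraction"`, `"intensity_linear"`, `"tiny_cnn"`.
#' @param spec An [input_spec()]; fixture models accept any spatial size.
#' @param region Logical/0-1 matrix (`height` x `width`) for
#'   `region_fraction`: the planted region whose mean intensity drives the
#'   class probability. Must be non-empty.
#' @param target_class 0-based class whose probability the region drives
#'   (default 1).
#' @param seed Integer seed for random weights (`intensity_linear`,
#'   `tiny_cnn`).
#' @return A [classifier_handle()].
#' @export
make_planted_model <- function(kind = c("region_fraction", "intensity_linear",
                                        "tiny_cnn"),
                               spec = input_spec(), region = NULL,
                               target_class = 1L, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    region_fraction = make_region_fraction_model(spec, region, target_class),
    intensity_linear = make_intensity_linear_model(spec, seed),
    tiny_cnn = make_tiny_cnn(spec, seed))
}

# Probability of the target class equals the mean intensity over the planted
# region (all channels); remaining mass is split evenly over other classes.
# Scores coincide with probabilities for this bespoke model.
make_region_fraction_model <- function(spec, region, target_class = 1L) {
  if (is.null(region) || !any(region > 0)) {
    stop("spec error: region_fraction model requires a non-empty region",
         call. = FALSE)
  }
  stopifnot(nrow(region) == spec$height, ncol(region) == spec$width)
  reg <- region > 0
  nreg <- sum(reg) * spec$channels
  k <- spec$num_classes
  ti <- as.integer(target_class) + 1L
  probs_fn <- function(image) {
    s <- 0
    for (ch in seq_len(spec$channels)) s <- s + sum(image[, , ch][reg])
    m <- min(max(s / nreg, 0), 1)
    p <- rep((1 - m) / (k - 1), k)
    p[ti] <- m
    p
  }
  grad_fn <- function(image, target) {
    g <- array(0, dim(image))
    per <- if (target + 1L == ti) 1 / nreg else -1 / ((k - 1) * nreg)
    for (ch in seq_len(spec$channels)) g[, , ch][reg] <- per
    g
  }
  classifier_handle(
    identity = sprintf("region_fraction(|R|=%d)", sum(reg)),
    spec = spec,
    predict_scores = probs_fn,
    predict_probs = probs_fn,
    gradient = grad_fn)
}

# Softmax over linear functionals score_c(x) = <W_c, x>; gradients of the
# score are the stored weights exactly. Built on the sequential engine so
# DeepLIFT is available too.
make_intensity_linear_model <- function(spec, seed = 1L) {
  n <- spec$height * spec$width * spec$channels
  W <- with_seed(seed, matrix(stats::rnorm(n * spec$num_classes, sd = 1 / sqrt(n)),
                              n, spec$num_classes))
  net <- seqnet(list(layer_flatten(name = "flatten"),
                     layer_dense(W, rep(0, spec$num_classes), name = "fc")),
                spec)
  h <- handle_from_seqnet(net, sprintf("intensity_linear(seed=%d)", seed),
                          feature_layers = character())
  attr(h, "weights") <- W
  h
}

#' Linear-model weights of an `intensity_linear` fixture
#' @param handle Handle returned by [make_planted_model()].
#' @return Matrix `n_inputs x num_classes` (column-major over h, w, c).
#' @export
linear_weights <- function(handle) attr(handle, "weights")

# He-style seeded initialization
he_init <- function(kh, kw, cin, cout, seed) {
  with_seed(seed, array(stats::rnorm(kh * kw * cin * cout,
                                     sd = sqrt(2 / (kh * kw * cin))),
                        c(kh, kw, cin, cout)))
}

#' A two-convolution fixture CNN
#'
#' conv(3x3, stride 2) -> ReLU -> conv(3x3, stride 2) -> ReLU -> global
#' average pool -> channelwise normalization (inference mode, identity until
#' trained) -> dense. Works at any input size; exposes the two post-ReLU
#' convolutional stages as feature layers (`"relu2"` is the default CAM
#' layer). All layer types are in the DeepLIFT-Rescale supported set.
#'
#' @param spec An [input_spec()].
#' @param seed Seed for the random weights.
#' @param channels1,channels2 Widths of the two convolutional stages.
#' @return A [classifier_handle()]; the underlying network is stored in
#'   attribute `"net"` so training can update it.
#' @export
make_tiny_cnn <- function(spec = input_spec(), seed = 1L,
                          channels1 = 8L, channels2 = 8L) {
  W1 <- he_init(3, 3, spec$channels, channels1, seed)
  W2 <- he_init(3, 3, channels1, channels2, seed + 1L)
  Wf <- with_seed(seed + 2L, matrix(stats::rnorm(channels2 * spec$num_classes,
                                                 sd = 1 / sqrt(channels2)),
                                    channels2, spec$num_classes))
  net <- seqnet(list(
    layer_conv(W1, rep(0, channels1), stride = 2L, pad = 1L, name = "conv1"),
    layer_relu(name = "relu1"),
    layer_conv(W2, rep(0, channels2), stride = 2L, pad = 1L, name = "conv2"),
    layer_relu(name = "relu2"),
    layer_gap(name = "gap"),
    layer_affine(rep(1, channels2), rep(0, channels2), name = "norm"),
    layer_dense(Wf, rep(0, spec$num_classes), name = "fc")), spec)
  h <- handle_from_seqnet(net, sprintf("tiny_cnn(seed=%d)", seed),
                          feature_layers = c("relu2", "relu1"))
  attr(h, "net") <- net
  h
}

#' Single-feature-map fixture for CAM methods
#'
#' The model's only feature map is the block-mean luminance of the input
#' (pool x pool average pooling); class scores are fixed multiples of the map
#' mean. Its CAM maps therefore have a closed form: both Grad-CAM++ and
#' ScoreCAM collapse to (a positive multiple of) the upsampled activation
#' map.
#'
#' @param spec An [input_spec()].
#' @param pool Pooling block size; must divide height and width.
#' @param class_weights Per-class score multipliers.
#' @return A [classifier_handle()] exposing one feature layer `"pool"`.
#' @export
make_single_map_model <- function(spec = input_spec(), pool = 16L,
                                  class_weights = c(0.5, 2, 1, -1, 0.25)) {
  stopifnot(spec$height %% pool == 0, spec$width %% pool == 0,
            length(class_weights) == spec$num_classes)
  hb <- spec$height %/% pool; wb <- spec$width %/% pool
  lw <- c(0.299, 0.587, 0.114)[seq_len(spec$channels)]
  lw <- lw / sum(lw)
  pool_map <- function(image) {
    lum <- 0
    for (ch in seq_len(spec$channels)) lum <- lum + lw[ch] * image[, , ch]
    blocks <- matrix(0, hb, wb)
    for (i in seq_len(hb)) {
      rows <- (i - 1L) * pool + seq_len(pool)
      blocks[i, ] <- colMeans(matrix(lum[rows, , drop = FALSE], pool * pool, wb))
    }
    blocks
  }
  scores_fn <- function(image) class_weights * mean(pool_map(image))
  classifier_handle(
    identity = sprintf("single_map(pool=%d)", pool),
    spec = spec,
    predict_scores = scores_fn,
    gradient = function(image, target) {
      g <- array(0, dim(image))
      per <- class_weights[target + 1L] / (spec$height * spec$width)
      for (ch in seq_len(spec$channels)) g[, , ch] <- per * lw[ch]
      g
    },
    features = function(image, layer = NULL, target = NULL,
                        with_gradients = FALSE) {
      A <- array(pool_map(image), c(hb, wb, 1L))
      out <- list(maps = A)
      if (with_gradients) {
        out$grads <- array(class_weights[target + 1L] / (hb * wb), c(hb, wb, 1L))
      }
      out
    },
    layers = "pool")
}

#' Planted lesion-detector fixture
#'
#' A gradient-free handle whose single feature map is the block-pooled mean
#' absolute difference between the input and a stored lesion-free reference
#' image: it activates exactly where content was inserted. Class 2
#' ("diseased") score grows with the mean difference. Used as the planted
#' oracle in the lesion-insertion trend experiment.
#'
#' @param base Lesion-free reference image (`h x w x c` array).
#' @param pool Pooling block size.
#' @param num_classes Number of classes in the handle's spec.
#' @return A [classifier_handle()] exposing feature maps but no gradients.
#' @export
make_lesion_detector_model <- function(base, pool = 16L, num_classes = 5L) {
  d <- dim(base)
  stopifnot(length(d) == 3, d[1] %% pool == 0, d[2] %% pool == 0)
  spec <- input_spec(height = d[1], width = d[2], channels = d[3],
                     num_classes = num_classes)
  hb <- d[1] %/% pool; wb <- d[2] %/% pool
  diff_map <- function(image) {
    ad <- 0
    for (ch in seq_len(d[3])) ad <- ad + abs(image[, , ch] - base[, , ch])
    ad <- ad / d[3]
    # block means via two folds
    m <- matrix(0, hb, wb)
    for (i in seq_len(hb)) {
      rows <- (i - 1L) * pool + seq_len(pool)
      sub <- ad[rows, , drop = FALSE]
      m[i, ] <- colMeans(matrix(sub, pool * pool, wb))
    }
    m
  }
  w <- numeric(num_classes); w[3] <- 50; w[1] <- -50
  classifier_handle(
    identity = sprintf("lesion_detector(pool=%d)", pool),
    spec = spec,
    predict_scores = function(image) w * mean(diff_map(image)),
    features = function(image, layer = NULL, target = NULL,
                        with_gradients = FALSE) {
      if (with_gradients) {
        stop("capability error: lesion_detector exposes no gradients",
             call. = FALSE)
      }
      list(maps = array(diff_map(image), c(hb, wb, 1L)))
    },
    layers = "pool")
}

#' Drop the gradient capability of a handle
#'
#' Returns a copy of the handle with gradient tracking disabled, e.g. to
#' verify that ScoreCAM is genuinely gradient-free.
#'
#' @param handle A [classifier_handle()].
#' @return The handle without the `differentiable` capability.
#' @export
disable_gradients <- function(handle) {
  stopifnot(inherits(handle, "classifier_handle"))
  handle$gradient <- NULL
  handle$capabilities[["differentiable"]] <- FALSE
  if (!is.null(handle$features)) {
    inner <- handle$features
    id <- handle$identity
    handle$features <- function(image, layer = NULL, target = NULL,
                                with_gradients = FALSE) {
      if (with_gradients) {
        stop("capability error: gradient tracking disabled for '", id, "'",
             call. = FALSE)
      }
      inner(image, layer = layer, target = target, with_gradients = FALSE)
    }
  }
  handle
}

#' Train the tiny CNN on generated fundus scenes
#'
#' Seeded training of [make_tiny_cnn()] on a labelled set of synthetic
#' scenes (softmax cross-entropy on the grade label). Before optimization
#' the network's normalization layer is calibrated to the training-set
#' pooled-feature statistics (inference-mode batch normalization), which
#' conditions the head well: a few epochs of per-sample Adam on the dense
#' readout suffice on lesion-separable scenes. The convolutional stages keep
#' their seeded random weights (random-feature training), so the trained
#' model remains a fully inspectable fixture.
#'
#' @param images List of image arrays (all matching one spec).
#' @param labels Integer vector of 0-based grade labels.
#' @param epochs Number of passes over the data.
#' @param seed Seed controlling weight init and shuffling.
#' @param lr Adam learning rate.
#' @return A [classifier_handle()] for the trained network, with attribute
#'   `"history"` holding the per-epoch mean loss and training accuracy.
#' @export
train_tiny_cnn <- function(images, labels, epochs = 5L, seed = 1L,
                           lr = 0.05) {
  stopifnot(length(images) == length(labels), length(images) >= 2)
  if (length(unique(labels)) < 2) {
    stop("training error: need at least 2 classes present", call. = FALSE)
  }
  d <- dim(images[[1]])
  spec <- input_spec(height = d[1], width = d[2], channels = d[3],
                     num_classes = 5L)
  handle <- make_tiny_cnn(spec, seed = seed)
  net <- attr(handle, "net")
  # calibrate the normalization layer on pooled training features
  gap_idx <- match("gap", names(net$layers))
  feats <- t(vapply(images, function(x) {
    net_forward(net, x, cache = TRUE)$acts[[gap_idx + 1L]]
  }, numeric(length(net$layers[[gap_idx + 1L]]$scale))))
  mu <- colMeans(feats)
  sdv <- pmax(apply(feats, 2, stats::sd), 1e-6)
  net$layers[[gap_idx + 1L]]$scale <- 1 / sdv
  net$layers[[gap_idx + 1L]]$shift <- -mu / sdv
  # per-sample Adam on the convolution and dense parameters
  adam <- list(); t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed * 1000L + ep, sample.int(length(images)))
    losses <- numeric(length(ord)); hits <- logical(length(ord))
    for (j in seq_along(ord)) {
      x <- images[[ord[j]]]; y <- labels[[ord[j]]]
      fw <- net_forward(net, x, cache = TRUE)
      p <- softmax(fw$scores)
      losses[j] <- -log(max(p[y + 1L], 1e-12))
      hits[j] <- (which.max(p) - 1L) == y
      dsc <- p; dsc[y + 1L] <- dsc[y + 1L] - 1
      bk <- net_backward(net, fw$acts, fw$scores, y, dscores = dsc,
                         param_grads = TRUE)
      t_step <- t_step + 1
      for (i in seq_along(net$layers)) {
        pg <- bk$pgrads[[i]]
        if (is.null(pg) || net$layers[[i]]$type != "dense") next
        key <- as.character(i)
        if (is.null(adam[[key]])) {
          adam[[key]] <- list(mW = 0 * pg$dW, vW = 0 * pg$dW,
                              mb = 0 * pg$db, vb = 0 * pg$db)
        }
        st <- adam[[key]]
        st$mW <- b1 * st$mW + (1 - b1) * pg$dW
        st$vW <- b2 * st$vW + (1 - b2) * pg$dW^2
        st$mb <- b1 * st$mb + (1 - b1) * pg$db
        st$vb <- b2 * st$vb + (1 - b2) * pg$db^2
        adam[[key]] <- st
        net$layers[[i]]$W <- net$layers[[i]]$W -
          lr * (st$mW / (1 - b1^t_step)) / (sqrt(st$vW / (1 - b2^t_step)) + eps)
        net$layers[[i]]$b <- net$layers[[i]]$b -
          lr * (st$mb / (1 - b1^t_step)) / (sqrt(st$vb / (1 - b2^t_step)) + eps)
      }
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         acc = mean(hits)))
  }
  out <- handle_from_seqnet(net, sprintf("tiny_cnn_trained(seed=%d)", seed),
                            feature_layers = c("relu2", "relu1"))
  attr(out, "net") <- net
  attr(out, "history") <- history
  out
}
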