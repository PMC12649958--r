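# A minimal sequential network engine in base R. It exists so that fixture
# classifiers (linear softmax models, tiny CNNs) have exact, inspectable
# forward, gradient and DeepLIFT semantics; every layer type here is in the
# DeepLIFT-Rescale supported set (linear/convolution/ReLU/pooling).
#
# Layer constructors return tagged lists; a network is a list of layers plus
# an input_spec. Convolutions are computed by looping over the (small) kernel
# offsets with vectorized slice arithmetic, which is fast enough for
# 224 x 224 inputs at desk scale.

layer_conv <- function(W, b, stride = 1L, pad = 1L, name = NULL) {
  stopifnot(length(dim(W)) == 4, length(b) == dim(W)[4])
  list(type = "conv", W = W, b = b, stride = as.integer(stride),
       pad = as.integer(pad), name = name)
}
layer_relu <- function(name = NULL) list(type = "relu", name = name)
layer_gap <- function(name = NULL) list(type = "gap", name = name)
layer_flatten <- function(name = NULL) list(type = "flatten", name = name)
layer_dense <- function(W, b, name = NULL) {
  stopifnot(is.matrix(W), length(b) == ncol(W))
  list(type = "dense", W = W, b = b, name = name)
}
# channelwise normalization in inference mode: y = scale * x + shift, with
# fixed statistics (the batch-norm analogue); acts on pooled feature vectors
layer_affine <- function(scale, shift, name = NULL) {
  stopifnot(length(scale) == length(shift))
  list(type = "affine", scale = scale, shift = shift, name = name)
}

seqnet <- function(layers, spec) {
  names(layers) <- vapply(seq_along(layers), function(i) {
    if (!is.null(layers[[i]]$name)) layers[[i]]$name
    else paste0(layers[[i]]$type, i)
  }, character(1))
  structure(list(layers = layers, spec = spec), class = "seqnet")
}

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

conv_forward <- function(x, W, b, stride, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  xp <- pad_array(x, pad)
  hp <- (dim(xp)[1] - kh) %/% stride + 1L
  wp <- (dim(xp)[2] - kw) %/% stride + 1L
  out <- matrix(0, hp * wp, cout)
  for (ky in seq_len(kh)) {
    rows <- seq(ky, by = stride, length.out = hp)
    for (kx in seq_len(kw)) {
      cols <- seq(kx, by = stride, length.out = wp)
      xs <- xp[rows, cols, , drop = FALSE]
      out <- out + matrix(xs, hp * wp, cin) %*% W[ky, kx, , , drop = TRUE]
    }
  }
  out <- sweep(out, 2, b, "+")
  array(out, c(hp, wp, cout))
}

# gradient w.r.t. the convolution input, given gradient w.r.t. its output
conv_backward_input <- function(dout, W, stride, pad, in_dim) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  hp <- dim(dout)[1]; wp <- dim(dout)[2]
  dm <- matrix(dout, hp * wp, cout)
  dxp <- array(0, c(in_dim[1] + 2 * pad, in_dim[2] + 2 * pad, cin))
  for (ky in seq_len(kh)) {
    rows <- seq(ky, by = stride, length.out = hp)
    for (kx in seq_len(kw)) {
      cols <- seq(kx, by = stride, length.out = wp)
      dxs <- dm %*% t(matrix(W[ky, kx, , ], cin, cout))
      dxp[rows, cols, ] <- dxp[rows, cols, ] + array(dxs, c(hp, wp, cin))
    }
  }
  dxp[pad + seq_len(in_dim[1]), pad + seq_len(in_dim[2]), , drop = FALSE]
}

conv_backward_params <- function(x, dout, W, stride, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  xp <- pad_array(x, pad)
  hp <- dim(dout)[1]; wp <- dim(dout)[2]
  dm <- matrix(dout, hp * wp, cout)
  dW <- array(0, dim(W))
  for (ky in seq_len(kh)) {
    rows <- seq(ky, by = stride, length.out = hp)
    for (kx in seq_len(kw)) {
      cols <- seq(kx, by = stride, length.out = wp)
      xs <- matrix(xp[rows, cols, , drop = FALSE], hp * wp, cin)
      dW[ky, kx, , ] <- t(xs) %*% dm
    }
  }
  list(dW = dW, db = colSums(dm))
}

# forward pass; cache keeps the input of every layer (needed for backprop)
net_forward <- function(net, x, cache = FALSE) {
  acts <- if (cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (cache) acts[[i]] <- x
    x <- switch(ly$type,
      conv = conv_forward(x, ly$W, ly$b, ly$stride, ly$pad),
      relu = { x[x < 0] <- 0; x },
      gap = apply(x, 3, mean),
      flatten = as.vector(x),
      dense = as.vector(crossprod(ly$W, x)) + ly$b,
      affine = ly$scale * x + ly$shift,
      stop("unknown layer type ", ly$type))
  }
  list(scores = x, acts = acts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# backward pass from the target-class score. Returns the gradient w.r.t. the
# output of layer `stop_after` (0 = the network input); optionally collects
# parameter gradients for training.
net_backward <- function(net, acts, scores, target, stop_after = 0L,
                         dscores = NULL, param_grads = FALSE) {
  n <- length(net$layers)
  if (is.null(dscores)) {
    dscores <- numeric(length(scores))
    dscores[target + 1L] <- 1
  }
  g <- dscores
  pgrads <- if (param_grads) vector("list", n) else NULL
  for (i in rev(seq_len(n))) {
    ly <- net$layers[[i]]
    x <- acts[[i]]
    g <- switch(ly$type,
      conv = {
        if (param_grads) pgrads[[i]] <- conv_backward_params(x, g, ly$W, ly$stride, ly$pad)
        conv_backward_input(g, ly$W, ly$stride, ly$pad, dim(x))
      },
      relu = g * (x > 0),
      gap = {
        d <- dim(x)
        array(rep(g, each = d[1] * d[2]) / (d[1] * d[2]), d)
      },
      flatten = array(g, dim(x)),
      dense = {
        if (param_grads) pgrads[[i]] <- list(dW = outer(x, g), db = g)
        as.vector(ly$W %*% g)
      },
      affine = ly$scale * g)
    if (i == stop_after + 1L && !param_grads) return(g)
  }
  if (param_grads) list(dinput = g, pgrads = pgrads) else g
}

net_input_gradient <- function(net, x, target) {
  fw <- net_forward(net, x, cache = TRUE)
  net_backward(net, fw$acts, fw$scores, target, stop_after = 0L)
}

# indices of layers whose output is a spatial activation stack; the feature
# layer id refers to the *output* of that layer (post-ReLU for conv stages)
net_feature_layer_ids <- function(net) {
  ids <- character()
  for (i in seq_along(net$layers)) {
    ty <- net$layers[[i]]$type
    if (ty %in% c("conv", "relu")) ids <- c(ids, names(net$layers)[i])
  }
  ids
}

net_feature_maps <- function(net, x, layer, target = NULL,
                             with_gradients = FALSE) {
  idx <- match(layer, names(net$layers))
  if (is.na(idx)) stop("configuration error: unknown layer id '", layer, "'",
                       call. = FALSE)
  fw <- net_forward(net, x, cache = TRUE)
  maps <- if (idx == length(net$layers)) fw$scores else fw$acts[[idx + 1L]]
  if (length(dim(maps)) != 3) {
    stop("configuration error: layer '", layer, "' has no spatial activations",
         call. = FALSE)
  }
  out <- list(maps = maps)
  if (with_gradients) {
    out$grads <- net_backward(net, fw$acts, fw$scores, target, stop_after = idx)
  }
  out
}

# DeepLIFT with the Rescale rule. Multipliers are propagated from the target
# score back to the input; linear layers use their (bias-free) transpose,
# ReLU uses delta-out / delta-in when |delta-in| > eps and the local gradient
# otherwise. Satisfies summation-to-delta by construction.
net_deeplift <- function(net, x, baseline, target, eps = 1e-7) {
  fx <- net_forward(net, x, cache = TRUE)
  fb <- net_forward(net, baseline, cache = TRUE)
  n <- length(net$layers)
  m <- numeric(length(fx$scores))
  m[target + 1L] <- 1
  for (i in rev(seq_len(n))) {
    ly <- net$layers[[i]]
    xi <- fx$acts[[i]]; bi <- fb$acts[[i]]
    m <- switch(ly$type,
      conv = conv_backward_input(m, ly$W, ly$stride, ly$pad, dim(xi)),
      relu = {
        din <- xi - bi
        dout <- pmax(xi, 0) - pmax(bi, 0)
        mult <- ifelse(abs(din) > eps, dout / ifelse(din == 0, 1, din), (xi > 0) * 1)
        r <- m * mult
        dim(r) <- dim(xi)
        r
      },
      gap = {
        d <- dim(xi)
        array(rep(m, each = d[1] * d[2]) / (d[1] * d[2]), d)
      },
      flatten = array(m, dim(xi)),
      dense = as.vector(ly$W %*% m),
      affine = ly$scale * m)
  }
  m * (x - baseline)
}

#' Build a classifier handle around a sequential fixture network
#'
#' Exposes the full model-interface contract (scores, softmax probabilities,
#' input gradients, feature maps with gradients, DeepLIFT-Rescale) for a
#' network built from supported primitive layers.
#'
#' @param net Internal `seqnet` object.
#' @param identity Model name.
#' @param feature_layers Character vector of exposed feature-layer ids; the
#'   first is the default CAM layer. `NULL` exposes the last spatial stage.
#' @return A [classifier_handle()].
#' @keywords internal
handle_from_seqnet <- function(net, identity, feature_layers = NULL) {
  if (is.null(feature_layers)) {
    ids <- net_feature_layer_ids(net)
    feature_layers <- if (length(ids)) ids[length(ids)] else character()
  }
  classifier_handle(
    identity = identity,
    spec = net$spec,
    predict_scores = function(image) net_forward(net, image)$scores,
    gradient = function(image, target) net_input_gradient(net, image, target),
    features = if (length(feature_layers)) {
      function(image, layer = NULL, target = NULL, with_gradients = FALSE) {
        net_feature_maps(net, image, layer %||% feature_layers[[1]],
                         target = target, with_gradients = with_gradients)
      }
    },
    layers = feature_layers,
    deeplift = function(image, baseline, target) {
      net_deeplift(net, image, baseline, target)
    }
  )
}
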