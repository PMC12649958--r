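test_that("planted region model maps mean intensity to confidence", {
  spec <- spec_small(10)
  reg <- matrix(FALSE, 10, 10); reg[1:4, 1:5] <- TRUE
  h <- make_planted_model("region_fraction", spec, region = reg)
  white <- array(1, c(10, 10, 3))
  black <- array(0, c(10, 10, 3))
  expect_equal(predict_confidence(h, white, 1), 1.0)
  expect_equal(predict_confidence(h, black, 1), 0.0)
  expect_equal(sum(predict_probabilities(h, rand_image(10, 3))), 1,
               tolerance = 1e-9)
})

test_that("probabilities normalize and predictions are deterministic across fixture models", {
  spec <- spec_small(8)
  models <- list(
    region = make_planted_model("region_fraction", spec,
                                region = diag(8) > 0),
    linear = make_planted_model("intensity_linear", spec, seed = 3),
    cnn = make_planted_model("tiny_cnn", spec, seed = 5))
  for (h in models) {
    for (s in 1:10) {
      img <- rand_image(8, 100 + s)
      p <- predict_probabilities(h, img)
      expect_equal(sum(p), 1, tolerance = 1e-6)
      expect_true(all(p >= 0))
      expect_identical(p, predict_probabilities(h, img))
    }
  }
})

test_that("analytic gradients match central finite differences on 8x8 inputs", {
  spec <- spec_small(8)
  img <- rand_image(8, 7)
  models <- list(
    region = make_planted_model("region_fraction", spec,
                                region = matrix(c(TRUE, FALSE), 8, 8)),
    linear = make_planted_model("intensity_linear", spec, seed = 3),
    cnn = make_planted_model("tiny_cnn", spec, seed = 5),
    single = make_single_map_model(spec_small(8), pool = 4))
  for (nm in names(models)) {
    h <- models[[nm]]
    g <- input_gradient(h, img, 1)
    fd <- finite_diff_gradient(h, img, 1)
    expect_lt(max(abs(g - fd)), 1e-3)
  }
})

test_that("linear model gradient equals its stored weights exactly", {
  spec <- spec_small(6)
  h <- make_planted_model("intensity_linear", spec, seed = 9)
  img <- rand_image(6, 2)
  for (cls in c(0L, 3L)) {
    g <- input_gradient(h, img, cls)
    expect_equal(as.vector(g), linear_weights(h)[, cls + 1L])
  }
})

test_that("constant model has an all-zero gradient", {
  spec <- spec_small(6)
  h <- make_constant_model(spec)
  g <- input_gradient(h, rand_image(6, 4), 2)
  expect_true(all(g == 0))
})

test_that("contract violations raise informative errors", {
  spec <- spec_small(8)
  h <- make_planted_model("intensity_linear", spec)
  bad <- array(0.5, c(4, 4, 3))
  expect_error(predict_confidence(h, bad, 1), "input-contract")
  expect_error(predict_confidence(h, rand_image(8), 7), "input-contract")
  hr <- make_planted_model("region_fraction", spec, region = diag(8) > 0)
  expect_error(feature_maps(hr, rand_image(8)), "capability")
  nog <- disable_gradients(h)
  expect_error(input_gradient(nog, rand_image(8), 1), "capability")
  expect_error(make_planted_model("region_fraction", spec,
                                  region = matrix(FALSE, 8, 8)), "region")
})

test_that("feature maps have the architecture's spatial size and honour layer ids", {
  h <- make_single_map_model(input_spec(32, 32, 3), pool = 8)
  img <- rand_image(32, 5)
  fm <- feature_maps(h, img)
  expect_equal(dim(fm$maps), c(4L, 4L, 1L))
  expect_error(feature_maps(h, img, layer = "nope"), "configuration")
  hc <- make_tiny_cnn(spec_small(16), seed = 2)
  fm2 <- feature_maps(hc, rand_image(16, 6), layer = "relu1")
  expect_equal(dim(fm2$maps), c(8L, 8L, 8L))
})

test_that("an identity convolution peaks at a delta image's location", {
  spec <- input_spec(9, 9, 1, num_classes = 5)
  W <- array(0, c(3, 3, 1, 1)); W[2, 2, 1, 1] <- 1  # identity kernel
  net <- fundusXAI:::seqnet(list(
    fundusXAI:::layer_conv(W, 0, stride = 1L, pad = 1L, name = "conv1"),
    fundusXAI:::layer_gap(name = "gap"),
    fundusXAI:::layer_dense(matrix(1, 1, 5), rep(0, 5), name = "fc")), spec)
  h <- fundusXAI:::handle_from_seqnet(net, "identity_conv",
                                      feature_layers = "conv1")
  delta <- array(0, c(9, 9, 1)); delta[4, 6, 1] <- 1
  fm <- feature_maps(h, delta, layer = "conv1")
  peak <- which(fm$maps[, , 1] == max(fm$maps[, , 1]), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(4L, 6L))
  # direct convolution oracle: identity kernel reproduces the input
  expect_equal(fm$maps[, , 1], delta[, , 1])
})
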