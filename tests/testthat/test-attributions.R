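black_like <- function(img) array(0, dim(img))

test_that("closed forms hold on the linear fixture for all reference-based methods", {
  spec <- spec_small(6)
  h <- make_planted_model("intensity_linear", spec, seed = 4)
  W <- linear_weights(h)
  img <- rand_image(6, 8)
  target <- 2L
  wt <- array(W[, target + 1L], dim(img))

  vg <- vanilla_gradient(h, img, target)
  expect_equal(vg$raw, wt)
  expect_equal(vg$map2d, aggregate_channels(wt))

  for (steps in c(1L, 4L, 64L)) {
    ig <- integrated_gradients(h, img, target,
                               attribution_config(ig_steps = steps))
    expect_equal(ig$raw, wt * img, tolerance = 1e-12)
  }

  dl <- deeplift_rescale(h, img, target)
  expect_equal(dl$raw, wt * img, tolerance = 1e-12)

  # expected-gradients is exact for a linear model with a single baseline
  sh <- shap_attribution(h, img, target,
                         attribution_config(shap_samples = 16))
  expect_equal(sh$raw, wt * img, tolerance = 1e-12)
})

test_that("smoothgrad averages to the linear weights within Monte-Carlo error", {
  spec <- spec_small(4)
  h <- make_planted_model("intensity_linear", spec, seed = 6)
  W <- linear_weights(h)
  img <- rand_image(4, 3)
  cfg <- attribution_config(sg_samples = 1000L, sg_sigma = 0.3, rng_seed = 42L)
  sg <- smoothgrad(h, img, 1L, cfg)
  # for a linear model every sample's gradient is exactly w: zero variance
  expect_equal(as.vector(sg$raw), W[, 2], tolerance = 1e-10)
})

test_that("stochastic methods are bit-reproducible for a fixed seed", {
  h <- make_planted_model("tiny_cnn", spec_small(8), seed = 5)
  img <- rand_image(8, 9)
  cfg <- attribution_config(sg_samples = 5L, shap_samples = 5L, rng_seed = 7L)
  expect_identical(smoothgrad(h, img, 1, cfg)$raw,
                   smoothgrad(h, img, 1, cfg)$raw)
  expect_identical(shap_attribution(h, img, 1, cfg)$raw,
                   shap_attribution(h, img, 1, cfg)$raw)
  cfg2 <- attribution_config(sg_samples = 5L, shap_samples = 5L, rng_seed = 8L)
  expect_false(identical(smoothgrad(h, img, 1, cfg)$raw,
                         smoothgrad(h, img, 1, cfg2)$raw))
})

test_that("smoothgrad with zero noise is bit-identical to the vanilla gradient", {
  h <- make_planted_model("tiny_cnn", spec_small(8), seed = 5)
  img <- rand_image(8, 9)
  sg <- smoothgrad(h, img, 2, attribution_config(sg_sigma = 0))
  vg <- vanilla_gradient(h, img, 2)
  expect_identical(sg$raw, vg$raw)
})

test_that("IG and DeepLIFT satisfy the completeness axiom on the tiny CNN", {
  spec <- input_spec(16, 16, 3)
  h <- make_planted_model("tiny_cnn", spec, seed = 11)
  img <- rand_image(16, 21)
  target <- 1L
  black <- black_like(img)
  delta <- predict_scores(h, img)[target + 1L] -
    predict_scores(h, black)[target + 1L]

  ig <- integrated_gradients(h, img, target,
                             attribution_config(ig_steps = 256L))
  expect_lt(abs(sum(ig$raw) - delta), 1e-2 * abs(delta) + 1e-4)

  dl <- deeplift_rescale(h, img, target)
  expect_lt(abs(sum(dl$raw) - delta), 1e-5)
})

test_that("reference-based methods vanish when the image equals the baseline", {
  h <- make_planted_model("tiny_cnn", spec_small(8), seed = 5)
  black <- array(0, c(8, 8, 3))
  cfg <- attribution_config()
  expect_true(all(integrated_gradients(h, black, 1, cfg)$raw == 0))
  expect_true(all(shap_attribution(h, black, 1, cfg)$raw == 0))
  expect_true(all(deeplift_rescale(h, black, 1, cfg)$raw == 0))
})

test_that("every method returns a zero map on a constant-output model", {
  spec <- spec_small(8)
  h <- make_constant_model(spec)
  img <- rand_image(8, 13)
  cfg <- attribution_config(sg_samples = 3L, shap_samples = 3L)
  for (m in c("gradient", "smoothgrad", "integrated_gradients", "shap",
              "deeplift")) {
    sal <- compute_saliency(h, img, 1, m, cfg)
    expect_true(all(sal$map2d == 0), info = m)
  }
})

test_that("channel aggregation sums absolute values and is permutation-invariant", {
  raw <- array(0, c(2, 2, 3))
  raw[1, 1, ] <- c(1, -1, 0)
  expect_equal(aggregate_channels(raw)[1, 1], 2)
  expect_true(all(aggregate_channels(array(0, c(3, 3, 3))) == 0))
  r <- withr::with_seed(5, array(rnorm(2 * 2 * 3), c(2, 2, 3)))
  expect_equal(aggregate_channels(r), aggregate_channels(r[, , c(3, 1, 2)]))
  expect_error(aggregate_channels(array(NaN, c(2, 2, 1))), "numeric")
})

test_that("baseline configuration is validated", {
  h <- make_planted_model("intensity_linear", spec_small(8))
  img <- rand_image(8)
  expect_error(integrated_gradients(h, img, 1,
                                    attribution_config(baseline = "white")),
               "config")
  expect_error(shap_attribution(h, img, 1,
                                attribution_config(baseline = list())),
               "config")
  expect_error(integrated_gradients(h, img, 1,
                                    attribution_config(baseline = array(0, c(2, 2, 3)))),
               "config|contract")
})
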