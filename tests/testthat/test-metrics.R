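test_that("min-max normalization maps extremes to [0, 1] and is idempotent", {
  m <- matrix(c(0, 127.5, 255, 63.75), 2, 2)
  nm <- normalize_minmax(m)
  expect_equal(nm, matrix(c(0, 0.5, 1, 0.25), 2, 2))
  expect_equal(normalize_minmax(nm), nm)
  cm <- normalize_minmax(matrix(3, 4, 4))
  expect_true(isTRUE(attr(cm, "degenerate")))
  expect_true(all(cm == 0.5))
  expect_equal(normalize_minmax(cm)[1, 1], 0.5)
})

test_that("distributions normalize to unit mass with degenerate fallback", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
  d <- to_distribution(m)
  expect_equal(d$p[1, 1], 0.5)
  expect_equal(sum(d$p), 1)
  delta <- matrix(0, 3, 3); delta[2, 2] <- 5
  expect_equal(to_distribution(delta)$p[2, 2], 1)
  z <- to_distribution(matrix(0, 3, 3))
  expect_true(z$degenerate)
  expect_equal(sum(z$p), 1)
  for (s in 1:20) {
    expect_equal(sum(to_distribution(matrix(withr::with_seed(s, runif(36)),
                                            6, 6))$p), 1)
  }
  expect_error(to_distribution(matrix(-1, 2, 2)), "contract")
})

test_that("entropy attains its closed-form values and bounds", {
  delta <- matrix(0, 5, 5); delta[3, 3] <- 1
  expect_equal(entropy(to_distribution(delta)), 0)
  two <- matrix(0, 4, 4); two[1, 1] <- two[4, 4] <- 1
  expect_equal(entropy(to_distribution(two)), 1.0)
  unif224 <- matrix(1, 224, 224)
  expect_equal(saliency_entropy(unif224), log2(224 * 224), tolerance = 1e-12)
  expect_equal(log2(224 * 224), 15.61471, tolerance = 1e-5)
  for (s in 1:10) {
    H <- saliency_entropy(matrix(withr::with_seed(s, runif(64)), 8, 8))
    expect_gte(H, 0); expect_lte(H, log2(64))
  }
})

test_that("perturbation curve matches the planted-region closed form", {
  spec <- input_spec(10, 10, 3)
  reg <- matrix(FALSE, 10, 10); reg[1:4, 1:5] <- TRUE  # 20 px = 20 %
  h <- make_planted_model("region_fraction", spec, region = reg)
  white <- array(1, c(10, 10, 3))
  sal <- matrix(0, 10, 10); sal[reg] <- 1
  cur <- perturbation_curve(h, white, sal, 1)
  expect_length(cur$confidences, 51)
  expect_equal(cur$ratios[1], 0)
  expect_equal(cur$K, 50)
  n <- 100; R <- sum(reg)
  closed <- c(1, sapply(1:50, function(k) {
    masked_in_R <- min(ceiling(k * 0.02 * n), R)
    (R - masked_in_R) / R
  }))
  expect_lt(max(abs(cur$confidences - closed)), 1e-6)
  # AOPC equals the hand-summed mean drop
  expect_equal(aopc(cur), mean(1 - closed[-1]), tolerance = 1e-12)
})

test_that("constant models give flat curves and zero AOPC", {
  spec <- spec_small(8)
  h <- make_constant_model(spec)
  img <- rand_image(8, 3)
  cur <- perturbation_curve(h, img, matrix(runif(64), 8, 8), 1)
  expect_true(all(abs(cur$confidences - cur$confidences[1]) < 1e-12))
  expect_equal(aopc(cur), 0)
})

test_that("aopc reaches 1 for a maximal confidence collapse", {
  cur <- structure(list(ratios = seq(0, 1, by = 0.02),
                        confidences = c(1, rep(0, 50)), K = 50L),
                   class = "perturbation_curve")
  expect_equal(aopc(cur), 1.0)
})

test_that("perturbation settings are validated", {
  spec <- spec_small(8)
  h <- make_constant_model(spec)
  img <- rand_image(8, 3)
  expect_error(perturbation_curve(h, img, matrix(1, 8, 8), 1, step = 0.03),
               "config")
  expect_error(perturbation_curve(h, img, matrix(1, 4, 4), 1), "aligned")
})

test_that("percentile binarization retains the top decile exactly", {
  m <- matrix(sample(1:100), 10, 10)
  bin <- binarize_top_percentile(m, 0.9)
  expect_equal(sum(bin$highlight), 10L)
  expect_setequal(m[bin$highlight], 91:100)
  expect_warning(binarize_top_percentile(matrix(1, 5, 5)), "empty")
  for (s in 1:10) {
    mm <- matrix(withr::with_seed(s, rpois(100, 4)), 10, 10)
    b <- suppressWarnings(binarize_top_percentile(mm, 0.9))
    ties <- sum(mm == b$threshold_value)
    expect_lte(sum(b$highlight), 10 + ties)
  }
})

test_that("recall and dice reproduce closed-form overlap cases", {
  truth <- matrix(FALSE, 4, 4); truth[1, 1:4] <- TRUE       # |B| = 4
  hl <- matrix(FALSE, 4, 4); hl[1, 1:3] <- TRUE             # TP = 3, FN = 1
  expect_equal(overlap_recall(hl, truth), 0.75)
  expect_equal(overlap_recall(matrix(TRUE, 4, 4), truth), 1.0)
  expect_equal(overlap_dice(truth, truth), 1.0)
  disj <- matrix(FALSE, 4, 4); disj[4, ] <- TRUE
  expect_equal(overlap_dice(disj, truth), 0.0)
  a <- matrix(FALSE, 5, 5); a[1:2, 1:5] <- TRUE             # |A| = 10
  b <- matrix(FALSE, 5, 5); b[2:3, 1:5] <- TRUE             # |B| = 10, |A^B| = 5
  expect_equal(overlap_dice(a, b), 0.5)
  expect_warning(r <- overlap_recall(hl, matrix(FALSE, 4, 4)), "undefined")
  expect_true(is.na(r))
  expect_warning(d <- overlap_dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
                 "undefined")
  expect_true(is.na(d))
})

test_that("recall and dice are invariant under joint spatial permutation", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      a <- matrix(runif(36) > 0.6, 6, 6)
      b <- matrix(runif(36) > 0.7, 6, 6)
      if (!any(b)) b[1, 1] <- TRUE
      perm <- sample(36)
      ap <- matrix(as.vector(a)[perm], 6, 6)
      bp <- matrix(as.vector(b)[perm], 6, 6)
      expect_equal(overlap_recall(a, b), overlap_recall(ap, bp))
      expect_equal(suppressWarnings(overlap_dice(a, b)),
                   suppressWarnings(overlap_dice(ap, bp)))
    }
  })
})

test_that("indicator saliency beats random maps in AOPC on the planted model", {
  spec <- input_spec(10, 10, 3)
  reg <- matrix(FALSE, 10, 10); reg[3:6, 3:7] <- TRUE
  h <- make_planted_model("region_fraction", spec, region = reg)
  white <- array(1, c(10, 10, 3))
  sal <- matrix(0, 10, 10); sal[reg] <- 1
  a_ind <- aopc(perturbation_curve(h, white, sal, 1))
  a_rand <- sapply(1:20, function(s) {
    rs <- matrix(withr::with_seed(300 + s, runif(100)), 10, 10)
    aopc(perturbation_curve(h, white, rs, 1))
  })
  expect_gt(a_ind, mean(a_rand))
})

test_that("the monotone planted model yields a non-increasing curve under correct saliency", {
  spec <- input_spec(12, 12, 3)
  reg <- matrix(FALSE, 12, 12); reg[2:9, 2:9] <- TRUE
  h <- make_planted_model("region_fraction", spec, region = reg)
  img <- rand_image(12, 17)
  sal <- matrix(0, 12, 12); sal[reg] <- img[, , 1][reg] + 1
  cur <- perturbation_curve(h, img, sal, 1)
  expect_true(all(diff(cur$confidences) <= 1e-12))
})

test_that("evaluate_batch emits one complete record per image-method pair", {
  spec <- input_spec(16, 16, 3)
  h <- make_planted_model("tiny_cnn", spec, seed = 2)
  imgs <- list(rand_image(16, 1), rand_image(16, 2))
  mask2 <- matrix(FALSE, 16, 16); mask2[4:8, 4:8] <- TRUE
  recs <- evaluate_batch(h, imgs, labels = c(0L, 2L),
                         masks = list(NULL, mask2),
                         methods = c("gradient", "deeplift"),
                         config = attribution_config(ig_steps = 4))
  expect_equal(nrow(recs), 4L)
  g0 <- recs[recs$label == 0, ]
  expect_true(all(is.na(g0$recall)) && all(is.na(g0$dice)))
  g2 <- recs[recs$label == 2, ]
  expect_true(all(!is.na(g2$recall)) && all(!is.na(g2$dice)))
  expect_true(all(is.na(recs$error)))
  # per-label mean equals the hand-computed mean of per-image values
  summ <- summarize_records(recs)
  expect_equal(summ$AOPC_Score[summ$Label == 2],
               mean(g2$aopc))
  expect_equal(summ$Entropy[summ$Label == 0], mean(g0$entropy))
})

test_that("metrics on a saved-and-reloaded saliency map are bit-identical", {
  spec <- input_spec(16, 16, 3)
  h <- make_planted_model("tiny_cnn", spec, seed = 2)
  img <- rand_image(16, 5)
  sal <- vanilla_gradient(h, img, 1)
  path <- tempfile(fileext = ".rds")
  save_saliency(sal, path, png = FALSE)
  sal2 <- load_saliency(path)
  expect_identical(sal$raw, sal2$raw)
  expect_identical(saliency_entropy(sal$map2d), saliency_entropy(sal2$map2d))
  expect_identical(
    perturbation_curve(h, img, sal$map2d, 1)$confidences,
    perturbation_curve(h, img, sal2$map2d, 1)$confidences)
})
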