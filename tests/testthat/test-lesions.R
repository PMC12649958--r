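test_that("polygon rasterization follows the pixel-centre even-odd rule", {
  sq <- polygon_annotation(rbind(c(2, 3), c(2, 13), c(12, 13), c(12, 3)),
                           "hemorrhage")
  m <- polygon_to_mask(sq, c(20, 20))
  expect_equal(sum(m), 100L)  # 10x10 axis-aligned square
  expect_identical(m, brute_polygon_mask(sq$vertices, c(20, 20)))

  tri <- polygon_annotation(rbind(c(0, 0), c(0, 8), c(8, 0)), "microaneurysm")
  mt <- polygon_to_mask(tri, c(10, 10))
  expect_identical(mt, brute_polygon_mask(tri$vertices, c(10, 10)))
  expect_lte(abs(sum(mt) - 32), 8)  # area 8*8/2 within one pixel-row

  withr::with_seed(9, {
    for (rep in 1:5) {
      v <- cbind(runif(5, 1, 15), runif(5, 1, 15))
      expect_identical(polygon_to_mask(v, c(16, 16)),
                       brute_polygon_mask(v, c(16, 16)))
    }
  })
})

test_that("degenerate and out-of-bounds polygons are handled", {
  coll <- rbind(c(1, 1), c(5, 5), c(9, 9))
  expect_warning(m <- polygon_to_mask(coll, c(12, 12)), "empty|degenerate")
  expect_false(any(m))
  expect_error(polygon_to_mask(rbind(c(-2, 1), c(5, 5), c(1, 9)), c(12, 12)),
               "annotation")
})

test_that("extracted patches have a feathered alpha that is 0 on the border and 1 inside", {
  img <- withr::with_seed(3, array(runif(40 * 40 * 3), c(40, 40, 3)))
  big <- polygon_annotation(rbind(c(8, 8), c(8, 30), c(30, 30), c(30, 8)),
                            "hemorrhage")
  p <- extract_patch(img, big)
  expect_true(all(p$alpha[1, ] == 0) && all(p$alpha[nrow(p$alpha), ] == 0))
  expect_true(all(p$alpha[, 1] == 0) && all(p$alpha[, ncol(p$alpha)] == 0))
  # deep interior (>= 3x feather radius from the edge) saturates at 1
  interior <- p$alpha[10:14, 10:14]
  expect_true(all(abs(interior - 1) < 1e-6))
  expect_equal(dim(p$pixels)[1:2], dim(p$alpha))
})

test_that("compositing a patch back at its source location is a near no-op", {
  img <- withr::with_seed(4, array(runif(40 * 40 * 3), c(40, 40, 3)))
  ann <- polygon_annotation(rbind(c(10, 10), c(10, 25), c(25, 25), c(25, 10)),
                            "hemorrhage")
  p <- extract_patch(img, ann)
  bl <- fundusXAI:::blend_patch(img, p, p$source$bbox[1] + 1L,
                                p$source$bbox[2] + 1L)
  # alpha-blending source pixels onto themselves changes nothing anywhere
  expect_lt(max(abs(bl$image - img)), 1e-12)
})

test_that("composition produces the requested insertion sequences deterministically", {
  pool <- make_patch_pool(size = 224, seed = 11)
  base <- generate_fundus(fundus_scene_spec(size = 224, seed = 99))$image
  ma_counts <- c(14L, 12L, 10L, 8L, 6L)
  hem_counts <- c(13L, 11L, 9L, 7L, 5L)
  seq_ma <- compose_sequence(base, pool$microaneurysm, ma_counts, seed = 5)
  expect_equal(vapply(seq_ma, function(s) nrow(s$masks$placements), 0L),
               ma_counts)
  seq_hem <- compose_sequence(base, pool$hemorrhage, hem_counts, seed = 5)
  expect_equal(vapply(seq_hem, function(s) nrow(s$masks$placements), 0L),
               hem_counts)
  # determinism and seed sensitivity
  seq_ma2 <- compose_sequence(base, pool$microaneurysm, ma_counts, seed = 5)
  expect_identical(seq_ma[[1]]$image, seq_ma2[[1]]$image)
  seq_ma3 <- compose_sequence(base, pool$microaneurysm, ma_counts, seed = 6)
  expect_false(identical(seq_ma[[1]]$image, seq_ma3[[1]]$image))
  # locality: untouched outside the (dilated) lesion supports
  s1 <- seq_ma[[1]]
  patch_reach <- max(vapply(pool$microaneurysm,
                            function(p) max(dim(p$alpha)), 0L))
  outside <- !dilate_disc(s1$masks$union, patch_reach)
  dev <- abs(s1$image - base)
  expect_equal(max(dev[array(rep(outside, 3), dim = dim(base))]), 0)
  # logged centres lie inside the union mask
  pl <- s1$masks$placements
  expect_true(all(s1$masks$union[cbind(pl$row + 1L, pl$col + 1L)]))
})

test_that("trend overlap score has its closed-form values on simple cases", {
  mask <- matrix(FALSE, 20, 20); mask[5:8, 5:8] <- TRUE
  msk <- lesion_mask_set(list(microaneurysm = mask))
  inside <- matrix(0, 20, 20); inside[6, 6] <- 3
  expect_equal(trend_overlap_score(inside, msk, margin = 0), 1.0)
  unif <- matrix(1, 20, 20)
  dil <- dilate_disc(mask, 5)
  expect_equal(trend_overlap_score(unif, msk, margin = 5), sum(dil) / 400)
  expect_warning(
    na <- trend_overlap_score(unif, matrix(FALSE, 20, 20)), "undefined")
  expect_true(is.na(na))
})

test_that("the planted detector's ScoreCAM beats uniform saliency at every count", {
  pool <- make_patch_pool(size = 224, seed = 11)
  base <- generate_fundus(fundus_scene_spec(size = 224, seed = 99))$image
  det <- make_lesion_detector_model(base, pool = 16)
  tr <- run_trend_analysis(det, base, pool$microaneurysm,
                           c(14L, 10L, 6L), target = 2L, seed = 5)
  expect_equal(nrow(tr), 3L)
  expect_true(all(tr$overlap > tr$uniform_baseline))
  arts <- attr(tr, "artifacts")
  expect_length(arts, 3L)
  for (a in arts) expect_true(all(a$saliency$map2d >= 0))
})
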