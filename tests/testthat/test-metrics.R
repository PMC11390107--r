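quantize_and_simulate <- function(img, severity = 0.8) {
  q <- quantize(img)
  list(q = q, s = simulate_quantized(q, severity))
}

test_that("mean pixel-wise distance: zero at severity 0, ~0 on grayscale", {
  img <- random_small_image(12, 10, 5, seed = 21)
  qs0 <- quantize_and_simulate(img, 0)
  expect_equal(mean_pixelwise_distance(qs0$q, qs0$s), 0)
  gray <- raster_image(array(rep(seq(0.1, 0.9, length.out = 30), 3),
                             dim = c(5, 6, 3)))
  qs <- quantize_and_simulate(gray, 0.8)
  expect_lt(mean_pixelwise_distance(qs$q, qs$s), 0.005)
})

test_that("mean pixel-wise distance equals a hand computation on 2 pixels", {
  img <- raster_image(array(c(1, 0, 0, 1, 0, 0), dim = c(1, 2, 3)))
  qs <- quantize_and_simulate(img, 0.8)
  red <- c(1, 0, 0); green <- c(0, 1, 0)
  by_hand <- mean(c(
    delta_e2000(srgb_to_lab(red), srgb_to_lab(simulate_deutan(red, 0.8))),
    delta_e2000(srgb_to_lab(green),
                srgb_to_lab(simulate_deutan(green, 0.8))))) / 100
  expect_equal(mean_pixelwise_distance(qs$q, qs$s), by_hand,
               tolerance = 1e-12)
  expect_error(mean_pixelwise_distance(qs$q, quantize_and_simulate(
    random_small_image(3, 3, 2, 1), 0.8)$s), "dimensions")
})

test_that("enumerate_pairs excludes achromatics and enumerates C(k,2)", {
  img <- two_block_image(c(1, 0, 0), c(0, 1, 0))       # + gray background
  qs <- quantize_and_simulate(img)
  pairs <- enumerate_pairs(qs$q, qs$s)
  expect_equal(nrow(pairs), 1)                          # gray excluded
  expect_true(all(pairs$ia < pairs$ib))

  # 4 chromatic colors -> 6 pairs
  pal <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0.5, 0))
  px <- array(0, dim = c(2, 2, 3))
  for (k in 1:3) px[, , k] <- matrix(pal[, k], 2, 2)
  qs4 <- quantize_and_simulate(raster_image(px))
  expect_equal(nrow(enumerate_pairs(qs4$q, qs4$s)), 6)

  # ratio matches a direct two-color computation
  two <- raster_image(array(c(1, 0, 0, 1, 0, 0), dim = c(1, 2, 3)))
  qs2 <- quantize_and_simulate(two)
  p2 <- enumerate_pairs(qs2$q, qs2$s)
  d_o <- delta_e2000(srgb_to_lab(c(1, 0, 0)), srgb_to_lab(c(0, 1, 0)))
  sim <- simulate_deutan(rbind(c(1, 0, 0), c(0, 1, 0)), 0.8)
  d_s <- delta_e2000(srgb_to_lab(sim[1, ]), srgb_to_lab(sim[2, ]))
  expect_equal(p2$ratio, d_o / d_s, tolerance = 1e-12)
})

test_that("max_ratio selects by largest original distance, not ratio", {
  pairs <- data.frame(ia = c(1, 1), ib = c(2, 3),
                      dist_orig = c(50, 30), dist_sim = c(25, 10 / 3),
                      ratio = c(2, 9))
  expect_equal(max_ratio(pairs), 2)
  expect_equal(max_ratio(pairs[0, , drop = FALSE]), 0)
  expect_equal(max_ratio(pairs[2, , drop = FALSE]), 9)
})

test_that("high_ratio_count uses a strict threshold", {
  pairs <- data.frame(ratio = c(4.9, 5.0, 5.1))
  expect_equal(high_ratio_count(pairs), 1)
  expect_equal(high_ratio_count(pairs[0, , drop = FALSE]), 0)
  expect_equal(high_ratio_count(pairs, threshold = 4.85), 3)
})

test_that("high-ratio pixel proportion counts the union of pair colors", {
  img <- two_block_image(red_green$a, red_green$b, w = 50, h = 20,
                         block_w = 10, gap = 0)  # 40% colored, 60% gray
  qs <- quantize_and_simulate(img)
  pairs <- enumerate_pairs(qs$q, qs$s)
  expect_equal(high_ratio_count(pairs), 1)
  expect_equal(high_ratio_pixel_proportion(qs$q, pairs), 0.4)
  expect_equal(high_ratio_pixel_proportion(qs$q, pairs, threshold = 1e6), 0)
})

test_that("mean_spatial_distance matches tiny enumerations", {
  # 2x1: red at x=1, green at x=2 -> single cross pair, distance 1
  img <- raster_image(array(0, dim = c(1, 2, 3)))
  for (k in 1:3) {
    img$pixels[1, 1, k] <- red_green$a[k]
    img$pixels[1, 2, k] <- red_green$b[k]
  }
  qs <- quantize_and_simulate(img)
  pairs <- enumerate_pairs(qs$q, qs$s)
  expect_equal(mean_spatial_distance(qs$q, pairs), 1.0)

  # 3x1: red at x=1, green at x in {2,3} -> mean (1+2)/2
  img3 <- raster_image(array(0, dim = c(1, 3, 3)))
  for (k in 1:3) {
    img3$pixels[1, 1, k] <- red_green$a[k]
    img3$pixels[1, 2:3, k] <- red_green$b[k]
  }
  qs3 <- quantize_and_simulate(img3)
  expect_equal(mean_spatial_distance(qs3$q, enumerate_pairs(qs3$q, qs3$s)),
               1.5)
  # no high-ratio pairs -> NA marker
  expect_true(is.na(mean_spatial_distance(qs3$q,
                                          enumerate_pairs(qs3$q, qs3$s),
                                          threshold = 1e6)))
})

test_that("capped subsampling approximates the exact spatial mean", {
  img <- two_block_image(red_green$a, red_green$b, w = 40, h = 20,
                         block_w = 20, gap = 0)   # 20x20 two-block layout
  qs <- quantize_and_simulate(img)
  pairs <- enumerate_pairs(qs$q, qs$s)
  exact <- mean_spatial_distance(qs$q, pairs, cap = Inf)
  capped <- mean_spatial_distance(qs$q, pairs, cap = 1e4, seed = 5)
  expect_equal(capped, exact, tolerance = 0.01)
  # determinism of the seeded subsample
  expect_identical(capped, mean_spatial_distance(qs$q, pairs, cap = 1e4,
                                                 seed = 5))
})

test_that("all five metrics match the brute-force oracle exactly", {
  for (seed in 1:12) {
    img <- random_small_image(sample(3:8, 1), sample(3:8, 1),
                              sample(2:6, 1), seed = seed)
    mine <- compute_metric_vector(img, target_h = dim(img$pixels)[1],
                                  cap = Inf)
    oracle <- bf_metrics(img)
    for (f in c("mean_pixelwise_dist", "max_ratio", "high_ratio_count",
                "high_ratio_pixel_prop", "mean_spatial_dist")) {
      expect_metric_equal(mine, oracle, f)
    }
  }
})

test_that("metric vector flags grayscale with empty pair metrics", {
  gray <- raster_image(array(rep(c(0.1, 0.45, 0.8), each = 100),
                             dim = c(10, 30, 3)))
  mv <- compute_metric_vector(gray, target_h = 10)
  expect_true(mv$grayscale)
  expect_lt(mv$mean_pixelwise_dist, 0.005)
  expect_equal(mv$max_ratio, 0)
  expect_equal(mv$high_ratio_count, 0)
  expect_equal(mv$high_ratio_pixel_prop, 0)
  expect_true(is.na(mv$mean_spatial_dist))
})

test_that("moving confusable blocks apart increases spatial distance only", {
  near <- two_block_image(red_green$a, red_green$b, w = 60, h = 20,
                          block_w = 10, gap = 0)
  far <- two_block_image(red_green$a, red_green$b, w = 60, h = 20,
                         block_w = 10, gap = 30)
  mv_near <- compute_metric_vector(near, target_h = 20, cap = Inf)
  mv_far <- compute_metric_vector(far, target_h = 20, cap = Inf)
  expect_gt(mv_far$mean_spatial_dist, mv_near$mean_spatial_dist)
  # translation-invariant metrics unchanged by the layout shift
  expect_equal(mv_far$mean_pixelwise_dist, mv_near$mean_pixelwise_dist)
  expect_equal(mv_far$max_ratio, mv_near$max_ratio)
  expect_equal(mv_far$high_ratio_count, mv_near$high_ratio_count)
  expect_equal(mv_far$high_ratio_pixel_prop, mv_near$high_ratio_pixel_prop)
})

test_that("high_ratio metrics are monotone in the threshold", {
  img <- random_small_image(10, 10, 6, seed = 33)
  q <- quantize(img)
  s <- simulate_quantized(q)
  pairs <- enumerate_pairs(q, s)
  thresholds <- c(10, 5, 2, 1, 0.5)
  counts <- vapply(thresholds, function(t) high_ratio_count(pairs, t),
                   numeric(1))
  props <- vapply(thresholds, function(t) {
    high_ratio_pixel_proportion(q, pairs, t)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(diff(props) >= 0))
})

test_that("rank_based_scores matches brute-force ranking with ties and NAs", {
  set.seed(77)
  for (rep in 1:3) {
    n <- 50
    metrics <- data.frame(
      mean_pixelwise_dist = round(runif(n), 2),   # rounding forces ties
      max_ratio = sample(c(0, 2, 6, 9), n, replace = TRUE),
      high_ratio_count = sample(0:3, n, replace = TRUE),
      high_ratio_pixel_prop = round(runif(n), 1),
      mean_spatial_dist = ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 100))))
    rs <- rank_based_scores(metrics)
    expect_equal(rs$combined, bf_rank_scores(metrics))
    expect_true(all(rs[, 1:5] >= 1 & rs[, 1:5] <= n))
  }
})

test_that("combined rank scores are permutation-invariant", {
  set.seed(5)
  metrics <- data.frame(
    mean_pixelwise_dist = runif(20), max_ratio = runif(20, 0, 10),
    high_ratio_count = sample(0:4, 20, TRUE),
    high_ratio_pixel_prop = runif(20),
    mean_spatial_dist = ifelse(runif(20) < 0.2, NA, runif(20, 0, 80)))
  perm <- sample(20)
  rs <- rank_based_scores(metrics)
  rs_p <- rank_based_scores(metrics[perm, ])
  expect_equal(rs_p$combined, rs$combined[perm])
  expect_equal(rank_based_scores(metrics[rep(1, 5), ])$combined,
               rep(3, 5))   # identical vectors tie at the average rank
  expect_error(rank_based_scores(metrics[0, ]), "empty")
})
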