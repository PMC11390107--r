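# The five per-image color-accessibility metrics and the corpus-level
# rank-based combined score.
#
# "Original" below always means the resized, quantized image; "simulated"
# means the same image after deuteranopia simulation applied palette-wise
# (so palettes correspond positionally).

metric_columns <- c("mean_pixelwise_dist", "max_ratio", "high_ratio_count",
                    "high_ratio_pixel_prop", "mean_spatial_dist", "grayscale")

#' Simulate deuteranopia on a quantized image
#'
#' The simulation matrix is applied to the palette only; the index map is
#' shared, so palette entry i of the result is the simulated version of
#' palette entry i of the input.
#'
#' @param q A `quantized_image`.
#' @inheritParams simulate_deutan
#' @return A `quantized_image` with simulated palette.
#' @export
simulate_quantized <- function(q, severity = 0.8, linear_rgb = FALSE) {
  q$palette <- simulate_deutan(q$palette, severity, linear_rgb)
  q
}

#' Mean pixel-wise color distance between original and simulated image
#'
#' The CIEDE2000 difference between each pixel and its simulated counterpart,
#' averaged over all pixels and divided by 100 so values live on a 0-1-ish
#' scale. Grayscale images score ~0 because the simulation fixes achromatic
#' colors.
#'
#' @param orig,sim `quantized_image`s with positionally corresponding
#'   palettes (see [simulate_quantized()]).
#' @return Non-negative scalar.
#' @export
mean_pixelwise_distance <- function(orig, sim) {
  if (orig$width != sim$width || orig$height != sim$height) {
    stop("original and simulated images must have the same dimensions",
         call. = FALSE)
  }
  d <- delta_e2000(srgb_to_lab(orig$palette), srgb_to_lab(sim$palette))
  sum(d * orig$counts) / sum(orig$counts) / 100
}

#' Enumerate chromatic color pairs with original/simulated distances
#'
#' Black, white, and gray palette entries are excluded; every unordered pair
#' of the remaining colors is scored with its CIEDE2000 distance in the
#' original palette, in the simulated palette, and the ratio of the two. The
#' simulated distance is floored at `eps` before division and the ratio is
#' capped at 1e6.
#'
#' @param orig,sim `quantized_image`s with positionally corresponding
#'   palettes.
#' @param spread_tol Achromatic channel-spread tolerance in 8-bit units.
#' @param eps Floor for the simulated distance (default 1e-6).
#' @return A data.frame with one row per pair: `ia`, `ib` (palette indices,
#'   ia < ib), `dist_orig`, `dist_sim`, `ratio`. Zero rows when fewer than
#'   two chromatic colors exist.
#' @export
enumerate_pairs <- function(orig, sim, spread_tol = 10, eps = 1e-6) {
  chrom <- which(!is_achromatic(orig$palette, spread_tol))
  empty <- data.frame(ia = integer(), ib = integer(), dist_orig = numeric(),
                      dist_sim = numeric(), ratio = numeric())
  if (length(chrom) < 2) return(empty)
  pr <- utils::combn(chrom, 2)
  lab_o <- srgb_to_lab(orig$palette)
  lab_s <- srgb_to_lab(sim$palette)
  d_o <- delta_e2000(lab_o[pr[1, ], , drop = FALSE],
                     lab_o[pr[2, ], , drop = FALSE])
  d_s <- delta_e2000(lab_s[pr[1, ], , drop = FALSE],
                     lab_s[pr[2, ], , drop = FALSE])
  ratio <- pmin(d_o / pmax(d_s, eps), 1e6)
  data.frame(ia = pr[1, ], ib = pr[2, ], dist_orig = d_o, dist_sim = d_s,
             ratio = ratio)
}

#' Ratio for the color pair with the largest original distance
#'
#' Selects the pair with the largest distance in the original image (the
#' highest-contrast pair for normal trichromats) and reports its
#' original-to-simulated distance ratio; 0 when no chromatic pairs exist.
#'
#' @param pairs Output of [enumerate_pairs()].
#' @return Non-negative scalar.
#' @export
max_ratio <- function(pairs) {
  if (nrow(pairs) == 0) return(0)
  pairs$ratio[which.max(pairs$dist_orig)]
}

#' Number of high-ratio color pairs
#'
#' @param pairs Output of [enumerate_pairs()].
#' @param threshold Ratio threshold; pairs with ratio strictly greater count
#'   (default 5).
#' @return Non-negative integer.
#' @export
high_ratio_count <- function(pairs, threshold = 5) {
  sum(pairs$ratio > threshold)
}

#' Proportion of pixels using a color from any high-ratio pair
#'
#' @param q The original `quantized_image`.
#' @param pairs Output of [enumerate_pairs()] for `q`.
#' @param threshold Ratio threshold (default 5, strict).
#' @return Real in \[0, 1\].
#' @export
high_ratio_pixel_proportion <- function(q, pairs, threshold = 5) {
  hi <- pairs[pairs$ratio > threshold, , drop = FALSE]
  if (nrow(hi) == 0) return(0)
  cols <- unique(c(hi$ia, hi$ib))
  sum(q$counts[cols]) / sum(q$counts)
}

# Mean Euclidean distance between all pixels of palette color a and all of
# color b; subsampled to `cap` cross pairs when the full cross product is
# larger. Positions are (col, row) in pixels of the resized image.
.pair_spatial_mean <- function(idx, a, b, cap) {
  pa <- which(idx == a)
  pb <- which(idx == b)
  h <- nrow(idx)
  ax <- ((pa - 1) %/% h) + 1; ay <- ((pa - 1) %% h) + 1
  bx <- ((pb - 1) %/% h) + 1; by <- ((pb - 1) %% h) + 1
  n <- length(pa) * length(pb)
  if (is.finite(cap) && n > cap) {
    k <- sample.int(n, cap)  # uniform over the cross product
    ia <- ((k - 1) %% length(pa)) + 1
    ib <- ((k - 1) %/% length(pa)) + 1
    mean(sqrt((ax[ia] - bx[ib])^2 + (ay[ia] - by[ib])^2))
  } else {
    mean(sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2))
  }
}

#' Mean spatial distance between pixels of high-ratio color pairs
#'
#' For each high-ratio pair, the Euclidean distance (in pixels of the resized
#' image) between every pixel of one color and every pixel of the other is
#' averaged; the metric is the unweighted mean of these per-pair means.
#' Confusable colors that sit close together are more likely to cause
#' problems than distant ones, so small values are worse. When a pair's
#' cross-product of pixels exceeds `cap`, a seeded uniform subsample of `cap`
#' cross pairs is used.
#'
#' @param q The original `quantized_image`.
#' @param pairs Output of [enumerate_pairs()] for `q`.
#' @param threshold Ratio threshold (default 5, strict).
#' @param cap Subsampling cap on cross pairs per color pair (default 1e5;
#'   `Inf` for exact).
#' @param seed Integer seed for the subsample.
#' @param pool If `TRUE`, pool all cross pairs across color pairs instead of
#'   averaging per-pair means.
#' @return Scalar, or `NA_real_` when no high-ratio pairs exist (an undefined
#'   marker, not zero: zero would falsely signal maximal proximity).
#' @export
mean_spatial_distance <- function(q, pairs, threshold = 5, cap = 1e5,
                                  seed = 1L, pool = FALSE) {
  hi <- pairs[pairs$ratio > threshold, , drop = FALSE]
  if (nrow(hi) == 0) return(NA_real_)
  vals <- with_local_seed(seed, {
    mapply(function(a, b) {
      m <- .pair_spatial_mean(q$index, a, b, cap)
      w <- q$counts[a] * q$counts[b]
      c(m, w)
    }, hi$ia, hi$ib)
  })
  if (pool) {
    sum(vals[1, ] * vals[2, ]) / sum(vals[2, ])
  } else {
    mean(vals[1, ])
  }
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Compute the full metric vector for one image
#'
#' Runs the screening pipeline on a decoded image: resize to a standard
#' height, quantize to a bounded palette, simulate deuteranopia palette-wise,
#' then compute the five metrics plus the grayscale flag.
#'
#' @param img A `raster_image`.
#' @param severity Simulation severity (default 0.8, moderate-to-severe
#'   deuteranopia).
#' @param target_h Standard height in pixels (default 300).
#' @param max_colors Palette bound (default 256).
#' @param spread_tol Achromatic tolerance, 8-bit units (default 10).
#' @param ratio_threshold High-ratio threshold (default 5, strict).
#' @param eps Simulated-distance floor (default 1e-6).
#' @param cap,seed Spatial-distance subsampling controls.
#' @return A one-row data.frame with columns `mean_pixelwise_dist`,
#'   `max_ratio`, `high_ratio_count`, `high_ratio_pixel_prop`,
#'   `mean_spatial_dist` (`NA` when no high-ratio pairs), `grayscale`.
#' @export
#' @examples
#' fx <- make_fixture(fixture_spec("confusable_blocks"))
#' compute_metric_vector(fx$image)
compute_metric_vector <- function(img, severity = 0.8, target_h = 300,
                                  max_colors = 256, spread_tol = 10,
                                  ratio_threshold = 5, eps = 1e-6,
                                  cap = 1e5, seed = 1L) {
  q <- quantize(resize_to_height(img, target_h), max_colors)
  s <- simulate_quantized(q, severity)
  pairs <- enumerate_pairs(q, s, spread_tol, eps)
  data.frame(
    mean_pixelwise_dist = mean_pixelwise_distance(q, s),
    max_ratio = max_ratio(pairs),
    high_ratio_count = high_ratio_count(pairs, ratio_threshold),
    high_ratio_pixel_prop = high_ratio_pixel_proportion(q, pairs,
                                                        ratio_threshold),
    mean_spatial_dist = mean_spatial_distance(q, pairs, ratio_threshold,
                                              cap, seed),
    grayscale = detect_grayscale(q, spread_tol))
}

#' Rank-based combined accessibility score for a corpus
#'
#' Each image is ranked per metric with rank 1 = most problematic: for the
#' four metrics where larger is worse, the largest value gets rank 1; for the
#' mean spatial distance, the smallest value gets rank 1 (confusable colors
#' close together are worse) and undefined values rank as least problematic.
#' Ties receive the average of the tied ranks. The combined score is the
#' arithmetic mean of the five ranks; smaller combined scores flag images
#' for review first.
#'
#' @param metrics A data.frame with the five metric columns (one row per
#'   image), e.g. row-bound outputs of [compute_metric_vector()].
#' @return A data.frame with the five per-metric ranks (`rank_` prefix) and
#'   `combined`.
#' @export
rank_based_scores <- function(metrics) {
  if (nrow(metrics) == 0) stop("corpus is empty", call. = FALSE)
  desc_rank <- function(x) rank(-x, ties.method = "average")
  spatial <- metrics$mean_spatial_dist
  spatial[is.na(spatial)] <- Inf
  out <- data.frame(
    rank_mean_pixelwise_dist = desc_rank(metrics$mean_pixelwise_dist),
    rank_max_ratio = desc_rank(metrics$max_ratio),
    rank_high_ratio_count = desc_rank(metrics$high_ratio_count),
    rank_high_ratio_pixel_prop = desc_rank(metrics$high_ratio_pixel_prop),
    rank_mean_spatial_dist = rank(spatial, ties.method = "average"))
  out$combined <- rowMeans(out)
  out
}
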