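# Deterministic synthetic fixtures with certified chromatic structure.
#
# Fixtures stand in for real scientific figures: solid color blocks with
# controllable palette and spacing. Every fixture is certified at generation
# time by recomputing the metric facts it promises (confusability is a
# property of the simulated color geometry, not of color names, so the
# promises are checked, never assumed).

# Color pairs verified to have original/simulated CIEDE2000 ratio > 5 at
# severity 0.8 (red/green/orange family, the classic deutan confusion axis).
.confusable_pairs <- list(
  rbind(c(253, 120, 44), c(150, 155, 36)) / 255,
  rbind(c(252, 115, 43), c(80, 178, 20)) / 255,
  rbind(c(253, 211, 50), c(135, 249, 6)) / 255,
  rbind(c(236, 135, 34), c(162, 164, 6)) / 255,
  rbind(c(251, 179, 62), c(159, 218, 19)) / 255)

# Pairs verified to keep ratio well below 5 (contrast survives simulation).
.friendly_pairs <- list(
  rbind(c(30, 90, 200), c(235, 140, 30)) / 255,
  rbind(c(40, 80, 190), c(240, 220, 60)) / 255,
  rbind(c(120, 60, 170), c(230, 200, 60)) / 255)

#' Specify a synthetic fixture
#'
#' @param kind One of `"grayscale"`, `"confusable_blocks"`,
#'   `"friendly_blocks"`, `"labeled_blocks"`, `"gradient"`.
#' @param width,height Image dimensions in pixels.
#' @param palette A 2 x 3 sRGB matrix for block kinds (defaults to a
#'   verified pair for the kind), or a vector of gray levels for
#'   `"grayscale"`.
#' @param gap Columns of neutral gray separating the two blocks (block
#'   kinds; 0 = adjacent).
#' @param seed Integer seed (reserved for randomized layouts).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("grayscale", "confusable_blocks",
                                  "friendly_blocks", "labeled_blocks",
                                  "gradient"),
                         width = 100, height = 300, palette = NULL,
                         gap = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(width >= 4, height >= 4, gap >= 0, gap <= width - 2)
  if (is.null(palette)) {
    palette <- switch(kind,
                      grayscale = c(0.15, 0.5, 0.85),
                      confusable_blocks = ,
                      labeled_blocks = .confusable_pairs[[1]],
                      friendly_blocks = .friendly_pairs[[1]],
                      gradient = NULL)
  }
  structure(list(kind = kind, width = width, height = height,
                 palette = palette, gap = gap, seed = as.integer(seed)),
            class = "fixture_spec")
}

.render_blocks <- function(spec, labeled = FALSE) {
  w <- spec$width; h <- spec$height; gap <- spec$gap
  px <- array(0.5, dim = c(h, w, 3))  # neutral gray background
  bw <- (w - gap) %/% 2
  for (k in 1:3) {
    px[, seq_len(bw), k] <- spec$palette[1, k]
    px[, (w - bw + 1):w, k] <- spec$palette[2, k]
  }
  if (labeled) {  # black annotation bars atop each block
    bar <- seq_len(max(2, h %/% 20))
    px[bar, seq_len(bw), ] <- 0
    px[bar, (w - bw + 1):w, ] <- 0
  }
  px
}

.render_fixture <- function(spec) {
  px <- switch(spec$kind,
    grayscale = {
      g <- rep(spec$palette, length.out = spec$width)
      stripes <- matrix(rep(g, each = spec$height), spec$height, spec$width)
      array(rep(stripes, 3), dim = c(spec$height, spec$width, 3))
    },
    confusable_blocks = .render_blocks(spec),
    friendly_blocks = .render_blocks(spec),
    labeled_blocks = .render_blocks(spec, labeled = TRUE),
    gradient = {
      ramp <- seq(0, 1, length.out = spec$width)
      px <- array(0, dim = c(spec$height, spec$width, 3))
      px[, , 1] <- matrix(rep(ramp, each = spec$height), spec$height)
      px[, , 2] <- 0.5
      px[, , 3] <- matrix(rep(rev(ramp), each = spec$height), spec$height)
      px
    })
  raster_image(px, source_id = sprintf("fixture:%s", spec$kind))
}

#' Generate a certified fixture
#'
#' Renders the image described by `spec`, recomputes its metric facts with
#' the screening pipeline, and refuses to return a fixture whose certificate
#' does not hold (e.g. a "friendly" palette that is actually confusable).
#'
#' @param spec A [fixture_spec()].
#' @param severity Simulation severity used for certification (default 0.8).
#' @return A `certified_fixture`: `image` (a `raster_image`), `label` (a
#'   review label string), `certificate` (named list of checked facts), and
#'   the originating `spec`.
#' @export
make_fixture <- function(spec, severity = 0.8) {
  stopifnot(inherits(spec, "fixture_spec"))
  img <- .render_fixture(spec)
  mv <- compute_metric_vector(img, severity = severity,
                              target_h = spec$height)
  cert <- switch(spec$kind,
    grayscale = {
      if (!mv$grayscale) stop("fixture certificate failed: image not ",
                              "detected as grayscale", call. = FALSE)
      list(grayscale = TRUE)
    },
    confusable_blocks = ,
    labeled_blocks = {
      if (mv$high_ratio_count < 1) {
        stop("fixture certificate failed: palette has no high-ratio pair ",
             "at severity ", severity, call. = FALSE)
      }
      list(high_ratio_count = mv$high_ratio_count,
           high_ratio_pixel_prop = mv$high_ratio_pixel_prop,
           mean_spatial_dist = mv$mean_spatial_dist)
    },
    friendly_blocks = {
      if (mv$high_ratio_count != 0) {
        stop("fixture certificate failed: 'friendly' palette has ",
             mv$high_ratio_count, " high-ratio pair(s)", call. = FALSE)
      }
      list(high_ratio_count = 0)
    },
    gradient = list())
  label <- switch(spec$kind,
                  grayscale = "grayscale",
                  confusable_blocks = "definitely_problematic",
                  labeled_blocks = "definitely_problematic",
                  friendly_blocks = "definitely_okay",
                  gradient = "definitely_okay")
  structure(list(image = img, label = label, certificate = cert,
                 metrics = mv, spec = spec),
            class = "certified_fixture")
}

#' Generate a labeled corpus of certified fixtures
#'
#' Produces exactly `round(n * problem_fraction)` problematic fixtures
#' (confusable palettes, adjacent blocks) and fills the rest with friendly
#' or grayscale fixtures, emulating the class imbalance of a manually
#' reviewed figure corpus. Deterministic given `seed`.
#'
#' @param n Corpus size (>= 20).
#' @param problem_fraction Fraction of problematic images in (0, 1).
#' @param seed Integer seed.
#' @param width,height Fixture dimensions.
#' @return A list of `certified_fixture` objects, shuffled deterministically.
#' @export
make_labeled_corpus <- function(n, problem_fraction = 0.1, seed = 1L,
                                width = 100, height = 300) {
  stopifnot(n >= 20, problem_fraction > 0, problem_fraction < 1)
  n_prob <- round(n * problem_fraction)
  if (n_prob < 1 || n_prob >= n) stop("infeasible label counts", call. = FALSE)
  with_local_seed(seed, {
    fixtures <- vector("list", n)
    for (i in seq_len(n_prob)) {
      pal <- .confusable_pairs[[(i - 1) %% length(.confusable_pairs) + 1]]
      sp <- fixture_spec("confusable_blocks", width = width, height = height,
                         palette = pal, gap = 0, seed = seed + i)
      fixtures[[i]] <- make_fixture(sp)
      fixtures[[i]]$image$source_id <- sprintf("corpus_%04d_problematic", i)
    }
    for (i in (n_prob + 1):n) {
      j <- i - n_prob
      if (j %% 4 == 0) {
        sp <- fixture_spec("grayscale", width = width, height = height,
                           seed = seed + i)
      } else {
        pal <- .friendly_pairs[[(j - 1) %% length(.friendly_pairs) + 1]]
        sp <- fixture_spec("friendly_blocks", width = width, height = height,
                           palette = pal, gap = 0, seed = seed + i)
      }
      fixtures[[i]] <- make_fixture(sp)
      fixtures[[i]]$label <- "definitely_okay"   # grayscale is safe by definition
      fixtures[[i]]$image$source_id <- sprintf("corpus_%04d_okay", i)
    }
    fixtures[sample.int(n)]
  })
}

#' Write a corpus of fixtures to disk with a manifest
#'
#' @param fixtures List of `certified_fixture` objects.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV (columns: path, label, plus certificate
#'   summary columns), invisibly.
#' @export
write_corpus <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(fixtures, function(fx) {
    fname <- paste0(fx$image$source_id, ".png")
    write_png(fx$image, file.path(dir, fname))
    data.frame(path = fname, label = fx$label,
               high_ratio_count = fx$metrics$high_ratio_count,
               grayscale = fx$metrics$grayscale)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
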