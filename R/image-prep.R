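# Image preparation: decoding, alpha compositing, resizing, median-cut
# quantization, and grayscale screening.

#' Construct a raster image
#'
#' @param pixels Numeric array of dim c(height, width, 3), sRGB in \[0, 1\].
#' @param source_id Opaque provenance string (defaults to "<memory>").
#' @return A `raster_image` object.
#' @export
raster_image <- function(pixels, source_id = "<memory>") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (any(pixels < 0 | pixels > 1)) stop("pixel values must lie in [0, 1]",
                                         call. = FALSE)
  structure(list(pixels = pixels, source_id = source_id),
            class = "raster_image")
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

image_width <- function(img) dim(img$pixels)[2]
image_height <- function(img) dim(img$pixels)[1]

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %dx%d  %s>\n", d[2], d[1], x$source_id))
  invisible(x)
}

#' Load a PNG or JPEG image as sRGB
#'
#' Grayscale images are expanded to three channels; an alpha channel, if
#' present, is composited over a white background (journal figures render on
#' white).
#'
#' @param path Path to a `.png`, `.jpg`, or `.jpeg` file.
#' @return A `raster_image` with `source_id` set to the path.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           stop("unsupported image format '", ext, "': ", path,
                call. = FALSE)),
    error = function(e) stop("failed to decode ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (is.matrix(raw)) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  nc <- dim(raw)[3]
  if (nc == 2) {  # gray + alpha
    gray <- raw[, , 1]
    raw <- array(c(rep(gray, 3), raw[, , 2]), dim = c(dim(gray), 4))
    nc <- 4
  }
  if (nc == 4) {
    a <- raw[, , 4]
    rgb <- raw[, , 1:3, drop = FALSE]
    for (k in 1:3) rgb[, , k] <- rgb[, , k] * a + (1 - a)
    raw <- rgb
  }
  raster_image(raw[, , 1:3, drop = FALSE], source_id = path)
}

#' Write a raster image as PNG
#'
#' @param img A `raster_image`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  png::writePNG(img$pixels, target = path)
  invisible(path)
}

# Bilinear resampling to an arbitrary size. Sample positions use the
# half-pixel convention so up- and down-scaling stay centered.
.resize_bilinear <- function(px, out_h, out_w) {
  in_h <- dim(px)[1]; in_w <- dim(px)[2]
  ys <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), in_h - 1)
  x0 <- pmin(pmax(floor(xs), 0), in_w - 1)
  y1 <- pmin(y0 + 1, in_h - 1)
  x1 <- pmin(x0 + 1, in_w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1)
  wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, 3))
  for (k in 1:3) {
    ch <- px[, , k]
    top <- ch[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx) +
      ch[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx)
    bot <- ch[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx) +
      ch[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
    out[, , k] <- top + bot
  }
  out
}

#' Resize an image to a fixed height, preserving aspect ratio
#'
#' Standardizing the height makes spatial-distance metrics comparable across
#' a corpus and bounds the cost of quantization. Bilinear resampling;
#' upscaling is permitted.
#'
#' @param img A `raster_image`.
#' @param target_h Output height in pixels (default 300).
#' @return A `raster_image` of height `target_h` and proportional width.
#' @export
resize_to_height <- function(img, target_h = 300) {
  stopifnot(inherits(img, "raster_image"), target_h >= 1)
  h <- image_height(img); w <- image_width(img)
  if (h == target_h) return(img)
  out_w <- max(1L, as.integer(round(w * target_h / h)))
  img$pixels <- .resize_bilinear(img$pixels, as.integer(target_h), out_w)
  img
}

#' Resize an image to an exact width x height
#'
#' Used for classifier input where both dimensions are standardized (aspect
#' ratio is not preserved).
#'
#' @param img A `raster_image`.
#' @param size Output side length in pixels.
#' @return A `raster_image` of dimensions `size` x `size`.
#' @export
resize_to_square <- function(img, size) {
  stopifnot(inherits(img, "raster_image"), size >= 1)
  img$pixels <- .resize_bilinear(img$pixels, as.integer(size),
                                 as.integer(size))
  img
}

#' Quantize an image to at most `max_colors` colors (median cut)
#'
#' Deterministic median-cut without dithering: colors are binned in 8-bit
#' space, the box with the largest single-channel range is split at its
#' weighted median (range ties broken in R > G > B channel order, box ties by
#' creation order), and each final box is represented by its pixel-weighted
#' mean color. If the image already has at most `max_colors` distinct 8-bit
#' colors, the palette is exactly those colors.
#'
#' @param img A `raster_image`.
#' @param max_colors Palette size bound (default 256; must be >= 2).
#' @return A `quantized_image`: `palette` (K x 3 matrix, \[0, 1\] sRGB),
#'   `index` (height x width integer matrix of 1-based palette indices),
#'   `counts` (pixels per palette entry), plus dimensions and `source_id`.
#' @export
quantize <- function(img, max_colors = 256) {
  stopifnot(inherits(img, "raster_image"))
  if (max_colors < 2) stop("`max_colors` must be at least 2", call. = FALSE)
  h <- image_height(img); w <- image_width(img)
  flat <- round(matrix(img$pixels, ncol = 3) * 255)  # n x 3 in 0..255
  code <- flat[, 1] * 65536 + flat[, 2] * 256 + flat[, 3]
  tab <- sort(unique(code))
  pix_u <- match(code, tab)                  # pixel -> unique-color row
  ucols <- cbind(tab %/% 65536, (tab %/% 256) %% 256, tab %% 256)
  ucnt <- tabulate(pix_u, nbins = length(tab))

  if (length(tab) <= max_colors) {
    pal_u <- seq_along(tab)                  # identity: exact palette
    assign_u <- seq_along(tab)
    pal <- ucols
  } else {
    boxes <- list(seq_along(tab))            # member unique-color rows
    repeat {
      if (length(boxes) >= max_colors) break
      ranges <- vapply(boxes, function(m) {
        if (length(m) < 2) return(-1)
        max(apply(ucols[m, , drop = FALSE], 2, function(v) max(v) - min(v)))
      }, numeric(1))
      if (all(ranges <= 0)) break
      bi <- which.max(ranges)                # first max: deterministic
      m <- boxes[[bi]]
      sub <- ucols[m, , drop = FALSE]
      ch <- which.max(apply(sub, 2, function(v) max(v) - min(v)))  # R>G>B
      ord <- order(sub[, ch], tab[m])        # stable: code as tiebreak
      m <- m[ord]
      cs <- cumsum(ucnt[m])
      half <- cs[length(cs)] / 2
      cut <- which(cs >= half)[1]
      if (cut >= length(m)) cut <- length(m) - 1
      boxes[[bi]] <- m[seq_len(cut)]
      boxes[[length(boxes) + 1]] <- m[(cut + 1):length(m)]
    }
    pal <- t(vapply(boxes, function(m) {
      round(colSums(ucols[m, , drop = FALSE] * ucnt[m]) / sum(ucnt[m]))
    }, numeric(3)))
    assign_u <- integer(length(tab))
    for (i in seq_along(boxes)) assign_u[boxes[[i]]] <- i
    # merging boxes whose means round to the same 8-bit color keeps palette
    # entries pairwise distinct
    pcode <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
    keep <- !duplicated(pcode)
    remap <- match(pcode, pcode[keep])
    pal <- pal[keep, , drop = FALSE]
    assign_u <- remap[assign_u]
  }

  idx <- matrix(assign_u[pix_u], nrow = h, ncol = w)
  counts <- tabulate(idx, nbins = nrow(pal))
  structure(list(palette = pal / 255,
                 index = idx,
                 counts = counts,
                 width = w, height = h,
                 source_id = img$source_id),
            class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image %dx%d, %d colors  %s>\n",
              x$width, x$height, nrow(x$palette), x$source_id))
  invisible(x)
}

#' Reconstruct a raster image from a quantized image
#'
#' @param q A `quantized_image`.
#' @return A `raster_image` where each pixel carries its palette color.
#' @export
unquantize <- function(q) {
  px <- array(0, dim = c(q$height, q$width, 3))
  for (k in 1:3) px[, , k] <- matrix(q$palette[q$index, k],
                                     q$height, q$width)
  raster_image(px, source_id = q$source_id)
}

#' Is a quantized image grayscale?
#'
#' True when every palette color is achromatic at the given channel-spread
#' tolerance. Screening on the quantized palette (rather than raw pixels)
#' keeps JPEG chroma noise from defeating the test.
#'
#' @param q A `quantized_image`.
#' @param spread_tol 8-bit channel-spread tolerance (default 10).
#' @return Logical flag.
#' @export
detect_grayscale <- function(q, spread_tol = 10) {
  all(is_achromatic(q$palette, spread_tol))
}
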