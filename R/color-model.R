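# Color model: sRGB <-> Lab conversion, the CIEDE2000 color difference, and
# severity-parameterized deuteranomaly simulation matrices.
#
# All color arguments are numeric matrices with one row per color and three
# columns (R, G, B in [0, 1], gamma-encoded sRGB; or L, a, b for Lab).
# Single colors may be given as length-3 vectors.

# Published deuteranomaly simulation matrices at severities 0, 0.1, ..., 1
# (shift-theory model of anomalous M-cone sensitivity). Row-stochastic, so
# grays are fixed points at every severity.
.deutan_table <- local({
  vals <- list(
    c(1, 0, 0, 0, 1, 0, 0, 0, 1),
    c(0.866435, 0.177704, -0.044139, 0.049567, 0.939063, 0.011370,
      -0.003453, 0.007233, 0.996220),
    c(0.760729, 0.319078, -0.079807, 0.090568, 0.889315, 0.020117,
      -0.006027, 0.013325, 0.992702),
    c(0.675425, 0.433850, -0.109275, 0.125303, 0.847755, 0.026942,
      -0.007950, 0.018572, 0.989378),
    c(0.605511, 0.528560, -0.134071, 0.155318, 0.812366, 0.032316,
      -0.009376, 0.023176, 0.986200),
    c(0.547494, 0.607765, -0.155259, 0.181692, 0.781742, 0.036566,
      -0.010410, 0.027275, 0.983136),
    c(0.498864, 0.674741, -0.173604, 0.205199, 0.754872, 0.039929,
      -0.011131, 0.030969, 0.980162),
    c(0.457771, 0.731899, -0.189670, 0.226409, 0.731012, 0.042579,
      -0.011595, 0.034333, 0.977261),
    c(0.422823, 0.781057, -0.203881, 0.245752, 0.709602, 0.044646,
      -0.011843, 0.037423, 0.974421),
    c(0.392952, 0.823610, -0.216562, 0.263559, 0.690210, 0.046232,
      -0.011910, 0.040281, 0.971630),
    c(0.367322, 0.860646, -0.227968, 0.280085, 0.672501, 0.047413,
      -0.011820, 0.042940, 0.968881))
  lapply(vals, function(v) matrix(v, 3, 3, byrow = TRUE))
})

.as_color_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  stopifnot(ncol(x) == 3)
  x
}

#' Deuteranomaly simulation matrix at a given severity
#'
#' Returns the 3x3 linear transform that maps sRGB colors to their
#' deuteranomalous appearance. Severity 0 is the identity (normal trichromacy),
#' severity 1 full deuteranopia; severities between the published 0.1 steps are
#' linearly interpolated between the two adjacent matrices.
#'
#' @param severity Real in \[0, 1\].
#' @return A 3x3 numeric matrix whose rows each sum to 1, so achromatic colors
#'   are preserved.
#' @export
#' @examples
#' deutan_matrix(0)       # identity
#' deutan_matrix(0.8)     # the default screening severity
deutan_matrix <- function(severity) {
  if (!is.numeric(severity) || length(severity) != 1 || is.na(severity) ||
      severity < 0 || severity > 1) {
    stop("`severity` must be a single number in [0, 1]", call. = FALSE)
  }
  pos <- severity * 10
  lo <- floor(pos)
  hi <- ceiling(pos)
  if (lo == hi) return(.deutan_table[[lo + 1]])
  w <- pos - lo
  (1 - w) * .deutan_table[[lo + 1]] + w * .deutan_table[[hi + 1]]
}

#' Simulate deuteranopia on an image or color matrix
#'
#' Applies the severity-interpolated deuteranomaly matrix per pixel. By
#' default the matrix is applied to gamma-encoded sRGB values, matching the
#' behavior of the simulation tooling this pipeline is calibrated against;
#' `linear_rgb = TRUE` applies it in linearized RGB instead. Out-of-gamut
#' results are clipped to \[0, 1\].
#'
#' @param img A `raster_image` (see [load_image()]) or an n x 3 color matrix.
#' @param severity Real in \[0, 1\]; default 0.8.
#' @param linear_rgb Apply the matrix in linear RGB rather than gamma-encoded.
#' @return An object of the same kind as `img`, same dimensions.
#' @export
simulate_deutan <- function(img, severity = 0.8, linear_rgb = FALSE) {
  if (inherits(img, "raster_image")) {
    px <- img$pixels
    if (length(px) == 0) stop("cannot simulate an empty image", call. = FALSE)
    flat <- matrix(px, ncol = 3)
    out <- simulate_deutan(flat, severity, linear_rgb)
    img$pixels <- array(out, dim = dim(px))
    return(img)
  }
  m <- deutan_matrix(severity)
  x <- .as_color_matrix(img)
  if (linear_rgb) {
    out <- .srgb_delinearize(.srgb_linearize(x) %*% t(m))
  } else {
    out <- x %*% t(m)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

.srgb_linearize <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

.srgb_delinearize <- function(x) {
  x[x < 0] <- 0
  ifelse(x <= 0.0031308, x * 12.92, 1.055 * x^(1 / 2.4) - 0.055)
}

# sRGB (D65) -> XYZ, 2 degree observer
.rgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                     0.2126729, 0.7151522, 0.0721750,
                     0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
.d65 <- c(0.950470, 1.000000, 1.088830)

#' Convert gamma-encoded sRGB to CIE L*a*b*
#'
#' Uses the D65 white point and 2 degree observer: channels are linearized,
#' mapped to XYZ, then to Lab.
#'
#' @param rgb An n x 3 matrix (or length-3 vector) of sRGB values in \[0, 1\].
#' @return An n x 3 matrix with columns L (0-100), a, b.
#' @export
srgb_to_lab <- function(rgb) {
  x <- .as_color_matrix(rgb)
  xyz <- .srgb_linearize(x) %*% t(.rgb2xyz)
  xyz <- sweep(xyz, 2, .d65, "/")
  eps <- 216 / 24389
  kap <- 24389 / 27
  f <- ifelse(xyz > eps, xyz^(1 / 3), (kap * xyz + 16) / 116)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' CIEDE2000 color difference
#'
#' The CIE 2000 color-difference formula on L*a*b* coordinates, with the
#' parametric weights kL = kC = kH = 1. Symmetric in its arguments and zero
#' exactly for identical colors; note CIEDE2000 does not satisfy the triangle
#' inequality, so it is a difference, not a metric.
#'
#' @param lab1,lab2 n x 3 Lab matrices (or length-3 vectors); rows are paired.
#' @return Numeric vector of non-negative differences.
#' @export
#' @examples
#' delta_e2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))  # 2.0425
delta_e2000 <- function(lab1, lab2) {
  x <- .as_color_matrix(lab1)
  y <- .as_color_matrix(lab2)
  if (nrow(x) == 1 && nrow(y) > 1) x <- x[rep(1, nrow(y)), , drop = FALSE]
  if (nrow(y) == 1 && nrow(x) > 1) y <- y[rep(1, nrow(x)), , drop = FALSE]
  stopifnot(nrow(x) == nrow(y))

  L1 <- x[, 1]; a1 <- x[, 2]; b1 <- x[, 3]
  L2 <- y[, 1]; a2 <- y[, 2]; b2 <- y[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  h1p <- atan2(b1, a1p) %% (2 * pi)
  h2p <- atan2(b2, a2p) %% (2 * pi)
  h1p[C1p == 0] <- 0
  h2p[C2p == 0] <- 0

  dLp <- L2 - L1
  dCp <- C2p - C1p

  dhp <- h2p - h1p
  dhp <- ifelse(dhp > pi, dhp - 2 * pi, ifelse(dhp < -pi, dhp + 2 * pi, dhp))
  dhp[C1p * C2p == 0] <- 0
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2

  hsum <- h1p + h2p
  hbp <- ifelse(abs(h1p - h2p) <= pi, hsum / 2,
                ifelse(hsum < 2 * pi, hsum / 2 + pi, hsum / 2 - pi))
  hbp[C1p * C2p == 0] <- hsum[C1p * C2p == 0]

  Tt <- 1 - 0.17 * cos(hbp - pi / 6) + 0.24 * cos(2 * hbp) +
    0.32 * cos(3 * hbp + pi / 30) - 0.20 * cos(4 * hbp - 63 * pi / 180)

  dtheta <- (30 * pi / 180) * exp(-(((hbp * 180 / pi) - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + (0.015 * (Lbp - 50)^2) / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta) * RC

  as.numeric(abs(sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
                        RT * (dCp / SC) * (dHp / SH))))
}

#' Test whether a color is achromatic (black, white, or gray)
#'
#' A color counts as achromatic when the spread between its largest and
#' smallest channel is at most `spread_tol` 8-bit units. Achromatic palette
#' entries are excluded from color-pair metrics because they survive
#' deuteranopia simulation unchanged.
#'
#' @param rgb An n x 3 sRGB matrix (or length-3 vector), values in \[0, 1\].
#' @param spread_tol Maximum channel spread in 8-bit units (default 10).
#' @return Logical vector.
#' @export
is_achromatic <- function(rgb, spread_tol = 10) {
  stopifnot(spread_tol >= 0)
  x <- round(.as_color_matrix(rgb) * 255)
  apply(x, 1, max) - apply(x, 1, min) <= spread_tol
}
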