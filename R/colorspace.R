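# Color-space conversions and perceptual color differences.
#
# All conversions assume device colors are sRGB (IEC 61966-2-1) with gamma
# companding, the D65 standard illuminant and the CIE 1931 2-degree observer,
# with the reference white scaled to Y = 100. These are the conventions of
# browser color pickers, the source of the data this package analyzes.

# sRGB (linear) -> XYZ, D65, 2-degree observer (IEC 61966-2-1 matrix)
.RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

.XYZ2RGB <- solve(.RGB2XYZ)

# Reference white: image of RGB (1,1,1), so white maps to the white point
# exactly. Xn = 95.0470, Yn = 100.0000, Zn = 108.8830 (to 4 decimals).
.WHITE <- as.numeric(.RGB2XYZ %*% rep(1, 3)) * 100

.as_color_matrix <- function(x, what = "color") {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) {
      stop(what, " input must be a length-3 vector or an n x 3 matrix",
           call. = FALSE)
    }
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) {
    stop(what, " input must have 3 columns", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

.check_rgb <- function(rgb) {
  rgb <- .as_color_matrix(rgb, "RGB")
  if (anyNA(rgb)) stop("RGB input contains missing values", call. = FALSE)
  if (any(rgb < 0 | rgb > 255)) {
    stop("RGB channels must lie in [0, 255]", call. = FALSE)
  }
  if (any(rgb != round(rgb))) {
    # Device RGB is integer by contract; refuse to round silently.
    stop("RGB channels must be integers in [0, 255]", call. = FALSE)
  }
  rgb
}

.srgb_decompand <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

.srgb_compand <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Convert integer sRGB to CIE XYZ (D65, Y = 100)
#'
#' @param rgb Integer RGB channels in \[0, 255\]: a length-3 vector or an
#'   n x 3 matrix (one color per row).
#' @return An n x 3 matrix with columns `X`, `Y`, `Z`. The reference white
#'   (255, 255, 255) maps exactly to the D65 white point
#'   (95.047, 100, 108.883).
#' @export
rgb_to_xyz <- function(rgb) {
  rgb <- .check_rgb(rgb)
  lin <- .srgb_decompand(rgb / 255)
  xyz <- lin %*% t(.RGB2XYZ) * 100
  dimnames(xyz) <- list(NULL, c("X", "Y", "Z"))
  xyz
}

#' Convert integer sRGB to CIELuv (D65)
#'
#' Lightness `L` lies in \[0, 100\] for in-gamut input; `u` runs along a
#' green-red continuum and `v` along a blue-yellow continuum.
#'
#' @inheritParams rgb_to_xyz
#' @return An n x 3 matrix with columns `L`, `u`, `v`.
#' @export
rgb_to_luv <- function(rgb) {
  xyz <- rgb_to_xyz(rgb)
  X <- xyz[, 1]; Y <- xyz[, 2]; Z <- xyz[, 3]
  wn <- .WHITE
  upn <- 4 * wn[1] / (wn[1] + 15 * wn[2] + 3 * wn[3])
  vpn <- 9 * wn[2] / (wn[1] + 15 * wn[2] + 3 * wn[3])
  denom <- X + 15 * Y + 3 * Z
  # black has undefined chromaticity; put it at the white point so u = v = 0
  up <- ifelse(denom > 0, 4 * X / denom, upn)
  vp <- ifelse(denom > 0, 9 * Y / denom, vpn)
  yr <- Y / wn[2]
  L <- ifelse(yr > (6 / 29)^3, 116 * yr^(1 / 3) - 16, (29 / 3)^3 * yr)
  out <- cbind(L = L, u = 13 * L * (up - upn), v = 13 * L * (vp - vpn))
  rownames(out) <- NULL
  out
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' Convert integer sRGB to CIELab (D65)
#'
#' `L` is identical to the CIELuv lightness for the same input; `a` runs
#' along a green-red continuum (like `u`) and `b` along a blue-yellow
#' continuum (like `v`).
#'
#' @inheritParams rgb_to_xyz
#' @return An n x 3 matrix with columns `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(rgb) {
  xyz <- rgb_to_xyz(rgb)
  xyz_to_lab(xyz)
}

#' Convert CIE XYZ (D65, Y = 100) to CIELab
#'
#' @param xyz An n x 3 matrix (or length-3 vector) of tristimulus values.
#' @return An n x 3 matrix with columns `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(xyz) {
  xyz <- .as_color_matrix(xyz, "XYZ")
  fx <- .lab_f(xyz[, 1] / .WHITE[1])
  fy <- .lab_f(xyz[, 2] / .WHITE[2])
  fz <- .lab_f(xyz[, 3] / .WHITE[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  rownames(out) <- NULL
  out
}

#' Convert CIELab (D65) back to integer sRGB
#'
#' Inverse of [rgb_to_lab()] up to rounding. Out-of-gamut coordinates are
#' clipped to the RGB cube; used by the synthetic-data generator, which
#' draws colors in Lab and must express them as device RGB.
#'
#' @param lab An n x 3 matrix (or length-3 vector) of `L`, `a`, `b`.
#' @return An n x 3 integer matrix with columns `r`, `g`, `b` in \[0, 255\].
#' @export
lab_to_rgb <- function(lab) {
  lab <- .as_color_matrix(lab, "Lab")
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  d <- 6 / 29
  finv <- function(t) ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx) * .WHITE[1], finv(fy) * .WHITE[2],
               finv(fz) * .WHITE[3])
  lin <- xyz %*% t(.XYZ2RGB) / 100
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  rgb <- round(.srgb_compand(lin) * 255)
  rgb[rgb < 0] <- 0
  rgb[rgb > 255] <- 255
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

#' Euclidean distance in CIELuv
#'
#' The elementary distance of the temporal-consistency score: plain
#' Euclidean distance over (L, u, v).
#'
#' @param p,q Luv coordinates: length-3 vectors or n x 3 matrices
#'   (rows are paired when both are matrices).
#' @return Nonnegative distance(s).
#' @export
luv_distance <- function(p, q) {
  p <- .as_color_matrix(p, "Luv")
  q <- .as_color_matrix(q, "Luv")
  if (nrow(p) == 1L && nrow(q) > 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1L && nrow(p) > 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
  sqrt(rowSums((p - q)^2))
}

#' CIEDE2000 color difference
#'
#' Full CIEDE2000 formula between CIELab colors, including the lightness,
#' chroma and hue weighting functions and the blue-region rotation term.
#' Symmetric in its arguments and zero exactly for identical colors.
#'
#' @param lab1,lab2 Lab coordinates: length-3 vectors or n x 3 matrices
#'   (rows paired).
#' @param kL,kC,kH Parametric weighting factors; the reference conditions
#'   (all 1) are the default.
#' @return Nonnegative difference(s).
#' @export
delta_e2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  lab1 <- .as_color_matrix(lab1, "Lab")
  lab2 <- .as_color_matrix(lab2, "Lab")
  if (nrow(lab1) == 1L && nrow(lab2) > 1L)
    lab1 <- lab1[rep(1L, nrow(lab2)), , drop = FALSE]
  if (nrow(lab2) == 1L && nrow(lab1) > 1L)
    lab2 <- lab2[rep(1L, nrow(lab1)), , drop = FALSE]
  stopifnot(nrow(lab1) == nrow(lab2))

  deg2rad <- pi / 180
  rad2deg <- 180 / pi
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hangle <- function(a, b) {
    h <- atan2(b, a) * rad2deg
    h <- ifelse(h < 0, h + 360, h)
    ifelse(a == 0 & b == 0, 0, h)
  }
  h1p <- hangle(a1p, b1)
  h2p <- hangle(a2p, b2)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  hd <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(hd) <= 180, hd,
         ifelse(hd > 180, hd - 360, hd + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * deg2rad)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(hd) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tt <- 1 - 0.17 * cos((hbp - 30) * deg2rad) +
            0.24 * cos(2 * hbp * deg2rad) +
            0.32 * cos((3 * hbp + 6) * deg2rad) -
            0.20 * cos((4 * hbp - 63) * deg2rad)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * deg2rad) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
       RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}
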