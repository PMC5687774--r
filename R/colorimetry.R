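# Device-independent colour conversions and colour-difference metrics.
# Tristimulus convention: reference white has Y = 100.  All conversions use
# the CIE D65 illuminant with the CIE 1931 2-degree standard observer.

#' D65 reference white (2-degree observer)
#'
#' Tristimulus values of the D65 white point, `Y` normalised to 100.
#' @export
D65_WHITE <- c(X = 95.047, Y = 100, Z = 108.883)

# sRGB (IEC 61966-2-1) linear-RGB -> XYZ matrix, D65, rows X/Y/Z, Y in [0,1].
SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)

#' Linear RGB (sRGB primaries) to CIEXYZ
#'
#' Maps linear-light RGB in `[0, 1]` to tristimulus values with white
#' `Y = 100`.  Used by the simulator to assign reference XYZ to chart
#' patches of known reflectance.
#'
#' @param rgb length-3 vector or n x 3 matrix of linear RGB values.
#' @return vector or matrix of XYZ values.
#' @export
linear_rgb_to_xyz <- function(rgb) {
  v <- if (is.matrix(rgb)) rgb else matrix(rgb, 1)
  out <- v %*% t(SRGB_TO_XYZ) * 100
  colnames(out) <- c("X", "Y", "Z")
  if (is.matrix(rgb)) out else drop(out)
}

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

lab_f_inv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' CIEXYZ to CIEL*a*b*
#'
#' Standard CIE 1976 formulae with the two-piece cube-root compression
#' (linear branch below (6/29)^3).
#'
#' @param xyz length-3 vector or n x 3 matrix of tristimulus values.
#' @param white reference white tristimulus, strictly positive
#'   (default D65, `Y = 100`).
#' @return vector or matrix with columns `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(xyz, white = D65_WHITE) {
  if (any(!is.finite(white)) || any(white <= 0)) {
    stop("reference white must have strictly positive components")
  }
  v <- if (is.matrix(xyz)) xyz else matrix(xyz, 1)
  fx <- lab_f(v[, 1] / white[1])
  fy <- lab_f(v[, 2] / white[2])
  fz <- lab_f(v[, 3] / white[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (is.matrix(xyz)) out else drop(out)
}

#' @rdname xyz_to_lab
#' @param lab length-3 vector or n x 3 matrix of L*, a*, b* values.
#' @export
lab_to_xyz <- function(lab, white = D65_WHITE) {
  v <- if (is.matrix(lab)) lab else matrix(lab, 1)
  fy <- (v[, 1] + 16) / 116
  fx <- fy + v[, 2] / 500
  fz <- fy - v[, 3] / 200
  out <- cbind(X = white[1] * lab_f_inv(fx),
               Y = white[2] * lab_f_inv(fy),
               Z = white[3] * lab_f_inv(fz))
  if (is.matrix(lab)) out else drop(out)
}

#' RGB to hue-saturation-intensity
#'
#' Geometric HSI model: `I = (R+G+B)/3`, `S = 1 - min/I` (0 when `I = 0`),
#' hue from the arccos formula.  Achromatic pixels report `H = 0` by
#' convention.
#'
#' @param rgb length-3 vector or n x 3 matrix with components in `[0, 1]`.
#' @return vector or matrix with columns `H` (degrees, `[0, 360)`),
#'   `S` in `[0, 1]`, `I` in `[0, 1]`.
#' @export
rgb_to_hsi <- function(rgb) {
  v <- if (is.matrix(rgb)) rgb else matrix(rgb, 1)
  r <- v[, 1]; g <- v[, 2]; b <- v[, 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 1), -1), 1)) * 180 / pi
  h <- ifelse(b > g, 360 - theta, theta)
  h[s == 0] <- 0
  h[h >= 360] <- 0
  out <- cbind(H = h, S = pmin(pmax(s, 0), 1), I = i)
  if (is.matrix(rgb)) out else drop(out)
}

#' CIEXYZ to CIE 1931 chromaticity
#'
#' @param xyz length-3 vector or n x 3 matrix; each row must have
#'   `X + Y + Z > 0`.
#' @return vector or matrix with columns `x`, `y`.
#' @export
xyz_to_xy <- function(xyz) {
  v <- if (is.matrix(xyz)) xyz else matrix(xyz, 1)
  s <- rowSums(v)
  if (any(s <= 0)) stop("X + Y + Z must be positive")
  out <- cbind(x = v[, 1] / s, y = v[, 2] / s)
  if (is.matrix(xyz)) out else drop(out)
}

#' CIE76 colour difference
#'
#' Euclidean distance in CIEL*a*b* (the plain Delta E*ab metric).
#'
#' @param lab1,lab2 length-3 vectors or conformable n x 3 matrices.
#' @return nonnegative difference(s).
#' @export
delta_e_ab <- function(lab1, lab2) {
  a <- if (is.matrix(lab1)) lab1 else matrix(lab1, 1)
  b <- if (is.matrix(lab2)) lab2 else matrix(lab2, 1)
  d <- sqrt(rowSums((a - b)^2))
  if (is.matrix(lab1) || is.matrix(lab2)) d else drop(d)
}

#' sRGB transfer function
#'
#' Encode linear-light values to gamma-compressed sRGB and back; used when a
#' plain (non-characterised) image must be interpreted in Lab.
#'
#' @param x numeric vector/array in `[0, 1]`.
#' @export
srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

#' @rdname srgb_encode
#' @export
srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' Pixel matrix conversions between working colour spaces
#'
#' Converts an n x 3 matrix of sRGB-encoded pixel values into the requested
#' working space.  For `"lab"` without a supplied XYZ matrix the pixels are
#' assumed sRGB-encoded under D65.  For `"hsi"` the circular hue coordinate
#' is embedded as `(S cos H, S sin H, I)` so Euclidean clustering respects
#' hue wrap-around.
#'
#' @param px n x 3 matrix of RGB values in `[0, 1]`.
#' @param space one of `"rgb"`, `"hsi"`, `"lab"`.
#' @param xyz optional n x 3 matrix of camera-characterised tristimulus
#'   values matching `px` row-for-row.
#' @return n x 3 numeric matrix in the working space.
#' @export
pixels_to_space <- function(px, space = c("rgb", "hsi", "lab"), xyz = NULL) {
  space <- match.arg(space)
  if (space == "rgb") return(px)
  if (space == "hsi") {
    h <- rgb_to_hsi(px)
    ang <- h[, 1] * pi / 180
    return(cbind(h[, 2] * cos(ang), h[, 2] * sin(ang), h[, 3]))
  }
  if (is.null(xyz)) xyz <- linear_rgb_to_xyz(srgb_decode(px))
  unname(xyz_to_lab(xyz))
}
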