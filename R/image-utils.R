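# Low-level image containers and numerics shared by all stages.
# An RGB image is an H x W x 3 numeric array with channel values in [0, 1];
# greyscale images are H x W matrices.  Pixel coordinates are 1-based
# (row, col) internally and serialised 0-based row-major in JSON sidecars.

#' Construct an RGB image array
#'
#' @param data numeric vector or array of length `h * w * 3`.
#' @param h,w image height and width in pixels.
#' @return an `h x w x 3` array clipped to `[0, 1]`.
#' @export
rgb_image <- function(data, h, w) {
  a <- array(as.numeric(data), dim = c(h, w, 3L))
  clip01(a)
}

#' @rdname rgb_image
#' @param x object to test.
#' @export
is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

assert_rgb_image <- function(x, what = "image") {
  if (!is_rgb_image(x)) stop(what, " must be an H x W x 3 numeric array")
  invisible(x)
}

#' Convert an RGB image to greyscale (ITU-R BT.601 luma)
#'
#' @param img RGB image array.
#' @return numeric matrix of the same height/width.
#' @export
to_grey <- function(img) {
  assert_rgb_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Quantise to / restore from 8-bit channel values
#'
#' `to_raw8` rounds channels to integers 0..255; `from_raw8` maps them back
#' to `[0, 1]`.  Encryption operates on the 8-bit representation.
#'
#' @param img RGB image array in `[0, 1]`.
#' @return integer array (`to_raw8`) or numeric array (`from_raw8`).
#' @export
to_raw8 <- function(img) {
  a <- round(clip01(img) * 255)
  storage.mode(a) <- "integer"
  a
}

#' @rdname to_raw8
#' @param q integer array of 8-bit values.
#' @export
from_raw8 <- function(q) {
  a <- q / 255
  dim(a) <- dim(q)
  a
}

#' Read / write PNG images
#'
#' Thin wrappers over the \pkg{png} package keeping the H x W x 3 layout.
#'
#' @param path file path.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' @rdname read_image
#' @param img RGB image array.
#' @export
write_image <- function(img, path) {
  png::writePNG(clip01(img), path)
  invisible(path)
}

# --- separable convolution (reflect boundary) -------------------------------

reflect_index <- function(n, off) {
  i <- seq_len(n) + off
  i[i < 1L] <- 2L - i[i < 1L]
  i[i > n] <- 2L * n - i[i > n]
  i
}

conv_axis <- function(mat, kern, axis) {
  half <- (length(kern) - 1L) %/% 2L
  out <- matrix(0, nrow(mat), ncol(mat))
  for (t in seq_along(kern)) {
    off <- t - 1L - half
    if (axis == 1L) {
      out <- out + kern[t] * mat[reflect_index(nrow(mat), off), , drop = FALSE]
    } else {
      out <- out + kern[t] * mat[, reflect_index(ncol(mat), off), drop = FALSE]
    }
  }
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

conv_sep <- function(mat, kern) conv_axis(conv_axis(mat, kern, 1L), kern, 2L)

#' Gaussian smoothing filter
#'
#' Channel-wise separable Gaussian convolution with reflecting boundary,
#' used as the pre-segmentation noise filter.
#'
#' @param img RGB image array or greyscale matrix.
#' @param sigma_px kernel standard deviation in pixels (> 0).
#' @return smoothed image of identical shape.
#' @export
gaussian_smooth <- function(img, sigma_px) {
  if (!is.numeric(sigma_px) || sigma_px <= 0) stop("sigma_px must be > 0")
  k <- gaussian_kernel(sigma_px)
  if (is.matrix(img)) return(conv_sep(img, k))
  assert_rgb_image(img)
  out <- img
  for (ch in 1:3) out[, , ch] <- conv_sep(img[, , ch], k)
  out
}

# --- sampling and warping ---------------------------------------------------

# Bilinear sample of a matrix at fractional (x = col, y = row), 1-based.
# Points outside the support return `fill`.
bilinear_mat <- function(mat, x, y, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= w & y0 + 1 <= h
  # clamp indices so arithmetic stays in range; mask afterwards
  x0c <- pmin(pmax(x0, 1), w - 1); y0c <- pmin(pmax(y0, 1), h - 1)
  i00 <- cbind(y0c, x0c); i01 <- cbind(y0c, x0c + 1)
  i10 <- cbind(y0c + 1, x0c); i11 <- cbind(y0c + 1, x0c + 1)
  v <- (1 - fy) * ((1 - fx) * mat[i00] + fx * mat[i01]) +
    fy * ((1 - fx) * mat[i10] + fx * mat[i11])
  v[!ok] <- fill
  v
}

bilinear_img <- function(img, x, y, fill = 0) {
  sapply(1:3, function(ch) bilinear_mat(img[, , ch], x, y, fill))
}

# Bilinear image resize to (h, w).
resize_img <- function(img, h, w) {
  sh <- dim(img)[1] / h; sw <- dim(img)[2] / w
  yy <- (seq_len(h) - 0.5) * sh + 0.5
  xx <- (seq_len(w) - 0.5) * sw + 0.5
  g <- expand.grid(y = yy, x = xx)
  if (is.matrix(img)) {
    return(matrix(bilinear_mat(img, g$x, g$y), h, w))
  }
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(bilinear_mat(img[, , ch], g$x, g$y), h, w)
  out
}

# --- homography -------------------------------------------------------------

# Fit H (3x3, H[3,3] = 1 scale-fixed by normalisation) mapping src -> dst,
# both n x 2 matrices of (x, y).  Normalised DLT.
fit_homography <- function(src, dst) {
  stopifnot(nrow(src) >= 4, nrow(dst) == nrow(src))
  norm_pts <- function(p) {
    m <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, m)^2)) + 1e-12)
    t_mat <- matrix(c(s, 0, -s * m[1], 0, s, -s * m[2], 0, 0, 1), 3, 3, byrow = TRUE)
    list(p = cbind(p[, 1] * s - s * m[1], p[, 2] * s - s * m[2]), T = t_mat)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  a_mat <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    a_mat[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    a_mat[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  hvec <- svd(a_mat, nu = 0, nv = 9)$v[, 9]
  h_norm <- matrix(hvec, 3, 3, byrow = TRUE)
  h <- solve(nd$T) %*% h_norm %*% ns$T
  if (abs(h[3, 3]) > 1e-12) h <- h / h[3, 3]
  h
}

apply_homography <- function(h, pts) {
  p <- cbind(pts, 1) %*% t(h)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * y[c(2:nrow(p), 1)] - x[c(2:nrow(p), 1)] * y)) / 2
}

is_convex_quad <- function(p) {
  s <- numeric(4)
  for (i in 1:4) {
    a <- p[i, ]; b <- p[i %% 4 + 1, ]; c <- p[(i + 1) %% 4 + 1, ]
    s[i] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }
  all(s > 0) || all(s < 0)
}

# Seeded RANSAC homography; returns NULL when no model reaches min_inliers.
# `validate` lets callers veto degenerate candidate models (e.g. collapsed
# or non-convex projected quads); inlier support is counted over distinct
# destination locations so clustered repeated matches cannot fake support.
ransac_homography <- function(src, dst, thresh = 3, iters = 1000,
                              min_inliers = 12, seed = 1L,
                              validate = function(h) TRUE) {
  n <- nrow(src)
  if (n < 4) return(NULL)
  support <- function(inl) {
    if (!length(inl)) return(0L)
    nrow(unique(round(dst[inl, , drop = FALSE] / 2)))
  }
  spread_ok <- function(p) {
    d <- stats::dist(p)
    min(d) > 8
  }
  best_h <- NULL; best_n <- 0L
  set.seed(seed)
  for (it in seq_len(iters)) {
    idx <- sample.int(n, 4L)
    if (!spread_ok(src[idx, , drop = FALSE]) || !spread_ok(dst[idx, , drop = FALSE])) next
    h <- tryCatch(fit_homography(src[idx, , drop = FALSE], dst[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(h) || !all(is.finite(h)) || !validate(h)) next
    proj <- apply_homography(h, src)
    err <- sqrt(rowSums((proj - dst)^2))
    sup <- support(which(err < thresh))
    if (sup > best_n) {
      best_n <- sup; best_h <- h
    }
  }
  if (is.null(best_h) || best_n < max(4L, min_inliers)) return(NULL)
  # refit on the consensus set, keep only if still valid
  err <- sqrt(rowSums((apply_homography(best_h, src) - dst)^2))
  inl <- which(err < thresh)
  h <- tryCatch(fit_homography(src[inl, , drop = FALSE], dst[inl, , drop = FALSE]),
                error = function(e) NULL)
  if (!is.null(h) && all(is.finite(h)) && validate(h)) {
    err2 <- sqrt(rowSums((apply_homography(h, src) - dst)^2))
    if (support(which(err2 < thresh)) >= best_n) {
      best_h <- h; inl <- which(err2 < thresh)
    }
  }
  if (support(inl) < max(4L, min_inliers)) return(NULL)
  list(H = best_h, inliers = inl, n_inliers = support(inl))
}

# Deterministic sub-seed derivation: fold arbitrary numeric arguments into a
# 31-bit seed so that identical (seed, args) pairs reproduce bit-identically.
derive_subseed <- function(seed, ...) {
  vals <- c(seed, unlist(list(...)))
  acc <- 0
  for (v in vals) {
    acc <- (acc * 31 + (round(abs(v) * 1000) %% 1000003)) %% 2147483629
  }
  as.integer(acc + 1)
}
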