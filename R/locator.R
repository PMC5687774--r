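# Fiducial localisation.  A scale/rotation-tolerant local-feature pipeline:
# Harris corners with dominant-gradient orientation, normalised oriented
# patch descriptors, nearest-neighbour matching with Lowe's ratio test and
# seeded RANSAC homography estimation.  The detector sits behind a small
# contract (repeatable under in-plane rotation and moderate scaling) so a
# different backend could be swapped in.

#' Detect oriented corner features
#'
#' Harris corner detection on a greyscale image with 3 x 3 non-maximum
#' suppression; each keypoint carries a dominant-gradient orientation and a
#' normalised 8 x 8 oriented patch descriptor (64-D, zero mean, unit norm).
#'
#' @param grey greyscale matrix (at least 64 x 64) or RGB image (converted
#'   with BT.601 luma).
#' @param n_strongest maximum number of keypoints, ordered by response.
#' @param sigma_d,sigma_i derivative / integration Gaussian scales (px).
#' @param spacing descriptor sample spacing in pixels (the 12 x 12 grid
#'   then spans about 11 x `spacing` pixels, wide enough to capture module
#'   layout context on repetitive targets).
#' @return list with `xy` (n x 2 matrix of (x = col, y = row)),
#'   `response`, `angle` (radians), `desc` (n x 144 matrix).
#' @export
detect_features <- function(grey, n_strongest = 200L, sigma_d = 1,
                            sigma_i = 2, spacing = 5) {
  if (is_rgb_image(grey)) grey <- to_grey(grey)
  if (!is.matrix(grey)) stop("grey must be a matrix or RGB image")
  if (nrow(grey) < 64L || ncol(grey) < 64L) stop("image too small (< 64 x 64)")
  sm <- conv_sep(grey, gaussian_kernel(sigma_d))
  h <- nrow(sm); w <- ncol(sm)
  gx <- (sm[, c(2:w, w)] - sm[, c(1, 1:(w - 1))]) / 2
  gy <- (sm[c(2:h, h), ] - sm[c(1, 1:(h - 1)), ]) / 2
  ki <- gaussian_kernel(sigma_i)
  sxx <- conv_sep(gx * gx, ki); syy <- conv_sep(gy * gy, ki)
  sxy <- conv_sep(gx * gy, ki)
  resp <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  # 3 x 3 non-max suppression via shifted comparisons
  is_max <- resp > 1e-8
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- resp[reflect_index(h, dr), reflect_index(w, dc)]
    is_max <- is_max & (resp >= shifted)
  }
  border <- 16L
  is_max[c(1:border, (h - border + 1):h), ] <- FALSE
  is_max[, c(1:border, (w - border + 1):w)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(xy = matrix(0, 0, 2), response = numeric(0),
                angle = numeric(0), desc = matrix(0, 0, 144)))
  }
  r <- resp[idx]
  ord <- order(r, decreasing = TRUE)[seq_len(min(n_strongest, length(r)))]
  idx <- idx[ord, , drop = FALSE]
  r <- r[ord]
  d <- describe_patches(grey, idx[, 2], idx[, 1], spacing)
  list(xy = cbind(x = idx[, 2], y = idx[, 1]), response = r,
       angle = d$angle, desc = d$desc)
}

# Oriented 12 x 12 patch descriptor.  Orientation is the intensity-centroid
# angle over a circular neighbourhood (stable at symmetric corners where
# gradient orientation flips); samples are taken on a rotated grid with
# bilinear interpolation and normalised to zero mean / unit norm
# (affine-light invariant).  Out-of-support samples read as mid-grey.
describe_patches <- function(grey, x, y, spacing = 5, grid_n = 12L,
                             orient_radius = 12L) {
  offs <- expand.grid(dx = -orient_radius:orient_radius,
                      dy = -orient_radius:orient_radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= orient_radius^2, ]
  half <- (grid_n - 1) / 2
  po <- seq(-half, half) * spacing
  g <- expand.grid(u = po, v = po)
  n <- length(x)
  desc <- matrix(0, n, nrow(g))
  ang <- numeric(n)
  for (i in seq_len(n)) {
    vals <- bilinear_mat(grey, x[i] + offs$dx, y[i] + offs$dy, fill = 0.5)
    a <- atan2(sum(offs$dy * vals), sum(offs$dx * vals))
    ang[i] <- a
    ca <- cos(a); sa <- sin(a)
    desc[i, ] <- bilinear_mat(grey, x[i] + ca * g$u - sa * g$v,
                              y[i] + sa * g$u + ca * g$v, fill = 0.5)
  }
  desc <- desc - rowMeans(desc)
  nr <- sqrt(rowSums(desc^2))
  nr[nr < 1e-9] <- 1
  list(desc = desc / nr, angle = ang)
}

# Nearest-neighbour descriptor matching with Lowe ratio test and mutual
# nearest-neighbour consistency; returns index pairs.  Mutuality matters
# here because the fiducial's module pattern is highly self-similar.
match_descriptors <- function(desc_a, desc_b, ratio = 0.75) {
  if (nrow(desc_a) == 0L || nrow(desc_b) < 2L) return(cbind(integer(0), integer(0)))
  # squared distances via cross product (descriptors are unit norm)
  sim <- desc_a %*% t(desc_b)
  d2 <- pmax(2 - 2 * sim, 0)
  nn_b_of_a <- max.col(-d2)
  nn_a_of_b <- max.col(-t(d2))
  out <- matrix(0L, 0, 2)
  for (i in seq_len(nrow(d2))) {
    j <- nn_b_of_a[i]
    if (nn_a_of_b[j] != i) next
    o2 <- sort(d2[i, ], partial = 2)[2]
    if (d2[i, j] < ratio^2 * o2) out <- rbind(out, c(i, j))
  }
  out
}

#' Locate the fiducial template in a scene
#'
#' Detects features in both images (the template additionally over a small
#' scale pyramid), matches descriptors with the ratio test, and estimates a
#' template-to-scene homography by seeded RANSAC.  Raises a no-detection
#' error (class `holoquant_no_detection`) when fewer than `min_inliers`
#' geometrically consistent matches survive -- the "sensor not found,
#' re-capture" signal.
#'
#' @param scene,template RGB images (or greyscale matrices).
#' @param n_strongest keypoints kept per image.
#' @param ratio Lowe ratio-test threshold.
#' @param min_inliers minimum consistent matches for a detection.
#' @param scales template scale pyramid used for matching.
#' @param seed RANSAC seed.
#' @return object of class `detection`: `quad` (4 x 2 template corners
#'   (x, y) projected into the scene, TL/TR/BR/BL), `H` (template-to-scene
#'   homography), `n_matched`, `inlier_ratio`.
#' @export
match_template <- function(scene, template, n_strongest = 250L, ratio = 0.8,
                           min_inliers = 12L,
                           scales = c(1, 0.93, 0.86, 0.8, 0.74),
                           seed = 1L) {
  g_scene <- if (is_rgb_image(scene)) to_grey(scene) else scene
  g_tpl <- if (is_rgb_image(template)) to_grey(template) else template
  f_scene <- detect_features(g_scene, n_strongest)
  tpl_xy <- NULL; tpl_desc <- NULL
  for (s in scales) {
    gs <- if (s == 1) g_tpl else resize_img(g_tpl, round(nrow(g_tpl) * s),
                                            round(ncol(g_tpl) * s))
    if (nrow(gs) < 64L || ncol(gs) < 64L) next
    fs <- detect_features(gs, n_strongest)
    if (nrow(fs$xy) == 0L) next
    tpl_xy <- rbind(tpl_xy, fs$xy / s)  # map back to template frame
    tpl_desc <- rbind(tpl_desc, fs$desc)
  }
  no_det <- function(msg) {
    stop(structure(class = c("holoquant_no_detection", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  if (is.null(tpl_xy) || nrow(f_scene$xy) < 4L) no_det("sensor not found: too few features")
  m <- match_descriptors(tpl_desc, f_scene$desc, ratio)
  if (nrow(m) < max(4L, min_inliers)) no_det("sensor not found: too few matches")
  th <- nrow(g_tpl); tw <- ncol(g_tpl)
  corners <- cbind(c(1, tw, tw, 1), c(1, 1, th, th))
  tpl_area <- th * tw
  scene_area <- nrow(g_scene) * ncol(g_scene)
  validate <- function(h) {
    q <- apply_homography(h, corners)
    if (!all(is.finite(q))) return(FALSE)
    a <- polygon_area(q)
    is_convex_quad(q) && a > 0.05 * tpl_area && a < 4 * scene_area
  }
  fit <- ransac_homography(tpl_xy[m[, 1], , drop = FALSE],
                           f_scene$xy[m[, 2], , drop = FALSE],
                           thresh = 3, iters = 1500, min_inliers = min_inliers,
                           seed = seed, validate = validate)
  if (is.null(fit)) no_det("sensor not found: no consistent geometry")
  quad <- apply_homography(fit$H, corners)
  structure(list(quad = quad, H = fit$H, n_matched = fit$n_inliers,
                 inlier_ratio = fit$n_inliers / nrow(m)),
            class = "detection")
}

#' Rectify the detected quad and cut out the central hologram window
#'
#' Inverse-warps the detected quadrilateral to an axis-aligned square and
#' returns the central `layout` fraction (the hologram window) together
#' with its footprint mask in scene coordinates.
#'
#' @param scene RGB image.
#' @param det a [match_template()] detection (or any list with `quad`).
#' @param layout central fraction of the rectified square to keep, `(0, 1]`.
#' @param out_size rectified square side in pixels.
#' @return list `patch` (RGB array), `mask` (logical matrix in scene
#'   coordinates), `quad_patch` (scene-coordinate corners of the window).
#' @export
extract_roi_patch <- function(scene, det, layout = 0.22, out_size = 96L) {
  assert_rgb_image(scene)
  quad <- det$quad
  if (layout <= 0 || layout > 1) stop("layout must be in (0, 1]")
  # homography mapping unit square corners -> quad
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  h <- tryCatch(fit_homography(sq, quad), error = function(e) stop("numeric-error: degenerate homography"))
  if (!all(is.finite(h))) stop("numeric-error: degenerate homography")
  lo <- 0.5 - layout / 2; hi <- 0.5 + layout / 2
  uu <- seq(lo, hi, length.out = out_size)
  g <- expand.grid(v = uu, u = uu)  # v = row direction
  pts <- apply_homography(h, cbind(g$u, g$v))
  patch <- array(bilinear_img(scene, pts[, 1], pts[, 2]), c(out_size, out_size, 3L))
  # footprint mask in scene coordinates
  hs <- dim(scene)[1]; ws <- dim(scene)[2]
  quad_patch <- apply_homography(h, cbind(c(lo, hi, hi, lo), c(lo, lo, hi, hi)))
  rr <- max(1, floor(min(quad_patch[, 2]))):min(hs, ceiling(max(quad_patch[, 2])))
  cc <- max(1, floor(min(quad_patch[, 1]))):min(ws, ceiling(max(quad_patch[, 1])))
  mask <- matrix(FALSE, hs, ws)
  if (length(rr) && length(cc)) {
    gg <- expand.grid(y = rr, x = cc)
    back <- apply_homography(solve(h), cbind(gg$x, gg$y))
    inside <- back[, 1] >= lo & back[, 1] <= hi & back[, 2] >= lo & back[, 2] <= hi
    mask[cbind(gg$y, gg$x)[inside, , drop = FALSE]] <- TRUE
  }
  list(patch = patch, mask = mask, quad_patch = quad_patch, H_unit = h)
}

#' Map a label mask on the rectified window back into scene coordinates
#'
#' @param sel logical `out_size x out_size` matrix on the window grid.
#' @param roi result of [extract_roi_patch()].
#' @param scene_dim `c(H, W)` of the scene.
#' @param layout the layout fraction used for extraction.
#' @return logical H x W scene mask.
#' @export
window_mask_to_scene <- function(sel, roi, scene_dim, layout = 0.22) {
  out_size <- nrow(sel)
  lo <- 0.5 - layout / 2; hi <- 0.5 + layout / 2
  hs <- scene_dim[1]; ws <- scene_dim[2]
  mask <- matrix(FALSE, hs, ws)
  qp <- roi$quad_patch
  rr <- max(1, floor(min(qp[, 2]))):min(hs, ceiling(max(qp[, 2])))
  cc <- max(1, floor(min(qp[, 1]))):min(ws, ceiling(max(qp[, 1])))
  if (!length(rr) || !length(cc)) return(mask)
  gg <- expand.grid(y = rr, x = cc)
  back <- apply_homography(solve(roi$H_unit), cbind(gg$x, gg$y))
  u <- (back[, 1] - lo) / (hi - lo); v <- (back[, 2] - lo) / (hi - lo)
  inside <- u >= 0 & u <= 1 & v >= 0 & v <= 1
  ri <- pmin(pmax(round(v * (out_size - 1)) + 1, 1), out_size)
  ci <- pmin(pmax(round(u * (out_size - 1)) + 1, 1), out_size)
  hit <- inside & sel[cbind(ri, ci)]
  mask[cbind(gg$y, gg$x)[hit, , drop = FALSE]] <- TRUE
  mask
}

#' Serialise a detection to JSON
#'
#' Corners are written 0-based as `[row, col]`, top-left clockwise.
#' @param det a detection.
#' @param path output path.
#' @export
write_detection <- function(det, path) {
  jsonlite::write_json(list(
    quad_rc0 = lapply(seq_len(4), function(i) c(det$quad[i, 2] - 1, det$quad[i, 1] - 1)),
    n_matched = det$n_matched, inlier_ratio = det$inlier_ratio),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
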