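# Agreement between segmentation methods: one-way intraclass correlation
# on the ROI colour coordinates (targets = the three coordinates of a
# colour space, methods = segmentation algorithms) and Bland-Altman limits
# of agreement.

#' Intraclass correlation coefficient (one-way form)
#'
#' `ICC = (MS_B - MS_W) / (MS_B + (k - 1) MS_W)` with
#' `MS_B = 1/(n-1) * sum_x k (m_x - mu)^2` and
#' `MS_W = 1/(n(k-1)) * sum (x - m_x)^2`, where rows of `values` are the
#' n targets and columns the k methods.
#'
#' @param values n x k numeric matrix, no missing cells, `n >= 2`,
#'   `k >= 2`.
#' @return object of class `icc_result`: `icc`, `ms_between`, `ms_within`.
#' @export
icc <- function(values) {
  v <- as.matrix(values)
  n <- nrow(v); k <- ncol(v)
  if (n < 2L || k < 2L) stop("need n >= 2 targets and k >= 2 methods")
  if (anyNA(v)) stop("missing cells are not allowed")
  m_x <- rowMeans(v)
  mu <- mean(v)
  ms_b <- sum(k * (m_x - mu)^2) / (n - 1)
  ms_w <- sum((v - m_x)^2) / (n * (k - 1))
  denom <- ms_b + (k - 1) * ms_w
  if (denom <= .Machine$double.eps) stop("degenerate data: zero total variance")
  structure(list(icc = (ms_b - ms_w) / denom, ms_between = ms_b, ms_within = ms_w),
            class = "icc_result")
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = col1 - col2`; bias is their mean and the limits are
#' `bias +/- 1.96 * sd(d)` with the sample (n - 1) standard deviation.
#'
#' @param pairs n x 2 matrix of paired measurements (`n >= 2`).
#' @param multiplier limit multiplier (1.96 for 95% limits).
#' @return object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `differences`, `means`.
#' @export
bland_altman <- function(pairs, multiplier = 1.96) {
  p <- as.matrix(pairs)
  if (nrow(p) < 2L || ncol(p) != 2L) stop("pairs must be an n x 2 matrix, n >= 2")
  d <- p[, 1] - p[, 2]
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - multiplier * s, loa_high = bias + multiplier * s,
                 differences = d, means = rowMeans(p)),
            class = "bland_altman_result")
}

#' Compare two segmentation methods over a scene set
#'
#' For each scene the ROI's three colour coordinates under each method form
#' a 3 x 2 agreement table; per-scene ICCs are averaged across scenes (the
#' pooled all-scenes table is also reported), and Bland-Altman statistics
#' are computed per coordinate over scenes.  Scenes where either method
#' failed are skipped with a warning.
#'
#' @param coords_a,coords_b lists (one element per scene) of length-3
#'   numeric ROI colour coordinates for methods a and b.
#' @return list `icc_per_scene`, `icc_mean`, `icc_pooled`,
#'   `bland_altman` (per-coordinate list), `n_used`, `n_skipped`.
#' @export
compare_methods <- function(coords_a, coords_b) {
  stopifnot(length(coords_a) == length(coords_b))
  ok <- vapply(seq_along(coords_a), function(i) {
    !is.null(coords_a[[i]]) && !is.null(coords_b[[i]]) &&
      all(is.finite(coords_a[[i]])) && all(is.finite(coords_b[[i]]))
  }, logical(1))
  if (!all(ok)) warning(sum(!ok), " scene(s) skipped (method failure)")
  a <- coords_a[ok]; b <- coords_b[ok]
  if (!length(a)) stop("no usable scenes")
  per_scene <- vapply(seq_along(a), function(i) {
    tryCatch(icc(cbind(a[[i]], b[[i]]))$icc, error = function(e) NA_real_)
  }, numeric(1))
  pooled <- icc(cbind(unlist(a), unlist(b)))
  # per-coordinate limits of agreement need at least two scenes
  ba <- if (length(a) >= 2) {
    lapply(1:3, function(j) {
      bland_altman(cbind(vapply(a, `[`, numeric(1), j),
                         vapply(b, `[`, numeric(1), j)))
    })
  }
  list(icc_per_scene = per_scene, icc_mean = mean(per_scene, na.rm = TRUE),
       icc_pooled = pooled$icc, bland_altman = ba,
       n_used = length(a), n_skipped = sum(!ok))
}
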