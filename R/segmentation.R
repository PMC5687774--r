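# Colour-cluster segmentation.  Pixels (optionally Gaussian-smoothed and
# converted to a working colour space) are clustered by k-means or fuzzy
# c-means for each candidate cluster count k; the Turi-Ray validity
# measure VM = y(k) * intra / inter selects k automatically, where intra is
# the mean squared distance of pixels to their own centre, inter the
# minimum squared distance between centres, and y a Gaussian-weighted
# function of k discouraging trivially small cluster counts.

#' Validity-measure parameters
#'
#' Defaults follow the study conditions: weight constant `m = 20`,
#' Gaussian cluster-count prior with mean 2 and SD 1, and a search range
#' of 2..10 clusters.  `sign_variant` selects between the cited criterion's
#' positive Gaussian multiplier (`"positive_gaussian"`, default) and the
#' literally printed negated form (`"as_printed"`).
#'
#' @param m_const weight constant.
#' @param mu,sigma Gaussian mean / SD of the cluster-count weighting.
#' @param k_min,k_max cluster-count search range (`k_min >= 2`).
#' @param sign_variant `"positive_gaussian"` or `"as_printed"`.
#' @export
vm_params <- function(m_const = 20, mu = 2, sigma = 1, k_min = 2L, k_max = 10L,
                      sign_variant = c("positive_gaussian", "as_printed")) {
  if (k_min < 2L || k_max < k_min || sigma <= 0) stop("invalid VM parameters")
  list(m_const = m_const, mu = mu, sigma = sigma,
       k_min = as.integer(k_min), k_max = as.integer(k_max),
       sign_variant = match.arg(sign_variant))
}

vm_multiplier <- function(k, params) {
  gauss <- stats::dnorm(k, params$mu, params$sigma)
  if (params$sign_variant == "as_printed") gauss <- -gauss
  params$m_const * gauss + 1
}

# seeded k-means++ initial centres
kmeanspp_init <- function(x, k, seed) {
  set.seed(seed)
  n <- nrow(x)
  centres <- matrix(0, k, ncol(x))
  centres[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centres[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      centres[j, ] <- x[sample.int(n, 1L), ]
    } else {
      centres[j, ] <- x[sample.int(n, 1L, prob = p), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centres[j, ])^2))
  }
  centres
}

#' k-means colour clustering
#'
#' Lloyd iterations from a seeded k-means++ initialisation (the standard
#' `stats::kmeans` engine does the iterating).  Deterministic given `seed`.
#'
#' @param pixels n x 3 matrix in the working colour space.
#' @param k number of clusters (`2 <= k <= n`).
#' @param seed RNG seed.
#' @param max_iter iteration cap.
#' @return object of class `segmentation_result`: `labels`, `centres`,
#'   `membership` (one-hot), `method`, `pixel_count`.
#' @export
kmeans_segment <- function(pixels, k, seed = 1L, max_iter = 300L) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (k < 2L || k > n) stop("need 2 <= k <= n")
  init <- unique(kmeanspp_init(pixels, k, seed))
  while (nrow(init) < k) {  # duplicate draws collapse: nudge
    init <- rbind(init, init[nrow(init), ] + 1e-6 * seq_len(ncol(init)))
  }
  km <- suppressWarnings(stats::kmeans(pixels, centers = init,
                                       iter.max = max_iter, algorithm = "Lloyd"))
  memb <- matrix(0, n, k)
  memb[cbind(seq_len(n), km$cluster)] <- 1
  structure(list(labels = km$cluster, centres = km$centers,
                 membership = memb, method = "kmeans", pixel_count = n),
            class = "segmentation_result")
}

#' Fuzzy c-means colour clustering
#'
#' Wraps `e1071::cmeans` with the same seeded k-means++ initial centres as
#' [kmeans_segment()]; hard labels are the argmax memberships.
#'
#' @inheritParams kmeans_segment
#' @param fuzzifier fuzziness exponent q > 1.
#' @export
fcm_segment <- function(pixels, k, fuzzifier = 2, seed = 1L, max_iter = 300L) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (k < 2L || k > n) stop("need 2 <= k <= n")
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  init <- kmeanspp_init(pixels, k, seed)
  init <- init + 1e-9 * matrix(seq_len(length(init)), nrow(init))  # distinct
  fit <- e1071::cmeans(pixels, centers = init, iter.max = max_iter,
                       method = "cmeans", m = fuzzifier)
  memb <- fit$membership
  structure(list(labels = apply(memb, 1, which.max), centres = fit$centers,
                 membership = memb, method = "fcm", pixel_count = n),
            class = "segmentation_result")
}

#' Turi-Ray validity measure for one segmentation
#'
#' `intra` is the mean over all M pixels of the squared distance to the own
#' cluster centre; `inter` the minimum squared distance between any two
#' centres; `y = m * N(mu, sigma)(k) + 1`; `vm = y * intra / inter`.
#'
#' @param seg a `segmentation_result` (hard labels are used).
#' @param pixels the n x 3 pixel matrix that was clustered.
#' @param params [vm_params()].
#' @return list `k`, `intra`, `inter`, `y`, `vm`.
#' @export
validity_measure <- function(seg, pixels, params = vm_params()) {
  pixels <- as.matrix(pixels)
  centres <- as.matrix(seg$centres)
  k <- nrow(centres)
  if (k < 2L) stop("need >= 2 centres")
  if (any(!is.finite(centres))) stop("degenerate clustering: empty cluster")
  d2c <- rowSums((pixels - centres[seg$labels, , drop = FALSE])^2)
  intra <- mean(d2c)
  dc <- as.matrix(stats::dist(centres))^2
  inter <- min(dc[upper.tri(dc)])
  if (inter <= .Machine$double.eps) stop("degenerate clustering: coincident centres")
  y <- vm_multiplier(k, params)
  list(k = k, intra = intra, inter = inter, y = y, vm = y * intra / inter)
}

#' Automatic segmentation with validity-driven cluster count
#'
#' Smooths the image, converts pixels to the working colour space, runs the
#' chosen clustering for every k in the search range (on a subsample when
#' the image is large), computes the validity measure and returns the
#' segmentation at the VM-minimising k with full-image labels assigned by
#' nearest centre.
#'
#' @param image RGB image array (or n x 3 pixel matrix).
#' @param method `"kmeans"` or `"fcm"`.
#' @param colour_space `"rgb"`, `"hsi"` or `"lab"`.
#' @param params [vm_params()].
#' @param seed RNG seed (subsampling + clustering initialisation).
#' @param smooth_sigma pre-smoothing sigma in px (0 disables; ignored for
#'   pixel-matrix input).
#' @param max_pixels clustering subsample cap.
#' @param xyz optional camera-characterised XYZ image/matrix for `"lab"`.
#' @return list `seg` (`segmentation_result` at the selected k, labels over
#'   all pixels), `vm_curve` (data.frame k/intra/inter/y/vm), `k_best`,
#'   `space_pixels` (working-space matrix of all pixels).
#' @export
auto_segment <- function(image, method = c("kmeans", "fcm"),
                         colour_space = c("lab", "rgb", "hsi"),
                         params = vm_params(), seed = 1L, smooth_sigma = 1,
                         max_pixels = 20000L, xyz = NULL) {
  method <- match.arg(method)
  colour_space <- match.arg(colour_space)
  if (is_rgb_image(image)) {
    img <- if (smooth_sigma > 0) gaussian_smooth(image, smooth_sigma) else image
    px <- matrix(img, prod(dim(img)[1:2]), 3L)
    if (!is.null(xyz) && is.array(xyz)) xyz <- matrix(xyz, prod(dim(img)[1:2]), 3L)
  } else {
    px <- as.matrix(image)
  }
  sp <- pixels_to_space(px, colour_space, xyz = xyz)
  n <- nrow(sp)
  set.seed(derive_subseed(seed, 55L))
  sub <- if (n > max_pixels) sort(sample.int(n, max_pixels)) else seq_len(n)
  recs <- list(); segs <- list()
  for (k in params$k_min:params$k_max) {
    if (k > length(sub)) break
    s <- tryCatch({
      if (method == "kmeans") kmeans_segment(sp[sub, , drop = FALSE], k, seed = derive_subseed(seed, k))
      else fcm_segment(sp[sub, , drop = FALSE], k, seed = derive_subseed(seed, k))
    }, error = function(e) NULL)
    if (is.null(s)) next
    v <- tryCatch(validity_measure(s, sp[sub, , drop = FALSE], params),
                  error = function(e) NULL)
    if (is.null(v)) next
    recs[[length(recs) + 1L]] <- v
    segs[[length(segs) + 1L]] <- s
  }
  if (!length(recs)) stop("no valid segmentation in the k range")
  curve <- do.call(rbind, lapply(recs, as.data.frame))
  best <- which.min(curve$vm)
  seg <- segs[[best]]
  # assign every pixel to the nearest centre of the winning model
  centres <- as.matrix(seg$centres)
  d2 <- sapply(seq_len(nrow(centres)), function(j) rowSums(sweep(sp, 2, centres[j, ])^2))
  labels <- max.col(-d2)
  memb <- matrix(0, n, nrow(centres))
  memb[cbind(seq_len(n), labels)] <- 1
  full <- structure(list(labels = labels, centres = centres,
                         membership = if (seg$method == "fcm") NULL else memb,
                         method = seg$method, pixel_count = n),
                    class = "segmentation_result")
  list(seg = full, vm_curve = curve, k_best = curve$k[best], space_pixels = sp)
}
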