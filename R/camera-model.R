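# Camera characterisation: per-channel gamma linearisation from a neutral
# grey ramp, flat-field (vignetting / spatial non-uniformity) correction
# from a uniform grey card, and polynomial regression from linearised RGB
# to CIEXYZ with colour-difference-driven model selection.

#' Estimate per-channel gamma from grey-patch responses
#'
#' Fits `value = luminance^(1/gamma)` per channel in the log-log domain by
#' least squares (an intercept absorbs any constant gain), so linearisation
#' applies `value^gamma`.
#'
#' @param grey_rgb n x 3 matrix of mean RGB values of neutral patches,
#'   components in `(0, 1]`.
#' @param grey_luminance length-n reference relative luminances in `(0, 1]`.
#' @return object of class `gamma_fit`: `gamma_rgb`, `fit_residual` (RMS of
#'   the log-domain residuals across channels).
#' @export
estimate_gamma <- function(grey_rgb, grey_luminance) {
  grey_rgb <- as.matrix(grey_rgb)
  ok <- grey_luminance > 0 & apply(grey_rgb > 0, 1, all)
  if (sum(ok) < 3L) stop("need >= 3 grey patches with nonzero values")
  if (length(unique(round(grey_luminance[ok], 12))) < 3L) {
    stop("grey luminances must be distinct")
  }
  lx <- log(grey_luminance[ok])
  gam <- numeric(3); res <- numeric(3)
  for (ch in 1:3) {
    ly <- log(grey_rgb[ok, ch])
    fit <- stats::lm.fit(cbind(1, lx), ly)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope <= 0) stop("degenerate gamma fit")
    gam[ch] <- 1 / slope
    res[ch] <- sqrt(mean(fit$residuals^2))
  }
  structure(list(gamma_rgb = gam, fit_residual = sqrt(mean(res^2))),
            class = "gamma_fit")
}

#' Linearise camera values with a fitted gamma
#' @param img RGB image array or n x 3 matrix.
#' @param gamma a [estimate_gamma()] result (or numeric length 3).
#' @export
apply_gamma <- function(img, gamma) {
  g <- if (inherits(gamma, "gamma_fit")) gamma$gamma_rgb else gamma
  if (is.matrix(img)) return(sweep(img, 2, g, "^"))
  assert_rgb_image(img)
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch]^g[ch]
  out
}

#' Fit a flat-field (spatial non-uniformity) correction from a grey card
#'
#' The card is smoothed by a low-order polynomial surface fit per channel
#' (noise would otherwise be amplified by the ratio, and unlike a boundary
#' convolution the surface has no edge bias, so a purely radial falloff is
#' recovered exactly); the per-pixel multiplicative gain is
#' `gain(x, y, ch) = mean_ch / smoothed(x, y, ch)` and the three channel
#' means are the calibration constants.
#'
#' @param grey_card RGB image of a uniform card.
#' @param degree polynomial surface degree (default 4).
#' @return object of class `flat_field`: `gain_map` (H x W x 3),
#'   `calibration_constants` (3).
#' @export
fit_flat_field <- function(grey_card, degree = 4L) {
  assert_rgb_image(grey_card)
  h <- dim(grey_card)[1]; w <- dim(grey_card)[2]
  yy <- (seq_len(h) - (h + 1) / 2) / h
  xx <- (seq_len(w) - (w + 1) / 2) / w
  g <- expand.grid(y = yy, x = xx)
  exps <- expand.grid(p = 0:degree, q = 0:degree)
  exps <- exps[exps$p + exps$q <= degree, ]
  basis <- mapply(function(p, q) g$x^p * g$y^q, exps$p, exps$q)
  qr_b <- qr(basis)
  sm <- grey_card
  for (ch in 1:3) {
    beta <- qr.coef(qr_b, as.vector(grey_card[, , ch]))
    sm[, , ch] <- matrix(basis %*% beta, h, w)
  }
  if (any(sm <= 0)) stop("numeric-error: grey card has zeros after smoothing")
  means <- apply(sm, 3, mean)
  gain <- sm
  for (ch in 1:3) gain[, , ch] <- means[ch] / sm[, , ch]
  structure(list(gain_map = gain, calibration_constants = means),
            class = "flat_field")
}

#' @rdname fit_flat_field
#' @param img image to correct (same shape as the card).
#' @param ff a `flat_field`.
#' @export
apply_flat_field <- function(img, ff) {
  if (!all(dim(img) == dim(ff$gain_map))) stop("shape mismatch with gain map")
  img * ff$gain_map
}

# --- polynomial model -------------------------------------------------------

#' Polynomial term-set presets
#'
#' Ordered exponent triples `(p, q, r)` defining augmented terms
#' `R^p G^q B^r` (the constant term is `(0, 0, 0)`).  Presets follow the
#' usual augmented-polynomial families used in camera characterisation:
#' `linear3`, `poly5`, `poly8`, `poly11` and the full degree-<=3 monomial
#' basis `poly20`.  Custom sets are plain integer matrices.
#'
#' @param name preset name.
#' @return integer matrix with columns `p`, `q`, `r`.
#' @export
term_set_preset <- function(name = c("linear3", "poly5", "poly8", "poly11", "poly20")) {
  name <- match.arg(name)
  t3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  cross <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  sq <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  rgb1 <- c(1, 1, 1)
  one <- c(0, 0, 0)
  m <- switch(name,
    linear3 = t3,
    poly5 = rbind(t3, rgb1, one),
    poly8 = rbind(t3, cross, rgb1, one),
    poly11 = rbind(t3, cross, sq, rgb1, one),
    poly20 = {
      g <- expand.grid(p = 0:3, q = 0:3, r = 0:3)
      g <- g[rowSums(g) <= 3, ]
      g <- g[order(rowSums(g), -g$p, -g$q), ]
      as.matrix(g)
    })
  m <- unname(as.matrix(m))
  storage.mode(m) <- "integer"
  colnames(m) <- c("p", "q", "r")
  m
}

#' Build the augmented term vector(s) for a term set
#'
#' @param rgb length-3 linearised RGB triple or n x 3 matrix.
#' @param term_set integer matrix of exponent triples.
#' @return numeric vector (or n x n_terms matrix) with element
#'   `i = R^p_i G^q_i B^r_i`.
#' @export
build_term_vector <- function(rgb, term_set) {
  if (is.null(dim(term_set)) || nrow(term_set) == 0L) stop("term_set must be nonempty")
  v <- if (is.matrix(rgb)) rgb else matrix(rgb, 1)
  out <- sapply(seq_len(nrow(term_set)), function(i) {
    v[, 1]^term_set[i, 1] * v[, 2]^term_set[i, 2] * v[, 3]^term_set[i, 3]
  })
  if (is.matrix(rgb)) matrix(out, nrow = nrow(v)) else unname(drop(out))
}

#' Fit a polynomial camera model
#'
#' Per-XYZ-channel least squares of reference tristimulus on the augmented
#' RGB terms, with the model's training quality summarised as the median
#' CIE76 colour difference over the fitted patches.
#'
#' @param patch_rgb n x 3 matrix of linearised, flat-fielded patch means.
#' @param patch_xyz n x 3 matrix of reference tristimulus values.
#' @param term_set exponent-triple matrix (see [term_set_preset()]).
#' @param white reference white for the Lab conversion.
#' @return object of class `poly_camera_model`: `term_set`, `coeffs`
#'   (3 x n_terms), `n_terms`, `median_dE`.
#' @export
fit_poly_model <- function(patch_rgb, patch_xyz, term_set, white = D65_WHITE) {
  patch_rgb <- as.matrix(patch_rgb); patch_xyz <- as.matrix(patch_xyz)
  n <- nrow(patch_rgb)
  if (n < nrow(term_set)) stop("need n >= number of terms (got n = ", n, ")")
  a_mat <- build_term_vector(patch_rgb, term_set)
  qr_a <- qr(a_mat)
  if (qr_a$rank < ncol(a_mat)) {
    stop("numeric-error: rank-deficient design; remove terms or add patches")
  }
  coeffs <- unname(t(qr.coef(qr_a, patch_xyz)))  # 3 x n_terms
  pred <- a_mat %*% t(coeffs)
  de <- delta_e_ab(xyz_to_lab(pred, white), xyz_to_lab(patch_xyz, white))
  structure(list(term_set = term_set, coeffs = coeffs,
                 n_terms = nrow(term_set), median_dE = stats::median(de)),
            class = "poly_camera_model")
}

#' Select the best model by median colour difference
#'
#' Argmin of `median_dE`; ties go to the model with fewer terms.
#'
#' @param candidates nonempty list of `poly_camera_model`s.
#' @export
select_model <- function(candidates) {
  if (length(candidates) == 0L) stop("empty candidate list")
  de <- vapply(candidates, function(m) m$median_dE, numeric(1))
  nt <- vapply(candidates, function(m) m$n_terms, numeric(1))
  candidates[[order(de, nt)[1]]]
}

#' Apply the full camera model to an image
#'
#' Pipeline order: gamma-linearise, flat-field multiply, per-pixel
#' augmented term vector, coefficient product.  The flat field must have
#' been fitted on a linearised grey card for the correction to be exact.
#'
#' @param image RGB image.
#' @param gamma `gamma_fit` (or NULL to skip).
#' @param ff `flat_field` (or NULL to skip).
#' @param model `poly_camera_model`.
#' @return H x W x 3 XYZ image (white `Y = 100` scale).
#' @export
apply_camera_model <- function(image, gamma, ff, model) {
  assert_rgb_image(image)
  lin <- if (is.null(gamma)) image else apply_gamma(image, gamma)
  if (!is.null(ff)) lin <- apply_flat_field(lin, ff)
  d <- dim(lin)
  px <- matrix(lin, d[1] * d[2], 3L)
  xyz <- build_term_vector(px, model$term_set) %*% t(model$coeffs)
  array(xyz, d)
}

#' Characterise a simulated or real camera from chart + grey card imagery
#'
#' Order of operations: (1) estimate an encoded-domain flat field from the
#' grey card and divide it out of the chart (vignetting acts
#' multiplicatively on the encoded values); (2) estimate per-channel gamma
#' from the neutral ramp; (3) fit the linear-domain flat field on the
#' linearised grey card; (4) fit polynomial models on linearised,
#' flat-fielded patch means and keep the median-dE minimiser.
#'
#' @param chart_img chart image (camera output).
#' @param grey_card grey card image (camera output).
#' @param layout chart layout (from [chart_layout()] / render truth).
#' @param ref_xyz n x 3 reference tristimulus per patch.
#' @param grey_idx indices of the neutral ramp patches.
#' @param grey_luminance reference relative luminances of those patches.
#' @param term_sets list of term-set matrices to try.
#' @param patch_frac central fraction of each patch cell used for means.
#' @return list `gamma`, `ff` (linear-domain flat field), `model`,
#'   `candidates`, `patch_rgb_lin`.
#' @export
characterise_camera <- function(chart_img, grey_card, layout, ref_xyz,
                                grey_idx = 1:6,
                                grey_luminance = NULL,
                                term_sets = list(term_set_preset("linear3"),
                                                 term_set_preset("poly5"),
                                                 term_set_preset("poly8"),
                                                 term_set_preset("poly11"),
                                                 term_set_preset("poly20")),
                                patch_frac = 0.5) {
  ff_enc <- fit_flat_field(grey_card)
  # normalised encoded-domain gain (unit mean) so chart exposure is kept
  gain_enc <- ff_enc$gain_map
  for (ch in 1:3) gain_enc[, , ch] <- gain_enc[, , ch] / mean(gain_enc[, , ch])
  chart_flat <- chart_img * gain_enc
  means <- chart_patch_means(chart_flat, layout, patch_frac)
  if (is.null(grey_luminance)) grey_luminance <- ref_xyz[grey_idx, 2] / 100
  gamma <- estimate_gamma(means[grey_idx, , drop = FALSE], grey_luminance)
  ff_lin <- fit_flat_field(apply_gamma(grey_card, gamma))
  chart_lin <- apply_flat_field(apply_gamma(chart_img, gamma), ff_lin)
  means_lin <- chart_patch_means(chart_lin, layout, patch_frac)
  candidates <- lapply(term_sets, function(ts) {
    tryCatch(fit_poly_model(means_lin, ref_xyz, ts), error = function(e) NULL)
  })
  candidates <- Filter(Negate(is.null), candidates)
  if (!length(candidates)) stop("no polynomial model could be fitted")
  list(gamma = gamma, ff = ff_lin, model = select_model(candidates),
       candidates = candidates, patch_rgb_lin = means_lin)
}

#' Mean RGB of each chart patch
#'
#' Means are taken over the central `frac` of each patch cell to avoid
#' edge bleed.
#'
#' @param img chart image.
#' @param layout chart layout list (with `boxes`).
#' @param frac central fraction of the cell, `(0, 1]`.
#' @return n x 3 matrix of patch means.
#' @export
chart_patch_means <- function(img, layout, frac = 0.5) {
  t(vapply(layout$boxes, function(b) {
    rh <- b$r1 - b$r0; cw <- b$c1 - b$c0
    sh <- (1 - frac) / 2
    rr <- round(b$r0 + sh * rh):round(b$r1 - sh * rh)
    cc <- round(b$c0 + sh * cw):round(b$c1 - sh * cw)
    c(mean(img[rr, cc, 1]), mean(img[rr, cc, 2]), mean(img[rr, cc, 3]))
  }, numeric(3)))
}

#' Serialise / restore a camera model bundle as JSON
#'
#' The gain map is stored inline (row-major, 32-bit precision is ample for
#' a smooth field) so the whole characterisation travels in one file.
#'
#' @param chr result of [characterise_camera()].
#' @param path JSON path.
#' @export
write_camera_model <- function(chr, path) {
  gm <- chr$ff$gain_map
  jsonlite::write_json(list(
    gamma_rgb = chr$gamma$gamma_rgb,
    fit_residual = chr$gamma$fit_residual,
    calibration_constants = chr$ff$calibration_constants,
    gain_dim = dim(gm),
    gain_map = signif(as.numeric(gm), 7),
    term_set = unname(chr$model$term_set),
    coeffs = unname(chr$model$coeffs),
    median_dE = chr$model$median_dE), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_model
#' @export
read_camera_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- as.matrix(j$term_set); storage.mode(ts) <- "integer"
  list(
    gamma = structure(list(gamma_rgb = j$gamma_rgb, fit_residual = j$fit_residual),
                      class = "gamma_fit"),
    ff = structure(list(gain_map = array(j$gain_map, j$gain_dim),
                        calibration_constants = j$calibration_constants),
                   class = "flat_field"),
    model = structure(list(term_set = ts, coeffs = as.matrix(j$coeffs),
                           n_terms = nrow(ts), median_dE = j$median_dE),
                      class = "poly_camera_model"))
}
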