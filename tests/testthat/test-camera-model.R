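test_that("gamma is recovered exactly in the noiseless cases", {
  lum <- c(0.9, 0.59, 0.36, 0.2, 0.09, 0.03)
  greys <- matrix(rep(lum^(1 / 2.2), 3), ncol = 3)
  fit <- estimate_gamma(greys, lum)
  expect_equal(fit$gamma_rgb, rep(2.2, 3), tolerance = 1e-6)
  # identity camera
  fit1 <- estimate_gamma(matrix(rep(lum, 3), ncol = 3), lum)
  expect_equal(fit1$gamma_rgb, rep(1, 3), tolerance = 1e-6)
  expect_lt(fit1$fit_residual, 1e-9)
  expect_error(estimate_gamma(greys[1:2, ], lum[1:2]), ">= 3")
})

test_that("gamma recovery tolerates sensor noise", {
  errs <- vapply(1:12, function(i) {
    cam <- identity_camera(gamma_rgb = c(1.9, 2.1, 2.3), noise_sd = 0.005,
                           seed = i, size = 160L)
    ch <- render_chart(cam)
    means <- chart_patch_means(ch$img, ch$truth$layout)
    fit <- estimate_gamma(means[1:6, ], ch$truth$grey_luminance)
    max(abs(fit$gamma_rgb - c(1.9, 2.1, 2.3)))
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("flat-field correction flattens a vignetted card", {
  card <- render_grey_card(identity_camera(vignette_strength = 0.3, size = 128L))
  ff <- fit_flat_field(card)
  corrected <- apply_flat_field(card, ff)
  expect_lt(max(corrected) / min(corrected), 1.001)
  expect_equal(ff$calibration_constants, apply(card, 3, mean), tolerance = 1e-6)
  # no vignetting: gain is 1 everywhere
  flat <- render_grey_card(identity_camera(size = 96L))
  expect_lt(max(abs(fit_flat_field(flat)$gain_map - 1)), 1e-6)
})

test_that("term vectors are plain monomials", {
  ts <- rbind(c(1, 0, 0), c(2, 0, 0), c(0, 0, 0))
  expect_equal(build_term_vector(c(0.5, 1, 1), ts), c(0.5, 0.25, 1))
  expect_equal(build_term_vector(c(1, 1, 1), term_set_preset("poly20")),
               rep(1, 20))
  # permuting the term order permutes the vector identically
  p <- c(3, 1, 2)
  expect_equal(build_term_vector(c(0.3, 0.7, 0.2), ts[p, ]),
               build_term_vector(c(0.3, 0.7, 0.2), ts)[p])
  expect_equal(nrow(term_set_preset("poly11")), 11)
})

test_that("a linear camera is inverted exactly by the 3-term model", {
  cam <- identity_camera(mix_matrix = default_mix_matrix(), size = 192L)
  ch <- render_chart(cam)
  gc_img <- render_grey_card(cam)
  chr <- characterise_camera(ch$img, gc_img, ch$truth$layout, ch$truth$chart_xyz,
                             grey_luminance = ch$truth$grey_luminance,
                             term_sets = list(term_set_preset("linear3")))
  expect_lt(chr$model$median_dE, 1e-6)
  # recovered transform equals reference matrix composed with mix inverse
  want <- unname(holoquant:::SRGB_TO_XYZ %*% solve(default_mix_matrix()) * 100)
  got <- unname(chr$model$coeffs)
  # characterisation rescales values; compare up to the per-channel gain
  s <- want[1, 1] / got[1, 1]
  expect_equal(got * s, want, tolerance = 1e-4)
})

test_that("richer term sets do not fit worse on a nonlinear camera", {
  cam <- identity_camera(gamma_rgb = c(1.8, 2.0, 2.2),
                         mix_matrix = default_mix_matrix(), size = 192L)
  ch <- render_chart(cam)
  means <- chart_patch_means(ch$img, ch$truth$layout)
  # deliberately skip linearisation so the polynomial must absorb the curve
  m3 <- fit_poly_model(means, ch$truth$chart_xyz, term_set_preset("linear3"))
  m20 <- fit_poly_model(means, ch$truth$chart_xyz, term_set_preset("poly20"))
  expect_lte(m20$median_dE, m3$median_dE)
})

test_that("duplicated patches do not change the least-squares solution", {
  set.seed(5)
  rgb <- matrix(runif(36, 0.1, 0.9), 12, 3)
  xyz <- linear_rgb_to_xyz(rgb)
  m1 <- fit_poly_model(rgb, xyz, term_set_preset("poly5"))
  m2 <- fit_poly_model(rbind(rgb, rgb), rbind(xyz, xyz), term_set_preset("poly5"))
  expect_equal(m1$coeffs, m2$coeffs, tolerance = 1e-9)
})

test_that("model selection minimises median dE with a fewest-terms tie rule", {
  mk <- function(de, nt) structure(list(median_dE = de, n_terms = nt),
                                   class = "poly_camera_model")
  expect_equal(select_model(list(mk(5, 3)))$median_dE, 5)
  expect_equal(select_model(list(mk(5, 3), mk(2, 8), mk(3, 11)))$median_dE, 2)
  expect_equal(select_model(list(mk(2, 11), mk(2, 3)))$n_terms, 3)
  # permutation invariance
  cand <- list(mk(4, 5), mk(1, 8), mk(9, 3))
  expect_equal(select_model(cand)$median_dE, select_model(rev(cand))$median_dE)
  expect_error(select_model(list()), "empty")
})

test_that("full characterisation recovers simulator cameras", {
  set.seed(60)
  worst_gamma <- 0
  de_holdout <- numeric(0)
  for (i in 1:10) {
    g <- runif(3, 1.5, 2.5)
    cam <- camera_sim_config(gamma_rgb = g, vignette_strength = runif(1, 0, 0.4),
                             noise_sd = runif(1, 0, 0.005), seed = i, size = 192L)
    ch <- render_chart(cam)
    gc_img <- render_grey_card(cam)
    chr <- characterise_camera(ch$img, gc_img, ch$truth$layout,
                               ch$truth$chart_xyz,
                               grey_luminance = ch$truth$grey_luminance)
    worst_gamma <- max(worst_gamma, max(abs(chr$gamma$gamma_rgb - g) / g))
    # held-out patches: fresh chart with extra patches not used in the fit
    ch2 <- render_chart(cam, n_patches = 30L)
    lin <- apply_flat_field(apply_gamma(ch2$img, chr$gamma), chr$ff)
    means <- chart_patch_means(lin, ch2$truth$layout)
    hold <- 25:30
    pred <- build_term_vector(means[hold, ], chr$model$term_set) %*% t(chr$model$coeffs)
    de_holdout <- c(de_holdout,
                    stats::median(delta_e_ab(xyz_to_lab(pred),
                                             xyz_to_lab(ch2$truth$chart_xyz[hold, ]))))
  }
  expect_lt(worst_gamma, 0.03)
  expect_lt(stats::median(de_holdout), 2)
})

test_that("applying the camera model recovers scene colour in Lab", {
  cam <- camera_sim_config(seed = 42L, size = 192L)
  ch <- render_chart(cam)
  chr <- characterise_camera(ch$img, render_grey_card(cam), ch$truth$layout,
                             ch$truth$chart_xyz,
                             grey_luminance = ch$truth$grey_luminance)
  sc <- render_scene(cam, 4.5, clutter_level = 0, scene_id = 1L)
  xyz_img <- apply_camera_model(sc$img, chr$gamma, chr$ff, chr$model)
  px_xyz <- matrix(xyz_img, 192 * 192, 3)
  roi <- as.vector(sc$truth$roi_mask)
  got <- xyz_to_lab(colMeans(px_xyz[roi, ]))
  want <- xyz_to_lab(linear_rgb_to_xyz(holoquant:::hue_to_rgb(sc$truth$true_hue_deg)))
  expect_lt(delta_e_ab(got, want), 3)
  # constant image maps to a constant XYZ image
  const <- array(0.4, c(8, 8, 3))
  out <- apply_camera_model(const, NULL, NULL, chr$model)
  expect_lt(max(apply(out, 3, function(m) diff(range(m)))), 1e-12)
})

test_that("camera model bundle survives a JSON round trip", {
  cam <- camera_sim_config(seed = 8L, size = 128L)
  ch <- render_chart(cam)
  chr <- characterise_camera(ch$img, render_grey_card(cam), ch$truth$layout,
                             ch$truth$chart_xyz,
                             grey_luminance = ch$truth$grey_luminance)
  path <- file.path(tempdir(), "camera_rt.json")
  write_camera_model(chr, path)
  back <- read_camera_model(path)
  expect_equal(back$gamma$gamma_rgb, chr$gamma$gamma_rgb, tolerance = 1e-9)
  expect_equal(back$model$coeffs, unname(chr$model$coeffs), tolerance = 1e-9)
  expect_equal(back$ff$gain_map, chr$ff$gain_map, tolerance = 1e-5)
  unlink(path)
})
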