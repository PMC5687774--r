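# Scene/camera simulator.  Provides fully ground-truthed stand-ins for the
# physical test imagery: a colour chart with known reference XYZ, an 18%-grey
# balance card, and cluttered scenes containing a QR-style fiducial with a
# central circular "hologram" patch whose hue encodes pH over 3.00-6.50.
#
# Forward camera model per pixel:
#   out = clip( vignette(x, y) * (Mix %*% reflectance)^(1 / gamma) + noise )
# with per-channel gamma, an off-diagonal sensor mixing matrix, radial
# vignetting and i.i.d. additive Gaussian noise clipped to [0, 1].

#' Camera simulator configuration
#'
#' Defaults mirror the characterised handset of the study conditions:
#' per-channel gamma exponents (1.987, 1.899, 1.791), mild sensor channel
#' mixing, moderate vignetting and low additive noise.
#'
#' @param gamma_rgb three positive gamma exponents.
#' @param vignette_strength corner falloff fraction in `[0, 1)`.
#' @param mix_matrix nonsingular 3 x 3 sensor mixing matrix.
#' @param noise_sd additive Gaussian noise SD in channel units (>= 0).
#' @param seed integer RNG seed; identical seeds render bit-identically.
#' @param size default rendered image side in pixels.
#' @return object of class `camera_sim_config`.
#' @export
camera_sim_config <- function(gamma_rgb = c(1.987, 1.899, 1.791),
                              vignette_strength = 0.2,
                              mix_matrix = default_mix_matrix(),
                              noise_sd = 0.003,
                              seed = 1L,
                              size = 512L) {
  if (length(gamma_rgb) != 3L || any(gamma_rgb <= 0)) {
    stop("gamma_rgb must be three positive exponents")
  }
  if (vignette_strength < 0 || vignette_strength >= 1) {
    stop("vignette_strength must lie in [0, 1)")
  }
  if (!is.matrix(mix_matrix) || any(dim(mix_matrix) != 3L) ||
      abs(det(mix_matrix)) < 1e-10) {
    stop("mix_matrix must be a nonsingular 3 x 3 matrix")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(gamma_rgb = gamma_rgb,
                 vignette_strength = vignette_strength,
                 mix_matrix = mix_matrix,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 size = as.integer(size)),
            class = "camera_sim_config")
}

#' @rdname camera_sim_config
#' @export
default_mix_matrix <- function() {
  matrix(c(0.86, 0.09, 0.05,
           0.07, 0.85, 0.08,
           0.04, 0.09, 0.87), 3, 3, byrow = TRUE)
}

#' Identity camera (no gamma, mixing, vignetting or noise)
#' @param ... overrides passed to [camera_sim_config()].
#' @export
identity_camera <- function(...) {
  args <- utils::modifyList(list(gamma_rgb = c(1, 1, 1), vignette_strength = 0,
                                 mix_matrix = diag(3), noise_sd = 0),
                            list(...))
  do.call(camera_sim_config, args)
}

vignette_field <- function(h, w, strength) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rmax2 <- (h - cy)^2 + (w - cx)^2
  r2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
  1 - strength * r2 / rmax2
}

# Push a linear-reflectance image through the simulated camera.
camera_forward <- function(reflectance, config, rng_offset = 0L) {
  h <- dim(reflectance)[1]; w <- dim(reflectance)[2]
  px <- matrix(reflectance, h * w, 3L)
  mixed <- px %*% t(config$mix_matrix)
  mixed[mixed < 0] <- 0
  enc <- sweep(mixed, 2, 1 / config$gamma_rgb, "^")
  out <- array(enc, c(h, w, 3L))
  if (config$vignette_strength > 0) {
    v <- vignette_field(h, w, config$vignette_strength)
    for (ch in 1:3) out[, , ch] <- out[, , ch] * v
  }
  if (config$noise_sd > 0) {
    set.seed(derive_subseed(config$seed, 777L, rng_offset))
    out <- out + array(rnorm(h * w * 3L, 0, config$noise_sd), c(h, w, 3L))
  }
  clip01(out)
}

# --- pH <-> hue map ---------------------------------------------------------

#' Hue encoding of pH
#'
#' Piecewise-linear monotone map from pH in `[3, 6.5]` to hue in degrees,
#' descending from blue (240 deg at pH 3.00) through green to red (0 deg at
#' pH 6.50), steeper below pH 5 to mimic the sigmoidal swelling response.
#'
#' @param ph numeric pH values in `[3, 6.5]`.
#' @return hue in degrees.
#' @export
ph_to_hue <- function(ph) {
  if (any(ph < 3 - 1e-9 | ph > 6.5 + 1e-9)) stop("ph must lie in [3.00, 6.50]")
  ifelse(ph <= 5,
         240 - (240 - 100) * (ph - 3) / 2,
         100 - 100 * (ph - 5) / 1.5)
}

hue_to_rgb <- function(hue_deg, s = 0.85, v = 0.8) {
  hue_deg <- ((hue_deg %% 360) + 360) %% 360
  drop(col2rgb(hsv(hue_deg / 360, s, v))) / 255
}

# --- QR-style fiducial ------------------------------------------------------

QR_MODULES <- 25L
QR_QUIET <- 2L

# Deterministic binary module matrix: three finder squares, pseudo-random
# payload pattern, reserved black central space (7 x 7 modules).
qr_module_matrix <- function() {
  n <- QR_MODULES
  m <- matrix(1, n, n)
  finder <- matrix(1, 7, 7)
  finder[c(1, 7), ] <- 0; finder[, c(1, 7)] <- 0
  finder[3:5, 3:5] <- 0
  m[1:7, 1:7] <- finder
  m[1:7, (n - 6):n] <- finder
  m[(n - 6):n, 1:7] <- finder
  idx <- which(m == 1, arr.ind = TRUE)
  keep <- !(idx[, 1] <= 8 & idx[, 2] <= 8) &
    !(idx[, 1] <= 8 & idx[, 2] >= n - 7) &
    !(idx[, 1] >= n - 7 & idx[, 2] <= 8)
  payload <- idx[keep, , drop = FALSE]
  bits <- (payload[, 1] * 7 + payload[, 2] * 11 + payload[, 1] * payload[, 2]) %% 3
  m[payload] <- ifelse(bits == 0, 0, 1)
  ctr <- (n + 1) / 2
  m[(ctr - 3):(ctr + 3), (ctr - 3):(ctr + 3)] <- 0
  m
}

#' Render the fiducial template
#'
#' QR-style binary target with a reserved black central space; when `ph` (or
#' `hue_deg`) is given a circular hologram patch of that hue fills the
#' centre.  Returned mask marks hologram pixels.
#'
#' @param size_px template side in pixels.
#' @param ph optional pH whose mapped hue colours the hologram.
#' @param hue_deg optional explicit hue (overrides `ph`).
#' @return list with `img` (RGB array), `mask` (logical matrix),
#'   `centre` (x, y), `radius_px`.
#' @export
qr_template <- function(size_px = 232L, ph = NULL, hue_deg = NULL) {
  n_tot <- QR_MODULES + 2L * QR_QUIET
  mod <- matrix(1, n_tot, n_tot)
  mod[(QR_QUIET + 1):(QR_QUIET + QR_MODULES),
      (QR_QUIET + 1):(QR_QUIET + QR_MODULES)] <- qr_module_matrix()
  pix_mod <- floor((seq_len(size_px) - 1) / size_px * n_tot) + 1L
  grey <- mod[pix_mod, pix_mod]
  img <- array(rep(grey, 3L), c(size_px, size_px, 3L))
  ctr <- (size_px + 1) / 2
  radius <- 3.1 / n_tot * size_px
  mask <- matrix(FALSE, size_px, size_px)
  if (!is.null(ph) || !is.null(hue_deg)) {
    if (is.null(hue_deg)) hue_deg <- ph_to_hue(ph)
    col3 <- hue_to_rgb(hue_deg)
    d2 <- outer((seq_len(size_px) - ctr)^2, (seq_len(size_px) - ctr)^2, "+")
    mask <- d2 <= radius^2
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[mask] <- col3[ch]
      img[, , ch] <- pl
    }
  }
  list(img = img, mask = mask, centre = c(ctr, ctr), radius_px = radius)
}

# --- chart ------------------------------------------------------------------

chart_grey_levels <- c(0.90, 0.59, 0.36, 0.20, 0.09, 0.03)

chart_colour_set <- function(n_colour) {
  base <- rbind(
    c(0.45, 0.32, 0.27), c(0.76, 0.59, 0.51), c(0.38, 0.48, 0.61),
    c(0.34, 0.42, 0.26), c(0.52, 0.50, 0.69), c(0.40, 0.74, 0.67),
    c(0.85, 0.49, 0.16), c(0.28, 0.36, 0.65), c(0.76, 0.35, 0.38),
    c(0.36, 0.23, 0.42), c(0.62, 0.73, 0.25), c(0.90, 0.63, 0.18),
    c(0.20, 0.24, 0.59), c(0.28, 0.58, 0.29), c(0.69, 0.19, 0.23),
    c(0.93, 0.78, 0.13), c(0.73, 0.34, 0.58), c(0.17, 0.52, 0.63))
  if (n_colour <= nrow(base)) return(base[seq_len(n_colour), , drop = FALSE])
  extra_h <- (seq_len(n_colour - nrow(base)) * 137.508) %% 360
  rbind(base, t(vapply(extra_h, hue_to_rgb, numeric(3), s = 0.6, v = 0.55)))
}

#' Chart patch grid layout
#'
#' @param n_patches number of patches.
#' @param size image side in pixels.
#' @return list of per-patch cell boxes (`r0`, `r1`, `c0`, `c1`, 1-based
#'   inclusive) in row-major order, plus grid dims.
#' @export
chart_layout <- function(n_patches, size) {
  nc <- ceiling(sqrt(n_patches * 1.5))
  nr <- ceiling(n_patches / nc)
  margin <- round(size * 0.08)
  cw <- (size - 2 * margin) / nc
  ch <- (size - 2 * margin) / nr
  boxes <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    r <- (i - 1) %/% nc; c <- (i - 1) %% nc
    boxes[[i]] <- list(
      r0 = round(margin + r * ch + 0.12 * ch), r1 = round(margin + (r + 1) * ch - 0.12 * ch),
      c0 = round(margin + c * cw + 0.12 * cw), c1 = round(margin + (c + 1) * cw - 0.12 * cw))
  }
  list(boxes = boxes, nr = nr, nc = nc)
}

#' Render a reference colour chart through the simulated camera
#'
#' The first six patches are a neutral grey ramp (needed for gamma
#' estimation); the remainder are fixed chromatic patches.  Reference XYZ
#' per patch is derived from the known linear reflectance.
#'
#' @param config a [camera_sim_config()].
#' @param n_patches number of patches (>= 6).
#' @return list `img` (RGB array) and `truth` containing `chart_xyz`
#'   (n x 3), `reflectance` (n x 3 linear RGB), `layout`, `grey_idx`.
#' @export
render_chart <- function(config, n_patches = 24L) {
  if (n_patches < 6L) stop("n_patches must be >= 6 (grey ramp required)")
  size <- config$size
  refl <- rbind(matrix(rep(chart_grey_levels, 3L), ncol = 3L),
                chart_colour_set(n_patches - 6L))
  refl <- refl[seq_len(n_patches), , drop = FALSE]
  lay <- chart_layout(n_patches, size)
  scene <- array(0.25, c(size, size, 3L))
  for (i in seq_len(n_patches)) {
    b <- lay$boxes[[i]]
    # paint the full cell (pre-inset box grown back out)
    rr <- max(1, b$r0 - round(0.12 * (b$r1 - b$r0))):min(size, b$r1 + round(0.12 * (b$r1 - b$r0)))
    cc <- max(1, b$c0 - round(0.12 * (b$c1 - b$c0))):min(size, b$c1 + round(0.12 * (b$c1 - b$c0)))
    for (ch in 1:3) scene[rr, cc, ch] <- refl[i, ch]
  }
  img <- camera_forward(scene, config, rng_offset = 11L)
  list(img = img,
       truth = list(chart_xyz = linear_rgb_to_xyz(refl),
                    reflectance = refl, layout = lay, grey_idx = 1:6,
                    grey_luminance = chart_grey_levels[seq_len(min(6, n_patches))]))
}

#' Render a uniform grey balance card
#'
#' @param config a [camera_sim_config()].
#' @param reflectance uniform card reflectance (default 18% grey).
#' @return RGB image whose only spatial structure is vignetting and noise.
#' @export
render_grey_card <- function(config, reflectance = 0.18) {
  scene <- array(reflectance, c(config$size, config$size, 3L))
  camera_forward(scene, config, rng_offset = 13L)
}

# --- scenes -----------------------------------------------------------------

#' Render a cluttered sensor scene through the simulated camera
#'
#' Places the hologram-in-QR fiducial at a random (seeded) similarity
#' transform over a cluttered background with shadow gradients, specular
#' highlights and coloured distractors, then applies the forward camera
#' model.  For `clutter_level > 0.5` one distractor is forced to lie within
#' 20 degrees of the hologram hue (a deliberate hard negative).
#'
#' @param config a [camera_sim_config()].
#' @param ph pH value in `[3.00, 6.50]`.
#' @param clutter_level fraction in `[0, 1]` scaling distractor count and
#'   highlight/shadow strength.
#' @param hue_offset_deg per-sensor hue shift (sensor batch variability).
#' @param scene_id extra integer folded into the RNG stream so distinct
#'   scenes at equal (ph, clutter) differ.
#' @return list `img` and `truth` (`roi_mask`, `quad` as 4 x 2 (x, y)
#'   corners TL/TR/BR/BL, `true_hue_deg`, `true_ph`, `H` template-to-scene
#'   homography, `roi_centre`, `roi_radius`).
#' @export
render_scene <- function(config, ph, clutter_level = 0.3,
                         hue_offset_deg = 0, scene_id = 0L) {
  if (ph < 3 - 1e-9 || ph > 6.5 + 1e-9) stop("ph must lie in [3.00, 6.50]")
  if (clutter_level < 0 || clutter_level > 1) stop("clutter_level must lie in [0, 1]")
  size <- config$size
  set.seed(derive_subseed(config$seed, round(ph * 100), round(clutter_level * 100),
                          scene_id, 991L))
  hue <- ph_to_hue(ph) + hue_offset_deg

  # background reflectance: low-saturation base + shadow ramp + distractors
  base_col <- hue_to_rgb(runif(1, 0, 360), s = 0.12, v = runif(1, 0.45, 0.65))
  scene <- array(rep(base_col, each = size * size), c(size, size, 3L))
  if (clutter_level > 0) {
    # diagonal shadow gradient
    ramp <- outer(seq(0, 1, length.out = size), seq(0, 1, length.out = size), "+") / 2
    shade <- 1 - 0.45 * clutter_level * ramp
    for (ch in 1:3) scene[, , ch] <- scene[, , ch] * shade
    n_obj <- round(8 * clutter_level)
    obj_hues <- runif(n_obj, 0, 360)
    if (clutter_level > 0.5 && n_obj >= 1) {
      obj_hues[1] <- (hue + runif(1, -15, 15)) %% 360
    }
    for (i in seq_len(n_obj)) {
      col3 <- hue_to_rgb(obj_hues[i], s = runif(1, 0.5, 0.9), v = runif(1, 0.4, 0.8))
      cx <- runif(1, 1, size); cy <- runif(1, 1, size)
      rx <- runif(1, 0.03, 0.10) * size; ry <- runif(1, 0.03, 0.10) * size
      rows <- matrix(seq_len(size), size, size)
      cols <- matrix(seq_len(size), size, size, byrow = TRUE)
      inside <- ((cols - cx) / rx)^2 + ((rows - cy) / ry)^2 <= 1
      for (ch in 1:3) {
        pl <- scene[, , ch]; pl[inside] <- col3[ch]; scene[, , ch] <- pl
      }
    }
  }

  # paste fiducial at a random similarity transform
  tpl_size <- round(size * 0.44)
  tpl <- qr_template(tpl_size, hue_deg = hue)
  ang <- runif(1, -25, 25) * pi / 180
  scl <- runif(1, 0.75, 1.05)
  half <- tpl_size * scl * 0.75  # keep quad inside frame
  tx <- runif(1, half, size - half); ty <- runif(1, half, size - half)
  rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2, byrow = TRUE)
  ctr <- (tpl_size + 1) / 2
  hom <- diag(3)
  hom[1:2, 1:2] <- scl * rot
  hom[1:2, 3] <- c(tx, ty) - scl * rot %*% c(ctr, ctr)
  hom_inv <- solve(hom)
  # inverse-warp: for each scene pixel inside the mapped template, sample
  corners_tpl <- cbind(c(1, tpl_size, tpl_size, 1), c(1, 1, tpl_size, tpl_size))
  quad <- apply_homography(hom, corners_tpl)
  rr <- max(1, floor(min(quad[, 2]))):min(size, ceiling(max(quad[, 2])))
  cc <- max(1, floor(min(quad[, 1]))):min(size, ceiling(max(quad[, 1])))
  g <- expand.grid(y = rr, x = cc)
  src <- apply_homography(hom_inv, cbind(g$x, g$y))
  inside <- src[, 1] >= 1 & src[, 1] <= tpl_size & src[, 2] >= 1 & src[, 2] <= tpl_size
  if (any(inside)) {
    samp <- bilinear_img(tpl$img, src[inside, 1], src[inside, 2])
    lin_idx <- (g$x - 1L) * size + g$y
    for (ch in 1:3) {
      pl <- scene[, , ch]
      pl[lin_idx[inside]] <- samp[, ch]
      scene[, , ch] <- pl
    }
  }

  # specular highlights on top
  n_hi <- round(3 * clutter_level)
  for (i in seq_len(n_hi)) {
    cx <- runif(1, 1, size); cy <- runif(1, 1, size)
    sg <- runif(1, 0.02, 0.06) * size
    amp <- runif(1, 0.25, 0.5) * clutter_level
    blob <- amp * exp(-(outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+")) / (2 * sg^2))
    for (ch in 1:3) scene[, , ch] <- scene[, , ch] + blob
  }
  scene <- clip01(scene)

  roi_centre <- drop(apply_homography(hom, matrix(tpl$centre, 1)))
  roi_radius <- tpl$radius_px * scl
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  roi_mask <- (cols - roi_centre[1])^2 + (rows - roi_centre[2])^2 <= roi_radius^2

  img <- camera_forward(scene, config,
                        rng_offset = derive_subseed(round(ph * 100), scene_id))
  list(img = img,
       truth = list(roi_mask = roi_mask, quad = quad,
                    true_hue_deg = ((hue %% 360) + 360) %% 360, true_ph = ph,
                    H = hom, roi_centre = roi_centre, roi_radius = roi_radius,
                    chart_xyz = NULL))
}

# --- sidecar serialisation --------------------------------------------------

rle_encode_mask <- function(mask) {
  r <- rle(as.logical(t(mask)))  # row-major
  list(lengths = r$lengths, values = as.logical(r$values),
       h = nrow(mask), w = ncol(mask))
}

rle_decode_mask <- function(enc) {
  v <- inverse.rle(structure(list(lengths = enc$lengths,
                                  values = as.logical(enc$values)), class = "rle"))
  matrix(v, enc$h, enc$w, byrow = TRUE)
}

#' Write a rendered scene plus its ground-truth JSON sidecar
#'
#' The PNG stores the 8-bit image; the sidecar stores the truth with the
#' ROI mask run-length encoded row-major and the quad as four 0-based
#' `[row, col]` pairs.
#'
#' @param scene list as returned by [render_scene()].
#' @param path output PNG path (sidecar gets `.json` appended).
#' @export
write_scene <- function(scene, path) {
  write_image(scene$img, path)
  tr <- scene$truth
  side <- list(
    roi_mask_rle = rle_encode_mask(tr$roi_mask),
    quad_rc0 = lapply(seq_len(4), function(i) c(tr$quad[i, 2] - 1, tr$quad[i, 1] - 1)),
    true_hue_deg = tr$true_hue_deg, true_ph = tr$true_ph)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  img <- read_image(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  quad <- t(vapply(seq_len(4), function(i) {
    rc <- unlist(side$quad_rc0[i, ])
    c(rc[2] + 1, rc[1] + 1)
  }, numeric(2)))
  list(img = img,
       truth = list(roi_mask = rle_decode_mask(side$roi_mask_rle),
                    quad = quad, true_hue_deg = side$true_hue_deg,
                    true_ph = side$true_ph))
}
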