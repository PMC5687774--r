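# End-to-end orchestration: dataset simulation, camera characterisation,
# localisation, segmentation, recognition, calibration and prediction, with
# a run manifest for reproducibility.

PH_LEVELS <- c(3.00, 4.00, 4.50, 4.75, 5.00, 5.25, 5.50, 5.75, 6.00, 6.25, 6.50)

#' Pipeline configuration
#'
#' @param colour_space working space for segmentation.
#' @param method segmentation method.
#' @param layout central fraction of the rectified fiducial used as the
#'   hologram window.
#' @param window_size rectified window resolution.
#' @param vm [vm_params()] for the window segmentation.
#' @param som_epochs SOM training epochs.
#' @param mlp [mlp_config()].
#' @param n_test_sensors sensors held out for testing.
#' @param seed global seed.
#' @export
pipeline_config <- function(colour_space = "lab", method = "kmeans",
                            layout = 0.26, window_size = 72L,
                            vm = vm_params(k_max = 6L),
                            som_epochs = 25L, mlp = mlp_config(),
                            n_test_sensors = 2L, seed = 1L) {
  list(colour_space = colour_space, method = method, layout = layout,
       window_size = as.integer(window_size), vm = vm,
       som_epochs = as.integer(som_epochs), mlp = mlp,
       n_test_sensors = as.integer(n_test_sensors), seed = as.integer(seed))
}

#' Simulate the full study image set
#'
#' Renders `n_sensors x length(ph_levels)` sensor scenes (66 with the
#' defaults: six sensor batches at eleven pH levels spanning 3.00-6.50)
#' plus the calibration imagery (chart and grey card) through one shared
#' camera.  Each sensor batch carries a small deterministic hue offset
#' emulating batch-to-batch variability.
#'
#' @param seed global seed.
#' @param n_sensors number of sensor batches.
#' @param ph_levels pH levels per sensor.
#' @param clutter_level scene clutter fraction.
#' @param camera optional [camera_sim_config()]; default uses `seed`.
#' @param size image side in pixels.
#' @return list `chart`, `grey_card`, `scenes` (each with `img`, `truth`,
#'   `sensor`, `ph`), `camera`.
#' @export
simulate_dataset <- function(seed = 1L, n_sensors = 6L, ph_levels = PH_LEVELS,
                             clutter_level = 0.3, camera = NULL, size = 512L) {
  if (is.null(camera)) camera <- camera_sim_config(seed = seed, size = size)
  set.seed(derive_subseed(seed, 17L))
  hue_offsets <- stats::rnorm(n_sensors, 0, 2)
  scenes <- list()
  sid <- 0L
  for (s in seq_len(n_sensors)) {
    for (ph in ph_levels) {
      sid <- sid + 1L
      sc <- render_scene(camera, ph, clutter_level,
                         hue_offset_deg = hue_offsets[s],
                         scene_id = sid)
      scenes[[sid]] <- list(img = sc$img, truth = sc$truth,
                            sensor = s, ph = ph)
    }
  }
  list(chart = render_chart(camera), grey_card = render_grey_card(camera),
       scenes = scenes, camera = camera)
}

#' Write a simulated dataset to disk
#'
#' PNG images with JSON truth sidecars, a chart/grey-card pair, the chart
#' reference values as CSV and a manifest.
#'
#' @param out_dir writable directory.
#' @param seed global seed.
#' @param ... passed to [simulate_dataset()].
#' @return invisibly, the directory.
#' @export
demo_dataset <- function(out_dir, seed = 1L, ...) {
  ds <- simulate_dataset(seed = seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "scenes"), showWarnings = FALSE)
  write_image(ds$chart$img, file.path(out_dir, "chart.png"))
  write_image(ds$grey_card, file.path(out_dir, "grey_card.png"))
  refs <- data.frame(patch_id = seq_len(nrow(ds$chart$truth$chart_xyz)),
                     ds$chart$truth$chart_xyz)
  utils::write.csv(refs, file.path(out_dir, "chart_refs.csv"), row.names = FALSE)
  files <- character(0)
  for (sc in ds$scenes) {
    f <- file.path(out_dir, "scenes",
                   sprintf("sensor%02d_ph%.2f.png", sc$sensor, sc$ph))
    write_scene(sc, f)
    files <- c(files, f)
  }
  jsonlite::write_json(list(seed = seed, n_scenes = length(files),
                            files = basename(files),
                            sensors = vapply(ds$scenes, `[[`, 0, "sensor"),
                            ph = vapply(ds$scenes, `[[`, 0, "ph")),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# small FNV-1a content hash for the run manifest
content_hash <- function(obj) {
  b <- as.integer(serialize(obj, NULL))
  h <- 2166136261
  for (chunk in split(b, ceiling(seq_along(b) / 65536))) {
    h <- (h + sum(chunk * (seq_along(chunk) %% 251 + 1))) %% 4294967291
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# Process one scene: locate, rectify, characterised XYZ, segment, describe.
# Returns NULL on no-detection.  Truth (when given) adds the fraction of
# each window segment inside the true ROI, for SOM training labels and IoU.
process_scene <- function(img, template, cam, cfg, truth = NULL, seed = 1L) {
  det <- tryCatch(match_template(img, template, seed = seed),
                  error = function(e) {
                    if (inherits(e, "holoquant_no_detection")) NULL else stop(e)
                  })
  if (is.null(det)) return(NULL)
  roi <- extract_roi_patch(img, det, layout = cfg$layout, out_size = cfg$window_size)
  xyz <- apply_camera_model_window(roi$patch, cam)
  seg_out <- auto_segment(roi$patch, method = cfg$method,
                          colour_space = cfg$colour_space, params = cfg$vm,
                          seed = seed, smooth_sigma = 1, xyz = xyz)
  desc <- segment_descriptors(roi$patch, seg_out$seg, xyz = xyz)
  if (!is.null(truth)) {
    # truth ROI sampled at window pixel positions
    lo <- 0.5 - cfg$layout / 2; hi <- 0.5 + cfg$layout / 2
    uu <- seq(lo, hi, length.out = cfg$window_size)
    g <- expand.grid(v = uu, u = uu)
    pts <- apply_homography(roi$H_unit, cbind(g$u, g$v))
    ri <- pmin(pmax(round(pts[, 2]), 1), nrow(truth$roi_mask))
    ci <- pmin(pmax(round(pts[, 1]), 1), ncol(truth$roi_mask))
    in_roi <- truth$roi_mask[cbind(ri, ci)]
    desc$frac_in_roi <- vapply(desc$segment_id, function(id) {
      mean(in_roi[seg_out$seg$labels == id])
    }, numeric(1))
  }
  list(det = det, roi = roi, seg = seg_out, desc = desc)
}

# Camera model applied to a small window patch: the polynomial acts on
# gamma-linearised values; the flat-field gain is a whole-frame map and is
# approximated by its mean over the frame for a localised window.
apply_camera_model_window <- function(patch, cam) {
  lin <- apply_gamma(patch, cam$gamma)
  gbar <- apply(cam$ff$gain_map, 3, mean)
  for (ch in 1:3) lin[, , ch] <- lin[, , ch] * gbar[ch]
  d <- dim(lin)
  px <- matrix(lin, d[1] * d[2], 3L)
  xyz <- build_term_vector(px, cam$model$term_set) %*% t(cam$model$coeffs)
  array(xyz, d)
}

#' Run the full colour-quantification pipeline on a simulated dataset
#'
#' Characterises the camera from the chart and grey card, locates the
#' fiducial in every scene, segments the rectified hologram window,
#' trains the SOM recogniser on training-sensor segments (labelled by
#' ground-truth overlap), extracts the 9-D descriptor of the recognised
#' hologram segment, trains the MLP calibration on the training sensors
#' and predicts pH for the held-out sensors.
#'
#' @param dataset as returned by [simulate_dataset()].
#' @param cfg [pipeline_config()].
#' @return list `camera`, `som`, `mlp`, `predictions` (data.frame),
#'   `metrics` (held-out `rmse`, `r2`), `iou` (per scene), `detect_rate`,
#'   `manifest`.
#' @export
run_pipeline <- function(dataset, cfg = pipeline_config()) {
  t0 <- proc.time()[3]
  stages <- list()
  ch <- dataset$chart
  cam <- characterise_camera(ch$img, dataset$grey_card, ch$truth$layout,
                             ch$truth$chart_xyz, grey_idx = ch$truth$grey_idx,
                             grey_luminance = ch$truth$grey_luminance)
  stages$characterise <- list(median_dE = cam$model$median_dE,
                              n_terms = cam$model$n_terms,
                              gamma = cam$gamma$gamma_rgb)
  # template sized to the nominal pasted fiducial so the matcher's scale
  # pyramid brackets the rendered scale range
  template <- qr_template(max(96L, round(0.44 * dim(dataset$scenes[[1]]$img)[1])))$img
  sensors <- vapply(dataset$scenes, `[[`, 0, "sensor")
  split <- split_dataset(
    data.frame(sensor = sensors, ph = vapply(dataset$scenes, `[[`, 0, "ph")),
    n_test = cfg$n_test_sensors, seed = cfg$seed)
  test_sensors <- split$test_sensors

  results <- vector("list", length(dataset$scenes))
  iou <- rep(NA_real_, length(dataset$scenes))
  for (i in seq_along(dataset$scenes)) {
    sc <- dataset$scenes[[i]]
    results[[i]] <- process_scene(sc$img, template, cam, cfg,
                                  truth = sc$truth,
                                  seed = derive_subseed(cfg$seed, i))
  }
  detect_rate <- mean(!vapply(results, is.null, logical(1)))

  # SOM training set: window segments of the training sensors
  train_rows <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (is.null(r) || sensors[i] %in% test_sensors) next
    d <- r$desc
    d$label <- ifelse(d$frac_in_roi > 0.5, "hologram", "background")
    train_rows[[length(train_rows) + 1L]] <- d
  }
  som_train_tab <- do.call(rbind, train_rows)
  som <- train_som(as.matrix(som_train_tab[, descriptor_cols()]),
                   som_train_tab$label, epochs = cfg$som_epochs,
                   seed = cfg$seed)

  # recognise ROI in every scene, collect descriptors + IoU
  desc_mat <- matrix(NA_real_, length(results), 9)
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (is.null(r)) next
    cls <- tryCatch(classify_segments(som, r$desc), error = function(e) {
      if (inherits(e, "holoquant_no_roi")) NULL else stop(e)
    })
    if (is.null(cls)) next
    row <- r$desc[r$desc$segment_id == cls$roi_segment_id, ]
    desc_mat[i, ] <- as.numeric(row[1, descriptor_cols()])
    sel <- matrix(r$seg$seg$labels == cls$roi_segment_id,
                  cfg$window_size, cfg$window_size)
    pred_mask <- window_mask_to_scene(sel, r$roi, dim(dataset$scenes[[i]]$img)[1:2],
                                      layout = cfg$layout)
    tm <- dataset$scenes[[i]]$truth$roi_mask
    iou[i] <- sum(pred_mask & tm) / sum(pred_mask | tm)
  }
  stages$recognise <- list(detect_rate = detect_rate,
                           mean_iou = mean(iou, na.rm = TRUE))

  ok <- !is.na(desc_mat[, 1])
  ph <- vapply(dataset$scenes, `[[`, 0, "ph")
  tr <- ok & !(sensors %in% test_sensors)
  te <- ok & (sensors %in% test_sensors)
  mlp <- train_mlp(desc_mat[tr, , drop = FALSE], ph[tr], cfg$mlp)
  ev <- evaluate_mlp(mlp, desc_mat[te, , drop = FALSE], ph[te])
  predictions <- data.frame(scene = which(te), sensor = sensors[te],
                            true_ph = ph[te],
                            predicted_ph = ev$table$predicted_ph)
  manifest <- list(
    config = cfg, test_sensors = test_sensors,
    stages = stages,
    hashes = list(predictions = content_hash(predictions)),
    elapsed_s = unname(proc.time()[3] - t0))
  list(camera = cam, som = som, mlp = mlp, predictions = predictions,
       metrics = list(rmse = ev$rmse, r2 = ev$r2), iou = iou,
       detect_rate = detect_rate, manifest = manifest)
}
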