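# Recognition of the sensor segment: Fisher-style class-separability
# scoring of candidate colour spaces, 9-dimensional hybrid colour
# descriptors per segment, and a calibrated self-organising map that
# labels segments and picks out the hologram.

#' Class separability of a feature set
#'
#' Within-class scatter `Sw = sum_i S_i` with
#' `S_i = sum_{n in C_i} (x_n - M_i)(x_n - M_i)^T`, between-class scatter
#' `Sb = sum_i N_i (M_i - M)(M_i - M)^T` about the size-weighted grand
#' mean.  The default criterion is `J = trace(Sw^-1 Sb)` (scale-invariant
#' Fisher form); `form = "product"` computes the literal `trace(Sb Sw)`.
#'
#' @param features n x d numeric matrix.
#' @param labels class label per row (>= 2 classes, each nonempty).
#' @param form `"inverse"` (default) or `"product"`.
#' @return object of class `separability_report`: `J`, `Sw`, `Sb`,
#'   `class_means`, `grand_mean`, `class_sizes`, `n_classes`.
#' @export
separability <- function(features, labels, form = c("inverse", "product")) {
  form <- match.arg(form)
  x <- as.matrix(features)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2L) stop("need >= 2 classes")
  d <- ncol(x)
  sw <- matrix(0, d, d); sb <- matrix(0, d, d)
  means <- matrix(0, length(cls), d, dimnames = list(cls, colnames(x)))
  sizes <- integer(length(cls))
  for (i in seq_along(cls)) {
    xi <- x[labels == cls[i], , drop = FALSE]
    sizes[i] <- nrow(xi)
    means[i, ] <- colMeans(xi)
    cx <- sweep(xi, 2, means[i, ])
    sw <- sw + t(cx) %*% cx
  }
  grand <- colSums(means * sizes) / sum(sizes)
  for (i in seq_along(cls)) {
    dm <- means[i, ] - grand
    sb <- sb + sizes[i] * tcrossprod(dm)
  }
  j <- if (form == "product") {
    sum(diag(sb %*% sw))
  } else {
    swi <- tryCatch(solve(sw), error = function(e) {
      bad <- cls[sizes <= 1][1]
      stop("singular within-class scatter",
           if (!is.na(bad)) paste0(" (class '", bad, "' has too few members)"))
    })
    sum(diag(swi %*% sb))
  }
  structure(list(J = j, Sw = sw, Sb = sb, class_means = means,
                 grand_mean = grand, class_sizes = sizes, total = sum(sizes),
                 n_classes = length(cls)),
            class = "separability_report")
}

circular_mean_deg <- function(deg, w = NULL) {
  a <- deg * pi / 180
  if (is.null(w)) w <- rep(1, length(a))
  m <- atan2(sum(w * sin(a)), sum(w * cos(a))) * 180 / pi
  ((m %% 360) + 360) %% 360
}

#' Hybrid 9-D colour descriptor of a segment
#'
#' Mean R, G, B, H, S, I, L*, a*, b* over the segment's pixels: RGB/HSI
#' from the (device) RGB image, Lab from the characterised XYZ image; hue
#' is averaged circularly (saturation-weighted).
#'
#' @param rgb_px n x 3 matrix of segment RGB pixel values.
#' @param xyz_px n x 3 matrix of matching tristimulus values (or NULL to
#'   assume sRGB encoding).
#' @return named length-9 numeric vector
#'   `(R, G, B, H, S, I, L, a, b)`.
#' @export
extract_descriptor <- function(rgb_px, xyz_px = NULL) {
  rgb_px <- as.matrix(rgb_px)
  if (nrow(rgb_px) == 0L) stop("empty segment")
  if (is.null(xyz_px)) xyz_px <- linear_rgb_to_xyz(srgb_decode(rgb_px))
  hsi <- rgb_to_hsi(rgb_px)
  lab <- xyz_to_lab(as.matrix(xyz_px))
  c(R = mean(rgb_px[, 1]), G = mean(rgb_px[, 2]), B = mean(rgb_px[, 3]),
    H = circular_mean_deg(hsi[, 1], w = pmax(hsi[, 2], 1e-6)),
    S = mean(hsi[, 2]), I = mean(hsi[, 3]),
    L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]))
}

#' Descriptors for every segment of a segmentation
#'
#' @param image RGB image.
#' @param seg `segmentation_result` with labels over all pixels.
#' @param xyz optional XYZ image aligned with `image`.
#' @return data.frame: `segment_id`, `pixel_count`, descriptor columns.
#' @export
segment_descriptors <- function(image, seg, xyz = NULL) {
  d <- dim(image)
  px <- matrix(image, d[1] * d[2], 3L)
  xz <- if (!is.null(xyz)) matrix(xyz, d[1] * d[2], 3L) else NULL
  ids <- sort(unique(seg$labels))
  rows <- lapply(ids, function(id) {
    sel <- seg$labels == id
    desc <- extract_descriptor(px[sel, , drop = FALSE],
                               if (!is.null(xz)) xz[sel, , drop = FALSE])
    data.frame(segment_id = id, pixel_count = sum(sel), t(desc))
  })
  do.call(rbind, rows)
}

# --- self-organising map ----------------------------------------------------

#' Train a calibrated self-organising map
#'
#' Batch SOM on a square node grid (default 10 x 10) with a Gaussian
#' neighbourhood whose radius shrinks linearly between epochs; inputs are
#' z-scored with training statistics stored in the model.  After the
#' unsupervised phase each node is labelled by the majority class of its
#' mapped training samples; empty nodes inherit the label of the nearest
#' labelled node on the grid.
#'
#' @param x n x d feature matrix.
#' @param labels class label per row.
#' @param grid_side nodes per side.
#' @param epochs training epochs.
#' @param radius0,radius1 initial / final neighbourhood radius (grid units).
#' @param seed RNG seed for codebook initialisation.
#' @return object of class `som_model`: `codebook` (nodes x d), `node_xy`,
#'   `node_labels`, `centering`/`scaling`, `qe_history`.
#' @export
train_som <- function(x, labels, grid_side = 10L, epochs = 30L,
                      radius0 = 5, radius1 = 0.5, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-9] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  n_nodes <- grid_side^2
  node_xy <- as.matrix(expand.grid(gx = seq_len(grid_side), gy = seq_len(grid_side)))
  set.seed(derive_subseed(seed, 404L))
  codebook <- z[sample.int(nrow(z), n_nodes, replace = nrow(z) < n_nodes), , drop = FALSE] +
    matrix(rnorm(n_nodes * ncol(z), 0, 0.01), n_nodes)
  grid_d2 <- as.matrix(stats::dist(node_xy))^2
  qe <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    r <- radius0 + (radius1 - radius0) * (ep - 1) / max(1, epochs - 1)
    d2 <- outer(rowSums(z^2), rowSums(codebook^2), "+") - 2 * z %*% t(codebook)
    bmu <- max.col(-d2)
    hmat <- exp(-grid_d2 / (2 * r^2))  # node x node neighbourhood
    w <- hmat[bmu, , drop = FALSE]     # n x nodes
    denom <- colSums(w)
    upd <- t(w) %*% z
    nz <- denom > 1e-12
    codebook[nz, ] <- upd[nz, , drop = FALSE] / denom[nz]
    # quantisation error after this epoch's update
    d2p <- outer(rowSums(z^2), rowSums(codebook^2), "+") - 2 * z %*% t(codebook)
    qe[ep] <- mean(sqrt(pmax(apply(d2p, 1, min), 0)))
  }
  # calibration
  d2 <- outer(rowSums(z^2), rowSums(codebook^2), "+") - 2 * z %*% t(codebook)
  bmu <- max.col(-d2)
  node_labels <- rep(NA_character_, n_nodes)
  for (j in seq_len(n_nodes)) {
    hit <- labels[bmu == j]
    if (length(hit)) node_labels[j] <- names(sort(table(hit), decreasing = TRUE))[1]
  }
  if (length(unique(labels)) == 1L && all(is.na(node_labels) | node_labels == labels[1])) {
    node_labels[] <- labels[1]
  }
  if (anyNA(node_labels)) {
    lab_idx <- which(!is.na(node_labels))
    for (j in which(is.na(node_labels))) {
      node_labels[j] <- node_labels[lab_idx[which.min(grid_d2[j, lab_idx])]]
    }
  }
  structure(list(codebook = codebook, node_xy = node_xy,
                 node_labels = node_labels, centering = ctr, scaling = scl,
                 qe_history = qe, grid_side = grid_side, seed = seed),
            class = "som_model")
}

#' @rdname train_som
#' @param model a `som_model`.
#' @param newdata m x d matrix of descriptors.
#' @export
som_classify <- function(model, newdata) {
  z <- sweep(sweep(as.matrix(newdata), 2, model$centering), 2, model$scaling, "/")
  d2 <- outer(rowSums(z^2), rowSums(model$codebook^2), "+") - 2 * z %*% t(model$codebook)
  model$node_labels[max.col(-d2)]
}

#' Recognise the hologram segment among classified segments
#'
#' Maps each segment descriptor to its best-matching SOM node; the ROI is
#' the segment labelled `roi_label` (ties broken by largest pixel count).
#' Raises a condition of class `holoquant_no_roi` when no segment gets the
#' ROI label -- the "re-capture" signal.
#'
#' @param model calibrated `som_model`.
#' @param desc_table data.frame from [segment_descriptors()].
#' @param roi_label class label marking the hologram.
#' @return list `labels` (per segment), `roi_segment_id`.
#' @export
classify_segments <- function(model, desc_table, roi_label = "hologram") {
  feats <- as.matrix(desc_table[, descriptor_cols(), drop = FALSE])
  labs <- som_classify(model, feats)
  hit <- which(labs == roi_label)
  if (!length(hit)) {
    stop(structure(class = c("holoquant_no_roi", "error", "condition"),
                   list(message = "no segment recognised as hologram: re-capture",
                        call = sys.call(-1))))
  }
  best <- hit[which.max(desc_table$pixel_count[hit])]
  list(labels = labs, roi_segment_id = desc_table$segment_id[best])
}

descriptor_cols <- function() c("R", "G", "B", "H", "S", "I", "L", "a", "b")
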