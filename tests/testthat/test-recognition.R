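test_that("separability matches the loop oracle on random instances", {
  set.seed(21)
  for (rep in 1:100) {
    c_n <- sample(2:4, 1)
    d <- sample(1:3, 1)
    labels <- rep(seq_len(c_n), times = sample(3:10, c_n, replace = TRUE))
    x <- matrix(rnorm(length(labels) * d, labels, 1), ncol = d)
    got <- separability(x, labels)
    expect_equal(got$J, j_oracle(x, labels), tolerance = 1e-9)
    gotp <- separability(x, labels, form = "product")
    expect_equal(gotp$J, j_oracle(x, labels, inverse = FALSE), tolerance = 1e-9)
  }
})

test_that("separability worked example and degenerate cases", {
  # 1-D classes {1,3} and {5,7}: Sw = 4, Sb = 16, J = 4
  x <- matrix(c(1, 3, 5, 7), ncol = 1)
  rep <- separability(x, c("a", "a", "b", "b"))
  expect_equal(drop(rep$Sw), 4)
  expect_equal(drop(rep$Sb), 16)
  expect_equal(rep$J, 4)
  # equal class means: Sb = 0 so J = 0
  x0 <- matrix(c(-1, 1, -1, 1), ncol = 1)
  expect_equal(separability(x0, c("a", "a", "b", "b"))$J, 0)
  # translation invariance
  set.seed(2)
  xx <- matrix(rnorm(30), 15, 2)
  ll <- rep(1:3, each = 5)
  expect_equal(separability(xx, ll)$J,
               separability(sweep(xx, 2, c(3, -7), "+"), ll)$J,
               tolerance = 1e-9)
  expect_error(separability(xx, rep(1, 15)), "classes")
})

test_that("Lab separates shadow/highlight classes better than RGB", {
  wins <- 0L
  for (seed in 1:20) {
    sh <- shaded_class_pixels(seed = seed)
    j_rgb <- separability(pixels_to_space(sh$pixels, "rgb"), sh$labels)$J
    j_lab <- separability(pixels_to_space(sh$pixels, "lab"), sh$labels)$J
    if (j_lab > j_rgb) wins <- wins + 1L
  }
  expect_gt(wins, 10L)  # directional ordering on average
})

test_that("descriptors are exact on flat segments and hue-circular", {
  col3 <- c(0.6, 0.2, 0.3)
  px <- matrix(rep(col3, each = 50), 50, 3)
  d <- extract_descriptor(px)
  expect_equal(unname(d[1:3]), col3, tolerance = 1e-9)
  expect_equal(unname(d[4:6]), unname(rgb_to_hsi(col3)), tolerance = 1e-6)
  expect_equal(unname(d[7:9]),
               unname(xyz_to_lab(linear_rgb_to_xyz(srgb_decode(col3)))),
               tolerance = 1e-6)
  expect_length(d, 9)
  # hue 10 and 350 average to 0, not 180
  mk <- function(h) {
    v <- drop(grDevices::col2rgb(grDevices::hsv(h / 360, 0.8, 0.8))) / 255
    matrix(rep(v, each = 25), 25, 3)
  }
  d2 <- extract_descriptor(rbind(mk(10), mk(350)))
  expect_lt(min(d2["H"], 360 - d2["H"]), 15)
  expect_error(extract_descriptor(matrix(0, 0, 3)), "empty")
})

test_that("descriptor of the simulator ROI matches truth-derived colour", {
  cam <- identity_camera(seed = 23L, size = 192L)
  sc <- render_scene(cam, 4.25, clutter_level = 0, scene_id = 2L)
  px <- matrix(sc$img, 192 * 192, 3)
  # interior of the ROI (the truth-derived reference colour has no
  # boundary anti-aliasing, so compare like with like)
  rows <- matrix(seq_len(192), 192, 192)
  cols <- matrix(seq_len(192), 192, 192, byrow = TRUE)
  ctr <- sc$truth$roi_centre
  interior <- (cols - ctr[1])^2 + (rows - ctr[2])^2 <=
    (0.8 * sc$truth$roi_radius)^2
  d <- extract_descriptor(px[as.vector(interior), ])
  want_rgb <- holoquant:::hue_to_rgb(sc$truth$true_hue_deg)
  lab_got <- d[7:9]
  lab_want <- xyz_to_lab(linear_rgb_to_xyz(srgb_decode(want_rgb)))
  expect_lt(delta_e_ab(lab_got, lab_want), 2)
})

test_that("SOM learns separable classes and is deterministic", {
  set.seed(31)
  n <- 100
  mk_class <- function(mu) matrix(rnorm(n * 9, mu, 1), n, 9)
  x <- rbind(mk_class(0), mk_class(6))
  y <- rep(c("background", "hologram"), each = n)
  tr <- c(1:80, 101:180); te <- setdiff(seq_len(2 * n), tr)
  m <- train_som(x[tr, ], y[tr], epochs = 20, seed = 5)
  acc <- mean(som_classify(m, x[te, ]) == y[te])
  expect_gte(acc, 0.95)
  m2 <- train_som(x[tr, ], y[tr], epochs = 20, seed = 5)
  expect_identical(m$codebook, m2$codebook)
  expect_equal(nrow(m$codebook), 100)  # 10 x 10 grid
  # quantisation error shrinks as the map settles
  expect_true(all(diff(m$qe_history) <= 1e-9))
})

test_that("single-class data labels the whole map with a warning-free pass", {
  set.seed(7)
  x <- matrix(rnorm(40 * 9), 40, 9)
  m <- train_som(x, rep("only", 40), epochs = 5, seed = 2)
  expect_true(all(m$node_labels == "only"))
  expect_equal(unique(som_classify(m, x)), "only")
})

test_that("segment classification returns the hologram and signals its absence", {
  set.seed(33)
  x <- rbind(matrix(rnorm(60 * 9, 0, 0.5), 60, 9),
             matrix(rnorm(60 * 9, 5, 0.5), 60, 9))
  y <- rep(c("background", "hologram"), each = 60)
  m <- train_som(x, y, epochs = 15, seed = 9)
  # a descriptor equal to a codebook vector gets that node's label
  z <- m$codebook[17, ] * m$scaling + m$centering
  expect_equal(som_classify(m, matrix(z, 1)), m$node_labels[17])
  tab <- data.frame(segment_id = 1:3, pixel_count = c(50, 200, 120),
                    rbind(x[61, ], x[61, ] + 0.1, x[1, ]))
  names(tab)[3:11] <- holoquant:::descriptor_cols()
  cls <- classify_segments(m, tab)
  expect_equal(cls$roi_segment_id, 2)  # larger of the two hologram segments
  bg <- data.frame(segment_id = 1, pixel_count = 10, t(x[1, ]))
  names(bg)[3:11] <- holoquant:::descriptor_cols()
  expect_error(classify_segments(m, bg), class = "holoquant_no_roi")
})
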