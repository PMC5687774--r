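# Shared fixture builders (all generated in code, seeded).

random_rgb_image <- function(h, w, seed = 1L) {
  set.seed(seed)
  holoquant:::from_raw8(array(sample(0:255, h * w * 3L, replace = TRUE),
                              c(h, w, 3L)))
}

# Piecewise-smooth "natural" test image: soft gradient + a few shapes.
natural_image <- function(size = 64L, seed = 1L) {
  set.seed(seed)
  img <- array(0, c(size, size, 3L))
  gx <- matrix(seq(0.2, 0.7, length.out = size), size, size, byrow = TRUE)
  for (ch in 1:3) img[, , ch] <- gx * runif(1, 0.7, 1.2)
  for (i in 1:4) {
    r0 <- sample(size - 16L, 1); c0 <- sample(size - 16L, 1)
    img[r0:(r0 + 14L), c0:(c0 + 14L), ] <-
      rep(runif(3), each = 15L * 15L)
  }
  holoquant:::clip01(gaussian_smooth(img, 1))
}

# Pixel cloud of well-separated colour blobs; returns pixels + labels.
blob_pixels <- function(k = 2L, n_per = 100L, sep = 10, sd = 0.02, seed = 1L) {
  set.seed(seed)
  centres <- matrix(runif(k * 3L), k, 3L)
  # push centres apart to sep * sd separation
  for (i in seq_len(k)) centres[i, ] <- centres[i, ] * 0.2 + (i - 1) / k
  px <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_per * 3L, centres[i, ], sd), n_per, 3L, byrow = TRUE)
  }))
  list(pixels = px, labels = rep(seq_len(k), each = n_per), centres = centres)
}

# Flat multi-patch image with known cluster count.
flat_patch_image <- function(cols, h = 48L, noise_sd = 0.01, seed = 1L) {
  set.seed(seed)
  k <- length(cols)
  w <- 20L * k
  img <- array(0, c(h, w, 3L))
  for (i in seq_len(k)) {
    for (ch in 1:3) img[, ((i - 1L) * 20L + 1L):(i * 20L), ch] <- cols[[i]][ch]
  }
  holoquant:::clip01(img + array(rnorm(h * w * 3L, 0, noise_sd), dim(img)))
}

# Pixel clouds imitating objects of distinct hue seen through shadows and
# highlights: per-pixel multiplicative brightness plus additive glare.
shaded_class_pixels <- function(seed = 1L, n_per = 150L) {
  set.seed(seed)
  base <- rbind(c(0.7, 0.25, 0.2),   # reddish object
                c(0.2, 0.3, 0.7),    # bluish object
                c(0.45, 0.45, 0.4))  # grey background
  px <- NULL; labels <- NULL
  for (i in seq_len(nrow(base))) {
    bright <- runif(n_per, 0.35, 1)          # shadows
    glare <- rbinom(n_per, 1, 0.15) * runif(n_per, 0.1, 0.35)
    p <- outer(bright, base[i, ]) + glare
    p <- p + matrix(rnorm(n_per * 3L, 0, 0.01), n_per)
    px <- rbind(px, pmin(pmax(p, 0), 1))
    labels <- c(labels, rep(i, n_per))
  }
  list(pixels = px, labels = labels)
}

expect_no_error <- function(expr) expect_error(expr, NA)
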