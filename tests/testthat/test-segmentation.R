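test_that("Gaussian smoothing preserves constants and reduces noise", {
  const <- array(0.42, c(20, 20, 3))
  expect_equal(gaussian_smooth(const, 2), const, tolerance = 1e-12)
  # normalised kernel: impulse response sums to 1
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  expect_equal(sum(gaussian_smooth(imp, 1.5)), 1, tolerance = 1e-9)
  set.seed(8)
  noise <- array(runif(20 * 20 * 3), c(20, 20, 3))
  expect_lt(var(as.vector(gaussian_smooth(noise, 1.5))), var(as.vector(noise)))
  expect_error(gaussian_smooth(const, 0), "sigma")
})

test_that("k-means separates well-separated blobs exactly and is deterministic", {
  bl <- blob_pixels(k = 2, n_per = 80, sd = 0.01, seed = 2)
  seg <- kmeans_segment(bl$pixels, 2, seed = 4)
  agree <- max(mean(seg$labels == bl$labels), mean(seg$labels == 3 - bl$labels))
  expect_equal(agree, 1)
  seg2 <- kmeans_segment(bl$pixels, 2, seed = 4)
  expect_identical(seg$labels, seg2$labels)
  # n = k distinct pixels: every pixel its own cluster, intra = 0
  px <- diag(3) * 0.9
  segk <- kmeans_segment(px, 3, seed = 1)
  expect_equal(sort(segk$labels), 1:3)
  vm <- validity_measure(segk, px)
  expect_equal(vm$intra, 0)
  expect_equal(vm$vm, 0)
  expect_error(kmeans_segment(px, 5, seed = 1), "k <= n")
})

test_that("fuzzy memberships are a partition and harden to k-means labels", {
  bl <- blob_pixels(k = 2, n_per = 80, sd = 0.01, seed = 5)
  fc <- fcm_segment(bl$pixels, 2, seed = 4)
  expect_equal(rowSums(fc$membership), rep(1, nrow(bl$pixels)), tolerance = 1e-9)
  km <- kmeans_segment(bl$pixels, 2, seed = 4)
  agree <- max(mean(km$labels == fc$labels), mean(km$labels == 3 - fc$labels))
  expect_equal(agree, 1)
  # pixel exactly at a centre gets (numerically) full membership
  cent <- fc$centres[1, , drop = FALSE]
  fc2 <- fcm_segment(rbind(bl$pixels, cent), 2, seed = 4)
  expect_gt(max(fc2$membership[nrow(bl$pixels) + 1, ]), 0.999)
})

test_that("validity measure matches the brute-force oracle on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(6:20, 1)
    k <- sample(2:4, 1)
    px <- matrix(runif(n * 3), n, 3)
    seg <- kmeans_segment(px, k, seed = rep)
    p <- vm_params(m_const = runif(1, 5, 30), mu = runif(1, 1.5, 3),
                   sigma = runif(1, 0.5, 2))
    got <- validity_measure(seg, px, p)
    want <- vm_oracle(px, seg$labels, seg$centres, p$m_const, p$mu, p$sigma)
    expect_equal(got$vm, want, tolerance = 1e-9)
    # literal printed sign variant against the oracle too
    p2 <- vm_params(m_const = p$m_const, mu = p$mu, sigma = p$sigma,
                    sign_variant = "as_printed")
    got2 <- validity_measure(seg, px, p2)
    want2 <- vm_oracle(px, seg$labels, seg$centres, p$m_const, p$mu, p$sigma,
                       positive = FALSE)
    expect_equal(got2$vm, want2, tolerance = 1e-9)
  }
})

test_that("the k = 2 multiplier evaluates to the closed-form values", {
  expect_equal(holoquant:::vm_multiplier(2, vm_params()),
               1 + 20 / sqrt(2 * pi), tolerance = 1e-9)
  expect_equal(holoquant:::vm_multiplier(2, vm_params(sign_variant = "as_printed")),
               1 - 20 / sqrt(2 * pi), tolerance = 1e-9)
  # the +1 keeps the intra/inter ratio for large k where the Gaussian dies
  expect_equal(holoquant:::vm_multiplier(10, vm_params()), 1, tolerance = 1e-6)
})

test_that("auto segmentation selects the planted cluster count", {
  img3 <- flat_patch_image(list(c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.1),
                                c(0.1, 0.1, 0.9)), seed = 3)
  out3 <- auto_segment(img3, "kmeans", "rgb", vm_params(k_max = 8),
                       seed = 1, smooth_sigma = 0)
  expect_equal(out3$k_best, 3)
  # five clusters: two objects + background + highlight + shadow analogue
  img5 <- flat_patch_image(list(c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.1),
                                c(0.1, 0.1, 0.9), c(0.9, 0.9, 0.1),
                                c(0.15, 0.15, 0.15)), seed = 4)
  out5 <- auto_segment(img5, "kmeans", "rgb", vm_params(k_max = 8),
                       seed = 1, smooth_sigma = 0)
  expect_equal(out5$k_best, 5)
  # collapsed range returns that k
  out1 <- auto_segment(img3, "kmeans", "rgb", vm_params(k_min = 4, k_max = 4),
                       seed = 1, smooth_sigma = 0)
  expect_equal(out1$k_best, 4)
})

test_that("auto segmentation is deterministic given its seed", {
  img <- flat_patch_image(list(c(0.8, 0.2, 0.2), c(0.2, 0.8, 0.2),
                               c(0.2, 0.2, 0.8)), noise_sd = 0.04, seed = 9)
  a <- auto_segment(img, "kmeans", "lab", vm_params(k_max = 5), seed = 7)
  b <- auto_segment(img, "kmeans", "lab", vm_params(k_max = 5), seed = 7)
  expect_identical(a$seg$labels, b$seg$labels)
  expect_identical(a$vm_curve, b$vm_curve)
})

test_that("k-means objective is nonincreasing across Lloyd iterations", {
  set.seed(14)
  px <- matrix(runif(900), 300, 3)
  wss <- vapply(1:8, function(it) {
    init <- holoquant:::kmeanspp_init(px, 4, seed = 3)
    suppressWarnings(stats::kmeans(px, init, iter.max = it,
                                   algorithm = "Lloyd"))$tot.withinss
  }, numeric(1))
  expect_true(all(diff(wss) <= 1e-9))
})
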