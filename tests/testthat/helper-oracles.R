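# Independent brute-force oracles (explicit loops, no shared code with the
# package implementations they check).

# Cluster-validity measure: mean within-cluster squared distance over all
# pixels, minimum squared centre separation, Gaussian-weighted multiplier.
vm_oracle <- function(pixels, labels, centres, m_const, mu, sigma, positive = TRUE) {
  m <- nrow(pixels)
  intra <- 0
  for (i in seq_len(m)) {
    ci <- centres[labels[i], ]
    intra <- intra + sum((pixels[i, ] - ci)^2)
  }
  intra <- intra / m
  inter <- Inf
  k <- nrow(centres)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    inter <- min(inter, sum((centres[i, ] - centres[j, ])^2))
  }
  gauss <- exp(-(k - mu)^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
  if (!positive) gauss <- -gauss
  (m_const * gauss + 1) * intra / inter
}

# Scatter-matrix class separability via explicit per-sample sums.
j_oracle <- function(x, labels, inverse = TRUE) {
  cls <- unique(labels)
  d <- ncol(x)
  sw <- matrix(0, d, d)
  means <- list(); sizes <- numeric(0)
  for (cl in cls) {
    xi <- x[labels == cl, , drop = FALSE]
    mi <- colMeans(xi)
    means[[as.character(cl)]] <- mi
    sizes <- c(sizes, nrow(xi))
    for (r in seq_len(nrow(xi))) {
      v <- xi[r, ] - mi
      sw <- sw + outer(v, v)
    }
  }
  grand <- Reduce(`+`, Map(`*`, means, sizes)) / sum(sizes)
  sb <- matrix(0, d, d)
  for (i in seq_along(cls)) {
    v <- means[[i]] - grand
    sb <- sb + sizes[i] * outer(v, v)
  }
  if (inverse) sum(diag(solve(sw) %*% sb)) else sum(diag(sb %*% sw))
}

# One-way ANOVA mean squares through stats::aov (an independent route).
icc_anova_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(value = as.vector(tab), target = factor(rep(seq_len(n), k)))
  an <- anova(stats::aov(value ~ target, df))
  msb <- an$`Mean Sq`[1]; msw <- an$`Mean Sq`[2]
  (msb - msw) / (msb + (k - 1) * msw)
}
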