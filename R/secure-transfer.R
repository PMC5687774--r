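# Secure transfer: personalised permutation/keystream image encryption
# (confusion + diffusion) and single-level 2-D orthogonal wavelet
# compression.  Pipeline order is compress-then-encrypt: permuted pixels
# destroy the smoothness wavelets exploit, so the coefficient byte stream
# is what gets encrypted for transport.

PASSCODE_ALPHABET <- c(as.character(0:9), letters)

#' Derive an encryption key from an alphanumeric passcode
#'
#' Each case-folded character is encoded over the 36-symbol alphabet
#' (0-9 -> 0-9, a-z -> 10-35); the seed is the big-endian base-36 value of
#' the code sequence reduced modulo 2^32.
#'
#' @param passcode non-empty string over `[a-zA-Z0-9]`.
#' @return object of class `passcode_key` with fields `codes`,
#'   `derived_seed`.
#' @export
derive_key <- function(passcode) {
  if (!is.character(passcode) || length(passcode) != 1L || nchar(passcode) == 0L) {
    stop("passcode must be a non-empty string")
  }
  chars <- strsplit(tolower(passcode), "")[[1]]
  codes <- match(chars, PASSCODE_ALPHABET) - 1L
  if (any(is.na(codes))) stop("passcode characters must be in [a-z0-9]")
  seed <- 0
  for (c in codes) seed <- (seed * 36 + c) %% 4294967296  # exact: < 2^53
  structure(list(codes = codes, derived_seed = seed), class = "passcode_key")
}

key_rng_seed <- function(key, stream = 0L) {
  as.integer((key$derived_seed + 104729 * stream) %% 2147483647)
}

# Keystream of n bytes (0..255) from the key.
key_stream <- function(key, n, stream = 1L) {
  set.seed(key_rng_seed(key, stream))
  sample.int(256L, n, replace = TRUE) - 1L
}

key_permutation <- function(key, n, stream = 2L) {
  set.seed(key_rng_seed(key, stream))
  sample.int(n)
}

#' Encrypt / decrypt an 8-bit RGB image
#'
#' Confusion: a key-seeded pseudo-random permutation of pixel positions
#' (applied jointly to all three channels).  Diffusion: XOR of every 8-bit
#' channel value with a key-seeded byte keystream.  The pair is an exact
#' bijection on 8-bit images.
#'
#' @param image RGB image array in `[0, 1]` (quantised internally to 8 bit).
#' @param key a [derive_key()] result.
#' @param diffuse apply the keystream XOR step (`TRUE`) or permutation only.
#' @return encrypted image array in `[0, 1]` of identical shape.
#' @export
encrypt_image <- function(image, key, diffuse = TRUE) {
  assert_rgb_image(image)
  q <- to_raw8(image)
  d <- dim(q)
  npix <- d[1] * d[2]
  perm <- key_permutation(key, npix)
  for (ch in 1:3) {
    pl <- q[, , ch]
    q[, , ch] <- pl[perm]
  }
  if (diffuse) {
    ks <- key_stream(key, length(q))
    q <- array(bitwXor(as.integer(q), ks), d)
  }
  from_raw8(q)
}

#' @rdname encrypt_image
#' @export
decrypt_image <- function(image, key, diffuse = TRUE) {
  assert_rgb_image(image)
  q <- to_raw8(image)
  d <- dim(q)
  if (diffuse) {
    ks <- key_stream(key, length(q))
    q <- array(bitwXor(as.integer(q), ks), d)
  }
  npix <- d[1] * d[2]
  perm <- key_permutation(key, npix)
  inv <- integer(npix)
  inv[perm] <- seq_len(npix)
  for (ch in 1:3) {
    pl <- q[, , ch]
    q[, , ch] <- pl[inv]
  }
  from_raw8(q)
}

# --- single-level 2-D orthogonal DWT ----------------------------------------

wavelet_filters <- function(wavelet = c("haar", "db2")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
              haar = c(1, 1) / sqrt(2),
              db2 = c(0.4829629131445341, 0.8365163037378079,
                      0.2241438680420134, -0.1294095225512604))
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(h = h, g = g)
}

# Analysis along columns of x (even row count), periodic extension:
#   a[i] = sum_k f[k+1] * x[(2i - 2 + k) mod N + 1]
dwt_cols <- function(x, f) {
  n <- nrow(x)
  out <- matrix(0, n / 2, ncol(x))
  for (k in seq_along(f)) {
    idx <- ((seq(0, n - 2, by = 2) + k - 1) %% n) + 1
    out <- out + f[k] * x[idx, , drop = FALSE]
  }
  out
}

# Synthesis: x[m] = sum_i a[i] h[(m - 2i) mod N] + d[i] g[(m - 2i) mod N]
idwt_cols <- function(a, d, flt) {
  n <- 2L * nrow(a)
  out <- matrix(0, n, ncol(a))
  for (k in seq_along(flt$h)) {
    rows <- ((seq(0, n - 2, by = 2) + k - 1) %% n) + 1
    out[rows, ] <- out[rows, ] + flt$h[k] * a + flt$g[k] * d
  }
  out
}

#' Single-level 2-D discrete wavelet transform
#'
#' Orthogonal analysis with periodic boundary handling; rows then columns.
#' Input dimensions must be even.
#'
#' @param x numeric matrix with even dimensions.
#' @param wavelet `"haar"` or `"db2"` (4-tap Daubechies).
#' @return list of subbands `LL`, `LH`, `HL`, `HH` (each half-size).
#' @export
dwt2 <- function(x, wavelet = "haar") {
  if (nrow(x) %% 2L || ncol(x) %% 2L) stop("dwt2 needs even dimensions")
  flt <- wavelet_filters(wavelet)
  lo <- dwt_cols(x, flt$h); hi <- dwt_cols(x, flt$g)
  list(LL = t(dwt_cols(t(lo), flt$h)), LH = t(dwt_cols(t(lo), flt$g)),
       HL = t(dwt_cols(t(hi), flt$h)), HH = t(dwt_cols(t(hi), flt$g)))
}

#' @rdname dwt2
#' @param bands subband list as produced by [dwt2()].
#' @export
idwt2 <- function(bands, wavelet = "haar") {
  flt <- wavelet_filters(wavelet)
  lo <- t(idwt_cols(t(bands$LL), t(bands$LH), flt))
  hi <- t(idwt_cols(t(bands$HL), t(bands$HH), flt))
  idwt_cols(lo, hi, flt)
}

# --- compression ------------------------------------------------------------

LL_QSCALE <- 100   # LL in [0, ~2.55] -> unsigned byte
DET_QSCALE <- 60   # details in about [-2.1, 2.1] -> signed byte

serialize_ints <- function(v, size) writeBin(as.integer(v), raw(), size = size, endian = "little")
deserialize_ints <- function(r, n, size, signed = TRUE) {
  readBin(r, "integer", n = n, size = size, signed = signed, endian = "little")
}

#' Wavelet image compression
#'
#' Per channel: single-level 2-D DWT, the approximation band kept in full,
#' detail coefficients hard-thresholded to the top `keep_fraction` by
#' magnitude, optional 8-bit quantisation, and deflate entropy coding.
#'
#' @param image RGB image array (even dimensions).
#' @param wavelet `"haar"` or `"db2"`.
#' @param keep_fraction fraction of detail coefficients retained, `(0, 1]`.
#' @param quantise quantise coefficients to 8 bits (set `FALSE` for an
#'   exact lossless round trip at `keep_fraction = 1`).
#' @return object of class `secure_payload` with `data` (raw vector),
#'   `wavelet`, `keep_fraction`, `original_shape`, `quantise`,
#'   `compression_ratio`, `psnr_db`.
#' @export
compress_image <- function(image, wavelet = c("haar", "db2"),
                           keep_fraction = 0.05, quantise = TRUE) {
  assert_rgb_image(image)
  wavelet <- match.arg(wavelet)
  if (keep_fraction <= 0 || keep_fraction > 1) stop("keep_fraction must be in (0, 1]")
  d <- dim(image)
  if (d[1] %% 2L || d[2] %% 2L) stop("image dimensions must be even")
  payload <- list()
  for (ch in 1:3) {
    bands <- dwt2(image[, , ch], wavelet)
    det <- c(bands$LH, bands$HL, bands$HH)
    if (keep_fraction < 1) {
      n_keep <- max(1L, floor(keep_fraction * length(det)))
      thr <- sort(abs(det), decreasing = TRUE)[n_keep]
      det[abs(det) < thr] <- 0
    }
    keep_idx <- which(det != 0)
    if (quantise) {
      ll_b <- as.raw(pmin(pmax(round(bands$LL * LL_QSCALE), 0), 255))
      dv <- pmin(pmax(round(det[keep_idx] * DET_QSCALE), -127), 127)
      # drop coefficients that quantise to zero
      nz <- dv != 0
      keep_idx <- keep_idx[nz]; dv <- dv[nz]
      body <- c(serialize_ints(length(keep_idx), 4L),
                ll_b,
                serialize_ints(diff(c(0L, keep_idx)), 4L),
                serialize_ints(dv, 1L))
    } else {
      body <- c(serialize_ints(length(keep_idx), 4L),
                writeBin(as.numeric(bands$LL), raw(), size = 8, endian = "little"),
                serialize_ints(diff(c(0L, keep_idx)), 4L),
                writeBin(as.numeric(det[keep_idx]), raw(), size = 8, endian = "little"))
    }
    payload[[ch]] <- body
  }
  blob <- memCompress(do.call(c, payload), type = "gzip")
  out <- structure(list(data = blob, wavelet = wavelet,
                        keep_fraction = keep_fraction,
                        original_shape = d, quantise = quantise),
                   class = "secure_payload")
  rec <- decompress_image(out)
  err2 <- mean((rec - image)^2)
  # below double-precision round-off the reconstruction is exact
  out$psnr_db <- if (err2 < 1e-28) Inf else 10 * log10(1 / err2)
  out$compression_ratio <- (d[1] * d[2] * 3) / length(blob)
  out
}

#' @rdname compress_image
#' @param payload a `secure_payload`.
#' @export
decompress_image <- function(payload) {
  if (!inherits(payload, "secure_payload")) stop("payload must be a secure_payload")
  raw_all <- tryCatch(memDecompress(payload$data, type = "gzip"),
                      error = function(e) stop("corrupted payload: ", conditionMessage(e)))
  d <- payload$original_shape
  hh <- d[1] / 2; ww <- d[2] / 2
  n_ll <- hh * ww; n_det <- 3 * n_ll
  img <- array(0, d)
  pos <- 1L
  take <- function(n) {
    if (n <= 0L) return(raw(0))
    r <- raw_all[pos:(pos + n - 1L)]
    pos <<- pos + n
    r
  }
  for (ch in 1:3) {
    n_keep <- deserialize_ints(take(4L), 1L, 4L)
    if (payload$quantise) {
      ll <- matrix(as.integer(take(n_ll)) / LL_QSCALE, hh, ww)
      idx <- cumsum(deserialize_ints(take(4L * n_keep), n_keep, 4L))
      dv <- deserialize_ints(take(n_keep), n_keep, 1L) / DET_QSCALE
    } else {
      ll <- matrix(readBin(take(8L * n_ll), "numeric", n_ll, endian = "little"), hh, ww)
      idx <- cumsum(deserialize_ints(take(4L * n_keep), n_keep, 4L))
      dv <- readBin(take(8L * n_keep), "numeric", n_keep, endian = "little")
    }
    det <- numeric(n_det)
    det[idx] <- dv
    bands <- list(LL = ll,
                  LH = matrix(det[seq_len(n_ll)], hh, ww),
                  HL = matrix(det[n_ll + seq_len(n_ll)], hh, ww),
                  HH = matrix(det[2 * n_ll + seq_len(n_ll)], hh, ww))
    img[, , ch] <- idwt2(bands, payload$wavelet)
  }
  clip01(img)
}

# --- packed transport format ------------------------------------------------

HSP_MAGIC <- charToRaw("HOLOSEC1")

#' Pack / unpack an image for secure transfer
#'
#' `secure_pack` compresses the image and encrypts the coefficient byte
#' stream with the passcode-derived keystream plus a byte permutation;
#' `secure_unpack` reverses both.  A wrong passcode yields garbage (with
#' overwhelming probability a format error), never the original image.
#'
#' @param image RGB image array.
#' @param passcode transfer passcode.
#' @param wavelet,keep_fraction,quantise see [compress_image()].
#' @param path optional file to write the packed bytes to.
#' @return `secure_pack`: raw vector (invisibly when `path` given);
#'   `secure_unpack`: the recovered RGB image.
#' @export
secure_pack <- function(image, passcode, wavelet = "haar",
                        keep_fraction = 0.05, quantise = TRUE, path = NULL) {
  key <- derive_key(passcode)
  payload <- compress_image(image, wavelet, keep_fraction, quantise)
  meta <- jsonlite::toJSON(list(wavelet = payload$wavelet,
                                keep_fraction = payload$keep_fraction,
                                quantise = payload$quantise,
                                shape = payload$original_shape), auto_unbox = TRUE)
  meta_raw <- charToRaw(as.character(meta))
  body <- payload$data
  perm <- key_permutation(key, length(body), stream = 3L)
  body <- body[perm]
  body <- as.raw(bitwXor(as.integer(body), key_stream(key, length(body), stream = 4L)))
  out <- c(HSP_MAGIC, writeBin(length(meta_raw), raw(), size = 4L, endian = "little"),
           meta_raw, body)
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname secure_pack
#' @param packed raw vector or path produced by `secure_pack`.
#' @export
secure_unpack <- function(packed, passcode) {
  if (is.character(packed)) packed <- readBin(packed, raw(), file.size(packed))
  if (length(packed) < 12L || !identical(packed[1:8], HSP_MAGIC)) {
    stop("not a holoquant secure payload")
  }
  key <- derive_key(passcode)
  meta_len <- readBin(packed[9:12], "integer", 1L, size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(packed[13:(12 + meta_len)]))
  body <- packed[-(1:(12 + meta_len))]
  body <- as.raw(bitwXor(as.integer(body), key_stream(key, length(body), stream = 4L)))
  perm <- key_permutation(key, length(body), stream = 3L)
  inv <- integer(length(body)); inv[perm] <- seq_along(body)
  body <- body[inv]
  payload <- structure(list(data = body, wavelet = meta$wavelet,
                            keep_fraction = meta$keep_fraction,
                            original_shape = meta$shape, quantise = meta$quantise),
                       class = "secure_payload")
  decompress_image(payload)
}
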