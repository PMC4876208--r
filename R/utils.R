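# Internal helpers: seeded RNG scoping, resampling, normalization, small FFT
# convolution machinery shared by the feature and ground-truth code.

.tsCache <- new.env(parent = emptyenv())

# Evaluate expr under a local RNG state; the caller's stream is untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seed from a master seed and a string key; stays < 2^31.
deriveSeed <- function(seed, key) {
  v <- utf8ToInt(as.character(key))
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h + 1) %% 2147483629)
}

popSd <- function(x) {
  if (length(x) < 1L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Divide a nonnegative map by its maximum; an all-zero map stays zero.
maxNormalize <- function(m) {
  mx <- max(m)
  if (mx <= 0) m * 0 else m / mx
}

minMaxNormalize <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) m * 0 else (m - lo) / (hi - lo)
}

# Bilinear resize with half-pixel-center alignment; exact identity when the
# target size equals the source size.
bilinearResize <- function(m, h, w) {
  sh <- nrow(m); sw <- ncol(m)
  if (h == sh && w == sw) return(m)
  yc <- (seq_len(h) - 0.5) * sh / h - 0.5
  xc <- (seq_len(w) - 0.5) * sw / w - 0.5
  yc <- pmin(pmax(yc, 0), sh - 1)
  xc <- pmin(pmax(xc, 0), sw - 1)
  y0 <- pmin(floor(yc), sh - 1); y1 <- pmin(y0 + 1, sh - 1)
  x0 <- pmin(floor(xc), sw - 1); x1 <- pmin(x0 + 1, sw - 1)
  fy <- yc - y0; fx <- xc - x0
  (1 - fy) %o% (1 - fx) * m[y0 + 1, x0 + 1, drop = FALSE] +
    (1 - fy) %o% fx * m[y0 + 1, x1 + 1, drop = FALSE] +
    fy %o% (1 - fx) * m[y1 + 1, x0 + 1, drop = FALSE] +
    fy %o% fx * m[y1 + 1, x1 + 1, drop = FALSE]
}

clampIndex <- function(n, d) pmin(pmax(seq_len(n) + d, 1L), n)

# Separable 5-tap binomial smoothing with replicated borders.
binomialBlur <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  out <- matrix(0, nrow(m), ncol(m))
  for (d in -2:2) out <- out + k[d + 3] * m[clampIndex(nrow(m), d), , drop = FALSE]
  res <- matrix(0, nrow(m), ncol(m))
  for (d in -2:2) res <- res + k[d + 3] * out[, clampIndex(ncol(m), d), drop = FALSE]
  res
}

# Gaussian pyramid: level 0 is the input; each further level is blurred and
# decimated by two (sizes 200, 100, 50, 25, 13, 7, 4 on the canonical frame).
gaussianPyramid <- function(m, nLevels = 7L) {
  pyr <- vector("list", nLevels)
  pyr[[1]] <- m
  for (l in seq_len(nLevels - 1L)) {
    b <- binomialBlur(pyr[[l]])
    pyr[[l + 1L]] <- b[seq(1, nrow(b), by = 2), seq(1, ncol(b), by = 2), drop = FALSE]
  }
  pyr
}

# Replicate-padded 'same' cross-correlation via FFT. Kernel spectra are cached
# per (padded size, cache key), which matters when many images are filtered
# with the same Gabor bank.
conv2same <- function(m, kern, cacheKey = NULL) {
  r <- (nrow(kern) - 1L) %/% 2L
  n <- nrow(m); p <- ncol(m)
  np <- n + 2L * r; pp <- p + 2L * r
  padRows <- c(rep(1L, r), seq_len(n), rep(n, r))
  padCols <- c(rep(1L, r), seq_len(p), rep(p, r))
  P <- m[padRows, padCols, drop = FALSE]
  key <- if (is.null(cacheKey)) NULL else paste0(cacheKey, "_", np, "x", pp)
  K <- if (!is.null(key) && !is.null(.tsCache[[key]])) {
    .tsCache[[key]]
  } else {
    kp <- matrix(0, np, pp)
    kp[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
    kf <- stats::fft(kp)
    if (!is.null(key)) .tsCache[[key]] <- kf
    kf
  }
  full <- Re(stats::fft(stats::fft(P) * Conj(K), inverse = TRUE)) / (np * pp)
  full[seq_len(n), seq_len(p), drop = FALSE]
}

fullPrecision <- function(x) formatC(x, digits = 17, format = "g")
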