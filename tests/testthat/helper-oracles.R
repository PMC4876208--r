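# Independent oracles and small fixture builders used across the suite.

# Exhaustive Mann-Whitney AUC over all positive-negative pixel pairs:
# P(score_pos > score_neg) + 0.5 P(equal).
bruteForceAuc <- function(pred, posMask) {
  p <- pred[posMask]
  q <- pred[!posMask]
  total <- 0
  for (v in p) total <- total + sum(v > q) + 0.5 * sum(v == q)
  total / (length(p) * length(q))
}

# Naive spatial-domain Gabor quadrature energy with replicated borders;
# mirrors the definition the package implements via FFT, computed the slow
# direct way at a subset of pixels.
directGaborEnergyAt <- function(img, thetaDeg, lambda, sigma, pixels) {
  r <- ceiling(2.5 * sigma)
  d <- seq(-r, r)
  dx <- matrix(d, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  dy <- matrix(d, 2 * r + 1, 2 * r + 1)
  th <- thetaDeg * pi / 180
  xr <- dx * cos(th) + dy * sin(th)
  env <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
  kEven <- env * cos(2 * pi * xr / lambda); kEven <- kEven - mean(kEven)
  kOdd <- env * cos(2 * pi * xr / lambda + pi / 2); kOdd <- kOdd - mean(kOdd)
  n <- nrow(img); m <- ncol(img)
  vapply(seq_len(nrow(pixels)), function(i) {
    yy <- pmin(pmax(pixels[i, 1] + d, 1), n)
    xx <- pmin(pmax(pixels[i, 2] + d, 1), m)
    patch <- img[yy, xx]
    sqrt(sum(patch * kEven)^2 + sum(patch * kOdd)^2)
  }, numeric(1))
}

# A tiny canonical dataset built directly in memory: two categories, a few
# images, deterministic gaze. Heavier feature-stage tests reuse it.
makeTinyDataset <- function(seed = 42, nImages = 4, nSubjects = 3,
                            nGaze = 20, mix = c(0.7, 0.2, 0.1),
                            categories = c("dog", "chair"),
                            targetPresentFraction = 0.5) {
  cfg <- syntheticConfig(
    nImagesPerCategory = nImages, categories = categories,
    targetPresentFraction = targetPresentFraction,
    nSubjects = nSubjects, nGazePerSubjectPerImage = nGaze,
    mix = mix, seed = seed)
  generateDataset(cfg)
}

# Flat gray canonical ImageRecord, optionally with a painted rectangle.
makeFlatImage <- function(value = 128, id = "flat") {
  n <- canonicalSize()
  new("ImageRecord", id = id,
      pixels = array(value, dim = c(n, n, 3)),
      category = "test", targetPresent = FALSE)
}

gazeFrame <- function(x, y, subject = "S1", image_id = "img") {
  data.frame(subject = rep_len(subject, length(x)),
             image_id = rep_len(image_id, length(x)),
             x = x, y = y, t = rep(NA_real_, length(x)),
             stringsAsFactors = FALSE)
}
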