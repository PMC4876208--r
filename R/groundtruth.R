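# Continuous fixation maps and dataset-level gaze statistics: entropy,
# center-bias fractions, target-hit rates, inter-observer maps, gaze counts.

#' Continuous fixation map from gaze points
#'
#' Sums an isotropic Gaussian of standard deviation `sigma` centered at each
#' gaze point's pixel and max-normalizes to `[0, 1]`. The Gaussian has full
#' support (no truncation), evaluated exactly via two separable kernel
#' products. An empty gaze set yields the all-zero map.
#'
#' @param gaze data.frame with canonical 0-based integer columns `x`, `y`.
#' @param sigma Gaussian standard deviation in pixels (default 10, about one
#'   degree of visual angle at a typical 65 cm viewing distance).
#' @return 200x200 matrix in `[0, 1]`.
#' @export
fixationMap <- function(gaze, sigma = 10) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  n <- canonicalSize()
  if (is.null(gaze) || !nrow(gaze)) return(matrix(0, n, n))
  x <- floor(gaze$x); y <- floor(gaze$y)
  if (any(x < 0 | x >= n | y < 0 | y >= n))
    stop("gaze coordinates outside the canonical frame", call. = FALSE)
  counts <- matrix(0, n, n)
  idx <- cbind(y + 1, x + 1)
  for (i in seq_len(nrow(idx))) counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1
  key <- sprintf("gaussKernel_%g", sigma)
  G <- .tsCache[[key]]
  if (is.null(G)) {
    G <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
    .tsCache[[key]] <- G
  }
  maxNormalize(G %*% counts %*% G)
}

#' Average a set of per-subject saliency maps
#'
#' Pixelwise mean of the maps, re-max-normalized to `[0, 1]`.
#'
#' @param maps non-empty list of 200x200 matrices.
#' @return 200x200 matrix in `[0, 1]`.
#' @export
averageSubjectMap <- function(maps) {
  if (!length(maps)) stop("averageSubjectMap needs at least one map", call. = FALSE)
  maxNormalize(Reduce(`+`, maps) / length(maps))
}

#' Shannon entropy of a saliency map
#'
#' Treats the map as a probability distribution over its pixels (values
#' normalized to sum to one) and returns the base-2 Shannon entropy, with
#' `0 log 0 = 0`. The uniform 200x200 map attains the maximum
#' `log2(40000) ~= 15.29` bits.
#'
#' @param map non-zero, nonnegative 200x200 matrix.
#' @return entropy in bits.
#' @export
mapEntropy <- function(map) {
  if (any(map < 0)) stop("map values must be nonnegative", call. = FALSE)
  s <- sum(map)
  if (s <= 0) stop("mapEntropy is undefined for an all-zero map", call. = FALSE)
  p <- map[map > 0] / s
  -sum(p * log2(p))
}

#' Fraction of gaze points inside concentric center regions
#'
#' For each area fraction `f` the center region is the axis-aligned rectangle
#' concentric with the frame, with the frame's aspect ratio and linear scale
#' `sqrt(f)` (so its area is exactly `f` of the frame). A point counts as
#' inside when its pixel's center lies inside the region.
#'
#' @param gaze non-empty data.frame with canonical columns `x`, `y`.
#' @param fractions area fractions in `(0, 1]` (defaults follow common
#'   center-bias reporting: 2%, 11%, 25%, 65%).
#' @return data.frame with columns `fraction` and `percent` (0-100).
#' @export
centerFractionStats <- function(gaze, fractions = c(0.02, 0.11, 0.25, 0.65)) {
  if (is.null(gaze) || !nrow(gaze))
    stop("centerFractionStats needs at least one gaze point", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  n <- canonicalSize()
  cx <- floor(gaze$x) + 0.5
  cy <- floor(gaze$y) + 0.5
  pct <- vapply(fractions, function(f) {
    s <- (n / 2) * sqrt(f)
    lo <- n / 2 - s; hi <- n / 2 + s
    100 * mean(cx >= lo & cx <= hi & cy >= lo & cy <= hi)
  }, numeric(1))
  data.frame(fraction = fractions, percent = pct)
}

#' Percentage of gaze points falling inside target boxes
#'
#' @param gaze non-empty data.frame with canonical columns `x`, `y`.
#' @param boxes box data.frame (canonical, half-open); zero rows give 0.
#' @return percentage in `[0, 100]`.
#' @export
targetHitStats <- function(gaze, boxes = emptyBoxes()) {
  if (is.null(gaze) || !nrow(gaze))
    stop("targetHitStats needs at least one gaze point", call. = FALSE)
  if (is.null(boxes) || !nrow(boxes)) return(0)
  px <- floor(gaze$x); py <- floor(gaze$y)
  inside <- rep(FALSE, length(px))
  for (i in seq_len(nrow(boxes))) {
    inside <- inside |
      (px >= boxes$xmin[i] & px < boxes$xmax[i] &
       py >= boxes$ymin[i] & py < boxes$ymax[i])
  }
  100 * mean(inside)
}

#' Inter-observer map for one image
#'
#' The fixation map built from the pooled gaze of every subject except the
#' one under test; used to measure between-subject consistency.
#'
#' @param dataset a [GazeDataset-class].
#' @param imageId image to analyze.
#' @param excludedSubject subject whose gaze is left out.
#' @param sigma smoothing standard deviation, see [fixationMap()].
#' @return 200x200 matrix in `[0, 1]`.
#' @export
interobserverMap <- function(dataset, imageId, excludedSubject, sigma = 10) {
  g <- gazePoints(dataset, imageId)
  if (length(unique(g$subject)) < 2L)
    stop(sprintf("image '%s' has fewer than two subjects with gaze", imageId),
         call. = FALSE)
  fixationMap(g[g$subject != excludedSubject, , drop = FALSE], sigma)
}

#' Mean gaze count per stimulus, by category and target presence
#'
#' Arithmetic mean of per-image gaze-point counts (images without gaze
#' contribute zero), grouped by category and target-present flag. Groups
#' with no images are absent from the output.
#'
#' @param dataset a [GazeDataset-class].
#' @return data.frame with columns `category`, `target_present`,
#'   `mean_gaze`, `n_images`, ordered by category then target flag.
#' @export
gazeCountSummary <- function(dataset) {
  info <- imageInfo(dataset)
  if (!nrow(info))
    return(data.frame(category = character(), target_present = logical(),
                      mean_gaze = numeric(), n_images = integer(),
                      stringsAsFactors = FALSE))
  agg <- aggregate(n_gaze ~ category + target_present, data = info, FUN = mean)
  cnt <- aggregate(n_gaze ~ category + target_present, data = info, FUN = length)
  out <- data.frame(category = agg$category,
                    target_present = agg$target_present,
                    mean_gaze = agg$n_gaze,
                    n_images = cnt$n_gaze,
                    stringsAsFactors = FALSE)
  out[order(out$category, out$target_present), , drop = FALSE]
}
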