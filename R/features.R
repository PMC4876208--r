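# Bottom-up conspicuity channels in the center-surround tradition: Gaussian
# pyramids of intensity, color-opponency and oriented-energy maps, across-
# scale differences, peak-promoting normalization, and summation at the
# canonical frame. Depths and filter constants are sized for a 200x200 frame
# and exposed through conspicuityConfig().

#' Configuration of the conspicuity channels
#'
#' Returns (and optionally overrides) the constants of the bottom-up
#' channels: pyramid depth, center scales, center-surround deltas, Gabor
#' wavelength/bandwidth/orientations and the local-maximum threshold of the
#' peak-promoting normalization operator.
#'
#' @param ... named overrides of the defaults.
#' @return named list of constants.
#' @export
conspicuityConfig <- function(...) {
  cfg <- list(
    nLevels = 7L,            # pyramid levels 0..6 on the 200x200 frame
    centerScales = c(2L, 3L),
    surroundDeltas = c(2L, 3L),
    gaborLambda = 7,         # carrier wavelength, px
    gaborSigma = 0.56 * 7,   # isotropic Gaussian envelope, px
    gaborOrientations = c(0, 45, 90, 135),
    localMaxThreshold = 0.05
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop(sprintf("unknown conspicuity option(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  cfg
}

# Peak-promotion operator: normalize to [0,1], then scale by (M - mbar)^2
# where M is the global max (1 after normalization) and mbar the mean of the
# other local maxima. Maps with a single dominant peak keep their weight;
# maps with many comparable peaks are suppressed.
normalizePeaks <- function(m, threshold = 0.05) {
  mx <- max(m)
  # maps whose dynamic range is at numerical-noise level (e.g. FFT residue
  # on a contrast-free image) are genuinely empty
  if (mx <= 1e-9) return(m * 0)
  m <- m / mx
  nr <- nrow(m); nc <- ncol(m)
  isMax <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & (m >= m[clampIndex(nr, dy), clampIndex(nc, dx)])
  }
  peaks <- m[isMax & m > threshold]
  if (!length(peaks)) return(m)
  peaks <- sort(peaks, decreasing = TRUE)[-1]  # drop one instance of the global max
  mbar <- if (length(peaks)) mean(peaks) else 0
  m * (1 - mbar)^2
}

# Across-scale center-surround differences of one pyramid (optionally against
# a second pyramid for double-opponency), normalized, upsampled to the
# canonical frame and summed.
centerSurroundSum <- function(pyr, pyrOpp = NULL, cfg) {
  n <- canonicalSize()
  acc <- matrix(0, n, n)
  for (cs in cfg$centerScales) {
    for (d in cfg$surroundDeltas) {
      s <- cs + d
      ctr <- pyr[[cs + 1L]]
      srd <- if (is.null(pyrOpp)) pyr[[s + 1L]] else pyrOpp[[s + 1L]]
      diffMap <- abs(ctr - bilinearResize(srd, nrow(ctr), ncol(ctr)))
      diffMap <- normalizePeaks(diffMap, cfg$localMaxThreshold)
      acc <- acc + bilinearResize(diffMap, n, n)
    }
  }
  acc
}

gaborKernel <- function(lambda, sigma, thetaDeg, phase) {
  r <- ceiling(2.5 * sigma)
  d <- seq(-r, r)
  dx <- matrix(d, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  dy <- matrix(d, 2 * r + 1, 2 * r + 1)
  th <- thetaDeg * pi / 180
  xr <- dx * cos(th) + dy * sin(th)
  k <- exp(-(dx^2 + dy^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda + phase)
  k - mean(k)  # zero DC response
}

#' Oriented Gabor energy of an intensity image
#'
#' Quadrature-pair Gabor energy at one orientation:
#' `sqrt(even^2 + odd^2)` of replicate-padded convolutions with zero-mean
#' even and odd Gabor kernels. Orientation 0 responds maximally to vertical
#' stripes (intensity varying along x).
#'
#' @param intensity numeric matrix.
#' @param thetaDeg orientation in degrees.
#' @param lambda carrier wavelength in pixels.
#' @param sigma Gaussian envelope standard deviation in pixels.
#' @return matrix of the same size.
#' @export
gaborEnergy <- function(intensity, thetaDeg, lambda = 7, sigma = 0.56 * lambda) {
  keyBase <- sprintf("gabor_%g_%g_%g", lambda, sigma, thetaDeg)
  ev <- conv2same(intensity, gaborKernel(lambda, sigma, thetaDeg, 0),
                  cacheKey = paste0(keyBase, "_even"))
  od <- conv2same(intensity, gaborKernel(lambda, sigma, thetaDeg, pi / 2),
                  cacheKey = paste0(keyBase, "_odd"))
  sqrt(ev^2 + od^2)
}

#' Bottom-up conspicuity channels of a canonical image
#'
#' Computes the color, intensity and orientation conspicuity maps of a
#' 200x200 RGB image by center-surround contrast on Gaussian pyramids:
#' intensity uses `I = (r + g + b)/3`; color uses red-green and blue-yellow
#' double-opponency; orientation uses Gabor energy at four orientations (the
#' energy is computed at full resolution and then itself pyramided). Each
#' across-scale difference map passes through the peak-promoting
#' normalization operator, is upsampled to 200x200 and summed per channel;
#' each channel is finally max-normalized to `[0, 1]`. A channel with no
#' contrast anywhere comes back as the all-zero map.
#'
#' @param image an [ImageRecord-class] or a `200 x 200 x 3` pixel array on
#'   the `[0, 255]` scale.
#' @param cfg constants from [conspicuityConfig()].
#' @return named list of three 200x200 matrices: `color`, `intensity`,
#'   `orientation`.
#' @export
conspicuityChannels <- function(image, cfg = conspicuityConfig()) {
  px <- if (is(image, "ImageRecord")) image@pixels else image
  n <- canonicalSize()
  if (!identical(dim(px)[1:2], c(n, n)) || length(dim(px)) != 3L)
    stop("conspicuityChannels requires a canonical 200x200 RGB image", call. = FALSE)
  r <- px[, , 1] / 255; g <- px[, , 2] / 255; b <- px[, , 3] / 255
  I <- (r + g + b) / 3

  # Broadly-tuned opponent channels (negative responses clipped at zero)
  R <- pmax(r - (g + b) / 2, 0)
  G <- pmax(g - (r + b) / 2, 0)
  B <- pmax(b - (r + g) / 2, 0)
  Y <- pmax((r + g) / 2 - abs(r - g) / 2 - b, 0)

  pyrI <- gaussianPyramid(I, cfg$nLevels)
  pyrRG <- gaussianPyramid(R - G, cfg$nLevels)
  pyrGR <- gaussianPyramid(G - R, cfg$nLevels)
  pyrBY <- gaussianPyramid(B - Y, cfg$nLevels)
  pyrYB <- gaussianPyramid(Y - B, cfg$nLevels)

  intensity <- centerSurroundSum(pyrI, NULL, cfg)
  color <- centerSurroundSum(pyrRG, pyrGR, cfg) +
    centerSurroundSum(pyrBY, pyrYB, cfg)

  orientation <- matrix(0, n, n)
  for (th in cfg$gaborOrientations) {
    en <- gaborEnergy(I, th, cfg$gaborLambda, cfg$gaborSigma)
    orientation <- orientation +
      centerSurroundSum(gaussianPyramid(en, cfg$nLevels), NULL, cfg)
  }

  list(color = maxNormalize(color),
       intensity = maxNormalize(intensity),
       orientation = maxNormalize(orientation))
}

#' Target-location feature map
#'
#' Inside each target box the value is the Euclidean distance from the pixel
#' center to the box center, divided by the box half-diagonal (so it lies in
#' `[0, 1]`, zero at the center). Where several boxes cover a pixel the
#' minimum normalized distance is taken; pixels outside every box are 0. The
#' optional inverted encoding maps covered pixels to `1 - distance` (peak at
#' the box center) and keeps 0 outside.
#'
#' @param boxes box data.frame in canonical coordinates (may have zero rows).
#' @param inverted logical; use the inverted (peaked) encoding.
#' @return 200x200 matrix in `[0, 1]`.
#' @export
targetFeatureMap <- function(boxes = emptyBoxes(), inverted = FALSE) {
  n <- canonicalSize()
  out <- matrix(0, n, n)
  if (is.null(boxes) || !nrow(boxes)) return(out)
  if (any(boxes$xmin < 0 | boxes$ymin < 0 | boxes$xmax > n | boxes$ymax > n))
    stop("bounding box outside the canonical 200x200 frame", call. = FALSE)
  dist <- matrix(Inf, n, n)
  for (i in seq_len(nrow(boxes))) {
    x0 <- boxes$xmin[i]; x1 <- boxes$xmax[i]
    y0 <- boxes$ymin[i]; y1 <- boxes$ymax[i]
    cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
    hd <- sqrt(((x1 - x0) / 2)^2 + ((y1 - y0) / 2)^2)
    xs <- seq(x0, x1 - 1) + 0.5
    ys <- seq(y0, y1 - 1) + 0.5
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+")) / hd
    rows <- (y0 + 1):y1; cols <- (x0 + 1):x1
    dist[rows, cols] <- pmin(dist[rows, cols], d)
  }
  covered <- is.finite(dist)
  out[covered] <- if (inverted) 1 - dist[covered] else dist[covered]
  out
}

#' Center-bias feature map
#'
#' Euclidean distance from each pixel center to the frame center, normalized
#' by the half-diagonal (distance from the frame center to a corner pixel
#' center) so values lie in `[0, 1]`, are 0 nearest the center and exactly 1
#' at the four corner pixels. The map is a fixed constant of the canonical
#' frame and is cached after the first call.
#'
#' @return 200x200 matrix in `[0, 1]`.
#' @export
centerBiasMap <- function() {
  if (!is.null(.tsCache[["centerBias"]])) return(.tsCache[["centerBias"]])
  n <- canonicalSize()
  c0 <- n / 2              # frame center in continuous coordinates
  p <- seq_len(n) - 0.5    # pixel centers
  d <- sqrt(outer((p - c0)^2, (p - c0)^2, "+"))
  m <- d / max(d)
  .tsCache[["centerBias"]] <- m
  m
}

#' Build the five-map feature stack of one image
#'
#' Runs the conspicuity channels, the target-location feature and the
#' center-bias feature and stacks them in the fixed order of
#' [featureNames()], each map individually max-normalized to `[0, 1]`
#' (all-zero maps stay zero).
#'
#' @param image canonical [ImageRecord-class] (200x200).
#' @param boxes canonical box data.frame for this image.
#' @param invertedTarget logical; use the inverted target encoding.
#' @param cfg conspicuity constants, see [conspicuityConfig()].
#' @return a [FeatureStack-class].
#' @export
buildFeatureStack <- function(image, boxes = emptyBoxes(),
                              invertedTarget = FALSE,
                              cfg = conspicuityConfig()) {
  n <- canonicalSize()
  ch <- conspicuityChannels(image, cfg)
  f <- array(0, dim = c(n, n, 5L), dimnames = list(NULL, NULL, featureNames()))
  f[, , "color"] <- ch$color
  f[, , "intensity"] <- ch$intensity
  f[, , "orientation"] <- ch$orientation
  f[, , "target"] <- maxNormalize(targetFeatureMap(boxes, inverted = invertedTarget))
  f[, , "center"] <- maxNormalize(centerBiasMap())
  id <- if (is(image, "ImageRecord")) image@id else "unnamed"
  new("FeatureStack", features = f, imageId = id)
}

#' Compute feature stacks for every image of a dataset
#'
#' @param dataset a [GazeDataset-class] whose images are canonical 200x200.
#' @param invertedTarget,cfg passed to [buildFeatureStack()].
#' @return named list of [FeatureStack-class], one per image.
#' @export
buildFeatureStacks <- function(dataset, invertedTarget = FALSE,
                               cfg = conspicuityConfig()) {
  ids <- imageIds(dataset)
  stacks <- lapply(ids, function(id)
    buildFeatureStack(getImage(dataset, id), boxesFor(dataset, id),
                      invertedTarget = invertedTarget, cfg = cfg))
  names(stacks) <- ids
  stacks
}

#' Export a feature stack as CSV
#'
#' Writes either five float-CSV maps (`<prefix>_<feature>.csv`) or a single
#' long table with columns `x, y, color, intensity, orientation, target,
#' center`.
#'
#' @param stack a [FeatureStack-class].
#' @param prefix output path prefix (maps mode) or file path (table mode).
#' @param mode `"maps"` or `"table"`.
#' @return invisibly, the paths written.
#' @export
writeFeatureStack <- function(stack, prefix, mode = c("maps", "table")) {
  mode <- match.arg(mode)
  if (mode == "maps") {
    paths <- character(0)
    for (nm in featureNames()) {
      p <- paste0(prefix, "_", nm, ".csv")
      writeSaliencyMap(featureMap(stack, nm), p, mode = "float_csv")
      paths <- c(paths, p)
    }
    invisible(paths)
  } else {
    n <- canonicalSize()
    grid <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
    tab <- cbind(grid, vapply(featureNames(), function(nm) {
      m <- featureMap(stack, nm)
      m[cbind(grid$y + 1, grid$x + 1)]
    }, numeric(nrow(grid))))
    utils::write.csv(tab, prefix, row.names = FALSE)
    invisible(prefix)
  }
}
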