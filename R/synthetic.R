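# Synthetic scene-and-gaze generator. Scenes are 200x200 noise backgrounds
# with colored distractor shapes and, on target-present stimuli, 1-4
# category-colored target rectangles. Per-subject gaze is an i.i.d. mixture
# of target-centered, image-center-biased and uniform components, emulating
# the structure task-driven eye-tracking data exhibits.

#' Configuration of the synthetic dataset generator
#'
#' Defaults emulate a desk-scale visual-search study: 8 search categories, 11
#' subjects, about 59% target-present stimuli per category, 1-4 targets per
#' target-present scene, and a gaze mixture dominated by the target (60%)
#' with a center-biased (30%) and a uniform (10%) component. `sigmaTarget`
#' and `sigmaCenter` are the Gaussian spreads (px) of the target-centered and
#' center-biased components on the 200x200 frame.
#'
#' @param nImagesPerCategory images per category (default 10).
#' @param categories category names (default: eight common object classes).
#' @param targetPresentFraction fraction of target-present images (0.59).
#' @param nSubjects simulated subjects (11).
#' @param nGazePerSubjectPerImage gaze samples per subject per image (30).
#' @param mix length-3 numeric `(p_target, p_center, p_uniform)`, summing
#'   to 1.
#' @param sigmaTarget,sigmaCenter component spreads in pixels (8 and 30).
#' @param nTargetsRange integer `(min, max)` targets per target-present
#'   scene (1-4).
#' @param boxSizeRange `(min, max)` box side length in pixels (20-60).
#' @param seed master seed.
#' @return validated configuration list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nImagesPerCategory = 10,
                            categories = c("airplane", "bicycle", "boat",
                                           "car", "cat", "chair", "dog",
                                           "horse"),
                            targetPresentFraction = 0.59,
                            nSubjects = 11,
                            nGazePerSubjectPerImage = 30,
                            mix = c(0.6, 0.3, 0.1),
                            sigmaTarget = 8,
                            sigmaCenter = 30,
                            nTargetsRange = c(1, 4),
                            boxSizeRange = c(20, 60),
                            seed = 1) {
  cfg <- list(nImagesPerCategory = as.integer(nImagesPerCategory),
              categories = categories,
              targetPresentFraction = targetPresentFraction,
              nSubjects = as.integer(nSubjects),
              nGazePerSubjectPerImage = as.integer(nGazePerSubjectPerImage),
              mix = as.numeric(mix), sigmaTarget = sigmaTarget,
              sigmaCenter = sigmaCenter,
              nTargetsRange = as.integer(nTargetsRange),
              boxSizeRange = as.numeric(boxSizeRange),
              seed = as.integer(seed))
  if (length(cfg$mix) != 3L || any(cfg$mix < 0) || abs(sum(cfg$mix) - 1) > 1e-12)
    stop("mix must be three nonnegative weights summing to 1", call. = FALSE)
  if (cfg$targetPresentFraction < 0 || cfg$targetPresentFraction > 1)
    stop("targetPresentFraction must lie in [0, 1]", call. = FALSE)
  if (cfg$nTargetsRange[1] < 1 || cfg$nTargetsRange[2] < cfg$nTargetsRange[1])
    stop("invalid nTargetsRange", call. = FALSE)
  if (cfg$boxSizeRange[1] < 2 || cfg$boxSizeRange[2] < cfg$boxSizeRange[1] ||
      cfg$boxSizeRange[2] > canonicalSize())
    stop("invalid boxSizeRange", call. = FALSE)
  if (cfg$sigmaTarget <= 0 || cfg$sigmaCenter <= 0)
    stop("component sigmas must be positive", call. = FALSE)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# Fixed palette: each category has its own fill color; distractors on a
# scene reuse the palette colors of the *other* categories, so bottom-up
# color contrast alone cannot identify the target.
basePalette <- function() {
  matrix(c(
    200, 60, 60,
    60, 200, 60,
    60, 60, 200,
    200, 200, 60,
    200, 60, 200,
    60, 200, 200,
    230, 140, 40,
    120, 80, 200
  ), ncol = 3, byrow = TRUE)
}

categoryPalette <- function(categories) {
  base <- basePalette()
  idx <- ((seq_along(categories) - 1) %% nrow(base)) + 1
  out <- base[idx, , drop = FALSE]
  rownames(out) <- categories
  out
}

# Axis-aligned overlap test on half-open boxes.
boxesOverlap <- function(b, xmin, ymin, xmax, ymax) {
  if (!nrow(b)) return(FALSE)
  any(b$xmin < xmax & b$xmax > xmin & b$ymin < ymax & b$ymax > ymin)
}

#' Generate one synthetic scene
#'
#' A 200x200 low-amplitude-noise background with 2-5 colored distractor
#' shapes (rectangles and discs in other categories' colors) and, when
#' `targetPresent`, a uniform 1-4 (per `nTargetsRange`) non-overlapping
#' target rectangles in the category's color, each recorded as a bounding
#' box.
#'
#' @param config a [syntheticConfig()].
#' @param category scene category (must be in `config$categories`).
#' @param targetPresent logical.
#' @param id image id (default derived from the category).
#' @param seed integer seed for this scene.
#' @return list with `image` ([ImageRecord-class]) and `boxes` (data.frame).
#' @export
generateScene <- function(config, category, targetPresent, id = NULL,
                          seed = config$seed) {
  n <- canonicalSize()
  if (!category %in% config$categories)
    stop(sprintf("unknown category '%s'", category), call. = FALSE)
  if (is.null(id)) id <- paste0(category, "_scene")
  pal <- categoryPalette(config$categories)
  withSeed(seed, {
    px <- array(rep(pmin(pmax(120 + matrix(stats::rnorm(n * n, 0, 8), n, n), 0), 255), 3),
                dim = c(n, n, 3))
    boxes <- emptyBoxes()
    if (targetPresent) {
      kTargets <- sample(seq(config$nTargetsRange[1], config$nTargetsRange[2]), 1)
      for (t in seq_len(kTargets)) {
        placed <- FALSE
        for (attempt in seq_len(1000)) {
          w <- round(stats::runif(1, config$boxSizeRange[1], config$boxSizeRange[2]))
          h <- round(stats::runif(1, config$boxSizeRange[1], config$boxSizeRange[2]))
          x0 <- sample(0:(n - w), 1); y0 <- sample(0:(n - h), 1)
          if (!boxesOverlap(boxes, x0, y0, x0 + w, y0 + h)) { placed <- TRUE; break }
        }
        if (!placed)
          stop("could not place non-overlapping target boxes after 1000 attempts",
               call. = FALSE)
        boxes <- rbind(boxes, data.frame(
          image_id = id, label = category,
          xmin = x0, ymin = y0, xmax = x0 + w, ymax = y0 + h,
          stringsAsFactors = FALSE))
        col <- pal[category, ]
        for (ch in 1:3)
          px[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), ch] <-
            pmin(pmax(col[ch] + stats::rnorm(h * w, 0, 5), 0), 255)
      }
    }
    catRow <- ((match(category, config$categories) - 1) %% nrow(basePalette())) + 1
    distractorPal <- basePalette()[-catRow, , drop = FALSE]
    nDistract <- sample(2:5, 1)
    placedBoxes <- boxes
    for (dIdx in seq_len(nDistract)) {
      dRow <- sample.int(nrow(distractorPal), 1)
      done <- FALSE
      for (attempt in seq_len(1000)) {
        w <- round(stats::runif(1, config$boxSizeRange[1], config$boxSizeRange[2]))
        h <- round(stats::runif(1, config$boxSizeRange[1], config$boxSizeRange[2]))
        x0 <- sample(0:(n - w), 1); y0 <- sample(0:(n - h), 1)
        if (!boxesOverlap(placedBoxes, x0, y0, x0 + w, y0 + h)) { done <- TRUE; break }
      }
      if (!done) next  # crowded scene: silently drop the distractor
      placedBoxes <- rbind(placedBoxes, data.frame(
        image_id = id, label = sprintf("distractor_%d", dRow),
        xmin = x0, ymin = y0, xmax = x0 + w, ymax = y0 + h,
        stringsAsFactors = FALSE))
      col <- distractorPal[dRow, ]
      if (dIdx %% 2 == 0) {
        for (ch in 1:3)
          px[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), ch] <-
            pmin(pmax(col[ch] + stats::rnorm(h * w, 0, 5), 0), 255)
      } else {
        cx <- x0 + w / 2; cy <- y0 + h / 2; rad <- min(w, h) / 2
        ys <- (y0 + 1):(y0 + h); xs <- (x0 + 1):(x0 + w)
        disc <- outer((ys - 0.5 - cy)^2, (xs - 0.5 - cx)^2, "+") <= rad^2
        for (ch in 1:3) {
          block <- px[ys, xs, ch]
          block[disc] <- pmin(pmax(col[ch] + stats::rnorm(sum(disc), 0, 5), 0), 255)
          px[ys, xs, ch] <- block
        }
      }
    }
    img <- new("ImageRecord", id = id, pixels = px, category = category,
               targetPresent = isTRUE(targetPresent))
    list(image = img, boxes = boxes)
  })
}

# Draw m in-frame points from one mixture component by truncated resampling.
sampleComponent <- function(m, mu, sigma) {
  n <- canonicalSize()
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < m) {
    need <- m - length(xs)
    x <- stats::rnorm(need, mu[1], sigma)
    y <- stats::rnorm(need, mu[2], sigma)
    keep <- x >= 0 & x < n & y >= 0 & y < n
    xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
  }
  cbind(xs, ys)
}

#' Simulate per-subject gaze on a scene
#'
#' Each subject contributes `nGazePerSubjectPerImage` i.i.d. points from the
#' mixture: with probability `p_target` a Gaussian (sd `sigmaTarget`) around
#' a uniformly chosen target-box center, with `p_center` a Gaussian (sd
#' `sigmaCenter`) at the frame center, otherwise uniform over the frame.
#' Out-of-frame draws are resampled. On scenes with no boxes the target
#' weight is dropped and the center/uniform weights renormalized (uniform if
#' both are zero). Coordinates are floored to canonical pixel indices.
#'
#' @param boxes box data.frame of the scene (possibly empty).
#' @param config a [syntheticConfig()].
#' @param imageId id recorded in the output.
#' @param seed integer seed.
#' @return gaze data.frame (`subject`, `image_id`, `x`, `y`, `t` = NA).
#' @export
simulateGaze <- function(boxes, config, imageId, seed = config$seed) {
  n <- canonicalSize()
  mix <- config$mix
  hasBoxes <- !is.null(boxes) && nrow(boxes) > 0
  if (!hasBoxes) {
    rest <- mix[2] + mix[3]
    mix <- if (rest > 0) c(0, mix[2] / rest, mix[3] / rest) else c(0, 0, 1)
  }
  withSeed(seed, {
    out <- list()
    for (s in seq_len(config$nSubjects)) {
      m <- config$nGazePerSubjectPerImage
      comp <- sample.int(3, m, replace = TRUE, prob = mix)
      pts <- matrix(0, m, 2)
      for (i in seq_len(m)) {
        pts[i, ] <- switch(comp[i],
          {
            j <- sample.int(nrow(boxes), 1)
            mu <- c((boxes$xmin[j] + boxes$xmax[j]) / 2,
                    (boxes$ymin[j] + boxes$ymax[j]) / 2)
            sampleComponent(1, mu, config$sigmaTarget)
          },
          sampleComponent(1, c(n / 2, n / 2), config$sigmaCenter),
          c(stats::runif(1, 0, n), stats::runif(1, 0, n)))
      }
      out[[s]] <- data.frame(
        subject = sprintf("S%02d", s), image_id = imageId,
        x = pmin(floor(pts[, 1]), n - 1), y = pmin(floor(pts[, 2]), n - 1),
        t = NA_real_, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate a full synthetic dataset
#'
#' For every category, `nImagesPerCategory` scenes (the first
#' `round(fraction * n)` target-present, the rest target-absent) with
#' per-subject gaze, reproducible from `config$seed`.
#'
#' @param config a [syntheticConfig()].
#' @return a [GazeDataset-class] with canonical 200x200 images.
#' @export
generateDataset <- function(config = syntheticConfig()) {
  images <- list(); gaze <- list(); boxes <- list()
  for (cc in config$categories) {
    nPresent <- round(config$targetPresentFraction * config$nImagesPerCategory)
    for (i in seq_len(config$nImagesPerCategory)) {
      id <- sprintf("%s_%03d", cc, i)
      present <- i <= nPresent
      sc <- generateScene(config, cc, present, id = id,
                          seed = deriveSeed(config$seed, paste0("scene_", id)))
      g <- simulateGaze(sc$boxes, config, id,
                        seed = deriveSeed(config$seed, paste0("gaze_", id)))
      images[[id]] <- sc$image
      gaze[[id]] <- g
      if (nrow(sc$boxes)) boxes[[id]] <- sc$boxes
    }
  }
  GazeDataset(images, do.call(rbind, gaze),
              if (length(boxes)) do.call(rbind, boxes) else emptyBoxes())
}
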