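test_that("contrast-free images yield all-zero conspicuity channels", {
  ch <- conspicuityChannels(makeFlatImage(128))
  expect_equal(ch$color, matrix(0, 200, 200))
  expect_equal(ch$intensity, matrix(0, 200, 200))
  expect_equal(ch$orientation, matrix(0, 200, 200))
})

test_that("achromatic images have a zero color channel", {
  n <- canonicalSize()
  set.seed(11)
  gray <- matrix(runif(n * n, 0, 255), n, n)
  img <- array(rep(gray, 3), dim = c(n, n, 3))
  ch <- conspicuityChannels(img)
  expect_equal(ch$color, matrix(0, n, n))
  expect_gt(max(ch$intensity), 0)
})

test_that("a bright square on a dark field peaks the intensity channel at the square", {
  n <- canonicalSize()
  img <- array(10, dim = c(n, n, 3))
  img[93:108, 93:108, ] <- 245  # 16x16 bright square
  ch <- conspicuityChannels(img)
  peak <- which(ch$intensity == max(ch$intensity), arr.ind = TRUE)[1, ]
  # largest surround level is 6 (downsampling factor 64): allow the peak
  # anywhere inside the square dilated by that radius
  expect_true(peak["row"] >= 93 - 64 && peak["row"] <= 108 + 64)
  expect_true(peak["col"] >= 93 - 64 && peak["col"] <= 108 + 64)

  # independent check: a brute-force multi-scale Gaussian center-surround
  # oracle on the same image also peaks at the square
  I <- img[, , 1] / 255
  oracle <- matrix(0, n, n)
  for (s in c(4, 8, 16)) {
    fine <- I
    coarseK <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * s^2))
    coarseK <- coarseK / rowSums(coarseK)
    coarse <- coarseK %*% I %*% t(coarseK)
    oracle <- oracle + abs(fine - coarse)
  }
  opeak <- which(oracle == max(oracle), arr.ind = TRUE)[1, ]
  expect_true(opeak["row"] >= 92 && opeak["row"] <= 109)
  expect_true(opeak["col"] >= 92 && opeak["col"] <= 109)
})

test_that("Gabor energy is orientation selective and matches direct convolution", {
  n <- canonicalSize()
  stripes <- matrix(rep(c(rep(1, 4), rep(0, 4)), length.out = n), n, n,
                    byrow = TRUE)  # vertical stripes, variation along x
  e0 <- gaborEnergy(stripes, 0)
  e90 <- gaborEnergy(stripes, 90)
  expect_gt(mean(e0), mean(e90))

  # direct spatial-domain oracle at interior pixels
  set.seed(5)
  pts <- cbind(sample(40:160, 6), sample(40:160, 6))
  for (th in c(0, 45, 90)) {
    mine <- gaborEnergy(stripes, th)[pts]
    oracle <- directGaborEnergyAt(stripes, th, 7, 0.56 * 7, pts)
    expect_equal(mine, oracle, tolerance = 1e-8)
  }
})

test_that("conspicuity is invariant to a constant intensity shift", {
  n <- canonicalSize()
  set.seed(21)
  base <- array(runif(n * n * 3, 40, 160), dim = c(n, n, 3))
  ch1 <- conspicuityChannels(base)
  ch2 <- conspicuityChannels(base + 40)
  expect_equal(ch1$intensity, ch2$intensity, tolerance = 1e-8)
  expect_equal(ch1$color, ch2$color, tolerance = 1e-8)
  expect_equal(ch1$orientation, ch2$orientation, tolerance = 1e-6)
})

test_that("target feature encodes normalized distance-to-box-center", {
  # odd-sized box: its center coincides with a pixel center
  box <- data.frame(image_id = "i", label = "t",
                    xmin = 50, ymin = 50, xmax = 59, ymax = 59)
  m <- targetFeatureMap(box)
  expect_equal(m[55, 55], 0)           # pixel (54,54) = box center
  expect_equal(m[10, 10], 0)           # outside every box
  expect_equal(m[1, 1], 0)
  # corner pixel approaches 1 (discretized by half a pixel per axis)
  halfDiag <- sqrt(2) * 4.5
  cornerExpected <- sqrt(2) * 4 / halfDiag
  expect_equal(m[51, 51], cornerExpected, tolerance = 1e-12)
  expect_lte(max(m), 1)

  # nested concentric boxes: minimum of the two normalized distances
  outer_ <- data.frame(image_id = "i", label = "t",
                       xmin = 40, ymin = 40, xmax = 80, ymax = 80)
  inner_ <- data.frame(image_id = "i", label = "t",
                       xmin = 50, ymin = 50, xmax = 70, ymax = 70)
  both <- rbind(outer_, inner_)
  mm <- targetFeatureMap(both)
  # candidate pixel (55, 60): enumerate both encodings directly
  px <- c(55.5, 60.5)  # pixel centers of x = 55, y = 60
  dOuter <- sqrt(sum((px - c(60, 60))^2)) / sqrt(2 * 20^2)
  dInner <- sqrt(sum((px - c(60, 60))^2)) / sqrt(2 * 10^2)
  expect_equal(mm[61, 56], min(dOuter, dInner), tolerance = 1e-12)

  # inverted encoding peaks at the box center and is 0 outside
  inv <- targetFeatureMap(box, inverted = TRUE)
  expect_equal(inv[55, 55], 1)
  expect_equal(inv[10, 10], 0)

  expect_error(targetFeatureMap(data.frame(image_id = "i", label = "t",
                                           xmin = -5, ymin = 0,
                                           xmax = 10, ymax = 10)),
               "canonical")
})

test_that("target map is zero everywhere iff there are no boxes", {
  expect_equal(targetFeatureMap(emptyBoxes()), matrix(0, 200, 200))
  set.seed(8)
  for (i in 1:5) {
    x0 <- sample(0:150, 1); y0 <- sample(0:150, 1)
    b <- data.frame(image_id = "i", label = "t", xmin = x0, ymin = y0,
                    xmax = x0 + sample(5:40, 1), ymax = y0 + sample(5:40, 1))
    expect_gt(sum(targetFeatureMap(b) > 0), 0)
  }
})

test_that("center-bias map is symmetric, extremal at corners, and cached", {
  m <- centerBiasMap()
  # the four pixels around the frame center share the minimum
  ctr <- c(m[100, 100], m[100, 101], m[101, 100], m[101, 101])
  expect_equal(max(ctr) - min(ctr), 0)
  expect_equal(min(m), m[100, 100])
  expect_equal(m[1, 1], 1)
  # invariant under quarter turns
  rot90 <- function(x) t(apply(x, 2, rev))
  expect_equal(m, rot90(m), tolerance = 1e-12)
  expect_identical(centerBiasMap(), m)  # byte-identical cached artifact
})

test_that("feature stacks have five named in-range maps and are deterministic", {
  ds <- makeTinyDataset(seed = 9, nImages = 2)
  id <- imageIds(ds)[1]
  st <- buildFeatureStack(getImage(ds, id), boxesFor(ds, id))
  expect_s4_class(st, "FeatureStack")
  expect_identical(dimnames(featureArray(st))[[3]], featureNames())
  expect_true(all(is.finite(featureArray(st))))
  expect_gte(min(featureArray(st)), 0)
  expect_lte(max(featureArray(st)), 1)

  # no boxes: target plane zero, others untouched
  st0 <- buildFeatureStack(getImage(ds, id), emptyBoxes())
  expect_equal(featureMap(st0, "target"), matrix(0, 200, 200))
  expect_equal(featureMap(st0, "color"), featureMap(st, "color"))

  # determinism
  st2 <- buildFeatureStack(getImage(ds, id), boxesFor(ds, id))
  expect_identical(featureArray(st), featureArray(st2))
})

test_that("feature values stay in range on random images and boxes (fuzz)", {
  n <- canonicalSize()
  set.seed(31)
  for (i in 1:3) {
    img <- array(runif(n * n * 3, 0, 255), dim = c(n, n, 3))
    x0 <- sample(0:180, 1); y0 <- sample(0:180, 1)
    b <- data.frame(image_id = "i", label = "t", xmin = x0, ymin = y0,
                    xmax = min(x0 + sample(3:50, 1), n),
                    ymax = min(y0 + sample(3:50, 1), n))
    rec <- new("ImageRecord", id = "fuzz", pixels = img,
               category = "c", targetPresent = TRUE)
    f <- featureArray(buildFeatureStack(rec, b))
    expect_true(all(is.finite(f)))
    expect_gte(min(f), 0)
    expect_lte(max(f), 1)
  }
})
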