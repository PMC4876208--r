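test_that("training-pixel sampling respects strata, counts and determinism", {
  set.seed(4)
  map <- matrix(runif(40000), 200, 200)
  s <- sampleTrainingPixels(map, seed = 1)
  expect_equal(sum(s$label == 1), 20)
  expect_equal(sum(s$label == -1), 20)
  expect_equal(nrow(unique(s[, c("x", "y")])), 40)  # all distinct pixels
  expect_true(all(s$value[s$label == 1] >= quantile(map, 0.8)))
  expect_true(all(s$value[s$label == -1] <= quantile(map, 0.7)))

  # value looked up at the right pixel
  expect_equal(s$value, map[cbind(s$y + 1, s$x + 1)])

  expect_identical(sampleTrainingPixels(map, seed = 7),
                   sampleTrainingPixels(map, seed = 7))
  expect_false(identical(sampleTrainingPixels(map, seed = 7),
                         sampleTrainingPixels(map, seed = 8)))

  # two-level map whose top stratum is exactly the 1-valued pixels
  two <- matrix(0, 200, 200)
  two[seq_len(8000)] <- 1
  s2 <- sampleTrainingPixels(two, seed = 2)
  expect_true(all(s2$value[s2$label == 1] == 1))
  expect_true(all(s2$value[s2$label == -1] == 0))

  expect_error(sampleTrainingPixels(matrix(0, 200, 200)), "all-zero")
  expect_error(sampleTrainingPixels(map, nPos = 50000), "top stratum")
})

test_that("assembled training sets look up the named feature planes", {
  ds <- makeTinyDataset(seed = 13, nImages = 2)
  ids <- imageIds(ds)[1:2]
  stacks <- lapply(ids, function(id)
    buildFeatureStack(getImage(ds, id), boxesFor(ds, id)))
  names(stacks) <- ids
  samples <- rbind(
    data.frame(image_id = ids[1], x = c(5, 100), y = c(10, 150), label = c(1, -1)),
    data.frame(image_id = ids[2], x = 60, y = 70, label = 1))
  ts <- assembleTrainingSet(stacks, samples)
  expect_equal(dim(ts$X), c(3, 5))
  expect_equal(colnames(ts$X), featureNames())
  expect_equal(unname(ts$X[1, "center"]),
               featureMap(stacks[[ids[1]]], "center")[11, 6])
  expect_equal(unname(ts$X[3, "target"]),
               featureMap(stacks[[ids[2]]], "target")[71, 61])
  expect_equal(ts$y, c(1, -1, 1))

  samples$image_id[2] <- "ghost"
  expect_error(assembleTrainingSet(stacks, samples), "ghost")
})

test_that("standardization is train-estimated and leak-free", {
  set.seed(6)
  X <- cbind(a = rnorm(100, 5, 2), b = runif(100))
  st <- standardizeFeatures(X, other = X)
  expect_lt(max(abs(colMeans(st$train))), 1e-9)
  expect_lt(max(abs(apply(st$train, 2, sd) - 1)), 1e-9)
  expect_identical(st$train, st$other)

  Y <- cbind(a = rnorm(10, 100, 1), b = runif(10))
  st2 <- standardizeFeatures(X, other = Y)
  expect_equal(st2$other, sweep(sweep(Y, 2, st2$means), 2, st2$sds, "/"))

  Xc <- cbind(a = rnorm(10), b = rep(3, 10))
  expect_error(standardizeFeatures(Xc), "b")
})

test_that("the linear max-margin fit finds separating directions deterministically", {
  n <- 60
  X <- cbind(f1 = rep(c(1, -1), each = n), f2 = rep(0, 2 * n))
  y <- rep(c(1, -1), each = n)
  fit <- trainLinearSvm(X, y)
  expect_gt(fit$weights[["f1"]], 0)
  expect_lt(abs(fit$weights[["f2"]]), 1e-3)

  flip <- trainLinearSvm(X, -y)
  expect_equal(flip$weights, -fit$weights, tolerance = 1e-6)
  expect_equal(flip$bias, -fit$bias, tolerance = 1e-6)

  expect_identical(trainLinearSvm(X, y), trainLinearSvm(X, y))
  expect_error(trainLinearSvm(X, rep(1, 2 * n)), "both classes")
})

test_that("the learned direction agrees with a logistic-regression oracle", {
  ds <- makeTinyDataset(seed = 33, nImages = 5, nSubjects = 4, nGaze = 40,
                        mix = c(0.9, 0.05, 0.05))
  stacks <- buildFeatureStacks(ds)
  model <- fitSaliencyModel(ds, stacks, category = "all", seed = 3)
  w <- modelWeights(model)

  # refit the same training set with glm as an independent reference
  info <- imageInfo(ds)
  ids <- info$image_id[info$n_gaze > 0]
  samples <- do.call(rbind, lapply(ids, function(id) {
    tm <- fixationMap(gazePoints(ds, id), 10)
    s <- sampleTrainingPixels(tm, seed = TaskSaliency:::deriveSeed(3, paste0("sample_", id)))
    s$image_id <- id
    s
  }))
  ts <- assembleTrainingSet(stacks, samples)
  st <- standardizeFeatures(ts$X)
  glmFit <- suppressWarnings(
    glm((ts$y + 1) / 2 ~ st$train, family = binomial()))
  wGlm <- coef(glmFit)[-1]
  names(wGlm) <- colnames(st$train)

  # the two fits point the same way: high cosine similarity and matching
  # signs on the decisive features
  cosine <- sum(w * wGlm) / sqrt(sum(w^2) * sum(wGlm^2))
  expect_gt(cosine, 0.9)
  expect_gt(w[["target"]] * wGlm[["target"]], 0)
  expect_gt(w[["center"]] * wGlm[["center"]], 0)
})

test_that("saliency prediction is a standardized weighted sum with min-max scaling", {
  ds <- makeTinyDataset(seed = 14, nImages = 2)
  id <- imageIds(ds)[1]
  stack <- buildFeatureStack(getImage(ds, id), boxesFor(ds, id))

  mk <- function(w, bias = 0) new("TrainedModel",
    weights = w, bias = bias,
    featureMeans = setNames(rep(0, 5), featureNames()),
    featureSds = setNames(rep(1, 5), featureNames()),
    category = "t", cost = 1)

  oneHot <- mk(setNames(c(0, 0, 0, 0, -1), featureNames()))
  pred <- predictSaliency(oneHot, stack)
  ctr <- featureMap(stack, "center")
  expect_equal(pred, (max(ctr) - ctr) / (max(ctr) - min(ctr)), tolerance = 1e-12)
  expect_equal(which.max(pred), which.min(ctr))  # peak at the frame center

  flat <- mk(setNames(rep(0, 5), featureNames()))
  expect_equal(predictSaliency(flat, stack), matrix(0, 200, 200))

  w <- setNames(c(0.2, -0.1, 0.4, 1.2, -0.8), featureNames())
  expect_equal(predictSaliency(mk(w, 0.3), stack),
               predictSaliency(mk(2 * w, 0.6), stack), tolerance = 1e-12)
})

test_that("cross-validation folds partition the images and reruns are identical", {
  ds <- makeTinyDataset(seed = 15, nImages = 4, nSubjects = 3, nGaze = 25)
  stacks <- buildFeatureStacks(ds)

  cv <- crossValidate(ds, stacks = stacks, k = 4, seed = 5)
  expect_equal(sort(cv@imageAuc$image_id), sort(imageIds(ds)))
  expect_equal(length(unique(cv@imageAuc$fold)), 4)
  expect_true(all(table(cv@imageAuc$image_id) == 1))
  expect_true(all(cv@imageAuc$auc >= 0 & cv@imageAuc$auc <= 1))

  cv2 <- crossValidate(ds, stacks = stacks, k = 4, seed = 5)
  expect_identical(cv@imageAuc, cv2@imageAuc)
  expect_identical(cv@foldAuc, cv2@foldAuc)

  # leave-one-image-out per category: k = images per category
  cvLoo <- crossValidate(ds, stacks = stacks, k = 4, sigma = 10, seed = 2)
  expect_equal(cvLoo@k, 4L)

  expect_error(crossValidate(ds, stacks = stacks, k = 50), "folds")
})

test_that("weight reports aggregate per category with population SD and ranks", {
  mk <- function(w, cat) new("TrainedModel",
    weights = setNames(w, featureNames()), bias = 0,
    featureMeans = setNames(rep(0, 5), featureNames()),
    featureSds = setNames(rep(1, 5), featureNames()),
    category = cat, cost = 1)
  w <- c(0.1, -0.5, 0.2, 1.5, -1.0)

  rep1 <- weightReport(list(mk(w, "dog"), mk(w, "dog")))
  expect_equal(rep1$std_weight, rep(0, 5))
  expect_equal(rep1$avg_weight, unname(w))
  expect_equal(rep1$abs_rank, c(5, 3, 4, 1, 2))

  rep2 <- weightReport(list(mk(w, "dog"), mk(-w, "dog")))
  expect_equal(rep2$avg_weight, rep(0, 5))

  rep3 <- weightReport(list(mk(w, "dog"), mk(w, "cat"),
                            mk(-w, "dog"), mk(2 * w, "cat")))
  expect_equal(unique(rep3$category), c("cat", "dog"))
  expect_equal(nrow(rep3), 10)

  expect_error(weightReport(list(mk(w, "dog"))), "two runs")
})

test_that("trained models round-trip through the flat text serialization", {
  ds <- makeTinyDataset(seed = 16, nImages = 2)
  stacks <- buildFeatureStacks(ds)
  m <- fitSaliencyModel(ds, stacks, category = "dog", seed = 4)
  p <- file.path(withr::local_tempdir(), "model.txt")
  writeTrainedModel(m, p)
  m2 <- readTrainedModel(p)
  expect_equal(modelWeights(m2), modelWeights(m))
  expect_equal(modelBias(m2), modelBias(m))
  expect_equal(m2@featureMeans, m@featureMeans)
  expect_equal(m2@featureSds, m@featureSds)
  expect_equal(modelCategory(m2), "dog")
})
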