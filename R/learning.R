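# Training-pixel sampling, feature standardization, the linear max-margin
# model, prediction and cross-validation.

#' Sample labeled training pixels from a ground-truth map
#'
#' Draws `nPos` pixels uniformly without replacement from the top `topFrac`
#' quantile of map values (label +1) and `nNeg` from the bottom `bottomFrac`
#' quantile (label -1). Quantile thresholds are computed over all 40,000
#' pixels and ties at a threshold belong to the stratum; a pixel already
#' drawn as a positive is never reused as a negative, so all samples are
#' distinct pixels.
#'
#' @param map non-zero 200x200 ground-truth saliency matrix.
#' @param nPos,nNeg sample counts (defaults 20 and 20).
#' @param topFrac,bottomFrac strata as value-quantile fractions (defaults:
#'   top 20% salient, bottom 70%).
#' @param seed optional integer; when given, sampling is done under a local
#'   RNG state so results are reproducible and the caller's stream is
#'   untouched.
#' @return data.frame with columns `x`, `y` (0-based), `label` (+1/-1) and
#'   `value` (the map value at the pixel).
#' @export
sampleTrainingPixels <- function(map, nPos = 20, nNeg = 20,
                                 topFrac = 0.20, bottomFrac = 0.70,
                                 seed = NULL) {
  n <- canonicalSize()
  v <- as.vector(map)  # column-major: index = x * 200 + y + 1
  if (max(v) <= 0)
    stop("cannot sample from an all-zero ground-truth map", call. = FALSE)
  thrTop <- stats::quantile(v, 1 - topFrac, names = FALSE)
  thrBot <- stats::quantile(v, bottomFrac, names = FALSE)
  top <- which(v >= thrTop)
  bottom <- which(v <= thrBot)
  if (length(top) < nPos)
    stop(sprintf("top stratum has %d pixels, need %d", length(top), nPos),
         call. = FALSE)
  withSeed(seed, {
    posIdx <- sample(top, nPos)
    bottom <- setdiff(bottom, posIdx)
    if (length(bottom) < nNeg)
      stop(sprintf("bottom stratum has %d pixels, need %d", length(bottom), nNeg),
           call. = FALSE)
    negIdx <- sample(bottom, nNeg)
    idx <- c(posIdx, negIdx)
    data.frame(
      x = (idx - 1) %/% n,
      y = (idx - 1) %% n,
      label = rep(c(1, -1), c(nPos, nNeg)),
      value = v[idx]
    )
  })
}

#' Assemble a training set from feature stacks and sampled pixels
#'
#' @param stacks named list of [FeatureStack-class] (names = image ids).
#' @param samples data.frame with columns `image_id`, `x`, `y`, `label`.
#' @param features feature subset to use, in [featureNames()] order.
#' @return list with `X` (N x features matrix), `y` (+1/-1 labels) and
#'   `provenance` (data.frame `image_id`, `x`, `y`).
#' @export
assembleTrainingSet <- function(stacks, samples, features = featureNames()) {
  features <- match.arg(features, featureNames(), several.ok = TRUE)
  dangling <- setdiff(unique(samples$image_id), names(stacks))
  if (length(dangling))
    stop(sprintf("samples reference images without feature stacks: %s",
                 paste(dangling, collapse = ", ")), call. = FALSE)
  X <- matrix(0, nrow(samples), length(features),
              dimnames = list(NULL, features))
  for (id in unique(samples$image_id)) {
    sel <- which(samples$image_id == id)
    f <- featureArray(stacks[[id]])
    for (nm in features)
      X[sel, nm] <- f[, , nm][cbind(samples$y[sel] + 1, samples$x[sel] + 1)]
  }
  list(X = X, y = samples$label,
       provenance = samples[, c("image_id", "x", "y")])
}

#' Standardize features to zero mean and unit variance
#'
#' Column means and standard deviations are estimated on `train` only; the
#' same statistics are applied to `other` (e.g. a test set), keeping the
#' evaluation leakage-free.
#'
#' @param train numeric matrix (rows = samples, named columns = features).
#' @param other optional matrix with the same columns.
#' @return list with `train`, `other` (or NULL), `means`, `sds`.
#' @export
standardizeFeatures <- function(train, other = NULL) {
  mu <- colMeans(train)
  sds <- apply(train, 2, stats::sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop(sprintf("zero-variance feature(s): %s",
                 paste(colnames(train)[zero], collapse = ", ")), call. = FALSE)
  scale2 <- function(m) sweep(sweep(m, 2, mu), 2, sds, "/")
  list(train = scale2(train),
       other = if (is.null(other)) NULL else scale2(other),
       means = mu, sds = sds)
}

#' Train the linear max-margin pixel classifier
#'
#' Fits a soft-margin linear support-vector machine (L2-regularized hinge
#' loss, cost `C`) on standardized features. The weight vector is recovered
#' from the support-vector expansion and oriented so that positive scores
#' favor the +1 (salient) class; training is deterministic for identical
#' inputs.
#'
#' @param X numeric matrix of standardized features (named columns).
#' @param y labels in `{+1, -1}`; both classes must be present.
#' @param C soft-margin cost (default 1).
#' @param tol optimizer termination tolerance.
#' @return list with `weights` (named), `bias`.
#' @export
trainLinearSvm <- function(X, y, C = 1, tol = 1e-6) {
  if (length(unique(y)) < 2L)
    stop("training requires both classes", call. = FALSE)
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "linear",
                    cost = C, tolerance = tol, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  s <- drop(X %*% w) + b
  if (mean(s[y == 1]) < mean(s[y == -1])) { w <- -w; b <- -b }
  names(w) <- colnames(X)
  list(weights = w, bias = b)
}

#' Fit a task-saliency model for one image set
#'
#' The complete per-category training stage: builds a continuous ground-truth
#' map per image from its pooled gaze (smoothing `sigma`), samples `nPos` +
#' `nNeg` pixels per image from the top/bottom strata, standardizes the
#' assembled features and trains the linear max-margin classifier.
#'
#' @param dataset a [GazeDataset-class] (canonical images).
#' @param stacks named list of [FeatureStack-class] covering `ids`.
#' @param ids image ids to train on (default: all images with gaze).
#' @param category category tag stored in the model.
#' @param sigma ground-truth smoothing in pixels.
#' @param C soft-margin cost.
#' @param nPos,nNeg,topFrac,bottomFrac passed to [sampleTrainingPixels()].
#' @param features feature subset to train on.
#' @param seed master seed; per-image sampling seeds are derived from it.
#' @param truthMaps optional named list of precomputed ground-truth maps
#'   (as from [fixationMap()]), to avoid recomputation across folds.
#' @return a [TrainedModel-class].
#' @export
fitSaliencyModel <- function(dataset, stacks, ids = NULL,
                             category = "all", sigma = 10, C = 1,
                             nPos = 20, nNeg = 20,
                             topFrac = 0.20, bottomFrac = 0.70,
                             features = featureNames(), seed = 1,
                             truthMaps = NULL) {
  if (is.null(ids)) {
    info <- imageInfo(dataset)
    ids <- info$image_id[info$n_gaze > 0]
  }
  if (!length(ids)) stop("no images with gaze to train on", call. = FALSE)
  samples <- do.call(rbind, lapply(ids, function(id) {
    tm <- if (!is.null(truthMaps)) truthMaps[[id]] else
      fixationMap(gazePoints(dataset, id), sigma)
    s <- sampleTrainingPixels(tm, nPos, nNeg, topFrac, bottomFrac,
                              seed = deriveSeed(seed, paste0("sample_", id)))
    s$image_id <- id
    s
  }))
  ts <- assembleTrainingSet(stacks, samples, features)
  # a feature can be constant across the sampled pixels (e.g. no sampled
  # pixel touches a target box); it carries no information for this fit,
  # so it is dropped from training and kept with weight 0
  sds0 <- apply(ts$X, 2, stats::sd)
  live <- names(sds0)[sds0 > 0]
  if (!length(live))
    stop("all features are constant across the sampled pixels", call. = FALSE)
  dropped <- setdiff(colnames(ts$X), live)
  if (length(dropped))
    warning(sprintf("constant feature(s) dropped from training: %s",
                    paste(dropped, collapse = ", ")))
  st <- standardizeFeatures(ts$X[, live, drop = FALSE])
  fit <- trainLinearSvm(st$train, ts$y, C = C)
  feats <- colnames(ts$X)
  weights <- stats::setNames(rep(0, length(feats)), feats)
  means <- stats::setNames(colMeans(ts$X), feats)
  sds <- stats::setNames(rep(1, length(feats)), feats)
  weights[live] <- fit$weights
  means[live] <- st$means
  sds[live] <- st$sds
  new("TrainedModel", weights = weights, bias = fit$bias,
      featureMeans = means, featureSds = sds,
      category = category, cost = C)
}

#' Predict a saliency map from a trained model
#'
#' Standardizes each pixel's feature values with the model's stored
#' statistics, takes the weighted sum plus bias, and min-max normalizes the
#' score map to `[0, 1]` (a constant score map becomes all-zero).
#'
#' @param model a [TrainedModel-class].
#' @param stack a [FeatureStack-class].
#' @return 200x200 matrix in `[0, 1]`.
#' @export
predictSaliency <- function(model, stack) {
  n <- canonicalSize()
  f <- featureArray(stack)
  score <- matrix(model@bias, n, n)
  for (nm in names(model@weights)) {
    z <- (f[, , nm] - model@featureMeans[[nm]]) / model@featureSds[[nm]]
    score <- score + model@weights[[nm]] * z
  }
  minMaxNormalize(score)
}

#' k-fold cross-validation of the task-saliency model
#'
#' Partitions the images uniformly at random into `k` folds (stratified by
#' category, so every fold sees every category). For each fold, one model
#' per category is trained on the remaining images and each held-out image
#' is scored by [aucScore()] of the predicted map against its pooled gaze
#' pixels. A fixed `seed` makes folds, sampling and training fully
#' reproducible.
#'
#' @param dataset a [GazeDataset-class] (canonical images, with gaze).
#' @param stacks optional precomputed stacks; computed when `NULL`.
#' @param k fold count (default 5).
#' @param sigma,C,nPos,nNeg,topFrac,bottomFrac,features as in
#'   [fitSaliencyModel()].
#' @param seed master seed.
#' @return a [CrossValResult-class].
#' @export
crossValidate <- function(dataset, stacks = NULL, k = 5, sigma = 10, C = 1,
                          nPos = 20, nNeg = 20, topFrac = 0.20,
                          bottomFrac = 0.70, features = featureNames(),
                          seed = 1) {
  info <- imageInfo(dataset)
  info <- info[info$n_gaze > 0, , drop = FALSE]
  if (nrow(info) < k)
    stop(sprintf("%d images with gaze cannot form %d folds", nrow(info), k),
         call. = FALSE)
  if (is.null(stacks)) stacks <- buildFeatureStacks(dataset)
  truthMaps <- lapply(stats::setNames(info$image_id, info$image_id),
                      function(id) fixationMap(gazePoints(dataset, id), sigma))
  fold <- integer(nrow(info))
  withSeed(deriveSeed(seed, "folds"), {
    for (cc in unique(info$category)) {
      sel <- which(info$category == cc)
      fold[sel] <- sample(rep_len(seq_len(k), length(sel)))
    }
  })
  rows <- list(); models <- vector("list", k); foldAuc <- numeric(k)
  for (f in seq_len(k)) {
    trainIds <- info$image_id[fold != f]
    testIds <- info$image_id[fold == f]
    catModels <- list()
    for (cc in sort(unique(info$category))) {
      cIds <- intersect(trainIds, info$image_id[info$category == cc])
      if (!length(cIds)) next
      catModels[[cc]] <- fitSaliencyModel(
        dataset, stacks, ids = cIds, category = cc, sigma = sigma, C = C,
        nPos = nPos, nNeg = nNeg, topFrac = topFrac, bottomFrac = bottomFrac,
        features = features, seed = deriveSeed(seed, paste0("fit_", f, "_", cc)),
        truthMaps = truthMaps)
    }
    models[[f]] <- catModels
    aucs <- numeric(0)
    for (id in testIds) {
      cc <- info$category[info$image_id == id]
      if (is.null(catModels[[cc]])) next
      pred <- predictSaliency(catModels[[cc]], stacks[[id]])
      a <- aucScore(pred, gazePoints(dataset, id))
      aucs <- c(aucs, a)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, category = cc, fold = f, auc = a,
        stringsAsFactors = FALSE)
    }
    foldAuc[f] <- mean(aucs)
  }
  new("CrossValResult",
      imageAuc = do.call(rbind, rows),
      foldAuc = foldAuc, models = models, k = as.integer(k))
}

#' Per-category weight statistics across runs
#'
#' Summarizes the learned weights of a collection of models (e.g. the
#' per-fold models of repeated cross-validation runs): for each category and
#' feature, the mean (`avg_weight`), the population standard deviation
#' (`std_weight`) across runs, and the rank of `|avg_weight|` within the
#' category (1 = largest magnitude).
#'
#' @param models list of at least two [TrainedModel-class] objects.
#' @return data.frame with columns `category`, `feature`, `avg_weight`,
#'   `std_weight`, `abs_rank`; categories alphabetical, features in
#'   [featureNames()] order.
#' @export
weightReport <- function(models) {
  if (length(models) < 2L)
    stop("weightReport needs models from at least two runs", call. = FALSE)
  cats <- sort(unique(vapply(models, modelCategory, character(1))))
  out <- list()
  for (cc in cats) {
    ms <- Filter(function(m) modelCategory(m) == cc, models)
    feats <- names(modelWeights(ms[[1]]))
    W <- do.call(rbind, lapply(ms, modelWeights))
    avg <- colMeans(W)
    std <- apply(W, 2, popSd)
    out[[cc]] <- data.frame(
      category = cc, feature = feats,
      avg_weight = unname(avg), std_weight = unname(std),
      abs_rank = rank(-abs(avg), ties.method = "first"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize a trained model to a flat key-value text file
#'
#' @param model a [TrainedModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrainedModel <- function(model, path) {
  lines <- c(
    paste0("category: ", model@category),
    paste0("C: ", fullPrecision(model@cost)),
    paste0("features: ", paste(names(model@weights), collapse = ",")),
    paste0("weights: ", paste(fullPrecision(model@weights), collapse = ",")),
    paste0("bias: ", fullPrecision(model@bias)),
    paste0("means: ", paste(fullPrecision(model@featureMeans), collapse = ",")),
    paste0("sds: ", paste(fullPrecision(model@featureSds), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTrainedModel
#' @export
readTrainedModel <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read model: no such file '%s'", path), call. = FALSE)
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  feats <- strsplit(vals[["features"]], ",", fixed = TRUE)[[1]]
  numv <- function(key) {
    x <- as.numeric(strsplit(vals[[key]], ",", fixed = TRUE)[[1]])
    stats::setNames(x, if (length(x) == length(feats)) feats else NULL)
  }
  new("TrainedModel",
      weights = numv("weights"), bias = as.numeric(vals[["bias"]]),
      featureMeans = numv("means"), featureSds = numv("sds"),
      category = vals[["category"]], cost = as.numeric(vals[["C"]]))
}
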