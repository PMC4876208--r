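# ROC/AUC scoring of saliency maps against fixated pixels, per-category
# aggregation and inter-observer consistency.

# Normalize the many ways of saying "these pixels are fixated" to a logical
# matrix matching the prediction: a logical matrix, linear indices, or a
# gaze data.frame with 0-based x (column), y (row).
positiveMask <- function(positives, dims = c(canonicalSize(), canonicalSize())) {
  if (is.matrix(positives) && is.logical(positives)) {
    if (!identical(dim(positives), as.integer(dims)))
      stop("positive mask dimensions must match the prediction", call. = FALSE)
    return(positives)
  }
  m <- matrix(FALSE, dims[1], dims[2])
  if (is.data.frame(positives)) {
    if (!nrow(positives)) return(m)
    x <- floor(positives$x); y <- floor(positives$y)
    if (any(x < 0 | x >= dims[2] | y < 0 | y >= dims[1]))
      stop("gaze coordinates outside the frame", call. = FALSE)
    m[cbind(y + 1, x + 1)] <- TRUE
    return(m)
  }
  m[as.integer(positives)] <- TRUE
  m
}

#' ROC curve of a saliency map against fixated pixels
#'
#' Pixels holding at least one gaze point are the positives; all remaining
#' pixels are negatives. The threshold is swept over the distinct predicted
#' values (plus sentinels), classifying pixels with values strictly greater
#' than the threshold as fixated; `tpr`/`fpr` are the fractions of positives
#' and negatives above threshold. The curve includes the endpoints (0,0) and
#' (1,1).
#'
#' @param pred 200x200 predicted saliency matrix.
#' @param positives fixated pixels: a logical 200x200 mask, linear indices,
#'   or a gaze data.frame with canonical `x`, `y`.
#' @return data.frame with columns `threshold` (descending), `fpr`, `tpr`.
#' @export
rocCurve <- function(pred, positives) {
  pos <- positiveMask(positives, dim(pred))
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC needs at least one positive and one negative pixel", call. = FALSE)
  v <- as.vector(pred)
  isPos <- as.vector(pos)
  ord <- order(v, decreasing = TRUE)
  vs <- v[ord]
  # last index of each distinct value
  grpEnd <- c(which(vs[-length(vs)] != vs[-1]), length(vs))
  cumPos <- cumsum(isPos[ord])[grpEnd]
  cumNeg <- cumsum(!isPos[ord])[grpEnd]
  # fraction strictly above u_j = cumulative counts through u_{j-1}
  thr <- c(Inf, vs[grpEnd], -Inf)
  tpr <- c(0, 0, cumPos[-length(cumPos)], nPos)[seq_along(thr)] / nPos
  fpr <- c(0, 0, cumNeg[-length(cumNeg)], nNeg)[seq_along(thr)] / nNeg
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Area under the ROC curve
#'
#' `aucScore` computes the AUC directly from the prediction and the fixated
#' pixels with the rank (Mann-Whitney) formulation, so that tied predicted
#' values contribute 1/2: the result equals
#' `P(score_pos > score_neg) + 0.5 P(score_pos == score_neg)`.
#' `aucFromCurve` integrates a [rocCurve()] by the trapezoidal rule; the two
#' agree.
#'
#' @param pred 200x200 predicted saliency matrix.
#' @param positives fixated pixels, as in [rocCurve()].
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(pred, positives) {
  pos <- positiveMask(positives, dim(pred))
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs at least one positive and one negative pixel", call. = FALSE)
  r <- rank(as.vector(pred), ties.method = "average")
  (sum(r[as.vector(pos)]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' @rdname aucScore
#' @param curve a data.frame from [rocCurve()].
#' @export
aucFromCurve <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  fpr <- curve$fpr[o]; tpr <- curve$tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Evaluate per-category models over a dataset
#'
#' For every image that has gaze, predicts a saliency map with the model of
#' the image's category and scores it by [aucScore()] against the image's
#' fixated pixels (all subjects pooled). Images without gaze, or whose
#' category has no model, are skipped with a warning.
#'
#' @param models named list of [TrainedModel-class], names = categories.
#' @param dataset a [GazeDataset-class] (canonical images).
#' @param stacks optional precomputed named list of [FeatureStack-class];
#'   computed on the fly when `NULL`.
#' @return list with `perImage` (data.frame `image_id`, `category`, `auc`)
#'   and `perCategory` (data.frame `category`, `avg_auc`, `std_auc`
#'   (population), `n_images`, categories in alphabetical order).
#' @export
evaluateDataset <- function(models, dataset, stacks = NULL) {
  info <- imageInfo(dataset)
  rows <- list()
  for (i in seq_len(nrow(info))) {
    id <- info$image_id[i]; cat <- info$category[i]
    g <- gazePoints(dataset, id)
    if (!nrow(g)) { warning(sprintf("image '%s' has no gaze; skipped", id)); next }
    if (is.null(models[[cat]])) {
      warning(sprintf("no model for category '%s'; image '%s' skipped", cat, id))
      next
    }
    stack <- if (!is.null(stacks)) stacks[[id]] else
      buildFeatureStack(getImage(dataset, id), boxesFor(dataset, id))
    pred <- predictSaliency(models[[cat]], stack)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = id, category = cat,
      auc = aucScore(pred, g), stringsAsFactors = FALSE)
  }
  perImage <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), category = character(), auc = numeric())
  cats <- sort(unique(perImage$category))
  perCategory <- data.frame(
    category = cats,
    avg_auc = vapply(cats, function(cc) mean(perImage$auc[perImage$category == cc]), numeric(1)),
    std_auc = vapply(cats, function(cc) popSd(perImage$auc[perImage$category == cc]), numeric(1)),
    n_images = vapply(cats, function(cc) sum(perImage$category == cc), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(perImage = perImage, perCategory = perCategory)
}

#' Inter-observer consistency
#'
#' For each image and each subject with gaze on it, scores the
#' inter-observer map (all other subjects pooled, smoothed with `sigma`)
#' against that subject's fixated pixels by AUC; averages over subjects
#' within each image first, then over images, grouped by category and
#' target-present flag. Images with a single subject are skipped with a
#' warning; groups with no images are absent.
#'
#' @param dataset a [GazeDataset-class].
#' @param sigma smoothing standard deviation for the pooled map.
#' @return data.frame with columns `category`, `target_present`, `avg_auc`,
#'   `std_auc` (population, across images), `n_images`.
#' @export
ioConsistency <- function(dataset, sigma = 10) {
  info <- imageInfo(dataset)
  rows <- list()
  for (i in seq_len(nrow(info))) {
    id <- info$image_id[i]
    g <- gazePoints(dataset, id)
    subjects <- unique(g$subject)
    if (length(subjects) < 2L) {
      warning(sprintf("image '%s' has fewer than two subjects; skipped", id))
      next
    }
    aucs <- vapply(subjects, function(s) {
      io <- fixationMap(g[g$subject != s, , drop = FALSE], sigma)
      aucScore(io, g[g$subject == s, , drop = FALSE])
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      category = info$category[i], target_present = info$target_present[i],
      auc = mean(aucs), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(category = character(), target_present = logical(),
                      avg_auc = numeric(), std_auc = numeric(),
                      n_images = integer(), stringsAsFactors = FALSE))
  per <- do.call(rbind, rows)
  key <- unique(per[, c("category", "target_present")])
  key <- key[order(key$category, key$target_present), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(key)), function(j) {
    sel <- per$category == key$category[j] & per$target_present == key$target_present[j]
    data.frame(category = key$category[j], target_present = key$target_present[j],
               avg_auc = mean(per$auc[sel]), std_auc = popSd(per$auc[sel]),
               n_images = sum(sel), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
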