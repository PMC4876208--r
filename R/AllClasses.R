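#' @import methods
NULL

#' Canonical working-frame size and feature order
#'
#' All analysis happens on a fixed 200x200 pixel frame; every saliency and
#' feature map in the package is a 200x200 numeric matrix indexed
#' `[y + 1, x + 1]` with 0-based pixel coordinates (`x` = column, `y` = row).
#' The five per-pixel features are always kept in the order
#' color, intensity, orientation, target, center.
#'
#' @return `canonicalSize()` returns the integer 200; `featureNames()` the
#'   character vector of the five feature names in canonical order.
#' @export
canonicalSize <- function() 200L

#' @rdname canonicalSize
#' @export
featureNames <- function() c("color", "intensity", "orientation", "target", "center")

#' ImageRecord: a stimulus image
#'
#' An RGB raster with an identifier, a search category and a target-present
#' flag. Pixels are stored as an `height x width x 3` array of intensities in
#' `[0, 255]`.
#'
#' @slot id character image identifier.
#' @slot pixels numeric array, `height x width x 3`, values in `[0, 255]`.
#' @slot category character search category the image belongs to.
#' @slot targetPresent logical, whether the image contains at least one
#'   annotated target.
#' @export
setClass("ImageRecord",
  representation(
    id = "character",
    pixels = "array",
    category = "character",
    targetPresent = "logical"
  )
)

setValidity("ImageRecord", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must be at least 1x1")
  if (any(!is.finite(p)))
    return("pixel intensities must be finite")
  if (min(p) < 0 || max(p) > 255)
    return("pixel intensities must lie in [0, 255]")
  if (length(object@id) != 1L || !nzchar(object@id))
    return("id must be a non-empty string")
  TRUE
})

#' @describeIn ImageRecord image width in pixels.
#' @param object,x an `ImageRecord`.
#' @export
imageWidth <- function(x) dim(x@pixels)[2]

#' @describeIn ImageRecord image height in pixels.
#' @export
imageHeight <- function(x) dim(x@pixels)[1]

#' @describeIn ImageRecord image identifier.
#' @export
imageId <- function(x) x@id

setMethod("show", "ImageRecord", function(object) {
  cat(sprintf(
    "ImageRecord '%s' (%dx%d, category '%s', target %s)\n",
    object@id, imageWidth(object), imageHeight(object), object@category,
    if (object@targetPresent) "present" else "absent"
  ))
})

#' GazeDataset: images, gaze points and target boxes
#'
#' The central container tying together stimuli, per-subject gaze samples and
#' target bounding boxes. Gaze coordinates and boxes are 0-based with `x` the
#' column and `y` the row; boxes are half-open `[xmin, xmax) x [ymin, ymax)`.
#'
#' @slot images named list of [ImageRecord-class] objects (names = ids).
#' @slot gaze data.frame with columns `subject`, `image_id`, `x`, `y` and an
#'   optional `t` (milliseconds).
#' @slot boxes data.frame with columns `image_id`, `label`, `xmin`, `ymin`,
#'   `xmax`, `ymax`.
#' @export
setClass("GazeDataset",
  representation(
    images = "list",
    gaze = "data.frame",
    boxes = "data.frame"
  )
)

setValidity("GazeDataset", function(object) {
  ids <- names(object@images)
  if (length(object@images) && (is.null(ids) || any(!nzchar(ids))))
    return("images must be a named list")
  for (im in object@images) {
    if (!is(im, "ImageRecord")) return("images must contain ImageRecord objects")
  }
  g <- object@gaze
  need <- c("subject", "image_id", "x", "y")
  if (!all(need %in% names(g)))
    return("gaze must have columns subject, image_id, x, y")
  if (nrow(g)) {
    bad <- !(g$image_id %in% ids)
    if (any(bad))
      return(sprintf("gaze references unknown image ids (e.g. '%s')",
                     g$image_id[which(bad)[1]]))
    for (id in unique(g$image_id)) {
      im <- object@images[[id]]
      sub <- g[g$image_id == id, ]
      if (any(sub$x < 0 | sub$x >= imageWidth(im) |
              sub$y < 0 | sub$y >= imageHeight(im)))
        return(sprintf("gaze coordinates out of bounds for image '%s'", id))
    }
  }
  b <- object@boxes
  needb <- c("image_id", "label", "xmin", "ymin", "xmax", "ymax")
  if (!all(needb %in% names(b)))
    return("boxes must have columns image_id, label, xmin, ymin, xmax, ymax")
  if (nrow(b)) {
    bad <- !(b$image_id %in% ids)
    if (any(bad))
      return(sprintf("boxes reference unknown image ids (e.g. '%s')",
                     b$image_id[which(bad)[1]]))
    if (any(b$xmax <= b$xmin | b$ymax <= b$ymin))
      return("degenerate bounding box (xmax <= xmin or ymax <= ymin)")
  }
  TRUE
})

#' Construct a GazeDataset
#'
#' @param images named list of [ImageRecord-class] objects.
#' @param gaze data.frame of gaze points (`subject`, `image_id`, `x`, `y`).
#' @param boxes data.frame of boxes (`image_id`, `label`, `xmin`, `ymin`,
#'   `xmax`, `ymax`); defaults to none.
#' @return a validated `GazeDataset`.
#' @export
GazeDataset <- function(images, gaze, boxes = emptyBoxes()) {
  if (is.null(names(images)))
    names(images) <- vapply(images, imageId, character(1))
  new("GazeDataset", images = images, gaze = as.data.frame(gaze),
      boxes = as.data.frame(boxes))
}

#' @describeIn GazeDataset an empty, correctly-typed box table.
#' @export
emptyBoxes <- function() {
  data.frame(image_id = character(), label = character(),
             xmin = numeric(), ymin = numeric(),
             xmax = numeric(), ymax = numeric(),
             stringsAsFactors = FALSE)
}

#' @describeIn GazeDataset ids of all images, in storage order.
#' @param x a `GazeDataset`.
#' @export
imageIds <- function(x) names(x@images)

#' @describeIn GazeDataset one image record by id.
#' @param id image identifier.
#' @export
getImage <- function(x, id) {
  if (!id %in% names(x@images))
    stop(sprintf("unknown image id '%s'", id), call. = FALSE)
  x@images[[id]]
}

#' @describeIn GazeDataset gaze table, optionally restricted to one image.
#' @export
gazePoints <- function(x, id = NULL) {
  if (is.null(id)) x@gaze else x@gaze[x@gaze$image_id == id, , drop = FALSE]
}

#' @describeIn GazeDataset box table, optionally restricted to one image.
#' @export
boxesFor <- function(x, id = NULL) {
  if (is.null(id)) x@boxes else x@boxes[x@boxes$image_id == id, , drop = FALSE]
}

#' @describeIn GazeDataset per-image summary (id, category, target_present,
#'   n_gaze, n_boxes).
#' @export
imageInfo <- function(x) {
  ids <- imageIds(x)
  data.frame(
    image_id = ids,
    category = vapply(x@images, function(i) i@category, character(1)),
    target_present = vapply(x@images, function(i) i@targetPresent, logical(1)),
    n_gaze = vapply(ids, function(id) sum(x@gaze$image_id == id), integer(1)),
    n_boxes = vapply(ids, function(id) sum(x@boxes$image_id == id), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

setMethod("show", "GazeDataset", function(object) {
  info <- imageInfo(object)
  cat(sprintf(
    "GazeDataset: %d images, %d categories, %d gaze points, %d boxes\n",
    length(object@images), length(unique(info$category)),
    nrow(object@gaze), nrow(object@boxes)
  ))
})

#' FeatureStack: the five per-pixel feature maps of one image
#'
#' A `200 x 200 x 5` array holding, in fixed order, the color, intensity and
#' orientation conspicuity maps, the target-location map and the center-bias
#' map, each individually max-normalized to `[0, 1]`.
#'
#' @slot features numeric array `200 x 200 x 5`, third dimension named by
#'   [featureNames()].
#' @slot imageId character id of the source image.
#' @export
setClass("FeatureStack",
  representation(features = "array", imageId = "character")
)

setValidity("FeatureStack", function(object) {
  f <- object@features
  n <- canonicalSize()
  if (!identical(dim(f), c(n, n, 5L)))
    return("features must be a 200 x 200 x 5 array")
  if (!identical(dimnames(f)[[3]], featureNames()))
    return("feature planes must be named color, intensity, orientation, target, center")
  if (any(!is.finite(f))) return("feature values must be finite")
  if (min(f) < 0 || max(f) > 1 + 1e-12) return("feature values must lie in [0, 1]")
  TRUE
})

#' @describeIn FeatureStack extract one named feature plane as a matrix.
#' @param x a `FeatureStack`.
#' @param name one of [featureNames()].
#' @export
featureMap <- function(x, name) {
  name <- match.arg(name, featureNames())
  x@features[, , name]
}

#' @describeIn FeatureStack the full `200 x 200 x 5` array.
#' @export
featureArray <- function(x) x@features

setMethod("show", "FeatureStack", function(object) {
  cat(sprintf("FeatureStack for image '%s' (200x200, 5 maps)\n", object@imageId))
})

#' TrainedModel: a linear task-saliency model
#'
#' Per-feature weights, bias and the training-set standardization statistics
#' of one linear max-margin model, tagged with the search category it was
#' trained for. Weights are expressed on standardized features, so their
#' magnitudes are directly comparable across features.
#'
#' @slot weights named numeric vector of per-feature weights.
#' @slot bias numeric intercept.
#' @slot featureMeans,featureSds named numeric vectors: the training-set
#'   per-feature mean and standard deviation used for standardization.
#' @slot category character category tag.
#' @slot cost numeric soft-margin regularization constant (the SVM's C).
#' @export
setClass("TrainedModel",
  representation(
    weights = "numeric",
    bias = "numeric",
    featureMeans = "numeric",
    featureSds = "numeric",
    category = "character",
    cost = "numeric"
  )
)

setValidity("TrainedModel", function(object) {
  nm <- names(object@weights)
  if (is.null(nm) || !all(nm %in% featureNames()))
    return("weights must be named by known features")
  if (!identical(nm, names(object@featureMeans)) ||
      !identical(nm, names(object@featureSds)))
    return("weights, featureMeans and featureSds must share names")
  if (any(!is.finite(object@weights)) || !is.finite(object@bias))
    return("weights and bias must be finite")
  if (any(object@featureSds <= 0))
    return("featureSds must be positive")
  TRUE
})

#' @describeIn TrainedModel named weight vector.
#' @param x a `TrainedModel`.
#' @export
modelWeights <- function(x) x@weights

#' @describeIn TrainedModel intercept.
#' @export
modelBias <- function(x) x@bias

#' @describeIn TrainedModel category tag.
#' @export
modelCategory <- function(x) x@category

#' @describeIn TrainedModel soft-margin cost used in training.
#' @export
modelCost <- function(x) x@cost

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel (category '%s', C = %g)\n", object@category, object@cost))
  w <- format(round(object@weights, 4))
  cat(paste(sprintf("  %-12s %s", names(object@weights), w), collapse = "\n"),
      sprintf("\n  %-12s %s\n", "bias", format(round(object@bias, 4))))
})

#' CrossValResult: k-fold cross-validation output
#'
#' @slot imageAuc data.frame with one row per evaluated held-out image
#'   (`image_id`, `category`, `fold`, `auc`).
#' @slot foldAuc numeric per-fold mean AUC.
#' @slot models list (one element per fold) of named per-category model lists.
#' @slot k integer fold count.
#' @export
setClass("CrossValResult",
  representation(
    imageAuc = "data.frame",
    foldAuc = "numeric",
    models = "list",
    k = "integer"
  )
)

#' @describeIn CrossValResult mean of per-fold AUCs.
#' @param x a `CrossValResult`.
#' @export
cvMeanAuc <- function(x) mean(x@foldAuc)

#' @describeIn CrossValResult population standard deviation of per-fold AUCs.
#' @export
cvSdAuc <- function(x) popSd(x@foldAuc)

#' @describeIn CrossValResult flat list of all per-fold, per-category models.
#' @export
cvModels <- function(x) unlist(x@models, recursive = FALSE, use.names = FALSE)

setMethod("show", "CrossValResult", function(object) {
  cat(sprintf(
    "CrossValResult: k = %d, mean AUC = %.4f (population SD %.4f)\n",
    object@k, cvMeanAuc(object), cvSdAuc(object)
  ))
})
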