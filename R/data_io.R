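#' Read a stimulus image from PNG or JPEG
#'
#' Reads an image file into an [ImageRecord-class]. Grayscale files are
#' expanded to three identical channels; an alpha channel, if present, is
#' dropped. Intensities are returned on the `[0, 255]` scale.
#'
#' @param path path to a PNG or JPEG file.
#' @param id image identifier; defaults to the file name without extension.
#' @param category search category tag.
#' @param targetPresent logical target-present flag.
#' @return an [ImageRecord-class].
#' @export
readImageRecord <- function(path, id = NULL,
                            category = "uncategorized",
                            targetPresent = FALSE) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  img <- tryCatch(EBImage::readImage(path), error = function(e)
    stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  a <- EBImage::imageData(img)  # x (col) by y (row) [by channel], in [0, 1]
  if (length(dim(a)) == 2L) {
    arr <- array(rep(t(a), 3L), dim = c(ncol(a), nrow(a), 3L))
  } else {
    arr <- aperm(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(2, 1, 3))
    if (dim(arr)[3] == 1L) arr <- array(rep(arr, 3L), dim = c(dim(arr)[1:2], 3L))
  }
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  new("ImageRecord", id = id, pixels = arr * 255,
      category = category, targetPresent = targetPresent)
}

#' Read gaze points from CSV
#'
#' Expects a header `subject,image_id,x,y` with an optional trailing `t`
#' column (milliseconds). Coordinates are 0-based pixels (`x` = column). When
#' `images` is supplied, every point is validated against the half-open bounds
#' of its image (`0 <= x < width`, `0 <= y < height`) and offending rows are
#' reported rather than clamped.
#'
#' @param path CSV file path.
#' @param images optional named list of [ImageRecord-class] used for bounds
#'   validation.
#' @return data.frame with columns `subject`, `image_id`, `x`, `y`, `t` (NA
#'   when absent), one row per data row in file order.
#' @export
readFixations <- function(path, images = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read fixations: no such file '%s'", path), call. = FALSE)
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "image_id", "x", "y")
  if (!all(need %in% names(g)))
    stop(sprintf("fixation CSV '%s' must have columns subject,image_id,x,y", path),
         call. = FALSE)
  if (!"t" %in% names(g)) g[["t"]] <- rep(NA_real_, nrow(g))
  g <- g[, c("subject", "image_id", "x", "y", "t")]
  if (!is.null(images) && nrow(g)) {
    unknown <- which(!(g$image_id %in% names(images)))
    if (length(unknown))
      stop(sprintf("fixation rows reference unknown images: rows %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    w <- vapply(g$image_id, function(id) imageWidth(images[[id]]), numeric(1))
    h <- vapply(g$image_id, function(id) imageHeight(images[[id]]), numeric(1))
    bad <- which(g$x < 0 | g$x >= w | g$y < 0 | g$y >= h)
    if (length(bad))
      stop(sprintf("gaze coordinates outside image bounds: rows %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  g
}

#' Read target bounding boxes
#'
#' `readVocBoxes` parses a Pascal-VOC-style XML annotation, whose `bndbox`
#' coordinates are 1-based inclusive, and converts them to the package's
#' 0-based half-open convention (`xmin' = xmin - 1`, `xmax' = xmax`, same for
#' `y`). `readBoxesCsv` reads an equivalent CSV
#' (`image_id,label,xmin,ymin,xmax,ymax`) that is already 0-based half-open.
#'
#' @param path annotation file path.
#' @param imageId id to attach to the boxes; for XML defaults to the
#'   annotation's `filename` without extension.
#' @return data.frame of boxes in the [GazeDataset-class] box-table layout.
#' @export
readVocBoxes <- function(path, imageId = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read annotation: no such file '%s'", path), call. = FALSE)
  doc <- xml2::read_xml(path)
  if (is.null(imageId)) {
    fn <- xml2::xml_find_first(doc, ".//filename")
    imageId <- if (inherits(fn, "xml_missing")) sub("\\.[^.]+$", "", basename(path))
               else sub("\\.[^.]+$", "", xml2::xml_text(fn))
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  if (!length(objs)) return(emptyBoxes())
  rows <- lapply(objs, function(o) {
    lab <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    num <- function(tag) as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", tag))))
    c(xmin = num("xmin") - 1, ymin = num("ymin") - 1,
      xmax = num("xmax"), ymax = num("ymax"), label = lab)
  })
  b <- data.frame(
    image_id = imageId,
    label = vapply(rows, function(r) r[["label"]], character(1)),
    xmin = as.numeric(vapply(rows, function(r) r[["xmin"]], character(1))),
    ymin = as.numeric(vapply(rows, function(r) r[["ymin"]], character(1))),
    xmax = as.numeric(vapply(rows, function(r) r[["xmax"]], character(1))),
    ymax = as.numeric(vapply(rows, function(r) r[["ymax"]], character(1))),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(b[, c("xmin", "ymin", "xmax", "ymax")]))))
    stop(sprintf("malformed bndbox coordinates in '%s'", path), call. = FALSE)
  bad <- which(b$xmax <= b$xmin | b$ymax <= b$ymin)
  if (length(bad))
    stop(sprintf("degenerate bounding box in '%s' (object %s)", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  b
}

#' @rdname readVocBoxes
#' @export
readBoxesCsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read boxes: no such file '%s'", path), call. = FALSE)
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "label", "xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(b)))
    stop(sprintf("box CSV '%s' must have columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  if (!nrow(b)) return(emptyBoxes())
  bad <- which(b$xmax <= b$xmin | b$ymax <= b$ymin)
  if (length(bad))
    stop(sprintf("degenerate bounding box in '%s' (rows %s)", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  b[, need]
}

#' Write and read saliency maps
#'
#' Maps are 200x200 matrices with values in `[0, 1]`. Mode `"png8"` stores an
#' 8-bit grayscale PNG, quantized as `floor(255 v + 0.5)` (round half away
#' from zero), so a round trip is exact to within 1/255 per pixel. Mode
#' `"float_csv"` stores a headerless CSV at 17 significant digits, giving a
#' bit-exact round trip.
#'
#' @param map numeric matrix with values in `[0, 1]`.
#' @param path output (input) file path.
#' @param mode `"png8"` or `"float_csv"`.
#' @return `writeSaliencyMap` returns `path` invisibly; `readSaliencyMap`
#'   returns the map matrix.
#' @export
writeSaliencyMap <- function(map, path, mode = c("png8", "float_csv")) {
  mode <- match.arg(mode)
  if (any(!is.finite(map)) || min(map) < 0 || max(map) > 1)
    stop("saliency map values must be finite and lie in [0, 1]", call. = FALSE)
  if (mode == "png8") {
    bytes <- floor(map * 255 + 0.5)
    png::writePNG(bytes / 255, target = path)
  } else {
    lines <- apply(map, 1, function(r) paste(fullPrecision(r), collapse = ","))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname writeSaliencyMap
#' @export
readSaliencyMap <- function(path, mode = c("png8", "float_csv")) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    stop(sprintf("cannot read saliency map: no such file '%s'", path), call. = FALSE)
  if (mode == "png8") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    v
  } else {
    rows <- strsplit(readLines(path), ",", fixed = TRUE)
    do.call(rbind, lapply(rows, as.numeric))
  }
}

#' Rescale an image and its annotations to the canonical 200x200 frame
#'
#' The image is resampled bilinearly; gaze coordinates are multiplied by
#' `(200/width, 200/height)` and floored to pixel indices; box corners are
#' scaled the same way (and floored), then expanded to at least 1x1 if the
#' scaling collapsed them.
#'
#' @param image an [ImageRecord-class].
#' @param gaze optional gaze data.frame for this image.
#' @param boxes optional box data.frame for this image.
#' @return list with elements `image` (canonical [ImageRecord-class]), `gaze`
#'   and `boxes` (rescaled copies of the inputs).
#' @export
rescaleToCanonical <- function(image, gaze = NULL, boxes = NULL) {
  n <- canonicalSize()
  w <- imageWidth(image); h <- imageHeight(image)
  sx <- n / w; sy <- n / h
  px <- image@pixels
  out <- array(0, dim = c(n, n, 3L))
  for (ch in 1:3) out[, , ch] <- bilinearResize(px[, , ch], n, n)
  img <- new("ImageRecord", id = image@id, pixels = out,
             category = image@category, targetPresent = image@targetPresent)
  if (!is.null(gaze) && nrow(gaze)) {
    gaze$x <- pmin(floor(gaze$x * sx), n - 1)
    gaze$y <- pmin(floor(gaze$y * sy), n - 1)
  }
  if (!is.null(boxes) && nrow(boxes)) {
    boxes$xmin <- floor(boxes$xmin * sx); boxes$xmax <- floor(boxes$xmax * sx)
    boxes$ymin <- floor(boxes$ymin * sy); boxes$ymax <- floor(boxes$ymax * sy)
    grow <- boxes$xmax <= boxes$xmin
    boxes$xmax[grow] <- pmin(boxes$xmin[grow] + 1, n)
    boxes$xmin[grow] <- boxes$xmax[grow] - 1
    grow <- boxes$ymax <= boxes$ymin
    boxes$ymax[grow] <- pmin(boxes$ymin[grow] + 1, n)
    boxes$ymin[grow] <- boxes$ymax[grow] - 1
  }
  list(image = img, gaze = gaze, boxes = boxes)
}
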