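#' Count matrices and polygon labels
#'
#' A bone-scan image is a *count matrix*: each pixel holds the integer number
#' of detected gamma counts (16-bit unsigned on disk), not a radiometrically
#' normalized intensity. `count_matrix()` wraps an integer matrix together
#' with its pixel size and view tag.
#'
#' @param counts integer matrix of non-negative counts (rows = y, cols = x).
#' @param view one of `"anterior"`, `"posterior"`, `"aggregated"`, `"unknown"`.
#' @param pixel_size_mm physical pixel edge length in millimetres. The
#'   default 2.26 mm is the usual acquisition setting for 256x1024
#'   whole-body planar scans.
#' @return An object of class `count_matrix` with fields `counts`, `height`,
#'   `width`, `pixel_size_mm`, `view`.
#' @export
count_matrix <- function(counts, view = "unknown", pixel_size_mm = 2.26) {
  if (!is.matrix(counts)) stop_fmt("`counts` must be a matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop_fmt("count matrix must be at least 1x1")
  if (anyNA(counts)) stop_fmt("counts contain missing values")
  if (any(counts < 0)) stop_fmt("counts must be non-negative")
  if (any(counts != floor(counts))) stop_fmt("counts must be integers")
  view <- match.arg(view, c("anterior", "posterior", "aggregated", "unknown"))
  structure(
    list(counts = matrix(as.numeric(counts), nrow(counts), ncol(counts)),
         height = nrow(counts), width = ncol(counts),
         pixel_size_mm = pixel_size_mm, view = view),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %dx%d (%s view), c_max = %d, pixel %.2f mm\n",
              x$height, x$width, x$view, as.integer(max(x$counts)),
              x$pixel_size_mm))
  invisible(x)
}

#' Read a bone-scan count matrix
#'
#' Reads a 16-bit grayscale PNG (counts are the stored integer sample
#' values; no rescaling) or a raw whitespace-separated integer matrix file
#' with a JSON sidecar (`<path>.json` holding `height`, `width`, `view`,
#' `pixel_size_mm`).
#'
#' @param path file to read (`.png` or anything else treated as raw matrix).
#' @param view view tag to attach; for raw files, defaults to the sidecar's.
#' @return a [count_matrix].
#' @export
read_scan <- function(path, view = "unknown") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] > 1L && !all(img[, , 1] == img[, , -1]))
        stop_fmt("format error: %s is not single-channel grayscale", path)
      img <- img[, , 1]
    }
    # readPNG scales k-bit samples to [0, 1] by (2^k - 1); undo the scaling
    # at the file's declared depth so stored counts are recovered exactly.
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 16L
    if (depth > 16L)
      stop_fmt("format error: pixel depth %d exceeds 16-bit in %s", depth, path)
    counts <- round(img * (2^depth - 1))
    meta <- read_sidecar(path)
    count_matrix(counts, view = if (view == "unknown" && !is.null(meta$view))
      meta$view else view,
      pixel_size_mm = if (!is.null(meta$pixel_size_mm))
        meta$pixel_size_mm else 2.26)
  } else {
    meta <- read_sidecar(path)
    counts <- as.matrix(utils::read.table(path))
    dimnames(counts) <- NULL
    if (any(counts < 0)) stop_fmt("format error: negative pixel values in %s", path)
    if (any(counts > 65535))
      stop_fmt("format error: pixel depth exceeds 16-bit in %s", path)
    if (!is.null(meta$height) &&
        (nrow(counts) != meta$height || ncol(counts) != meta$width))
      stop_fmt("format error: matrix is %dx%d but sidecar says %dx%d",
               nrow(counts), ncol(counts), meta$height, meta$width)
    count_matrix(counts,
                 view = if (view == "unknown" && !is.null(meta$view))
                   meta$view else view,
                 pixel_size_mm = if (!is.null(meta$pixel_size_mm))
                   meta$pixel_size_mm else 2.26)
  }
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

#' Write a count matrix
#'
#' Writes a 16-bit grayscale PNG (for `.png` paths) or a raw integer matrix
#' file; both get a JSON sidecar `<path>.json` with the metadata. Counts must
#' fit in uint16. Round-trips through [read_scan()] bit-exactly.
#'
#' @param m a [count_matrix].
#' @param path destination file.
#' @export
write_scan <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  if (max(m$counts) > 65535)
    stop_fmt("range error: count %d exceeds 65535", as.integer(max(m$counts)))
  cnt <- matrix(as.integer(m$counts), m$height, m$width)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    .cpp_write_png16(cnt, path.expand(path))
  } else {
    utils::write.table(cnt, path, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(height = m$height, width = m$width, view = m$view,
         pixel_size_mm = m$pixel_size_mm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Polygon lesion label
#'
#' A manual lesion label is a closed curve `l = <p1, ..., pm = p1>` of
#' (x, y) points in pixel units (x = column, y = row, 0-based, origin
#' top-left, the LabelMe convention). An unclosed point list is closed by
#' appending the first point.
#'
#' @param points numeric matrix with columns x, y.
#' @param lesion_id,annotator_id identifiers.
#' @return object of class `polygon_label`.
#' @export
polygon_label <- function(points, lesion_id = "lesion", annotator_id = "a1") {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop_fmt("points must be an m x 2 matrix")
  if (anyNA(points)) stop_fmt("polygon contains missing coordinates")
  if (nrow(points) >= 2L && all(points[1L, ] == points[nrow(points), ]))
    open_pts <- points[-nrow(points), , drop = FALSE]
  else open_pts <- points
  if (nrow(unique(open_pts)) < 3L)
    stop_fmt("validation error: polygon needs at least 3 distinct vertices")
  closed <- rbind(open_pts, open_pts[1L, ])
  dimnames(closed) <- list(NULL, c("x", "y"))
  structure(list(points = closed, lesion_id = lesion_id,
                 annotator_id = annotator_id),
            class = "polygon_label")
}

#' Annotation set: one image, several annotators
#'
#' Bundles the polygon labels drawn independently by several annotators on
#' one image. The consensus protocol ([consensus_select()]) requires exactly
#' three annotators, with lesions matched across annotators by `lesion_id`.
#'
#' @param labels list of [polygon_label] objects.
#' @param image_ref identifier of the annotated image.
#' @return object of class `annotation_set` with `labels_by_annotator`.
#' @export
annotation_set <- function(labels, image_ref = "") {
  stopifnot(all(vapply(labels, inherits, logical(1), "polygon_label")))
  ann <- vapply(labels, `[[`, character(1), "annotator_id")
  structure(list(image_ref = image_ref,
                 labels_by_annotator = split(labels, ann)),
            class = "annotation_set")
}

#' Read LabelMe polygon annotations
#'
#' Parses the LabelMe JSON dialect: a top-level `"shapes"` list whose
#' entries carry `"label"`, `"points"` (list of `[x, y]`) and
#' `"shape_type" = "polygon"`. Lesion and annotator identifiers are parsed
#' from labels of the form `"<lesion>/<annotator>"`; a plain label is the
#' lesion id with annotator `"a1"`.
#'
#' @param path JSON file.
#' @return an [annotation_set].
#' @export
read_labelme <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  shapes <- doc$shapes
  if (is.null(shapes)) shapes <- list()
  labels <- lapply(shapes, function(s) {
    if (!is.null(s$shape_type) && !identical(s$shape_type, "polygon"))
      stop_fmt("unsupported shape_type '%s'", s$shape_type)
    pts <- do.call(rbind, lapply(s$points, function(p) c(p[[1]], p[[2]])))
    lab <- if (is.null(s$label)) "lesion" else s$label
    parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
    polygon_label(pts, lesion_id = parts[1],
                  annotator_id = if (length(parts) > 1) parts[2] else "a1")
  })
  annotation_set(labels, image_ref = if (is.null(doc$imagePath)) ""
                 else doc$imagePath)
}

#' Write LabelMe polygon annotations
#'
#' Inverse of [read_labelme()]; coordinates are preserved to full double
#' precision (well beyond the 6 decimals the round-trip guarantees).
#'
#' @param a an [annotation_set].
#' @param path destination JSON file.
#' @export
write_labelme <- function(a, path) {
  stopifnot(inherits(a, "annotation_set"))
  labels <- unlist(a$labels_by_annotator, recursive = FALSE, use.names = FALSE)
  shapes <- lapply(labels, function(l) {
    list(label = paste(l$lesion_id, l$annotator_id, sep = "/"),
         points = lapply(seq_len(nrow(l$points)),
                         function(i) as.numeric(l$points[i, ])),
         shape_type = "polygon")
  })
  jsonlite::write_json(list(imagePath = a$image_ref, shapes = shapes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
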