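#' Rasterize a polygon label to a binary lesion mask
#'
#' A pixel belongs to the mask iff its centre (integer coordinates,
#' origin top-left) lies inside or on the closed polygon, under the
#' even-odd rule. Rasterization is deterministic; the downstream loss and
#' all evaluation metrics are pixel-based, so masks (not analytic polygon
#' geometry) are the working representation of a label.
#'
#' @param l a [polygon_label].
#' @param height,width target grid size in pixels.
#' @param source provenance tag: `"manual"`, `"predicted"` or
#'   `"synthetic-truth"`.
#' @return object of class `lesion_mask`: integer 0/1 matrix `$mask` plus
#'   `$source`.
#' @export
polygon_to_mask <- function(l, height, width, source = "manual") {
  stopifnot(inherits(l, "polygon_label"))
  pts <- l$points[-nrow(l$points), , drop = FALSE]  # drop closing point
  if (abs(shoelace_area(pts)) < .Machine$double.eps)
    stop_fmt("validation error: polygon '%s' has zero area", l$lesion_id)
  if (any(pts[, 1] < -0.5 | pts[, 1] > width - 0.5 |
          pts[, 2] < -0.5 | pts[, 2] > height - 0.5))
    stop_fmt("validation error: polygon '%s' extends outside the %dx%d image",
             l$lesion_id, height, width)
  m <- .cpp_polygon_raster(pts[, 1], pts[, 2], as.integer(height),
                           as.integer(width))
  lesion_mask(matrix(as.integer(m), height, width), source = source)
}

#' @rdname polygon_to_mask
#' @param mask integer/logical 0-1 matrix.
#' @export
lesion_mask <- function(mask, source = c("manual", "predicted",
                                         "synthetic-truth")) {
  source <- match.arg(source)
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!all(mask %in% c(0L, 1L))) stop_fmt("mask values must be 0 or 1")
  structure(list(mask = mask, source = source), class = "lesion_mask")
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Pairwise annotation area difference
#'
#' The agreement measure between two manual labels of the same lesion:
#' `deltaA = 1 - |A1 and A2| / |A1 or A2|`, one minus the pixel IoU of the
#' rasterized masks. Symmetric, 0 for identical labels, 1 for disjoint ones.
#'
#' @param l1,l2 [polygon_label]s on the same grid.
#' @param height,width grid size.
#' @return `deltaA` in \[0, 1\].
#' @export
area_difference <- function(l1, l2, height, width) {
  m1 <- polygon_to_mask(l1, height, width)$mask
  m2 <- polygon_to_mask(l2, height, width)$mask
  uni <- sum(m1 | m2)
  if (uni == 0L) stop_fmt("both masks are empty; IoU undefined")
  1 - sum(m1 & m2) / uni
}

#' Consensus ground-truth selection with an agreement gate
#'
#' Implements the triple-annotation protocol: each lesion is labelled
#' independently by exactly three annotators; if every pairwise area
#' difference is at most `t_delta_A` (default 5%), one of the three labels
#' is chosen uniformly at random (seeded) as ground truth, otherwise the
#' lesion is flagged for re-annotation (`accepted = FALSE`; restarting the
#' annotation loop is the caller's responsibility). Agreement is assessed
#' per lesion, matched across annotators by `lesion_id`.
#'
#' @param a an [annotation_set] with exactly 3 annotators.
#' @param height,width grid size for rasterization.
#' @param t_delta_A agreement threshold on the pairwise area difference.
#' @param seed integer seed for the random choice.
#' @return list with one entry per lesion id, each containing
#'   `pairwise_delta` (3 values), `accepted`, `chosen_annotator` (or `NA`),
#'   `threshold`, and the chosen `mask` (a `lesion_mask`, only when
#'   accepted); plus attribute `"accepted"` (all lesions accepted).
#' @export
consensus_select <- function(a, height, width, t_delta_A = 0.05, seed = 1L) {
  stopifnot(inherits(a, "annotation_set"))
  annotators <- names(a$labels_by_annotator)
  if (length(annotators) != 3L)
    stop_fmt("protocol error: consensus needs exactly 3 annotators, got %d",
             length(annotators))
  by_lesion <- list()
  for (ann in annotators)
    for (l in a$labels_by_annotator[[ann]])
      by_lesion[[l$lesion_id]] <- c(by_lesion[[l$lesion_id]], list(l))
  out <- list()
  for (k in seq_along(by_lesion)) {
    id <- names(by_lesion)[k]
    ls <- by_lesion[[id]]
    if (length(ls) != 3L)
      stop_fmt("matching error: lesion '%s' labelled by %d annotator(s), not 3",
               id, length(ls))
    pairs <- utils::combn(3L, 2L)
    deltas <- apply(pairs, 2L, function(p)
      area_difference(ls[[p[1]]], ls[[p[2]]], height, width))
    # the area difference is a ratio of integer pixel counts; compare with
    # a representation-error tolerance so the gate is exact at the boundary
    # (e.g. 1 - 38/40 must equal the 5% threshold, not exceed it by 4e-17)
    accepted <- max(deltas) <= t_delta_A + 1e-9
    chosen <- NA_character_
    res <- list(pairwise_delta = deltas, accepted = accepted,
                chosen_annotator = chosen, threshold = t_delta_A)
    if (accepted) {
      pick <- with_seed(derive_seed(seed, k), sample.int(3L, 1L))
      res$chosen_annotator <- ls[[pick]]$annotator_id
      res$mask <- polygon_to_mask(ls[[pick]], height, width)
      res$polygon <- ls[[pick]]
    }
    out[[id]] <- res
  }
  attr(out, "accepted") <- all(vapply(out, `[[`, logical(1), "accepted"))
  out
}
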