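#' Dual-view scan
#'
#' Pairs the anterior and posterior whole-body (or regional) views acquired
#' for one patient at one time point. Both views must have identical
#' dimensions.
#'
#' @param anterior,posterior [count_matrix] objects tagged with the
#'   corresponding views.
#' @param patient_id grouping key used by the patient-grouped split.
#' @return object of class `dual_view_scan`.
#' @export
dual_view_scan <- function(anterior, posterior, patient_id = "") {
  stopifnot(inherits(anterior, "count_matrix"),
            inherits(posterior, "count_matrix"))
  if (anterior$height != posterior$height || anterior$width != posterior$width)
    stop_fmt("shape error: anterior is %dx%d, posterior is %dx%d",
             anterior$height, anterior$width, posterior$height, posterior$width)
  if (anterior$view != "anterior" || posterior$view != "posterior")
    stop_fmt("views must be tagged 'anterior' and 'posterior'")
  structure(list(anterior = anterior, posterior = posterior,
                 patient_id = patient_id),
            class = "dual_view_scan")
}

#' Mirror a count matrix horizontally
#'
#' Reverses the column order (left-right flip); rows are unchanged. This is
#' the `Mirr` operation used before dual-view aggregation: the posterior
#' view images the patient from behind, so anatomical left/right is flipped
#' relative to the anterior view.
#'
#' @param m a [count_matrix].
#' @return the mirrored [count_matrix] (same view tag).
#' @export
mirror <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  out <- m
  out$counts <- m$counts[, m$width:1, drop = FALSE]
  out
}

#' Aggregate anterior and posterior views
#'
#' Pixel-wise addition of the anterior view and the horizontally mirrored
#' posterior view: `out[i, j] = anterior[i, j] + posterior[i, W - 1 - j]`
#' (0-based columns). A lesion visible in either view keeps a positive
#' count in the aggregate, which is the rationale for aggregating before
#' segmentation.
#'
#' @param scan a [dual_view_scan].
#' @return a [count_matrix] with `view = "aggregated"`.
#' @export
aggregate_views <- function(scan) {
  stopifnot(inherits(scan, "dual_view_scan"))
  agg <- scan$anterior$counts + mirror(scan$posterior)$counts
  count_matrix(agg, view = "aggregated",
               pixel_size_mm = scan$anterior$pixel_size_mm)
}

#' Crop the thoracic region from a whole-body scan
#'
#' Three-step decomposition: whole-body image -> body area -> upper body ->
#' thoracic region, returning a fixed 256x256 (or `out_size`) crop. The
#' body box is the bounding box of pixels with counts above
#' `noise_threshold` plus a small margin; the upper body is the top
#' `upper_fraction` of the body box; the thorax window starts below the
#' head/shoulder line located at `head_fraction` of the body height and is
#' width-centred on the body, zero-padded where it leaves the source image.
#'
#' @param m whole-body [count_matrix] (height >= width).
#' @param out_size side length of the square crop (default 256).
#' @param noise_threshold counts at or below this are background (default 0).
#' @param upper_fraction top fraction of the body box treated as upper body.
#' @param head_fraction fraction of body height above the thorax window.
#' @param margin pixels of margin added around the raw bounding box.
#' @return list with the cropped [count_matrix] (`$thorax`) and
#'   `$regions`, the three recorded boxes (`body_box`, `upper_body_box`,
#'   `thorax_box`), each `c(x0, x1, y0, y1)` half-open in source pixels.
#' @export
crop_thorax <- function(m, out_size = 256L, noise_threshold = 0,
                        upper_fraction = 0.45, head_fraction = 0.12,
                        margin = 2L) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$height < m$width)
    stop_fmt("expected a whole-body image (height >= width), got %dx%d",
             m$height, m$width)
  hit <- which(m$counts > noise_threshold, arr.ind = TRUE)
  if (nrow(hit) == 0L) stop_fmt("no body region detected")
  r0 <- max(1L, min(hit[, 1]) - margin); r1 <- min(m$height, max(hit[, 1]) + margin)
  c0 <- max(1L, min(hit[, 2]) - margin); c1 <- min(m$width, max(hit[, 2]) + margin)
  body_h <- r1 - r0 + 1L
  ub_r1 <- r0 + as.integer(round(upper_fraction * body_h)) - 1L
  top <- r0 + as.integer(round(head_fraction * body_h))
  # thorax rows [top, top + out_size); columns centred on the body box
  cc <- as.integer(round((c0 + c1) / 2))
  tc0 <- cc - out_size %/% 2L
  rows <- top:(top + out_size - 1L)
  cols <- tc0:(tc0 + out_size - 1L)
  out <- matrix(0, out_size, out_size)
  rin <- rows >= 1L & rows <= m$height
  cin <- cols >= 1L & cols <= m$width
  out[rin, cin] <- m$counts[rows[rin], cols[cin], drop = FALSE]
  box <- function(cs0, cs1, rs0, rs1)  # half-open, 0-based (x0, x1, y0, y1)
    c(x0 = cs0 - 1L, x1 = cs1, y0 = rs0 - 1L, y1 = rs1)
  clamp_r <- function(r) min(max(r, 1L), m$height)
  clamp_c <- function(x) min(max(x, 1L), m$width)
  regions <- list(
    body_box = box(c0, c1, r0, r1),
    upper_body_box = box(c0, c1, r0, min(ub_r1, r1)),
    thorax_box = box(clamp_c(max(cols[1], c0)), clamp_c(min(cols[out_size], c1)),
                     clamp_r(max(top, r0)),
                     clamp_r(min(top + out_size - 1L, min(ub_r1, r1)))))
  list(thorax = count_matrix(out, view = m$view,
                             pixel_size_mm = m$pixel_size_mm),
       regions = regions)
}

#' Normalize counts for network input
#'
#' Raw counts cannot be normalized into a fixed physical range (the maximum
#' count varies strongly from patient to patient), so normalization is an
#' explicit, recorded preprocessing step. The default `"max"` strategy
#' divides by the per-image maximum count, mapping into \[0, 1\] (an
#' all-zero image stays all-zero); `"fixed"` clips at `fixed_max` and
#' scales; `"percentile"` scales by the given upper count percentile and
#' clips at 1.
#'
#' @param m a [count_matrix].
#' @param strategy `"max"`, `"fixed"` or `"percentile"`.
#' @param fixed_max clip level for `"fixed"`.
#' @param probs upper percentile for `"percentile"` (default 0.99).
#' @return numeric matrix in \[0, 1\] with attribute `"normalization"`
#'   recording the strategy and scale used.
#' @export
normalize_for_network <- function(m, strategy = c("max", "fixed", "percentile"),
                                  fixed_max = 65535, probs = 0.99) {
  stopifnot(inherits(m, "count_matrix"))
  strategy <- match.arg(strategy)
  x <- m$counts
  scale <- switch(strategy,
                  max = max(x),
                  fixed = fixed_max,
                  percentile = as.numeric(stats::quantile(x, probs)))
  out <- if (scale <= 0) x * 0 else pmin(x / scale, 1)
  attr(out, "normalization") <- list(strategy = strategy, scale = scale)
  out
}
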