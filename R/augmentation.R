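#' Geometric transform specification
#'
#' A label-preserving spatial transform applied identically to an image,
#' its mask and (where applicable) its polygon labels: horizontal or
#' vertical flips, rotation about the image centre, or integer translation.
#'
#' @param kind `"hflip"`, `"vflip"`, `"rotate"` or `"translate"`.
#' @param angle_deg rotation angle in degrees (counter-clockwise in pixel
#'   coordinates with y pointing down).
#' @param shift integer `c(dx, dy)` translation in pixels.
#' @return a `geometric_transform` object.
#' @export
geometric_transform <- function(kind = c("hflip", "vflip", "rotate",
                                         "translate"),
                                angle_deg = 0, shift = c(0L, 0L)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, angle_deg = angle_deg,
                 shift = as.integer(shift)),
            class = "geometric_transform")
}

transform_matrix <- function(x, t, bilinear) {
  H <- nrow(x); W <- ncol(x)
  switch(t$kind,
    hflip = x[, W:1, drop = FALSE],
    vflip = x[H:1, , drop = FALSE],
    rotate = .cpp_rotate(x, t$angle_deg, bilinear),
    translate = {
      dx <- t$shift[1]; dy <- t$shift[2]
      if (abs(dx) >= W || abs(dy) >= H)
        stop_fmt("validation error: translation (%d, %d) exceeds image size",
                 dx, dy)
      out <- matrix(0, H, W)
      src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
      ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
      out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c], drop = FALSE]
      out
    })
}

transform_points <- function(pts, t, H, W) {
  switch(t$kind,
    hflip = cbind((W - 1) - pts[, 1], pts[, 2]),
    vflip = cbind(pts[, 1], (H - 1) - pts[, 2]),
    rotate = {
      th <- t$angle_deg * pi / 180
      cx <- (W - 1) / 2; cy <- (H - 1) / 2
      dx <- pts[, 1] - cx; dy <- pts[, 2] - cy
      cbind(cx + cos(th) * dx - sin(th) * dy,
            cy + sin(th) * dx + cos(th) * dy)
    },
    translate = cbind(pts[, 1] + t$shift[1], pts[, 2] + t$shift[2]))
}

#' Apply a geometric transform to an image and its mask
#'
#' Image and mask are warped with the same spatial map; the image uses
#' bilinear interpolation, the mask nearest-neighbour (so it stays
#' binary). Out-of-canvas regions are zero-filled.
#'
#' @param m a [count_matrix].
#' @param mask a [lesion_mask] of the same size (or `NULL`).
#' @param t a [geometric_transform].
#' @return list with the transformed `scan` and `mask`.
#' @export
apply_transform <- function(m, mask, t) {
  stopifnot(inherits(m, "count_matrix"), inherits(t, "geometric_transform"))
  img <- transform_matrix(m$counts, t, bilinear = TRUE)
  out_m <- count_matrix(pmin(round(pmax(img, 0)), 65535), view = m$view,
                        pixel_size_mm = m$pixel_size_mm)
  out_mask <- NULL
  if (!is.null(mask)) {
    mm <- transform_matrix(as_mask_matrix(mask) * 1.0, t, bilinear = FALSE)
    out_mask <- lesion_mask((mm > 0.5) * 1L, source = "manual")
  }
  list(scan = out_m, mask = out_mask)
}

#' Default augmentation recipe
#'
#' Flips x rotations x translations yielding 19 non-identity variants per
#' source (so originals plus variants give a twenty-fold expansion, the
#' scale at which a hundred-odd clinical scans become a trainable
#' data set).
#'
#' @return list of [geometric_transform]s (the identity combination is
#'   excluded).
#' @export
default_recipe <- function() {
  out <- list()
  for (flip in c(FALSE, TRUE))
    for (ang in c(-10, -5, 0, 5, 10))
      for (sh in list(c(0L, 0L), c(0L, 8L))) {
        if (!flip && ang == 0 && all(sh == 0L)) next
        steps <- list()
        if (flip) steps <- c(steps, list(geometric_transform("hflip")))
        if (ang != 0)
          steps <- c(steps, list(geometric_transform("rotate",
                                                     angle_deg = ang)))
        if (any(sh != 0L))
          steps <- c(steps, list(geometric_transform("translate",
                                                     shift = sh)))
        out <- c(out, list(steps))
      }
  out
}

#' Augment a dataset with geometric transforms
#'
#' Returns the original samples plus one transformed copy per recipe
#' entry (a recipe entry is a single transform or a list applied in
#' sequence). Every augmented sample records its provenance (source id
#' and transform chain) and inherits the source's patient key, so the
#' patient-grouped split keeps augmented copies on the same side as
#' their source.
#'
#' @param samples list of samples, each with `$image_cm` (a
#'   [count_matrix]) or `$aggregated`, optional `$truth`, `$sample_id`,
#'   and a patient key.
#' @param recipe list of transforms; `list()` returns the originals with
#'   a warning.
#' @param seed unused by the deterministic recipe, kept for interface
#'   stability with stochastic recipes.
#' @return list of samples; augmented ones carry `provenance` fields.
#' @export
augment_dataset <- function(samples, recipe = default_recipe(), seed = 1L) {
  if (length(samples) == 0L) stop_fmt("empty input")
  if (length(recipe) == 0L) {
    warning("empty recipe: returning originals only")
    return(samples)
  }
  out <- samples
  for (s in samples) {
    cm <- if (!is.null(s$aggregated)) s$aggregated else s$image_cm
    for (ri in seq_along(recipe)) {
      steps <- recipe[[ri]]
      if (inherits(steps, "geometric_transform")) steps <- list(steps)
      img <- cm; msk <- s$truth
      for (t in steps) {
        r <- apply_transform(img, msk, t)
        img <- r$scan; msk <- r$mask
      }
      aug <- s
      aug$aggregated <- img
      aug$image <- normalize_for_network(img)
      aug$truth <- msk
      aug$annotations <- NULL
      aug$sample_id <- sprintf("%s_aug%02d", s$sample_id, ri)
      aug$provenance <- list(source = s$sample_id, transform = ri)
      out <- c(out, list(aug))
    }
  }
  out
}
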