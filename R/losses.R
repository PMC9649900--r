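#' Region statistics of a soft segmentation
#'
#' For a normalized image `g` and a membership map `m` in \[0, 1\], computes
#' the soft area inside the curve and the mean intensities inside (`c1`) and
#' outside (`c2`): `c1 = sum(m g) / sum(m)`, `c2 = sum((1 - m) g) /
#' sum(1 - m)`. An empty region's mean is 0 by convention. With a hard
#' mask these are the exact arithmetic means over the two regions.
#'
#' @param g numeric matrix (normalized image).
#' @param m numeric matrix, same shape, values in \[0, 1\].
#' @return list `c1`, `c2`, `area_inside`.
#' @export
region_statistics <- function(g, m) {
  check_same_shape(g, m)
  a_in <- sum(m)
  a_out <- sum(1 - m)
  list(c1 = if (a_in > 0) sum(m * g) / a_in else 0,
       c2 = if (a_out > 0) sum((1 - m) * g) / a_out else 0,
       area_inside = a_in)
}

#' Unsupervised Chan-Vese region loss
#'
#' The region energy driving unlabeled training:
#' `lU = v * Area + sum m (g - c1)^2 + sum (1 - m) (g - c2)^2`,
#' a soft-membership relaxation of the two-phase piecewise-constant
#' Mumford-Shah (Chan-Vese) energy: an area penalty on the foreground plus
#' squared deviations from the region means inside and outside the curve.
#' Minimized when the membership map separates the image into two
#' near-constant regions with small foreground area.
#'
#' @param g normalized image matrix.
#' @param m membership matrix in \[0, 1\].
#' @param v area penalty weight (default 0.004).
#' @return scalar energy (a sum over pixels, not a mean).
#' @export
unsupervised_loss <- function(g, m, v = 0.004) {
  check_same_shape(g, m)
  rs <- region_statistics(g, m)
  v * rs$area_inside + sum(m * (g - rs$c1)^2) + sum((1 - m) * (g - rs$c2)^2)
}

# Gradient of the unsupervised loss w.r.t. m, with c1 and c2 treated as
# fixed at their current values (the classical alternating Chan-Vese
# update; the region means are re-estimated at every step).
unsupervised_loss_grad <- function(g, m, v = 0.004) {
  rs <- region_statistics(g, m)
  v + (g - rs$c1)^2 - (g - rs$c2)^2
}

#' Supervised label-guided loss
#'
#' The labeled-sample term: anisotropic total variation of the membership
#' map (forward differences, replicate boundary) plus a signed region term
#' `sum ((1 - mu)^2 - (0 - mu)^2) m = sum (1 - 2 mu) m`, where `mu` is the
#' per-pixel binary label (background labelled 0). The region term rewards
#' membership on lesion pixels (coefficient -1) and penalizes it on
#' background (+1); the TV term favours smooth, compact predictions.
#'
#' @param m membership matrix in \[0, 1\].
#' @param mu binary label matrix (a `lesion_mask` or 0/1 matrix).
#' @return scalar energy (sum over pixels/edges).
#' @export
supervised_loss <- function(m, mu) {
  mu <- as_mask_matrix(mu)
  check_same_shape(m, mu)
  if (!all(mu %in% c(0, 1))) stop_fmt("validation error: mu must be binary")
  total_variation(m) + sum((1 - 2 * mu) * m)
}

# Anisotropic TV: forward differences in x and y, replicate boundary
# (the boundary difference is zero and is simply omitted).
total_variation <- function(m) {
  H <- nrow(m); W <- ncol(m)
  tv <- 0
  if (H > 1L) tv <- tv + sum(abs(m[-1, , drop = FALSE] - m[-H, , drop = FALSE]))
  if (W > 1L) tv <- tv + sum(abs(m[, -1, drop = FALSE] - m[, -W, drop = FALSE]))
  tv
}

# Subgradient of the supervised loss w.r.t. m.
supervised_loss_grad <- function(m, mu) {
  mu <- as_mask_matrix(mu)
  H <- nrow(m); W <- ncol(m)
  gr <- (1 - 2 * mu)
  if (H > 1L) {
    s <- sign(m[-1, , drop = FALSE] - m[-H, , drop = FALSE])
    gr[-1, ] <- gr[-1, ] + s
    gr[-H, ] <- gr[-H, ] - s
  }
  if (W > 1L) {
    s <- sign(m[, -1, drop = FALSE] - m[, -W, drop = FALSE])
    gr[, -1] <- gr[, -1] + s
    gr[, -W] <- gr[, -W] - s
  }
  gr
}

#' Combined semi-supervised loss
#'
#' `l = lU + alpha * lS` for labeled samples; for unlabeled samples
#' (`mu = NULL`) the supervised term is absent and `l = lU` (with `l_S`
#' recorded as 0).
#'
#' @param g normalized image matrix.
#' @param m membership matrix.
#' @param mu binary label matrix, or `NULL` for an unlabeled sample.
#' @param alpha supervised weight (default 0.4).
#' @param v area weight passed to [unsupervised_loss()].
#' @return object of class `loss_components`: `l_U`, `l_S`, `l_total`,
#'   `alpha`, `v`, `labeled`.
#' @export
total_loss <- function(g, m, mu = NULL, alpha = 0.4, v = 0.004) {
  l_u <- unsupervised_loss(g, m, v)
  l_s <- if (is.null(mu)) 0 else supervised_loss(m, mu)
  structure(list(l_U = l_u, l_S = l_s,
                 l_total = if (is.null(mu)) l_u else l_u + alpha * l_s,
                 alpha = alpha, v = v, labeled = !is.null(mu)),
            class = "loss_components")
}

#' Pixel-wise confusion counts
#'
#' Lesion pixels are the positive class. `TP + FP + FN + TN` equals the
#' pixel count.
#'
#' @param pred,truth binary masks ([lesion_mask] or 0/1 matrices) of the
#'   same shape.
#' @return named vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- as_mask_matrix(pred); t <- as_mask_matrix(truth)
  check_same_shape(p, t)
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  c(TP = tp, FP = fp, FN = fn, TN = length(p) - tp - fp - fn)
}

#' Segmentation metrics from confusion counts
#'
#' Dice similarity coefficient `DSC = 2TP / (FP + 2TP + FN)`, class pixel
#' accuracy `CPA = TP / (TP + FP)` (precision) and `Recall = TP /
#' (TP + FN)`. Conventions for empty denominators: if prediction and truth
#' are both empty (`TP = FP = FN = 0`), `DSC = 1`, otherwise a zero Dice
#' denominator yields 0; CPA and Recall with zero denominators are
#' reported as `NA` and excluded from dataset averages.
#'
#' @param TP,FP,FN non-negative pixel counts (a named vector from
#'   [confusion_counts()] may be passed as `TP`).
#' @return named vector `c(DSC, CPA, Recall)`.
#' @export
seg_metrics <- function(TP, FP = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) >= 3) {
    cc <- TP; TP <- cc[["TP"]]; FP <- cc[["FP"]]; FN <- cc[["FN"]]
  }
  if (any(c(TP, FP, FN) < 0)) stop_fmt("counts must be non-negative")
  dsc <- if (FP + 2 * TP + FN == 0) 1 else 2 * TP / (FP + 2 * TP + FN)
  cpa <- if (TP + FP == 0) NA_real_ else TP / (TP + FP)
  rec <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  c(DSC = dsc, CPA = cpa, Recall = rec)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "lesion_mask")) x$mask else x
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop_fmt("shape mismatch: %s vs %s", paste(dim(a), collapse = "x"),
             paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

#' Classical Chan-Vese segmentation by direct descent
#'
#' Minimizes the relaxed two-phase region energy directly over the
#' membership map (no network): projected gradient descent with the
#' region means re-estimated at every step, membership clipped to
#' \[0, 1\]. The map is initialized from the normalized image itself —
#' a symmetric initialization leaves the two region means equal, and the
#' energy cannot break the tie. Serves both as a sanity check that the
#' unsupervised loss drives correct segmentations and as a
#' network-free baseline.
#'
#' @param g normalized image matrix in \[0, 1\].
#' @param v area penalty weight.
#' @param iterations descent steps.
#' @param step_size gradient step.
#' @return list with `membership`, `mask` (threshold 0.5) and `energy`
#'   (per-iteration values).
#' @export
chan_vese_segment <- function(g, v = 0.004, iterations = 500L,
                              step_size = 1) {
  rng <- range(g)
  m <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else g * 0
  energy <- numeric(iterations)
  for (it in seq_len(iterations)) {
    m <- pmin(pmax(m - step_size * unsupervised_loss_grad(g, m, v), 0), 1)
    energy[it] <- unsupervised_loss(g, m, v)
  }
  list(membership = m, mask = lesion_mask((m > 0.5) * 1L, "predicted"),
       energy = energy)
}
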