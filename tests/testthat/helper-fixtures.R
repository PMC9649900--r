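# shared fixtures: small random count matrices, squares, a tiny phantom spec

random_counts <- function(h, w, max = 65535L) {
  matrix(sample(0:max, h * w, replace = TRUE), h, w)
}

square_polygon <- function(x0, y0, side, lesion_id = "lesion",
                           annotator_id = "a1") {
  polygon_label(rbind(c(x0, y0), c(x0 + side, y0),
                      c(x0 + side, y0 + side), c(x0, y0 + side)),
                lesion_id = lesion_id, annotator_id = annotator_id)
}

tiny_phantom_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(image_size = 32L, lesions_per_image = c(1L, 2L),
         lesion_axes = c(2, 5), seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# independent per-pixel point-in-polygon oracle (crossing number on the
# closed vertex list, boundary-inclusive)
pip_oracle <- function(pts, height, width) {
  m <- matrix(FALSE, height, width)
  xs <- pts[, 1]; ys <- pts[, 2]
  nv <- length(xs)
  for (r in seq_len(height)) for (c in seq_len(width)) {
    px <- c - 1; py <- r - 1
    inside <- FALSE; boundary <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
      # on-segment test
      cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
      l2 <- (xj - xi)^2 + (yj - yi)^2
      dt <- (px - xi) * (xj - xi) + (py - yi) * (yj - yi)
      if (abs(cr) < 1e-9 * max(1, sqrt(l2)) && dt >= -1e-9 && dt <= l2 + 1e-9)
        boundary <- TRUE
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
    m[r, c] <- boundary || inside
  }
  m * 1L
}
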