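test_that("noiseless phantoms equal their analytic template and carry
           consistent ground truth", {
  spec <- tiny_phantom_spec(seed = 3, poisson_noise = FALSE)
  p1 <- generate_phantom(spec, 1L)
  p2 <- generate_phantom(spec, 1L)
  expect_identical(p1$scan$anterior$counts, p2$scan$anterior$counts)
  expect_identical(p1$truth$mask, p2$truth$mask)
  expect_equal(p1$truth$source, "synthetic-truth")
  expect_gt(sum(p1$truth$mask), 0)
  # lesion pixels are hotter than the torso background in the aggregate
  agg <- aggregate_views(p1$scan)
  inside <- agg$counts[p1$truth$mask == 1]
  expect_gt(min(inside), spec$background_level)
})

test_that("a zero-lesion spec yields an empty truth mask", {
  spec <- tiny_phantom_spec(seed = 5, lesions_per_image = c(0L, 0L))
  p <- generate_phantom(spec, 1L)
  expect_equal(sum(p$truth$mask), 0)
  expect_length(p$lesions, 0L)
})

test_that("posterior-only lesions are invisible in the anterior view but
           present in the aggregate", {
  spec <- tiny_phantom_spec(
    seed = 8, poisson_noise = FALSE, lesions_per_image = c(1L, 1L),
    lesion_view_probs = c(both = 0, anterior = 0, posterior = 1))
  p <- generate_phantom(spec, 2L)
  les <- p$truth$mask == 1
  # anterior carries only the torso template on lesion pixels
  bg <- generate_phantom(tiny_phantom_spec(
    seed = 8, poisson_noise = FALSE,
    lesions_per_image = c(0L, 0L)), 2L)$scan$anterior$counts
  expect_equal(p$scan$anterior$counts[les], bg[les])
  agg <- aggregate_views(p$scan)
  agg_bg <- aggregate_views(bg_scan <- generate_phantom(tiny_phantom_spec(
    seed = 8, poisson_noise = FALSE,
    lesions_per_image = c(0L, 0L)), 2L)$scan)
  expect_true(all(agg$counts[les] > agg_bg$counts[les]))
})

test_that("Poisson sampling is centred on the template", {
  spec <- tiny_phantom_spec(seed = 4, poisson_noise = FALSE,
                            lesions_per_image = c(1L, 1L))
  tpl <- generate_phantom(spec, 1L)$scan$anterior$counts
  # resample counts around the template and compare the pixel means
  set.seed(77)
  reps <- 1000L
  pick <- cbind(sample(32, 12, TRUE), sample(32, 12, TRUE))
  lam <- tpl[pick]
  draws <- matrix(rpois(reps * 12, rep(lam, each = reps)), reps)
  z <- abs(colMeans(draws) - lam) / sqrt(lam / reps)
  expect_true(all(z < 4))
})

test_that("ground-truth polygons rasterize consistently with the mask
           before jitter (DSC >= 0.95 per lesion)", {
  ns <- asNamespace("scintiseg")
  ep <- get("ellipse_polygon", ns)
  spec <- tiny_phantom_spec(seed = 9, lesions_per_image = c(1L, 1L))
  for (idx in 1:5) {
    p <- generate_phantom(spec, idx)
    l <- p$lesions[[1]]
    poly <- polygon_label(ep(l$cx, l$cy, l$a, l$b, l$phi))
    m <- polygon_to_mask(poly, 32, 32)
    dsc <- seg_metrics(confusion_counts(m, p$truth))[["DSC"]]
    expect_gte(dsc, 0.95)
  }
})

test_that("simulated triple annotations mostly pass the 5% agreement
           gate at the calibrated jitter", {
  spec <- phantom_spec(seed = 123)
  pass <- 0L; total <- 0L; deltas <- numeric(0)
  for (idx in 1:25) {
    p <- generate_phantom(spec, idx)
    cs <- consensus_select(p$annotations, spec$image_size, spec$image_size,
                           seed = idx)
    for (r in cs) {
      total <- total + 1L
      pass <- pass + r$accepted
      deltas <- c(deltas, r$pairwise_delta)
    }
  }
  expect_gte(pass / total, 0.85)
  expect_lt(mean(deltas), 0.05)
})

test_that("generate_dataset is byte-stable under a fixed seed and writes
           readable files", {
  spec <- tiny_phantom_spec(seed = 21)
  d1 <- generate_dataset(spec, 4)
  d2 <- generate_dataset(spec, 4)
  expect_identical(lapply(d1$samples, `[[`, "image"),
                   lapply(d2$samples, `[[`, "image"))
  expect_equal(nrow(d1$manifest), 4L)
  expect_equal(anyDuplicated(d1$manifest$patient), 0L)
  dir <- file.path(tempdir(), "phantomds")
  generate_dataset(spec, 2, dir = dir)
  m <- read_scan(file.path(dir, "S0001.png"))
  expect_equal(m$counts, d1$samples[[1]]$aggregated$counts)
  a <- read_labelme(file.path(dir, "S0001_labels.json"))
  expect_length(a$labels_by_annotator, 3L)
})

test_that("oracle segmentation pins the metrics and the supervised
           region term at their extremes", {
  spec <- tiny_phantom_spec(seed = 2, lesions_per_image = c(2L, 2L))
  p <- generate_phantom(spec, 1L)
  seg <- oracle_segmentation(p$truth)
  cc <- confusion_counts(seg$mask, p$truth)
  expect_equal(unname(seg_metrics(cc)), c(1, 1, 1))
  tv <- supervised_loss(seg$membership, matrix(0, 32, 32)) -
    sum(p$truth$mask)
  expect_equal(supervised_loss(seg$membership, p$truth) - tv,
               -sum(p$truth$mask))
  # one boundary polygon per (non-touching) lesion
  polys <- extract_lesion_boundaries(seg, min_area = 1L)
  ncomp <- max(scintiseg:::.cpp_label_components(p$truth$mask == 1L))
  expect_length(polys, ncomp)
})
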