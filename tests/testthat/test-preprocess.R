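test_that("mirror reverses columns, is an involution, and moves edge pixels", {
  cnt <- matrix(0L, 8, 256); cnt[3, 1] <- 7L
  m <- count_matrix(cnt)
  mm <- mirror(m)
  expect_equal(mm$counts[3, 256], 7)
  expect_equal(mm$counts[3, 1], 0)
  expect_equal(mirror(mm)$counts, m$counts)
  set.seed(1)
  r <- count_matrix(random_counts(5, 9))
  expect_equal(mirror(r)$counts, r$counts[, 9:1])
})

test_that("aggregate_views equals the flipped-index per-pixel oracle", {
  set.seed(7)
  for (trial in 1:5) {
    h <- sample(4:12, 1); w <- sample(4:12, 1)
    a <- random_counts(h, w, 500L); p <- random_counts(h, w, 500L)
    scan <- dual_view_scan(count_matrix(a, "anterior"),
                           count_matrix(p, "posterior"))
    agg <- aggregate_views(scan)
    oracle <- matrix(0, h, w)
    for (i in 1:h) for (j in 1:w) oracle[i, j] <- a[i, j] + p[i, w + 1 - j]
    expect_equal(agg$counts, oracle)
    expect_equal(agg$view, "aggregated")
  }
})

test_that("aggregation is the identity under a zero posterior and plain
           addition for a symmetric posterior", {
  a <- random_counts(6, 8, 100L)
  z <- dual_view_scan(count_matrix(a, "anterior"),
                      count_matrix(matrix(0L, 6, 8), "posterior"))
  expect_equal(aggregate_views(z)$counts, matrix(as.numeric(a), 6))
  sym <- random_counts(6, 4, 100L); sym <- cbind(sym, sym[, 4:1])
  s <- dual_view_scan(count_matrix(a, "anterior"),
                      count_matrix(sym, "posterior"))
  expect_equal(aggregate_views(s)$counts, a + sym)
})

test_that("dimension mismatches in dual views are rejected", {
  expect_error(dual_view_scan(count_matrix(matrix(0L, 4, 4), "anterior"),
                              count_matrix(matrix(0L, 4, 5), "posterior")),
               "shape error")
})

test_that("any pixel positive in either view stays positive after
           aggregation", {
  set.seed(3)
  a <- random_counts(10, 10, 3L); p <- random_counts(10, 10, 3L)
  agg <- aggregate_views(dual_view_scan(count_matrix(a, "anterior"),
                                        count_matrix(p, "posterior")))
  either <- (a > 0) | (p[, 10:1] > 0)
  expect_true(all(agg$counts[either] > 0))
})

make_body <- function(r0, r1, c0, c1, H = 1024L, W = 256L, level = 40L) {
  cnt <- matrix(0L, H, W)
  cnt[r0:r1, c0:c1] <- level
  count_matrix(cnt)
}

test_that("crop_thorax returns a 256x256 crop with nested boxes", {
  m <- make_body(100, 611, 1, 256)
  out <- crop_thorax(m)
  expect_equal(dim(out$thorax$counts), c(256L, 256L))
  b <- out$regions$body_box; u <- out$regions$upper_body_box
  t <- out$regions$thorax_box
  expect_true(t["y0"] >= u["y0"] && t["y1"] <= u["y1"])
  expect_true(u["y0"] >= b["y0"] && u["y1"] <= b["y1"])
  expect_true(b["x0"] >= 0 && b["y1"] <= 1024)
})

test_that("the body box is the (margin-padded) bounding box of nonzero
           counts", {
  m <- make_body(100, 611, 21, 200)
  b <- crop_thorax(m, margin = 0L)$regions$body_box
  # half-open 0-based: rows 100..611 (1-based) are y0 = 99, y1 = 611
  expect_equal(unname(b), c(20, 200, 99, 611))
})

test_that("translating the body translates the body box equally", {
  b1 <- crop_thorax(make_body(100, 611, 21, 200), margin = 0L)$regions$body_box
  b2 <- crop_thorax(make_body(110, 621, 31, 210), margin = 0L)$regions$body_box
  expect_equal(unname(b2 - b1), c(10, 10, 10, 10))
})

test_that("an all-zero scan has no detectable body", {
  expect_error(crop_thorax(count_matrix(matrix(0L, 512, 256))),
               "no body region")
})

test_that("normalization maps counts into [0,1] and is scale-invariant", {
  z <- normalize_for_network(count_matrix(matrix(0L, 4, 4)))
  expect_equal(as.numeric(z), rep(0, 16))
  cnt <- matrix(c(0L, 250L, 500L, 100L), 2)
  n <- normalize_for_network(count_matrix(cnt))
  expect_equal(max(n), 1)
  expect_equal(n[1, 2], 1)   # the 500-count pixel
  set.seed(5)
  for (k in c(2L, 7L)) {
    cnt <- random_counts(6, 6, 800L)
    expect_equal(normalize_for_network(count_matrix(cnt)),
                 normalize_for_network(count_matrix(k * cnt)),
                 ignore_attr = TRUE)
  }
  att <- attr(n, "normalization")
  expect_equal(att$strategy, "max")
  expect_equal(att$scale, 500)
})
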