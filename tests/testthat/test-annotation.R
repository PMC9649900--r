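test_that("axis-aligned square rasterization matches brute force: centers
           (2,2)-(5,5) give 16 pixels", {
  l <- polygon_label(rbind(c(2, 2), c(5, 2), c(5, 5), c(2, 5)))
  m <- polygon_to_mask(l, 10, 10)
  expect_equal(sum(m$mask), 16)
  expect_equal(m$mask, pip_oracle(l$points[-5, ], 10, 10))
})

test_that("rasterization equals the per-pixel point-in-polygon oracle on
           random polygons", {
  set.seed(11)
  for (trial in 1:10) {
    nv <- sample(3:7, 1)
    th <- sort(runif(nv, 0, 2 * pi))
    r <- runif(nv, 2, 6)
    pts <- cbind(7 + r * cos(th), 7 + r * sin(th))
    l <- polygon_label(pts)
    m <- polygon_to_mask(l, 15, 15)
    expect_equal(m$mask, pip_oracle(l$points[-nrow(l$points), ], 15, 15))
  }
})

test_that("out-of-bounds and zero-area polygons are rejected", {
  l <- square_polygon(8, 8, 5)
  expect_error(polygon_to_mask(l, 10, 10), "outside")
  deg <- polygon_label(rbind(c(1, 1), c(4, 4), c(2.5, 2.5), c(2, 2)))
  expect_error(polygon_to_mask(deg, 10, 10), "zero area")
})

test_that("convex polygon mask area is within a perimeter of the shoelace
           area", {
  set.seed(4)
  for (trial in 1:5) {
    r <- runif(1, 3, 8)
    th <- seq(0, 2 * pi, length.out = 17)[-17]
    pts <- cbind(12 + r * cos(th), 12 + r * sin(th))
    l <- polygon_label(pts)
    area <- abs(sum(pts[, 1] * c(pts[-1, 2], pts[1, 2]) -
                    c(pts[-1, 1], pts[1, 1]) * pts[, 2]) / 2)
    per <- sum(sqrt(rowSums((pts - pts[c(2:16, 1), ])^2)))
    expect_lt(abs(sum(polygon_to_mask(l, 25, 25)$mask) - area), per)
  }
})

test_that("area difference: identity 0, disjoint 1, half-overlap 2/3,
           symmetric", {
  a <- square_polygon(0, 0, 9)       # pixels 0..9 -> 10x10 = 100
  b <- square_polygon(0, 5, 9)       # rows 5..14 -> overlap rows 5..9
  c <- square_polygon(12, 12, 3)
  expect_equal(area_difference(a, a, 20, 20), 0)
  expect_equal(area_difference(a, c, 20, 20), 1)
  # overlap 10x5 = 50, union 200 - 50 = 150
  expect_equal(area_difference(a, b, 20, 20), 1 - 50 / 150)
  expect_equal(area_difference(a, b, 20, 20),
               area_difference(b, a, 20, 20))
  empty1 <- polygon_label(rbind(c(3.2, 3.2), c(3.8, 3.2), c(3.8, 3.8),
                                c(3.2, 3.8)))
  expect_error(area_difference(empty1, empty1, 10, 10), "empty")
})

test_that("shrinking the overlap of fixed-area squares never decreases
           the area difference", {
  a <- square_polygon(0, 0, 9)
  deltas <- vapply(c(0, 2, 4, 6, 8, 10), function(sh)
    area_difference(a, square_polygon(0, sh, 9), 25, 25), numeric(1))
  expect_true(all(diff(deltas) >= 0))
})

triplet <- function(polys) annotation_set(polys)

test_that("three identical labels are accepted with all deltas zero", {
  polys <- lapply(c("a1", "a2", "a3"), function(a)
    square_polygon(2, 2, 6, "l1", a))
  cs <- consensus_select(triplet(polys), 12, 12, seed = 5)
  expect_true(attr(cs, "accepted"))
  expect_equal(cs$l1$pairwise_delta, rep(0, 3))
  expect_true(cs$l1$chosen_annotator %in% c("a1", "a2", "a3"))
  expect_equal(sum(cs$l1$mask$mask), 49)
})

test_that("one disjoint label rejects the lesion", {
  polys <- list(square_polygon(2, 2, 6, "l1", "a1"),
                square_polygon(2, 2, 6, "l1", "a2"),
                square_polygon(12, 12, 3, "l1", "a3"))
  cs <- consensus_select(triplet(polys), 20, 20, seed = 5)
  expect_false(attr(cs, "accepted"))
  expect_false(cs$l1$accepted)
  expect_identical(cs$l1$chosen_annotator, NA_character_)
})

test_that("jittered triplets near the gate behave per the threshold and
           the seeded choice is reproducible", {
  # squares of side 20 shifted by 0 / 0 / 1 px: pairwise deltas are
  # {0, 2/23, 2/23}... use a larger square so deltas fall under 5%
  big <- function(sh, ann) square_polygon(1, 1 + sh, 40, "l1", ann)
  polys <- list(big(0, "a1"), big(0, "a2"), big(1, "a3"))
  # delta(a1,a3) = 1 - (41*40)/(41*42) = 2/42 = 0.0476 <= 0.05
  cs1 <- consensus_select(triplet(polys), 50, 50, seed = 9)
  expect_true(attr(cs1, "accepted"))
  expect_equal(max(cs1$l1$pairwise_delta), 2 / 42, tolerance = 1e-12)
  cs2 <- consensus_select(triplet(polys), 50, 50, seed = 9)
  expect_identical(cs1$l1$chosen_annotator, cs2$l1$chosen_annotator)
  # tighter threshold flips the decision exactly at the boundary
  cs3 <- consensus_select(triplet(polys), 50, 50, t_delta_A = 0.047,
                          seed = 9)
  expect_false(attr(cs3, "accepted"))
})

test_that("annotator-count and lesion-matching protocol errors", {
  two <- annotation_set(list(square_polygon(2, 2, 6, "l1", "a1"),
                             square_polygon(2, 2, 6, "l1", "a2")))
  expect_error(consensus_select(two, 12, 12), "protocol error")
  mis <- annotation_set(list(square_polygon(2, 2, 6, "l1", "a1"),
                             square_polygon(2, 2, 6, "l1", "a2"),
                             square_polygon(2, 2, 6, "l2", "a3")))
  expect_error(consensus_select(mis, 12, 12), "matching error")
})
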