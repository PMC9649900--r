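# scalar per-pixel loop oracles, kept deliberately naive and independent
# of the vectorized implementations

loop_region_stats <- function(g, m) {
  s_in <- s_out <- a_in <- a_out <- 0
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    a_in <- a_in + m[i, j]; a_out <- a_out + 1 - m[i, j]
    s_in <- s_in + m[i, j] * g[i, j]
    s_out <- s_out + (1 - m[i, j]) * g[i, j]
  }
  list(c1 = if (a_in > 0) s_in / a_in else 0,
       c2 = if (a_out > 0) s_out / a_out else 0, area = a_in)
}

loop_unsup <- function(g, m, v) {
  rs <- loop_region_stats(g, m)
  acc <- v * rs$area
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g)))
    acc <- acc + m[i, j] * (g[i, j] - rs$c1)^2 +
      (1 - m[i, j]) * (g[i, j] - rs$c2)^2
  acc
}

loop_sup <- function(m, mu) {
  H <- nrow(m); W <- ncol(m)
  acc <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (i < H) acc <- acc + abs(m[i + 1, j] - m[i, j])
    if (j < W) acc <- acc + abs(m[i, j + 1] - m[i, j])
    acc <- acc + ((1 - mu[i, j])^2 - (0 - mu[i, j])^2) * m[i, j]
  }
  acc
}

test_that("region statistics: hard two-level split recovers exact means;
           empty regions use the zero convention", {
  g <- matrix(0.1, 8, 8); g[3:6, 3:6] <- 0.8
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  rs <- region_statistics(g, m)
  expect_equal(rs$c1, 0.8)
  expect_equal(rs$c2, 0.1)
  expect_equal(rs$area_inside, 16)
  rs0 <- region_statistics(g, matrix(0, 8, 8))
  expect_equal(rs0$c1, 0)
  expect_equal(rs0$c2, mean(g))
})

test_that("vectorized losses match scalar loop oracles on random 16x16
           instances", {
  set.seed(21)
  for (trial in 1:100) {
    g <- matrix(runif(256), 16)
    m <- matrix(runif(256), 16)
    mu <- matrix(rbinom(256, 1, 0.3), 16)
    expect_lt(abs(unsupervised_loss(g, m, 0.004) - loop_unsup(g, m, 0.004)),
              1e-10)
    expect_lt(abs(supervised_loss(m, mu) - loop_sup(m, mu)), 1e-10)
    rs <- region_statistics(g, m); lo <- loop_region_stats(g, m)
    expect_lt(abs(rs$c1 - lo$c1) + abs(rs$c2 - lo$c2), 1e-10)
  }
})

test_that("worked unsupervised values: 4x4 block on 8x8 grid gives
           l_U = 0.064; degenerate memberships give closed forms", {
  g <- matrix(0.1, 8, 8); g[3:6, 3:6] <- 0.8
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  expect_equal(unsupervised_loss(g, m, v = 0.004), 0.004 * 16)
  expect_equal(unsupervised_loss(matrix(0.3, 5, 5), matrix(0, 5, 5)), 0)
  set.seed(2)
  g2 <- matrix(runif(36), 6)
  expect_equal(unsupervised_loss(g2, matrix(0, 6, 6)),
               sum((g2 - mean(g2))^2))
})

test_that("unsupervised residual terms are invariant to a constant shift
           of the image", {
  set.seed(8)
  g <- matrix(runif(64), 8); m <- matrix(runif(64), 8)
  v <- 0.004
  res <- function(gg) unsupervised_loss(gg, m, v) - v * sum(m)
  expect_equal(res(g), res(g + 0.37), tolerance = 1e-12)
})

test_that("supervised loss closed forms: zero membership, perfect hard
           prediction, all-ones on empty truth", {
  mu <- matrix(0, 6, 6); mu[2:4, 3:5] <- 1
  expect_equal(supervised_loss(matrix(0, 6, 6), mu), 0)
  # perfect prediction: region term is -|mu|; TV is the boundary edge count
  m <- mu
  edges <- loop_sup(mu, matrix(0, 6, 6))   # TV + |mu| (since mu acts as m)
  tv <- edges - sum(mu)
  expect_equal(supervised_loss(m, mu), tv - sum(mu))
  # all-one membership on empty truth: TV 0, region +N
  expect_equal(supervised_loss(matrix(1, 5, 7), matrix(0, 5, 7)), 35)
  expect_error(supervised_loss(m, mu * 0.5), "binary")
})

test_that("perfect-prediction region term equals -|mu| for random masks", {
  set.seed(13)
  for (trial in 1:10) {
    mu <- matrix(rbinom(100, 1, 0.4), 10)
    tv <- supervised_loss(mu, matrix(0, 10, 10)) - sum(mu)
    # region term = loss - TV = -|mu|
    expect_equal(supervised_loss(mu, mu) - tv, -sum(mu))
  }
})

test_that("combined loss branches: unlabeled drops the supervised term,
           alpha scales it, alpha = 0 reduces to unsupervised", {
  g <- matrix(0.1, 8, 8); g[3:6, 3:6] <- 0.8
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  lc_u <- total_loss(g, m, mu = NULL)
  expect_equal(lc_u$l_total, lc_u$l_U)
  expect_equal(lc_u$l_S, 0)
  lc <- total_loss(g, m, mu = m, alpha = 0.4, v = 0.004)
  expect_equal(lc$l_total, lc$l_U + 0.4 * lc$l_S)
  lc0 <- total_loss(g, m, mu = m, alpha = 0)
  expect_equal(lc0$l_total, lc0$l_U)
})

test_that("loss gradients agree with finite differences of the energies", {
  ns <- asNamespace("scintiseg")
  ugrad <- get("unsupervised_loss_grad", ns)
  sgrad <- get("supervised_loss_grad", ns)
  set.seed(31)
  g <- matrix(runif(36), 6); m <- matrix(runif(36, 0.05, 0.95), 6)
  mu <- matrix(rbinom(36, 1, 0.4), 6)
  eps <- 1e-6
  # unsupervised: gradient holds c1, c2 fixed (alternating scheme), so
  # compare against finite differences of the energy with frozen means
  rs <- region_statistics(g, m)
  frozen <- function(mm) 0.004 * sum(mm) + sum(mm * (g - rs$c1)^2) +
    sum((1 - mm) * (g - rs$c2)^2)
  gu <- ugrad(g, m, 0.004)
  gs <- sgrad(m, mu)
  for (k in sample(36, 6)) {
    mp <- m; mp[k] <- m[k] + eps
    mn <- m; mn[k] <- m[k] - eps
    expect_equal(gu[k], (frozen(mp) - frozen(mn)) / (2 * eps),
                 tolerance = 1e-4)
    expect_equal(gs[k], (supervised_loss(mp, mu) - supervised_loss(mn, mu)) /
                   (2 * eps), tolerance = 1e-4)
  }
})

test_that("confusion counts partition the image and follow set relations", {
  t <- matrix(0L, 10, 10); t[2:5, 2:5] <- 1L
  expect_equal(confusion_counts(t, t),
               c(TP = 16, FP = 0, FN = 0, TN = 84))
  sup <- t; sup[6:7, 2:6] <- 1L   # superset by 10 pixels
  cc <- confusion_counts(sup, t)
  expect_equal(cc[["FP"]], 10)
  expect_equal(cc[["FN"]], 0)
  dis <- matrix(0L, 10, 10); dis[8:9, 8:9] <- 1L
  expect_equal(confusion_counts(dis, t)[["TP"]], 0)
  expect_equal(sum(confusion_counts(sup, t)), 100)
})

test_that("metrics: worked value, perfect and empty predictions, and the
           0/0 conventions", {
  m <- seg_metrics(TP = 30, FP = 10, FN = 20)
  expect_equal(m[["DSC"]], 60 / 90)
  expect_equal(m[["CPA"]], 0.75)
  expect_equal(m[["Recall"]], 0.6)
  expect_equal(unname(seg_metrics(TP = 50, FP = 0, FN = 0)), c(1, 1, 1))
  e <- seg_metrics(TP = 0, FP = 0, FN = 25)
  expect_equal(e[["DSC"]], 0)
  expect_true(is.na(e[["CPA"]]))
  expect_equal(e[["Recall"]], 0)
  both_empty <- seg_metrics(TP = 0, FP = 0, FN = 0)
  expect_equal(both_empty[["DSC"]], 1)
  expect_error(seg_metrics(TP = -1, FP = 0, FN = 0), "non-negative")
})

test_that("DSC is symmetric in prediction and truth and metrics stay in
           [0, 1]", {
  set.seed(17)
  for (trial in 1:20) {
    a <- matrix(rbinom(64, 1, 0.4), 8); b <- matrix(rbinom(64, 1, 0.4), 8)
    d1 <- seg_metrics(confusion_counts(a, b))[["DSC"]]
    d2 <- seg_metrics(confusion_counts(b, a))[["DSC"]]
    expect_equal(d1, d2)
    mm <- seg_metrics(confusion_counts(a, b))
    expect_true(all(mm >= 0 & mm <= 1, na.rm = TRUE))
  }
})
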