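test_that("convolution arithmetic: the p = 0 dilated case and 'same'
           convolutions", {
  o <- conv_output_size(10, k = 3, d = 2, p = 0, s = 1)
  expect_equal(as.integer(o), 6L)
  expect_equal(attr(o, "n"), 5L)
  expect_equal(as.integer(conv_output_size(256, 3, 1, 1, 1)), 256L)
  expect_error(conv_output_size(4, k = 3, d = 3, p = 0), "size error")
})

test_that("conv_output_size predicts executed layer shapes on a grid of
           configurations", {
  ns <- asNamespace("scintiseg")
  conv <- get(".cpp_conv2d_fwd", ns)
  set.seed(3)
  checked <- 0L
  for (i in c(7, 10, 16, 23, 32)) for (k in c(1, 3, 5))
    for (d in c(1, 2, 3)) for (p in c(0, 1, 2)) for (s in c(1, 2)) {
      n <- k + (k - 1) * (d - 1)
      if (i + 2 * p < n) next
      x <- array(rnorm(i * i * 2), c(i, i, 2, 1))
      w <- array(rnorm(k * k * 2 * 3), c(k, k, 2, 3))
      y <- conv(x, w, NULL, as.integer(s), as.integer(p), as.integer(p),
                as.integer(d), as.integer(d))
      o <- as.integer(conv_output_size(i, k, d, p, s))
      expect_equal(dim(y)[1:2], c(o, o))
      checked <- checked + 1L
    }
  expect_gte(checked, 100L)
})

test_that("dilated residual block: identity configuration, shape
           preservation, and gradient flow through the skip path", {
  ns <- asNamespace("scintiseg")
  fwd <- get("nn_forward", ns); bwd <- get("nn_backward", ns)
  zg <- get("nn_zero_grad", ns)
  set.seed(5)
  blk <- dilated_residual_block(2L, 2L, dil = 2L)
  # zero the residual path, make the skip 1x1 the identity
  for (l in scintiseg:::nn_layers(blk$children$res)) {
    for (nm in names(l$params)) l$params[[nm]][] <- 0
    if (!is.null(l$params$gamma)) l$params$gamma[] <- 0
  }
  sk <- blk$children$skip
  sk$params$W[] <- 0
  sk$params$W[1, 1, 1, 1] <- 1; sk$params$W[1, 1, 2, 2] <- 1
  sk$params$b[] <- 0
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  expect_equal(fwd(blk, x, train = FALSE), x)
  # spatial dims preserved across sizes
  for (sz in c(32L, 64L)) {
    blk2 <- dilated_residual_block(3L, 4L)
    y <- fwd(blk2, array(rnorm(sz * sz * 3), c(sz, sz, 3, 1)), train = FALSE)
    expect_equal(dim(y), c(sz, sz, 4L, 1L))
  }
  # gradient reaches the input through the skip even when the residual
  # path is zeroed
  zg(blk)
  y <- fwd(blk, x, train = TRUE)
  dx <- bwd(blk, array(1, dim(y)))
  expect_gt(max(abs(dx)), 0)
})

test_that("inception block halves resolution, concatenates branch
           channels, and rejects odd sizes", {
  ns <- asNamespace("scintiseg")
  fwd <- get("nn_forward", ns)
  set.seed(9)
  blk <- inception_block(6L, branch_channels = 3L)
  y <- fwd(blk, array(rnorm(64 * 64 * 6), c(64, 64, 6, 1)), train = FALSE)
  expect_equal(dim(y), c(32L, 32L, 15L, 1L))   # 5 branches x 3 channels
  expect_error(fwd(blk, array(0, c(9, 9, 6, 1)), train = FALSE),
               "shape error")
})

test_that("recurrent step follows the feedforward-plus-recurrent form", {
  # 1x1 spatial scalar case: z = 0.5*2 + 0.25*3 + 1 = 2.75
  u <- array(2, c(1, 1, 1, 1)); xp <- array(3, c(1, 1, 1, 1))
  wf <- array(0.5, c(1, 1, 1, 1)); wr <- array(0.25, c(1, 1, 1, 1))
  z <- recurrent_step(u, xp, wf, wr, b = 1)
  expect_equal(as.numeric(z), 2.75)
  # W_R = 0 degenerates to plain feedforward convolution
  set.seed(2)
  u <- array(rnorm(6 * 6 * 2), c(6, 6, 2, 1))
  xp <- array(rnorm(6 * 6 * 3), c(6, 6, 3, 1))
  wf <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  wr0 <- array(0, c(3, 3, 3, 4))
  b <- rnorm(4)
  ff <- scintiseg:::.cpp_conv2d_fwd(u, wf, b, 1L, 1L, 1L, 1L, 1L)
  expect_equal(recurrent_step(u, xp, wf, wr0, b), ff)
  # zero state (t = 1 initialization) likewise
  wr <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  expect_equal(recurrent_step(u, array(0, dim(xp)), wf, wr, b), ff)
  expect_error(recurrent_step(u, array(0, c(5, 5, 3, 1)), wf, wr, b),
               "shape error")
})

test_that("forward produces a full-resolution membership map in [0, 1]
           and t = 1 equals the zero-state single pass", {
  cfg <- model_config(recurrence_t = 3L, stage_channels = c(3L, 4L),
                      input_size = 16L, seed = 77L)
  model <- build_model(cfg)
  set.seed(1)
  img <- matrix(runif(256), 16)
  seg <- forward(model, img)
  expect_equal(dim(seg$membership), c(16L, 16L))
  expect_true(all(seg$membership >= 0 & seg$membership <= 1))
  expect_equal(seg$membership, 1 / (1 + exp(-seg$logits)))
  expect_true(all(seg$mask$mask %in% c(0L, 1L)))
  s1 <- forward(model, img, t = 1L)
  s1b <- forward(model, img, t = 1L)
  expect_identical(s1$logits, s1b$logits)   # determinism
  s3 <- forward(model, img, t = 3L)
  expect_false(identical(s1$logits, s3$logits))  # recurrence does something
  expect_error(forward(model, img, t = 0L), "t must be")
  expect_error(forward(model, matrix(0, 8, 8)), "shape error")
})

test_that("unrolling adds no parameters under weight sharing but grows
           them without sharing", {
  n1 <- n_params(build_model(model_config(recurrence_t = 1L,
                                          stage_channels = c(3L, 4L),
                                          input_size = 16L)))
  n2 <- n_params(build_model(model_config(recurrence_t = 2L,
                                          stage_channels = c(3L, 4L),
                                          input_size = 16L)))
  n3 <- n_params(build_model(model_config(recurrence_t = 3L,
                                          stage_channels = c(3L, 4L),
                                          input_size = 16L)))
  expect_equal(n1, n2)
  expect_equal(n2, n3)
  m_ns <- build_model(model_config(recurrence_t = 3L,
                                   stage_channels = c(3L, 4L),
                                   input_size = 16L,
                                   share_recurrent_weights = FALSE))
  expect_gt(n_params(m_ns), 2 * n1)
})

test_that("fixed seed and input give bit-identical logits across fresh
           builds", {
  cfg <- model_config(recurrence_t = 2L, stage_channels = c(3L, 4L),
                      input_size = 16L, seed = 123L)
  img <- matrix(seq(0, 1, length.out = 256), 16)
  l1 <- forward(build_model(cfg), img)$logits
  l2 <- forward(build_model(cfg), img)$logits
  expect_identical(l1, l2)
})
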