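#' DCGAN configuration
#'
#' Hyperparameters of the deep-convolutional GAN used to synthesize
#' additional unlabeled training images. The discriminator is updated
#' `iterations_k` times per generator update (default 3).
#'
#' @param latent_dim channels of the spatial latent code `z ~ P_Z`.
#' @param iterations_k discriminator steps per generator step (>= 1).
#' @param image_size side length of generated images (a multiple of 8;
#'   default 32, the desk-scale profile).
#' @param base_channels generator/discriminator width.
#' @param lr_g,lr_d Adam learning rates.
#' @param batch_size minibatch size.
#' @param seed RNG seed for initialization, latent draws and batching.
#' @return a `gan_config` list.
#' @export
gan_config <- function(latent_dim = 16L, iterations_k = 3L, image_size = 32L,
                       base_channels = 8L, lr_g = 2e-3, lr_d = 2e-3,
                       batch_size = 16L, seed = 1L) {
  if (iterations_k < 1L) stop_fmt("iterations_k must be >= 1")
  if (image_size %% 8L != 0L) stop_fmt("image_size must be a multiple of 8")
  structure(as.list(environment()), class = "gan_config")
}

#' Minimax value of the GAN game
#'
#' `E[log D(x)] + E[log(1 - D(G(z)))]`, the quantity the discriminator
#' ascends and the generator descends. At the indifference point
#' `D = 1/2` everywhere the value is `-2 log 2`.
#'
#' @param d_real discriminator probabilities on real samples.
#' @param d_fake discriminator probabilities on generated samples.
#' @param eps clamping epsilon to keep the logs finite.
#' @return scalar value.
#' @export
gan_value <- function(d_real, d_fake, eps = 1e-12) {
  if (length(d_real) == 0L || length(d_fake) == 0L)
    stop_fmt("empty batch")
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(dr)) + mean(log(1 - df))
}

# generator: spatial latent (s/8 x s/8 x latent) -> three upsample+conv
# blocks -> 1-channel image through a logistic squash
build_generator <- function(cfg) {
  b <- cfg$base_channels
  nn_sequential(
    conv_bn_act(cfg$latent_dim, 2L * b, 3L),
    nn_upsample2(), conv_bn_act(2L * b, 2L * b, 3L),
    nn_upsample2(), conv_bn_act(2L * b, b, 3L),
    nn_upsample2(), conv_bn_act(b, b, 3L),
    nn_conv2d(b, 1L, 1L, bias = TRUE))
}

# discriminator: three stride-2 conv blocks -> 1x1 conv -> global mean
build_discriminator <- function(cfg) {
  b <- cfg$base_channels
  nn_sequential(
    conv_bn_act(1L, b, 3L, stride = 2L, pad = 1L),
    conv_bn_act(b, 2L * b, 3L, stride = 2L, pad = 1L),
    conv_bn_act(2L * b, 2L * b, 3L, stride = 2L, pad = 1L),
    nn_conv2d(2L * b, 1L, 1L, bias = TRUE))
}

gan_latent <- function(cfg, n) {
  s8 <- cfg$image_size %/% 8L
  array(stats::rnorm(s8 * s8 * cfg$latent_dim * n),
        c(s8, s8, cfg$latent_dim, n))
}

# discriminator probability head: global average of the logit map,
# squashed; backward spreads each image's gradient uniformly over the
# spatial positions of the logit map
disc_backward <- function(disc, dlogit, logit_dim) {
  hw <- logit_dim[1] * logit_dim[2]
  d <- array(rep(dlogit, each = hw), logit_dim)
  nn_backward(disc, d / hw)
}

#' Train a DCGAN on a set of images
#'
#' Alternating optimization: `iterations_k` discriminator ascent steps on
#' `E[log D(x)] + E[log(1 - D(G(z)))]` per single generator step (which
#' descends via the non-saturating surrogate `-E[log D(G(z))]`). Fully
#' seeded, so the loss history is reproducible on CPU.
#'
#' @param real_images list of matrices (values in \[0, 1\]) or an array
#'   (H, W, 1, N); all images must share the configured size.
#' @param cfg a [gan_config].
#' @param steps number of generator steps.
#' @return list with `generator`, `discriminator`, `cfg`, and `history`
#'   (data frame: step, d_steps, value, d_real, d_fake).
#' @export
train_dcgan <- function(real_images, cfg = gan_config(), steps = 50L) {
  if (is.list(real_images)) {
    dims <- vapply(real_images, function(x) dim(as.matrix(x)), integer(2))
    if (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L)
      stop_fmt("shape error: images have non-uniform sizes")
    x_all <- array(unlist(real_images),
                   c(dims[1, 1], dims[2, 1], 1L, length(real_images)))
  } else x_all <- real_images
  S <- cfg$image_size
  if (dim(x_all)[1] != S || dim(x_all)[2] != S)
    stop_fmt("shape error: images are %dx%d but config says %d",
             dim(x_all)[1], dim(x_all)[2], S)
  n <- dim(x_all)[4]
  with_seed(cfg$seed, {
    gen <- build_generator(cfg)
    disc <- build_discriminator(cfg)
    opt_g <- nn_adam(gen, lr = cfg$lr_g, beta1 = 0.5, weight_decay = 0)
    opt_d <- nn_adam(disc, lr = cfg$lr_d, beta1 = 0.5, weight_decay = 0)
    hist <- vector("list", steps)
    for (st in seq_len(steps)) {
      dr_mean <- df_mean <- 0
      for (kk in seq_len(cfg$iterations_k)) {
        idx <- sample.int(n, min(cfg$batch_size, n))
        xb <- x_all[, , , idx, drop = FALSE]
        z <- gan_latent(cfg, length(idx))
        fake <- logistic(nn_forward(gen, z, train = FALSE))
        nn_zero_grad(disc)
        lg_r <- nn_forward(disc, xb, TRUE)
        pr <- logistic(apply(lg_r, 4, mean))
        # d/dlogit of -log D(x) = D - 1 (ascent on log D)
        disc_backward(disc, pr - 1, dim(lg_r))
        lg_f <- nn_forward(disc, fake, TRUE)
        pf <- logistic(apply(lg_f, 4, mean))
        disc_backward(disc, pf, dim(lg_f))
        nn_adam_step(opt_d)
        dr_mean <- mean(pr); df_mean <- mean(pf)
      }
      # generator step (non-saturating): descend -E[log D(G(z))]
      z <- gan_latent(cfg, cfg$batch_size)
      nn_zero_grad(gen); nn_zero_grad(disc)
      glog <- nn_forward(gen, z, TRUE)
      fake <- logistic(glog)
      lg_f <- nn_forward(disc, fake, TRUE)
      pf <- logistic(apply(lg_f, 4, mean))
      dfake <- disc_backward(disc, pf - 1, dim(lg_f))
      dglog <- dfake * fake * (1 - fake)
      nn_backward(gen, dglog)
      nn_adam_step(opt_g)
      hist[[st]] <- data.frame(step = st, d_steps = cfg$iterations_k,
                               value = gan_value(dr_mean, df_mean),
                               d_real = dr_mean, d_fake = df_mean)
    }
    list(generator = gen, discriminator = disc, cfg = cfg,
         history = do.call(rbind, hist))
  })
}

#' Sample images from a (trained) generator
#'
#' @param gan result of [train_dcgan()] (or a list with `generator` and
#'   `cfg`).
#' @param n number of images (> 0).
#' @param seed seed for the latent draws.
#' @return array (S, S, 1, n) of values in \[0, 1\], with attribute
#'   `"provenance" = "gan"`. GAN samples carry no lesion masks and are
#'   used as unlabeled training material only.
#' @export
generate_gan_samples <- function(gan, n, seed = 1L) {
  if (n <= 0L) stop_fmt("validation error: n must be positive")
  with_seed(seed, {
    z <- gan_latent(gan$cfg, n)
    out <- logistic(nn_forward(gan$generator, z, train = FALSE))
    attr(out, "provenance") <- "gan"
    out
  })
}
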