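#' Output size of a (dilated) convolution
#'
#' For input size `i`, kernel `k`, dilation `d`, padding `p` and stride
#' `s`, the effective kernel is `n = k + (k - 1)(d - 1)` and the output
#' size is `o = floor((i + 2p - n) / s) + 1` (standard convolution
#' arithmetic).
#'
#' @param i input size in pixels.
#' @param k kernel size.
#' @param d dilation rate.
#' @param p padding.
#' @param s stride.
#' @return output size `o` (integer), with the effective kernel size as
#'   attribute `"n"`.
#' @export
conv_output_size <- function(i, k, d = 1L, p = 0L, s = 1L) {
  if (k < 1L || d < 1L || s < 1L || p < 0L)
    stop_fmt("invalid convolution spec (k >= 1, d >= 1, s >= 1, p >= 0)")
  n <- k + (k - 1L) * (d - 1L)
  if (i + 2L * p < n)
    stop_fmt("size error: input %d (+ 2x%d padding) smaller than effective kernel %d",
             i, p, n)
  o <- (i + 2L * p - n) %/% s + 1L
  structure(as.integer(o), n = as.integer(n))
}

# conv + BN + PReLU triple used throughout
conv_bn_act <- function(cin, cout, k = 3L, kw = k, stride = 1L, dil = 1L,
                        pad = "same") {
  nn_sequential(nn_conv2d(cin, cout, k, kw, stride = stride, pad = pad,
                          dil = dil, bias = FALSE),
                nn_bn(cout), nn_prelu(cout))
}

#' Dilated residual convolution block
#'
#' Two paths: the residual mapping path is DilatedConv-BN-PReLU twice
#' (kernel 3, configurable dilation), the skip path is a 1x1 conventional
#' convolution matching the channel counts; the block output is their
#' element-wise sum. Spatial size is preserved. The dilation enlarges the
#' receptive field without losing resolution; the skip path keeps
#' gradients flowing in deep stacks.
#'
#' @param cin,cout input/output channel counts.
#' @param dil dilation rate of both convolutions in the residual path.
#' @return a network module usable with the internal layer framework.
#' @export
dilated_residual_block <- function(cin, cout, dil = 2L) {
  new_layer("nn_residual",
            children = list(
              res = nn_sequential(conv_bn_act(cin, cout, 3L, dil = dil),
                                  conv_bn_act(cout, cout, 3L, dil = dil)),
              skip = nn_conv2d(cin, cout, 1L, bias = TRUE)))
}

#' @export
nn_forward.nn_residual <- function(layer, x, train = TRUE) {
  nn_forward(layer$children$res, x, train) +
    nn_forward(layer$children$skip, x, train)
}

#' @export
nn_backward.nn_residual <- function(layer, dy) {
  nn_backward(layer$children$skip, dy) + nn_backward(layer$children$res, dy)
}

#' Inception block (multi-scale, resolution-halving)
#'
#' Five parallel branches, each ending at stride 2 so the block halves the
#' grid resolution: factorized 1x3/3x1 convolutions, factorized 1x7/7x1
#' convolutions, a 1x1 convolution, a 5x5 convolution, and 2x2 max pooling
#' after a 1x1 convolution. Branch outputs are depth-concatenated, so the
#' output channel count is the sum of the branch widths.
#'
#' @param cin input channels.
#' @param branch_channels channels produced by each branch (default
#'   `max(2, cin %/% 2)`).
#' @return a network module; output has `5 * branch_channels` channels at
#'   half the input resolution. Input spatial size must be even.
#' @export
inception_block <- function(cin, branch_channels = max(2L, cin %/% 2L)) {
  b <- branch_channels
  new_layer("nn_inception",
            children = list(
              b13 = nn_sequential(conv_bn_act(cin, b, 1L),
                                  conv_bn_act(b, b, 1L, kw = 3L),
                                  conv_bn_act(b, b, 3L, kw = 1L, stride = 2L,
                                              pad = c(1L, 0L))),
              b17 = nn_sequential(conv_bn_act(cin, b, 1L),
                                  conv_bn_act(b, b, 1L, kw = 7L),
                                  conv_bn_act(b, b, 7L, kw = 1L, stride = 2L,
                                              pad = c(3L, 0L))),
              b11 = conv_bn_act(cin, b, 1L, stride = 2L, pad = 0L),
              b55 = conv_bn_act(cin, b, 5L, stride = 2L, pad = 2L),
              bmp = nn_sequential(conv_bn_act(cin, b, 1L), nn_maxpool2())),
            branch_channels = b)
}

#' @export
nn_forward.nn_inception <- function(layer, x, train = TRUE) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L)
    stop_fmt("shape error: inception block needs even spatial size, got %dx%d",
             d[1], d[2])
  ys <- lapply(layer$children, nn_forward, x = x, train = train)
  chs <- vapply(ys, function(y) dim(y)[3], integer(1))
  Ho <- dim(ys[[1]])[1]; Wo <- dim(ys[[1]])[2]; N <- d[4]
  out <- array(0, c(Ho, Wo, sum(chs), N))
  at <- 0L
  for (y in ys) {
    cc <- dim(y)[3]
    out[, , at + seq_len(cc), ] <- y
    at <- at + cc
  }
  if (train) push_cache(layer, chs)
  out
}

#' @export
nn_backward.nn_inception <- function(layer, dy) {
  chs <- pop_cache(layer)
  dx <- NULL
  at <- 0L
  for (i in seq_along(layer$children)) {
    dpart <- dy[, , at + seq_len(chs[i]), , drop = FALSE]
    at <- at + chs[i]
    g <- nn_backward(layer$children[[i]], dpart)
    dx <- if (is.null(dx)) g else dx + g
  }
  dx
}

#' One recurrent convolution step
#'
#' The elementwise recurrence of the feature extractor: the response of
#' feature map `k` at pixel (i, j) and time t is the feedforward
#' convolution of the current input plus the recurrent convolution of the
#' previous state plus a bias:
#' `z(t) = W_F * u(t) + W_R * x(t - 1) + b`.
#' Exposed directly for testing; inside the model the same computation is
#' performed by the shared entry convolutions of [build_model()].
#'
#' @param u feedforward input, array (H, W, Cin, N).
#' @param x_prev recurrent state, array (H, W, Cstate, N) (zeros at t = 1).
#' @param W_F feedforward kernel (KH, KW, Cin, K).
#' @param W_R recurrent kernel (KH, KW, Cstate, K).
#' @param b bias, length K.
#' @return array (H, W, K, N).
#' @export
recurrent_step <- function(u, x_prev, W_F, W_R, b) {
  if (!all(dim(u)[c(1, 2, 4)] == dim(x_prev)[c(1, 2, 4)]))
    stop_fmt("shape error: input and state are not spatially aligned")
  ph_f <- (dim(W_F)[1] - 1L) %/% 2L; pw_f <- (dim(W_F)[2] - 1L) %/% 2L
  ph_r <- (dim(W_R)[1] - 1L) %/% 2L; pw_r <- (dim(W_R)[2] - 1L) %/% 2L
  .cpp_conv2d_fwd(u, W_F, b, 1L, ph_f, pw_f, 1L, 1L) +
    .cpp_conv2d_fwd(x_prev, W_R, NULL, 1L, ph_r, pw_r, 1L, 1L)
}

# recurrent extractor container -------------------------------------------

#' @export
nn_forward.nn_recurrent <- function(layer, x, train = TRUE) {
  d <- dim(x)
  steps <- layer$t
  state <- array(0, c(d[1], d[2], layer$c_state, d[4]))
  for (s in seq_len(steps)) {
    u <- layer$unit(s)
    z <- nn_forward(u$conv_f, x, train) + nn_forward(u$conv_r, state, train)
    state <- nn_forward(u$body, z, train)
  }
  state
}

#' @export
nn_backward.nn_recurrent <- function(layer, dy) {
  dx <- NULL
  for (s in rev(seq_len(layer$t))) {
    u <- layer$unit(s)
    dz <- nn_backward(u$body, dy)
    g <- nn_backward(u$conv_f, dz)
    dx <- if (is.null(dx)) g else dx + g
    dy <- nn_backward(u$conv_r, dz)   # gradient into the previous state
  }
  dx
}

#' Model configuration
#'
#' Defaults describe the full-scale model: recurrence depth 3 (the optimum
#' found for this architecture), four encoder stages of 16/32/64/128
#' channels, dilation rate 2 in the residual paths, shared recurrent
#' weights, 256x256 input. The three structure switches
#' (`use_dilation`, `use_inception`, `use_residual`) reproduce the
#' ablation cases: all off is the plain-convolution baseline.
#'
#' @param recurrence_t number of unrolled extraction passes (>= 1).
#' @param stage_channels encoder channel widths, one per stage.
#' @param dilation dilation rates per stage (recycled).
#' @param share_recurrent_weights share weights across unroll steps. When
#'   `FALSE` every step owns a separate copy of the extractor, so the
#'   parameter count grows with `recurrence_t`.
#' @param input_size input side length in pixels; must be divisible by
#'   `2^length(stage_channels)`.
#' @param use_dilation,use_inception,use_residual structure switches.
#' @param inception_branch_channels per-branch width of the inception
#'   block (default half the deepest stage).
#' @param threshold binarization threshold on the membership map.
#' @param seed seed for weight initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(recurrence_t = 3L,
                         stage_channels = c(16L, 32L, 64L, 128L),
                         dilation = 2L,
                         share_recurrent_weights = TRUE,
                         input_size = 256L,
                         use_dilation = TRUE,
                         use_inception = TRUE,
                         use_residual = TRUE,
                         inception_branch_channels = NULL,
                         threshold = 0.5,
                         seed = 1L) {
  if (recurrence_t < 1L) stop_fmt("validation error: recurrence_t must be >= 1")
  ns <- length(stage_channels)
  if (input_size %% (2^ns) != 0L)
    stop_fmt("input_size %d not divisible by 2^%d", input_size, ns)
  structure(list(recurrence_t = as.integer(recurrence_t),
                 stage_channels = as.integer(stage_channels),
                 dilation = rep_len(as.integer(dilation), ns),
                 share_recurrent_weights = share_recurrent_weights,
                 input_size = as.integer(input_size),
                 use_dilation = use_dilation,
                 use_inception = use_inception,
                 use_residual = use_residual,
                 inception_branch_channels = inception_branch_channels,
                 threshold = threshold, seed = as.integer(seed)),
            class = "model_config")
}

# one extraction unit: entry convolutions + encoder/bottleneck/decoder body
build_unit <- function(cfg) {
  s <- cfg$stage_channels
  ns <- length(s)
  dil <- if (cfg$use_dilation) cfg$dilation else rep(1L, ns)
  stage_block <- function(cin, cout, d) {
    if (cfg$use_residual) dilated_residual_block(cin, cout, dil = d)
    else nn_sequential(conv_bn_act(cin, cout, 3L, dil = d),
                       conv_bn_act(cout, cout, 3L, dil = d))
  }
  enc <- list()
  cin <- s[1]
  for (j in seq_len(ns)) {
    enc <- c(enc, list(stage_block(cin, s[j], dil[j])))
    if (j < ns) enc <- c(enc, list(nn_maxpool2()))
    cin <- s[j]
  }
  bch <- if (is.null(cfg$inception_branch_channels))
    max(2L, s[ns] %/% 2L) else as.integer(cfg$inception_branch_channels)
  if (cfg$use_inception) {
    bottleneck <- inception_block(s[ns], bch)
    cbot <- 5L * bch
  } else {
    bottleneck <- conv_bn_act(s[ns], 5L * bch, 3L, stride = 2L, pad = 1L)
    cbot <- 5L * bch
  }
  dec <- list()
  cin <- cbot
  for (j in rev(seq_len(ns))) {
    dec <- c(dec, list(nn_upsample2(), conv_bn_act(cin, s[j], 3L)))
    cin <- s[j]
  }
  list(conv_f = nn_conv2d(1L, s[1], 3L, bias = TRUE),
       conv_r = nn_conv2d(s[1], s[1], 3L, bias = FALSE),
       body = nn_sequential(c(enc, list(bottleneck), dec)))
}

#' Build the recurrent segmentation model
#'
#' Assembles the recurrent feature-extraction network: an entry step
#' combining a feedforward convolution of the input image with a recurrent
#' convolution of the previous extractor state, an encoder of dilated
#' residual blocks with max pooling, an inception bottleneck, and a
#' decoder of bilinear upsampling plus conventional convolutions back to
#' full resolution. The extractor is unrolled `recurrence_t` times (zero
#' initial state); a 1x1 convolution head maps the final state to
#' per-pixel logits and the membership map is their logistic transform.
#'
#' @param cfg a [model_config].
#' @return object of class `seg_model`.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(cfg$seed, {
    s1 <- cfg$stage_channels[1]
    if (cfg$share_recurrent_weights) {
      unit <- build_unit(cfg)
      extractor <- new_layer("nn_recurrent",
                             children = unit,
                             c_state = s1, t = cfg$recurrence_t,
                             unit = function(step) unit)
    } else {
      units <- lapply(seq_len(cfg$recurrence_t), function(i) build_unit(cfg))
      extractor <- new_layer("nn_recurrent",
                             children = unlist(units, recursive = FALSE),
                             c_state = s1, t = cfg$recurrence_t,
                             unit = function(step) units[[step]])
    }
    head <- nn_conv2d(s1, 1L, 1L, bias = TRUE)
    structure(list(extractor = extractor, head = head, config = cfg),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<seg_model> t = %d (%s weights), stages [%s], ",
                     "dilated = %s, inception = %s, residual = %s, ",
                     "%s parameters\n"),
              cfg$recurrence_t,
              if (cfg$share_recurrent_weights) "shared" else "per-step",
              paste(cfg$stage_channels, collapse = ", "),
              cfg$use_dilation, cfg$use_inception, cfg$use_residual,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `seg_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  nn_n_params(model$extractor) + nn_n_params(model$head)
}

logistic <- function(x) 1 / (1 + exp(-x))

# batch forward: x (H, W, 1, N) -> list(logits, membership), both (H, W, 1, N)
seg_forward_batch <- function(model, x, train = TRUE, t = NULL) {
  model$extractor$t <- if (is.null(t)) model$config$recurrence_t
  else as.integer(t)
  state <- nn_forward(model$extractor, x, train)
  logits <- nn_forward(model$head, state, train)
  list(logits = logits, membership = logistic(logits))
}

# batch backward from d(loss)/d(logits)
seg_backward_batch <- function(model, dlogits) {
  dstate <- nn_backward(model$head, dlogits)
  nn_backward(model$extractor, dstate)
}

#' Segment one image
#'
#' Runs the model on a normalized image and returns the soft segmentation:
#' the per-pixel lesion-membership map in \[0, 1\], its logits, and the
#' binarized mask at the configured threshold.
#'
#' @param model a `seg_model` from [build_model()].
#' @param image normalized image matrix (`input_size` x `input_size`,
#'   values in \[0, 1\]; see [normalize_for_network()]).
#' @param t recurrence depth override (default: the model's configured
#'   `recurrence_t`); must be >= 1.
#' @return object of class `soft_segmentation` with `membership`,
#'   `logits`, `threshold` and `mask` (a [lesion_mask]).
#' @export
forward <- function(model, image, t = NULL) {
  stopifnot(inherits(model, "seg_model"))
  if (!is.null(t) && t < 1L) stop_fmt("validation error: t must be >= 1")
  if (!is.matrix(image) ||
      nrow(image) != model$config$input_size ||
      ncol(image) != model$config$input_size)
    stop_fmt("shape error: expected %dx%d image",
             model$config$input_size, model$config$input_size)
  x <- array(image, c(nrow(image), ncol(image), 1L, 1L))
  out <- seg_forward_batch(model, x, train = FALSE, t = t)
  soft_segmentation(matrix(out$logits[, , 1L, 1L], nrow(image)),
                    threshold = model$config$threshold)
}

#' @rdname forward
#' @param logits logits matrix.
#' @param threshold binarization threshold on the membership scale.
#' @export
soft_segmentation <- function(logits, threshold = 0.5) {
  membership <- logistic(logits)
  structure(list(membership = membership, logits = logits,
                 threshold = threshold,
                 mask = lesion_mask((membership > threshold) * 1L,
                                    source = "predicted")),
            class = "soft_segmentation")
}
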