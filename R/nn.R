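# Minimal CNN layer framework.
#
# Every layer is an environment holding `params` (named list of arrays),
# matching `grads`, and a `cache` *stack*.  `nn_forward(layer, x, train)`
# pushes one cache frame per call when training; `nn_backward(layer, dy)`
# pops the most recent frame and accumulates parameter gradients.  The
# stack discipline is what makes backpropagation-through-time of the
# recurrent feature extractor work with shared weights: unrolling pushes t
# frames, the reverse pass pops them in reverse order, and gradients from
# all steps accumulate into the same shared parameter arrays.
#
# Tensors are R arrays dim (H, W, C, N); the convolution, pooling and
# upsampling kernels are compiled (see src/nn_ops.cpp).

new_layer <- function(.cls, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$cache <- list()
  if (is.null(e$params)) e$params <- list()
  e$grads <- lapply(e$params, function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p)))
  class(e) <- c(.cls, "nn_layer")
  e
}

push_cache <- function(layer, val) layer$cache[[length(layer$cache) + 1L]] <- val
pop_cache <- function(layer) {
  n <- length(layer$cache)
  if (n == 0L) stop_fmt("backward called with empty cache in %s", class(layer)[1])
  val <- layer$cache[[n]]
  layer$cache[[n]] <- NULL
  val
}

#' @export
nn_forward <- function(layer, x, train = TRUE) UseMethod("nn_forward")
#' @export
nn_backward <- function(layer, dy) UseMethod("nn_backward")

# ---- convolution ----------------------------------------------------------

# `pad = "same"` resolves to (n - 1) / 2 per axis (odd effective kernels),
# preserving spatial size at stride 1.
nn_conv2d <- function(cin, cout, kh, kw = kh, stride = 1L, pad = "same",
                      dil = 1L, bias = TRUE) {
  dh <- if (length(dil) > 1) dil[1] else dil
  dw <- if (length(dil) > 1) dil[2] else dil
  nh <- kh + (kh - 1L) * (dh - 1L)
  nw <- kw + (kw - 1L) * (dw - 1L)
  if (identical(pad, "same")) {
    ph <- (nh - 1L) %/% 2L; pw <- (nw - 1L) %/% 2L
  } else if (identical(pad, "valid")) {
    ph <- 0L; pw <- 0L
  } else {
    ph <- if (length(pad) > 1) pad[1] else pad
    pw <- if (length(pad) > 1) pad[2] else pad
  }
  fan_in <- kh * kw * cin
  params <- list(W = array(stats::rnorm(kh * kw * cin * cout,
                                        sd = sqrt(2 / fan_in)),
                           dim = c(kh, kw, cin, cout)))
  if (bias) params$b <- numeric(cout)
  new_layer("nn_conv2d", cin = cin, cout = cout, kh = kh, kw = kw,
            stride = as.integer(stride), ph = as.integer(ph),
            pw = as.integer(pw), dh = as.integer(dh), dw = as.integer(dw),
            has_bias = bias, params = params)
}

#' @export
nn_forward.nn_conv2d <- function(layer, x, train = TRUE) {
  y <- if (layer$stride == 1L)
    .cpp_conv2d_s1_fwd(x, layer$params$W,
                       if (layer$has_bias) layer$params$b else NULL,
                       layer$ph, layer$pw, layer$dh, layer$dw)
  else
    .cpp_conv2d_fwd(x, layer$params$W,
                    if (layer$has_bias) layer$params$b else NULL,
                    layer$stride, layer$ph, layer$pw, layer$dh, layer$dw)
  if (train) push_cache(layer, x)
  y
}

#' @export
nn_backward.nn_conv2d <- function(layer, dy) {
  x <- pop_cache(layer)
  r <- if (layer$stride == 1L)
    .cpp_conv2d_s1_bwd(x, layer$params$W, dy, layer$has_bias,
                       layer$ph, layer$pw, layer$dh, layer$dw)
  else
    .cpp_conv2d_bwd(x, layer$params$W, dy, layer$has_bias,
                    layer$stride, layer$ph, layer$pw, layer$dh, layer$dw)
  layer$grads$W <- layer$grads$W + r$dw
  if (layer$has_bias) layer$grads$b <- layer$grads$b + r$db
  r$dx
}

# ---- batch normalization --------------------------------------------------

# Normalizes each channel over (H, W, N).  With batch size 1 this reduces
# to per-channel spatial (instance) statistics.
nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("nn_bn", c = c, momentum = momentum, eps = eps,
            params = list(gamma = rep(1, c), beta = rep(0, c)),
            running_mean = rep(0, c), running_var = rep(1, c))
}

#' @export
nn_forward.nn_bn <- function(layer, x, train = TRUE) {
  if (train) {
    r <- .cpp_bn_fwd(x, layer$params$gamma, layer$params$beta,
                     NULL, NULL, layer$eps)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * r$mean
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * r$var
    push_cache(layer, list(xhat = r$xhat, invstd = r$invstd))
  } else {
    r <- .cpp_bn_fwd(x, layer$params$gamma, layer$params$beta,
                     layer$running_mean, layer$running_var, layer$eps)
  }
  r$y
}

#' @export
nn_backward.nn_bn <- function(layer, dy) {
  cc <- pop_cache(layer)
  r <- .cpp_bn_bwd(dy, cc$xhat, cc$invstd, layer$params$gamma)
  layer$grads$gamma <- layer$grads$gamma + r$dgamma
  layer$grads$beta <- layer$grads$beta + r$dbeta
  r$dx
}

# ---- PReLU ----------------------------------------------------------------

nn_prelu <- function(c, init = 0.25) {
  new_layer("nn_prelu", c = c, params = list(a = rep(init, c)))
}

#' @export
nn_forward.nn_prelu <- function(layer, x, train = TRUE) {
  if (train) push_cache(layer, x)
  .cpp_prelu_fwd(x, layer$params$a)
}

#' @export
nn_backward.nn_prelu <- function(layer, dy) {
  x <- pop_cache(layer)
  r <- .cpp_prelu_bwd(x, layer$params$a, dy)
  layer$grads$a <- layer$grads$a + r$da
  dx <- r$dx
  dx
}

# ---- pooling / upsampling -------------------------------------------------

nn_maxpool2 <- function() new_layer("nn_maxpool2")

#' @export
nn_forward.nn_maxpool2 <- function(layer, x, train = TRUE) {
  r <- .cpp_maxpool2_fwd(x)
  if (train) push_cache(layer, list(idx = r$idx, xdim = dim(x)))
  r$y
}

#' @export
nn_backward.nn_maxpool2 <- function(layer, dy) {
  cc <- pop_cache(layer)
  .cpp_maxpool2_bwd(dy, cc$idx, as.integer(cc$xdim))
}

nn_upsample2 <- function() new_layer("nn_upsample2")

#' @export
nn_forward.nn_upsample2 <- function(layer, x, train = TRUE) {
  if (train) push_cache(layer, dim(x))
  .cpp_upsample2_fwd(x)
}

#' @export
nn_backward.nn_upsample2 <- function(layer, dy) {
  .cpp_upsample2_bwd(dy, as.integer(pop_cache(layer)))
}

# ---- containers -----------------------------------------------------------

nn_sequential <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !inherits(ch[[1]], "nn_layer"))
    ch <- ch[[1]]
  new_layer("nn_sequential", children = ch)
}

#' @export
nn_forward.nn_sequential <- function(layer, x, train = TRUE) {
  for (ch in layer$children) x <- nn_forward(ch, x, train)
  x
}

#' @export
nn_backward.nn_sequential <- function(layer, dy) {
  for (ch in rev(layer$children)) dy <- nn_backward(ch, dy)
  dy
}

# ---- bookkeeping ----------------------------------------------------------

# flatten a module tree (or plain list of modules) into the list of
# layers that own parameters
nn_layers <- function(layer, params_only = TRUE) {
  if (is.list(layer) && !inherits(layer, "nn_layer"))
    return(do.call(c, lapply(layer, nn_layers, params_only = params_only)))
  out <- list()
  if (!is.null(layer$children))
    for (ch in layer$children)
      out <- c(out, nn_layers(ch, params_only))
  if (!params_only || length(layer$params)) out <- c(out, list(layer))
  out
}

nn_zero_grad <- function(layer) {
  for (l in nn_layers(layer, params_only = FALSE)) {
    l$grads <- lapply(l$params, function(p)
      if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p)))
    l$cache <- list()
  }
  invisible(layer)
}

nn_n_params <- function(layer) {
  sum(vapply(nn_layers(layer),
             function(l) sum(vapply(l$params, length, integer(1))), numeric(1)))
}

# ---- Adam -----------------------------------------------------------------

# Adam with beta1 = learning momentum, beta2 = 0.999; L2 weight decay is
# applied to convolution weight tensors only (not biases, BN or PReLU
# parameters).
nn_adam <- function(model, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8, weight_decay = 1e-4) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- nn_layers(model)
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2
  opt$eps <- eps; opt$wd <- weight_decay; opt$t <- 0L
  for (l in opt$layers)
    l$adam <- lapply(l$params, function(p)
      list(m = array(0, if (is.null(dim(p))) length(p) else dim(p)),
           v = array(0, if (is.null(dim(p))) length(p) else dim(p))))
  opt
}

nn_adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (l in opt$layers) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (nm == "W" && opt$wd > 0) g <- g + opt$wd * l$params[[nm]]
      st <- l$adam[[nm]]
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
      l$adam[[nm]] <- st
      upd <- opt$lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
      p <- l$params[[nm]] - as.numeric(upd)
      if (!is.null(dim(l$params[[nm]]))) dim(p) <- dim(l$params[[nm]])
      l$params[[nm]] <- p
    }
  }
  invisible(opt)
}
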