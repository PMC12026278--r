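# Minimal dense-tensor neural-network core.
#
# Tensors are plain arrays with dim c(C, H, W, N) (channel fastest), so a
# 1x1 convolution is a single BLAS GEMM on the C x (H*W*N) matricization.
# Layers are environments carrying parameters, running statistics and the
# per-call cache needed by the hand-written backward pass. Everything is
# double precision and deterministic given the RNG state at build time.

new_param <- function(value, decay = TRUE) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  e$buf <- NULL      # momentum buffer, allocated lazily by the optimizer
  e$decay <- decay
  e
}

n_elements <- function(p) length(p$v)

#' Apply a layer or module to an input tensor
#' @param layer layer object.
#' @param x input array, dim c(C, H, W, N).
#' @param training logical; cache intermediates for the backward pass.
#' @return output array.
#' @export
nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")
#' Back-propagate a gradient through a layer, accumulating weight gradients
#' @param layer layer object previously run with training = TRUE.
#' @param dy gradient with respect to the layer output.
#' @return gradient with respect to the layer input.
#' @export
nn_backward <- function(layer, dy) UseMethod("nn_backward")
#' List the trainable parameter records of a layer or module
#' @param layer layer object.
#' @return named list of parameter environments (fields v, g).
#' @export
nn_params <- function(layer) UseMethod("nn_params")

#' @exportS3Method
nn_params.default <- function(layer) {
  out <- list()
  for (nm in layer$param_names) out[[nm]] <- layer[[nm]]
  if (!is.null(layer$layers)) {
    for (i in seq_along(layer$layers)) {
      sub <- nn_params(layer$layers[[i]])
      if (length(sub))
        names(sub) <- paste0(layer$name %||% "seq", i, ".", names(sub))
      out <- c(out, sub)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mat_chw <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L], prod(d[-1L]))
  x
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

## ---- convolution ---------------------------------------------------------

nn_conv <- function(cin, cout, k = 1L, stride = 1L, dilation = 1L,
                    bias = FALSE, name = "conv") {
  stopifnot(k %% 2L == 1L)
  l <- new.env(parent = emptyenv())
  l$cin <- cin; l$cout <- cout; l$k <- as.integer(k)
  l$stride <- as.integer(stride); l$dilation <- as.integer(dilation)
  l$pad <- as.integer(dilation * (k - 1L) / 2L)
  l$W <- new_param(he_init(cout, cin * k * k, fan_in = cin * k * k))
  l$param_names <- "W"
  if (bias) {
    l$b <- new_param(numeric(cout))
    l$param_names <- c("W", "b")
  }
  l$name <- name
  class(l) <- c("nn_conv", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_conv <- function(layer, x, training = FALSE) {
  d <- dim(x)
  stopifnot(d[1L] == layer$cin)
  if (layer$k == 1L && layer$stride == 1L) {
    layer$cache <- if (training) list(x = x, d = d) else NULL
    y <- layer$W$v %*% mat_chw(x)
  } else {
    p <- im2col_chw(x, d[1L], d[2L], d[3L], d[4L],
                    layer$k, layer$stride, layer$dilation, layer$pad)
    layer$cache <- if (training) list(p = p, d = d) else NULL
    y <- layer$W$v %*% p
  }
  if (!is.null(layer$b)) y <- y + layer$b$v
  ho <- conv_out_size(d[2L], layer$k, layer$stride, layer$dilation, layer$pad)
  wo <- conv_out_size(d[3L], layer$k, layer$stride, layer$dilation, layer$pad)
  dim(y) <- c(layer$cout, ho, wo, d[4L])
  y
}

#' @exportS3Method
nn_backward.nn_conv <- function(layer, dy) {
  cc <- layer$cache
  dym <- mat_chw(dy)
  if (!is.null(layer$b)) layer$b$g <- acc_grad(layer$b$g, rowSums(dym))
  if (layer$k == 1L && layer$stride == 1L) {
    xm <- mat_chw(cc$x)
    layer$W$g <- acc_grad(layer$W$g, tcrossprod(dym, xm))
    dx <- crossprod(layer$W$v, dym)
    dim(dx) <- cc$d
  } else {
    layer$W$g <- acc_grad(layer$W$g, tcrossprod(dym, cc$p))
    dp <- crossprod(layer$W$v, dym)
    dx <- col2im_chw(dp, cc$d[1L], cc$d[2L], cc$d[3L], cc$d[4L],
                     layer$k, layer$stride, layer$dilation, layer$pad)
    dim(dx) <- cc$d
  }
  layer$cache <- NULL
  dx
}

conv_out_size <- function(n, k, stride, dilation, pad) {
  (n + 2L * pad - dilation * (k - 1L) - 1L) %/% stride + 1L
}

acc_grad <- function(old, g) if (is.null(old)) g else old + g

## ---- depthwise convolution ----------------------------------------------

nn_dwconv <- function(ch, k, stride = 1L, dilation = 1L, name = "dwconv") {
  l <- new.env(parent = emptyenv())
  l$ch <- ch; l$k <- as.integer(k)
  l$stride <- as.integer(stride); l$dilation <- as.integer(dilation)
  l$pad <- as.integer(dilation * (k - 1L) / 2L)
  w <- array(stats::rnorm(ch * k * k, sd = sqrt(2 / (k * k))), c(ch, k, k))
  l$W <- new_param(w)
  l$param_names <- "W"
  l$name <- name
  class(l) <- c("nn_dwconv", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_dwconv <- function(layer, x, training = FALSE) {
  d <- dim(x)
  stopifnot(d[1L] == layer$ch)
  y <- dwconv_fwd(x, d[1L], d[2L], d[3L], d[4L], layer$W$v,
                  layer$k, layer$stride, layer$dilation, layer$pad)
  ho <- conv_out_size(d[2L], layer$k, layer$stride, layer$dilation, layer$pad)
  wo <- conv_out_size(d[3L], layer$k, layer$stride, layer$dilation, layer$pad)
  dim(y) <- c(layer$ch, ho, wo, d[4L])
  layer$cache <- if (training) list(x = x, d = d) else NULL
  y
}

#' @exportS3Method
nn_backward.nn_dwconv <- function(layer, dy) {
  cc <- layer$cache
  d <- cc$d
  dw <- dwconv_bwd_w(cc$x, dy, d[1L], d[2L], d[3L], d[4L],
                     layer$k, layer$stride, layer$dilation, layer$pad)
  dim(dw) <- c(layer$ch, layer$k, layer$k)
  layer$W$g <- acc_grad(layer$W$g, dw)
  dx <- dwconv_bwd_x(dy, d[1L], d[2L], d[3L], d[4L], layer$W$v,
                     layer$k, layer$stride, layer$dilation, layer$pad)
  dim(dx) <- d
  layer$cache <- NULL
  dx
}

## ---- batch normalization -------------------------------------------------

nn_bn <- function(ch, eps = 1e-3, momentum = 0.1, name = "bn") {
  l <- new.env(parent = emptyenv())
  l$ch <- ch; l$eps <- eps; l$momentum <- momentum
  l$gamma <- new_param(rep(1, ch), decay = FALSE)
  l$beta <- new_param(numeric(ch), decay = FALSE)
  l$run_mean <- numeric(ch)
  l$run_var <- rep(1, ch)
  l$param_names <- c("gamma", "beta")
  l$name <- name
  class(l) <- c("nn_bn", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_bn <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (training) {
    n <- prod(d) / d[1L]
    st <- bn_fwd_train(x, layer$ch, layer$eps)
    m <- layer$momentum
    layer$run_mean <- (1 - m) * layer$run_mean + m * st$mean
    layer$run_var <- (1 - m) * layer$run_var + m * st$var * n / max(n - 1, 1)
    layer$cache <- list(xhat = st$xhat, invstd = st$invstd, d = d)
    y <- bn_affine(st$xhat, layer$ch, layer$gamma$v, layer$beta$v)
  } else {
    invstd <- 1 / sqrt(layer$run_var + layer$eps)
    y <- bn_affine(x - rep(layer$run_mean, length.out = length(x)),
                   layer$ch, layer$gamma$v * invstd, layer$beta$v)
  }
  dim(y) <- d
  y
}

#' @exportS3Method
nn_backward.nn_bn <- function(layer, dy) {
  cc <- layer$cache
  bw <- bn_bwd(dy, cc$xhat, cc$invstd, layer$gamma$v, layer$ch)
  layer$gamma$g <- acc_grad(layer$gamma$g, bw$dgamma)
  layer$beta$g <- acc_grad(layer$beta$g, bw$dbeta)
  dx <- bw$dx
  dim(dx) <- cc$d
  layer$cache <- NULL
  dx
}

## ---- activations ---------------------------------------------------------

nn_act <- function(type = c("relu", "swish", "sigmoid"), name = type) {
  type <- match.arg(type)
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$param_names <- character()
  l$name <- name
  class(l) <- c("nn_act", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_act <- function(layer, x, training = FALSE) {
  d <- dim(x)
  y <- switch(layer$type,
    relu = { x[x < 0] <- 0; x },
    swish = swish_fwd(x),
    sigmoid = 1 / (1 + exp(-x))
  )
  dim(y) <- d
  if (training) {
    layer$cache <- switch(layer$type, relu = y, swish = x, sigmoid = y)
  }
  y
}

#' @exportS3Method
nn_backward.nn_act <- function(layer, dy) {
  cc <- layer$cache
  layer$cache <- NULL
  dx <- switch(layer$type,
    relu = dy * (cc > 0),
    swish = swish_bwd(cc, dy),
    sigmoid = dy * cc * (1 - cc)
  )
  dim(dx) <- dim(dy)
  dx
}

## ---- global average pooling ---------------------------------------------

nn_gap <- function(name = "gap") {
  l <- new.env(parent = emptyenv())
  l$param_names <- character()
  l$name <- name
  class(l) <- c("nn_gap", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_gap <- function(layer, x, training = FALSE) {
  d <- dim(x)
  dim(x) <- c(d[1L] * 1L, d[2L] * d[3L], d[4L])
  y <- apply(x, 3L, function(m) {
    dim(m) <- c(d[1L], d[2L] * d[3L])
    rowMeans(m)
  })
  dim(y) <- c(d[1L], 1L, 1L, d[4L])
  layer$cache <- if (training) d else NULL
  y
}

#' @exportS3Method
nn_backward.nn_gap <- function(layer, dy) {
  d <- layer$cache
  layer$cache <- NULL
  npx <- d[2L] * d[3L]
  dx <- array(0, d)
  g <- array(dy, c(d[1L], d[4L])) / npx
  for (n in seq_len(d[4L])) dx[, , , n] <- g[, n]
  dx
}

## ---- bilinear upsampling -------------------------------------------------

nn_upsample <- function(factor = 4L, name = "upsample") {
  l <- new.env(parent = emptyenv())
  l$factor <- as.integer(factor)
  l$param_names <- character()
  l$name <- name
  class(l) <- c("nn_upsample", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_upsample <- function(layer, x, training = FALSE) {
  d <- dim(x)
  ho <- d[2L] * layer$factor; wo <- d[3L] * layer$factor
  y <- resize_bilinear_fwd(x, d[1L], d[2L], d[3L], d[4L], ho, wo)
  dim(y) <- c(d[1L], ho, wo, d[4L])
  layer$cache <- if (training) d else NULL
  y
}

#' @exportS3Method
nn_backward.nn_upsample <- function(layer, dy) {
  d <- layer$cache
  layer$cache <- NULL
  do <- dim(dy)
  dx <- resize_bilinear_bwd(dy, d[1L], d[2L], d[3L], d[4L], do[2L], do[3L])
  dim(dx) <- d
  dx
}

## ---- sequential container ------------------------------------------------

nn_seq <- function(..., name = "seq") {
  l <- new.env(parent = emptyenv())
  l$layers <- list(...)
  l$param_names <- character()
  l$name <- name
  class(l) <- c("nn_seq", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_seq <- function(layer, x, training = FALSE) {
  for (sub in layer$layers) x <- nn_forward(sub, x, training)
  x
}

#' @exportS3Method
nn_backward.nn_seq <- function(layer, dy) {
  for (sub in rev(layer$layers)) dy <- nn_backward(sub, dy)
  dy
}

## ---- losses and the optimizer -------------------------------------------

#' Softmax cross-entropy over pixels
#'
#' Computes the mean pixel-wise cross-entropy between logits and integer
#' labels, together with the gradient with respect to the logits.
#'
#' @param logits array with dim `c(K, H, W, N)`.
#' @param labels integer array/matrix with dim `c(H, W, N)` (or `c(H, W)` for
#'   a single image), 0-based class ids in `0..K-1`.
#' @return list with elements `loss` (scalar), `grad` (same shape as logits)
#'   and `probs` (softmax scores).
#' @export
softmax_xent <- function(logits, labels) {
  d <- dim(logits)
  K <- d[1L]
  m <- mat_chw(logits)
  m <- m - rep(apply(m, 2L, max), each = K)
  e <- exp(m)
  p <- e / rep(colSums(e), each = K)
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= K)) stop("labels out of range for K = ", K)
  npix <- ncol(p)
  idx <- seq_len(npix)
  picked <- p[lab + 1L + (idx - 1L) * K]
  loss <- -mean(log(pmax(picked, 1e-12)))
  g <- p
  g[lab + 1L + (idx - 1L) * K] <- g[lab + 1L + (idx - 1L) * K] - 1
  g <- g / npix
  dim(g) <- d
  probs <- p
  dim(probs) <- d
  list(loss = loss, grad = g, probs = probs)
}

#' SGD parameter update with momentum and weight decay
#'
#' Applies one stochastic-gradient step in the PyTorch convention:
#' `g <- g + wd * w; buf <- mu * buf + g; w <- w - lr * buf`, then clears
#' the accumulated gradients.
#' @param params parameter list from [nn_params()].
#' @param lr learning rate.
#' @param momentum,weight_decay SGD hyper-parameters.
#' @export
sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (p in params) {
    if (is.null(p$g)) next
    g <- p$g
    if (p$decay && weight_decay > 0) g <- g + weight_decay * p$v
    if (momentum > 0) {
      if (is.null(p$buf)) p$buf <- g else p$buf <- momentum * p$buf + g
      g <- p$buf
    }
    p$v <- p$v - lr * g
    p$g <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}
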