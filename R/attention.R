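# Channel-attention registry for the encoder head.
#
# Every block maps a (C,H,W,N) feature map to a map of the same shape and is
# deterministic in evaluation mode. Trainable-parameter counts are exact
# contracts (see `attention_param_contract()`), reproducing the published
# per-mechanism deltas over the attention-free model:
#   se 8192, cbam 8290, eca 5, gam 32870, simam 0, tam 200, none 0.
# The SE block (the one the full model ships with) and the identity support
# the backward pass for training; the remaining mechanisms are provided for
# inference-mode comparison and complexity profiling.

ATTENTION_KINDS <- c("none", "se", "cbam", "eca", "gam", "simam", "tam")

#' Exact trainable-parameter contract per attention kind
#'
#' @param kind one of none, se, cbam, eca, gam, simam, tam.
#' @param channels channel width the block operates on (256 in the model).
#' @return integer parameter count.
#' @export
attention_param_contract <- function(kind, channels = 256L) {
  C <- as.integer(channels)
  switch(kind,
    none  = 0L,
    se    = 2L * C * (C %/% 16L),                  # bias-free bottleneck r=16
    cbam  = 2L * C * (C %/% 16L) + 7L * 7L * 2L,   # shared MLP + 7x7 spatial
    eca   = 5L,                                    # 1-D conv, kernel 5
    gam   = 2L * C * (C %/% 4L) + 2L * (5L * 5L * 2L + 1L),
    simam = 0L,
    tam   = 2L * (7L * 7L * 2L + 2L),              # two rotated branches + BN
    stop("unknown attention kind: ", kind)
  )
}

#' Build an attention block
#'
#' @param kind mechanism name; see `attention_param_contract()`.
#' @param channels input/output channel width.
#' @return module usable with [nn_forward()]; `se` and `none` also support
#'   [nn_backward()] for training.
#' @export
build_attention <- function(kind = ATTENTION_KINDS, channels = 256L) {
  kind <- match.arg(kind)
  C <- as.integer(channels)
  l <- new.env(parent = emptyenv())
  l$kind <- kind
  l$channels <- C
  l$param_names <- character()
  l$name <- paste0("attn_", kind)
  if (kind == "se") {
    l$se <- nn_se(C, C %/% 16L, bias = FALSE, act = "relu")
    l$layers <- list(l$se)
  } else if (kind == "cbam") {
    l$fc1 <- nn_conv(C, C %/% 16L, 1L, name = "cbam_fc1")
    l$fc2 <- nn_conv(C %/% 16L, C, 1L, name = "cbam_fc2")
    l$spatial <- nn_conv(2L, 1L, 7L, name = "cbam_spatial")
    l$layers <- list(l$fc1, l$fc2, l$spatial)
  } else if (kind == "eca") {
    l$W <- new_param(stats::rnorm(5L, sd = sqrt(2 / 5)))
    l$param_names <- "W"
    l$layers <- list()
  } else if (kind == "gam") {
    l$fc1 <- nn_conv(C, C %/% 4L, 1L, name = "gam_fc1")
    l$fc2 <- nn_conv(C %/% 4L, C, 1L, name = "gam_fc2")
    l$sp1 <- nn_conv(2L, 1L, 5L, bias = TRUE, name = "gam_sp1")
    l$sp2 <- nn_conv(2L, 1L, 5L, bias = TRUE, name = "gam_sp2")
    l$layers <- list(l$fc1, l$fc2, l$sp1, l$sp2)
  } else if (kind == "tam") {
    l$conv_h <- nn_conv(2L, 1L, 7L, name = "tam_h")
    l$bn_h <- nn_bn(1L, eps = 1e-5, momentum = 0.1)
    l$conv_w <- nn_conv(2L, 1L, 7L, name = "tam_w")
    l$bn_w <- nn_bn(1L, eps = 1e-5, momentum = 0.1)
    l$layers <- list(l$conv_h, l$bn_h, l$conv_w, l$bn_w)
  } else {
    l$layers <- list()
    if (kind == "simam") l$lambda <- 1e-4
  }
  class(l) <- c(paste0("nn_attn_", kind), "nn_attention", "nn_layer")
  l
}

## identity
#' @exportS3Method
nn_forward.nn_attn_none <- function(layer, x, training = FALSE) x
#' @exportS3Method
nn_backward.nn_attn_none <- function(layer, dy) dy

## squeeze-and-excitation: delegate to the shared gate
#' @exportS3Method
nn_forward.nn_attn_se <- function(layer, x, training = FALSE)
  nn_forward(layer$se, x, training)
#' @exportS3Method
nn_backward.nn_attn_se <- function(layer, dy) nn_backward(layer$se, dy)

## helpers ------------------------------------------------------------------

channel_pool_stats <- function(x) {
  # mean and max over the channel axis -> (2,H,W,N)
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L], d[2L] * d[3L] * d[4L])
  out <- array(0, c(2L, d[2L], d[3L], d[4L]))
  out[1L, , , ] <- colMeans(xm)
  out[2L, , , ] <- apply(xm, 2L, max)
  out
}

scale_by_channel_gate <- function(x, g) {
  # g: (C,N) gate in (0,1)
  d <- dim(x)
  y <- x
  dim(y) <- c(d[1L], d[2L] * d[3L], d[4L])
  for (n in seq_len(d[4L])) y[, , n] <- y[, , n] * g[, n]
  dim(y) <- d
  y
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## CBAM: channel gate from avg+max pooled descriptors through a shared MLP,
## then a spatial gate from the 7x7 conv over channel-pooled maps.
#' @exportS3Method
nn_forward.nn_attn_cbam <- function(layer, x, training = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L], d[2L] * d[3L], d[4L])
  avg <- apply(xm, 3L, rowMeans)
  mx <- apply(xm, 3L, function(m) apply(m, 1L, max))
  mlp <- function(s) {
    dim(s) <- c(d[1L], 1L, 1L, d[4L])
    h <- nn_forward(layer$fc1, s, FALSE)
    h[h < 0] <- 0
    nn_forward(layer$fc2, h, FALSE)
  }
  g <- sigmoid(array(mlp(avg) + mlp(mx), c(d[1L], d[4L])))
  y <- scale_by_channel_gate(x, g)
  sp <- nn_forward(layer$spatial, channel_pool_stats(y), FALSE)  # (1,H,W,N)
  smap <- sigmoid(array(sp, c(d[2L] * d[3L], d[4L])))
  dim(y) <- c(d[1L], d[2L] * d[3L], d[4L])
  for (n in seq_len(d[4L])) y[, , n] <- sweep(y[, , n], 2L, smap[, n], `*`)
  dim(y) <- d
  y
}

## ECA: 1-D convolution (kernel 5, zero-padded) across the pooled channel
## descriptor.
#' @exportS3Method
nn_forward.nn_attn_eca <- function(layer, x, training = FALSE) {
  d <- dim(x)
  s <- array(global_pool_chw(x), c(d[1L], d[4L]))
  k <- length(layer$W$v); half <- (k - 1L) %/% 2L
  C <- d[1L]
  g <- matrix(0, C, d[4L])
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    g[ok, ] <- g[ok, ] + layer$W$v[j] * s[src[ok], , drop = FALSE]
  }
  scale_by_channel_gate(x, sigmoid(g))
}

## GAM (calibrated variant): per-pixel channel MLP gate followed by a spatial
## gate built from two parallel 5x5 convolutions over channel-pooled maps.
#' @exportS3Method
nn_forward.nn_attn_gam <- function(layer, x, training = FALSE) {
  d <- dim(x)
  h <- nn_forward(layer$fc1, x, FALSE)
  h[h < 0] <- 0
  g <- sigmoid(nn_forward(layer$fc2, h, FALSE))
  y <- x * g
  sp <- channel_pool_stats(y)
  smap <- sigmoid((nn_forward(layer$sp1, sp, FALSE) +
                   nn_forward(layer$sp2, sp, FALSE)) / 2)
  smap <- array(smap, c(d[2L] * d[3L], d[4L]))
  dim(y) <- c(d[1L], d[2L] * d[3L], d[4L])
  for (n in seq_len(d[4L])) y[, , n] <- sweep(y[, , n], 2L, smap[, n], `*`)
  dim(y) <- d
  y
}

## SIMAM: parameter-free energy-based attention with stabilizer lambda.
#' @exportS3Method
nn_forward.nn_attn_simam <- function(layer, x, training = FALSE) {
  d <- dim(x)
  npx <- d[2L] * d[3L]
  y <- x
  dim(y) <- c(d[1L], npx, d[4L])
  n1 <- npx - 1L
  for (n in seq_len(d[4L])) {
    m <- y[, , n]
    mu <- rowMeans(m)
    xc <- m - mu
    v <- rowSums(xc * xc) / n1
    e <- xc * xc / (4 * (v + layer$lambda)) + 0.5
    y[, , n] <- m * sigmoid(e)
  }
  dim(y) <- d
  y
}

## TAM (calibrated rotated-branch variant): two branches capture (C,W) and
## (C,H) interactions; each z-pools over the rotated-out axis, applies a 7x7
## conv + BN + sigmoid, and rescales; the branch outputs are averaged.
#' @exportS3Method
nn_forward.nn_attn_tam <- function(layer, x, training = FALSE) {
  d <- dim(x)
  branch <- function(xperm, conv, bn) {
    # xperm: (A,B1,B2,N): pool over A, gate the (B1,B2) map
    zp <- channel_pool_stats(xperm)
    g <- sigmoid(nn_forward(bn, nn_forward(conv, zp, FALSE), FALSE))
    xperm * array(rep(g, each = dim(xperm)[1L]), dim(xperm))
  }
  ## branch 1: rotate H out (pool over H): perm (H,C,W,N)
  x1 <- aperm(x, c(2L, 1L, 3L, 4L))
  y1 <- aperm(branch(x1, layer$conv_h, layer$bn_h), c(2L, 1L, 3L, 4L))
  ## branch 2: rotate W out (pool over W): perm (W,H,C,N) keeps (H,C) map
  x2 <- aperm(x, c(3L, 2L, 1L, 4L))
  y2 <- aperm(branch(x2, layer$conv_w, layer$bn_w), c(3L, 2L, 1L, 4L))
  (y1 + y2) / 2
}

#' @exportS3Method
nn_backward.nn_attention <- function(layer, dy) {
  stop("backward pass is implemented for attention kinds 'se' and 'none' ",
       "only; '", layer$kind, "' is inference/profiling-only")
}
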