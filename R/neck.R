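# Multi-scale context modules operating on the 320-channel high-level map.
#
# Two necks are provided. `build_aspp()` is the classic atrous spatial
# pyramid: five parallel branches (1x1, three separable 3x3 atrous convs at
# rates 6/12/18, image-level pooling) concatenated and projected to 256
# channels, followed by a separable 3x3 refinement. `build_cwaspp()` is the
# lightweight cascaded-waterfall variant: a 1x1 input reduction, a chain of
# small-rate atrous convolutions each consuming its predecessor's output, an
# image-pooling branch, and a single 1x1 projection of the concatenated
# stages to 256 channels. The waterfall widths (32 reduced channels, 48 per
# stage, four stages) are pinned by the complexity calibration recorded in
# `cwaspp_defaults()`.

#' Default cascaded-waterfall neck configuration
#'
#' The free structural parameters of the waterfall neck, fixed once by
#' calibrating the assembled model's parameter/MAC totals against the
#' published complexity of the lightweight segmentation network
#' (6,793,767 parameters at 103 classes). Dilation rates do not affect
#' parameter or MAC counts; the progressive small-rate set (2, 4, 6, 8)
#' avoids the gridding artifact of large rates.
#'
#' @return list with reduced_channels, branch_channels, rates,
#'   include_image_pooling, out_channels.
#' @export
cwaspp_defaults <- function() {
  list(reduced_channels = 32L, branch_channels = 48L,
       rates = c(2L, 4L, 6L, 8L), include_image_pooling = TRUE,
       out_channels = 256L)
}

## ---- CWASPP --------------------------------------------------------------

#' Build the cascaded-waterfall atrous pooling neck
#'
#' @param in_channels channels of the high-level feature map (320 for the
#'   EfficientNet-B1 backbone).
#' @param reduced_channels width after the input 1x1 reduction.
#' @param branch_channels width of every cascade stage.
#' @param rates strictly increasing dilation rates, one per cascade stage.
#' @param include_image_pooling add a global-average-pooling branch.
#' @param out_channels width of the fused output (256).
#' @return neck module; apply with [nn_forward()].
#' @export
build_cwaspp <- function(in_channels = 320L,
                         reduced_channels = cwaspp_defaults()$reduced_channels,
                         branch_channels = cwaspp_defaults()$branch_channels,
                         rates = cwaspp_defaults()$rates,
                         include_image_pooling = TRUE,
                         out_channels = 256L) {
  if (any(diff(rates) <= 0) || any(rates <= 0))
    stop("cascade rates must be strictly increasing and positive")
  l <- new.env(parent = emptyenv())
  R <- as.integer(reduced_channels); B <- as.integer(branch_channels)
  l$mode <- "cwaspp"
  l$in_channels <- as.integer(in_channels)
  l$reduced_channels <- R; l$branch_channels <- B
  l$rates <- as.integer(rates)
  l$include_image_pooling <- isTRUE(include_image_pooling)
  l$out_channels <- as.integer(out_channels)
  l$reduce <- nn_seq(nn_conv(in_channels, R, 1L, bias = TRUE), nn_act("relu"),
                     name = "reduce")
  l$stages <- vector("list", length(rates))
  cin <- R
  for (i in seq_along(rates)) {
    l$stages[[i]] <- nn_seq(
      nn_conv(cin, B, 3L, dilation = rates[i], bias = TRUE),
      nn_act("relu"), name = sprintf("cascade%d", i))
    cin <- B
  }
  if (l$include_image_pooling)
    l$pool <- nn_seq(nn_conv(in_channels, B, 1L, bias = TRUE), nn_act("relu"),
                     name = "pool")
  concat_ch <- R + length(rates) * B + if (l$include_image_pooling) B else 0L
  l$concat_channels <- concat_ch
  l$fuse <- nn_seq(nn_conv(concat_ch, out_channels, 1L, bias = TRUE),
                   nn_act("relu"), name = "fuse")
  l$layers <- c(list(l$reduce), l$stages,
                if (l$include_image_pooling) list(l$pool), list(l$fuse))
  l$param_names <- character()
  l$name <- "cwaspp"
  class(l) <- c("nn_cwaspp", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_cwaspp <- function(layer, x, training = FALSE) {
  d <- dim(x)
  red <- nn_forward(layer$reduce, x, training)
  outs <- vector("list", length(layer$stages) + 2L)
  outs[[1L]] <- red
  h <- red
  for (i in seq_along(layer$stages)) {
    h <- nn_forward(layer$stages[[i]], h, training)
    outs[[i + 1L]] <- h
  }
  np <- length(layer$stages) + 1L
  if (layer$include_image_pooling) {
    pooled <- global_pool_chw(x)                        # (Cin,1,1,N)
    pv <- nn_forward(layer$pool, pooled, training)      # (B,1,1,N)
    outs[[np + 1L]] <- broadcast_spatial(pv, d[2L], d[3L])
  } else {
    outs <- outs[seq_len(np)]
  }
  cat_out <- concat_channels(outs)
  if (training) layer$cache <- list(d = d, widths = vapply(outs, function(o) dim(o)[1L], 1L))
  nn_forward(layer$fuse, cat_out, training)
}

#' @exportS3Method
nn_backward.nn_cwaspp <- function(layer, dy) {
  cc <- layer$cache
  layer$cache <- NULL
  dcat <- nn_backward(layer$fuse, dy)
  parts <- split_channels(dcat, cc$widths)
  dx <- array(0, cc$d)
  if (layer$include_image_pooling) {
    dp <- spatial_sum_chw(parts[[length(parts)]])       # (B,1,1,N)
    dpool <- nn_backward(layer$pool, dp)                # (Cin,1,1,N)
    dx <- dx + global_pool_bwd(dpool, cc$d)
    parts <- parts[-length(parts)]
  }
  g <- NULL
  for (i in rev(seq_along(layer$stages))) {
    g <- if (is.null(g)) parts[[i + 1L]] else g + parts[[i + 1L]]
    g <- nn_backward(layer$stages[[i]], g)
  }
  dred <- g + parts[[1L]]
  dx + nn_backward(layer$reduce, dred)
}

## ---- ASPP ----------------------------------------------------------------

#' Build the atrous spatial pyramid pooling neck
#'
#' Classic five-branch pyramid over the high-level map: a 1x1 convolution,
#' three depthwise-separable 3x3 atrous convolutions at the given rates,
#' and an image-pooling branch, concatenated and projected to
#' `out_channels`, followed by a separable 3x3 refinement convolution.
#'
#' @inheritParams build_cwaspp
#' @param rates the three dilation rates (6, 12, 18 by default).
#' @export
build_aspp <- function(in_channels = 320L, rates = c(6L, 12L, 18L),
                       out_channels = 256L) {
  if (any(rates <= 0)) stop("dilation rates must be positive")
  l <- new.env(parent = emptyenv())
  l$mode <- "aspp"
  l$in_channels <- as.integer(in_channels)
  l$rates <- as.integer(rates)
  l$out_channels <- as.integer(out_channels)
  bn <- function(ch) nn_bn(ch, eps = 1e-5, momentum = 0.1)
  l$b0 <- nn_seq(nn_conv(in_channels, out_channels, 1L), bn(out_channels),
                 nn_act("relu"), name = "aspp_1x1")
  l$branches <- lapply(seq_along(rates), function(i) {
    nn_seq(nn_dwconv(in_channels, 3L, dilation = rates[i]),
           nn_conv(in_channels, out_channels, 1L), bn(out_channels),
           nn_act("relu"), name = sprintf("aspp_r%d", rates[i]))
  })
  l$pool <- nn_seq(nn_conv(in_channels, out_channels, 1L), bn(out_channels),
                   nn_act("relu"), name = "aspp_pool")
  nb <- length(rates) + 2L
  l$project <- nn_seq(nn_conv(nb * out_channels, out_channels, 1L),
                      bn(out_channels), nn_act("relu"), name = "aspp_project")
  l$post <- nn_seq(nn_dwconv(out_channels, 3L),
                   nn_conv(out_channels, out_channels, 1L), bn(out_channels),
                   nn_act("relu"), name = "aspp_post")
  l$layers <- c(list(l$b0), l$branches, list(l$pool, l$project, l$post))
  l$param_names <- character()
  l$name <- "aspp"
  class(l) <- c("nn_aspp", "nn_layer")
  l
}

#' @exportS3Method
nn_forward.nn_aspp <- function(layer, x, training = FALSE) {
  d <- dim(x)
  outs <- c(list(nn_forward(layer$b0, x, training)),
            lapply(layer$branches, nn_forward, x = x, training = training))
  pooled <- global_pool_chw(x)
  pv <- nn_forward(layer$pool, pooled, training)
  outs <- c(outs, list(broadcast_spatial(pv, d[2L], d[3L])))
  if (training)
    layer$cache <- list(d = d, widths = vapply(outs, function(o) dim(o)[1L], 1L))
  h <- nn_forward(layer$project, concat_channels(outs), training)
  nn_forward(layer$post, h, training)
}

#' @exportS3Method
nn_backward.nn_aspp <- function(layer, dy) {
  cc <- layer$cache
  layer$cache <- NULL
  dh <- nn_backward(layer$post, dy)
  dcat <- nn_backward(layer$project, dh)
  parts <- split_channels(dcat, cc$widths)
  np <- length(parts)
  dp <- spatial_sum_chw(parts[[np]])
  dx <- global_pool_bwd(nn_backward(layer$pool, dp), cc$d)
  dx <- dx + nn_backward(layer$b0, parts[[1L]])
  for (i in seq_along(layer$branches))
    dx <- dx + nn_backward(layer$branches[[i]], parts[[i + 1L]])
  dx
}

#' Dispatch neck construction from a configuration list
#' @keywords internal
build_neck <- function(mode = c("cwaspp", "aspp"), in_channels = 320L, ...) {
  mode <- match.arg(mode)
  switch(mode,
         cwaspp = build_cwaspp(in_channels = in_channels, ...),
         aspp = build_aspp(in_channels = in_channels, ...))
}

## ---- shared small helpers -----------------------------------------------

global_pool_chw <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L], d[2L] * d[3L], d[4L])
  s <- apply(xm, 3L, rowMeans)
  dim(s) <- c(d[1L], 1L, 1L, d[4L])
  s
}

global_pool_bwd <- function(ds, d) {
  npx <- d[2L] * d[3L]
  g <- array(ds, c(d[1L], d[4L])) / npx
  dx <- array(0, c(d[1L], npx, d[4L]))
  for (n in seq_len(d[4L])) dx[, , n] <- g[, n]
  dim(dx) <- d
  dx
}

broadcast_spatial <- function(v, h, w) {
  d <- dim(v)                      # (C,1,1,N)
  out <- array(0, c(d[1L], h * w, d[4L]))
  vm <- array(v, c(d[1L], d[4L]))
  for (n in seq_len(d[4L])) out[, , n] <- vm[, n]
  dim(out) <- c(d[1L], h, w, d[4L])
  out
}

spatial_sum_chw <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L], d[2L] * d[3L], d[4L])
  s <- apply(xm, 3L, rowSums)
  dim(s) <- c(d[1L], 1L, 1L, d[4L])
  s
}

concat_channels <- function(parts) {
  d <- dim(parts[[1L]])
  widths <- vapply(parts, function(p) dim(p)[1L], 1L)
  out <- array(0, c(sum(widths), d[2L], d[3L], d[4L]))
  at <- 0L
  for (p in parts) {
    w <- dim(p)[1L]
    out[at + seq_len(w), , , ] <- p
    at <- at + w
  }
  out
}

split_channels <- function(x, widths) {
  out <- vector("list", length(widths))
  at <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- x[at + seq_len(widths[i]), , , , drop = FALSE]
    at <- at + widths[i]
  }
  out
}
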