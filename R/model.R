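# Full segmentation network: backbone -> neck -> attention -> DeepLabv3+
# decoder. Graph order:
#   backbone (low @1/4, high @1/16)
#   -> neck (fused to 256 by its output 1x1 projection)
#   -> attention on the 256-channel encoder head
#   -> bilinear upsample x4 -> concat with 1x1-reduced low-level map (48)
#   -> separable 3x3 fusion to 256 -> 1x1 classifier (K, biased)
#   -> bilinear upsample x4 back to input resolution.

#' Model configuration
#'
#' @param num_classes number of classes K including background (K >= 2).
#' @param neck "cwaspp" (lightweight cascaded waterfall, the default) or
#'   "aspp" (classic pyramid).
#' @param attention encoder-head attention kind; see
#'   [attention_param_contract()]. The shipped model uses "se"; "none" gives
#'   the attention-free lightweight baseline.
#' @param include_feature_head keep EfficientNet's 1280-channel top conv as
#'   (unused) parameters; see [build_efficientnet_b1()].
#' @param low_channels_reduced decoder width for the reduced low-level map.
#' @param fuse_channels decoder fusion width.
#' @return list of class `foodseg_config`.
#' @export
model_config <- function(num_classes, neck = c("cwaspp", "aspp"),
                         attention = "se", include_feature_head = TRUE,
                         low_channels_reduced = 48L, fuse_channels = 256L) {
  neck <- match.arg(neck)
  attention <- match.arg(attention, ATTENTION_KINDS)
  if (num_classes < 2L) stop("num_classes must be at least 2")
  structure(list(num_classes = as.integer(num_classes), neck = neck,
                 attention = attention,
                 include_feature_head = isTRUE(include_feature_head),
                 low_channels_reduced = as.integer(low_channels_reduced),
                 fuse_channels = as.integer(fuse_channels)),
            class = "foodseg_config")
}

#' Build the segmentation model
#'
#' @param cfg a [model_config()].
#' @param seed integer seed governing weight initialization; the same seed
#'   reproduces the same initial weights.
#' @return object of class `foodseg_model`.
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "foodseg_config"))
  if (!is.null(seed)) set.seed(seed)
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$backbone <- build_efficientnet_b1(include_feature_head = cfg$include_feature_head)
  m$neck <- build_neck(cfg$neck, in_channels = m$backbone$high_channels)
  m$attention <- build_attention(cfg$attention, channels = m$neck$out_channels)
  bn <- function(ch) nn_bn(ch, eps = 1e-5, momentum = 0.1)
  m$low_reduce <- nn_seq(nn_conv(m$backbone$low_channels,
                                 cfg$low_channels_reduced, 1L),
                         bn(cfg$low_channels_reduced), nn_act("relu"),
                         name = "low_reduce")
  m$up4 <- nn_upsample(4L, name = "decoder_up")
  fuse_in <- m$neck$out_channels + cfg$low_channels_reduced
  m$fuse <- nn_seq(nn_dwconv(fuse_in, 3L),
                   nn_conv(fuse_in, cfg$fuse_channels, 1L),
                   bn(cfg$fuse_channels), nn_act("relu"), name = "fuse")
  m$classifier <- nn_conv(cfg$fuse_channels, cfg$num_classes, 1L,
                          bias = TRUE, name = "classifier")
  m$up_final <- nn_upsample(4L, name = "final_up")
  m$layers <- list(m$backbone, m$neck, m$attention, m$low_reduce, m$fuse,
                   m$classifier)
  m$param_names <- character()
  m$name <- "foodseg"
  class(m) <- c("foodseg_model", "nn_layer")
  m
}

#' Forward pass: logits at input resolution
#'
#' @param model a [build_model()] result.
#' @param x image batch, array dim `c(3, H, W, N)`, values in `[0, 1]`,
#'   H and W divisible by 16.
#' @param training keep caches for [model_backward()] and use batch
#'   statistics in normalization layers.
#' @return logits, array dim `c(K, H, W, N)`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  feats <- backbone_extract(model$backbone, x, training)
  h <- nn_forward(model$neck, feats$high, training)
  h <- nn_forward(model$attention, h, training)
  h <- nn_forward(model$up4, h, training)
  low <- nn_forward(model$low_reduce, feats$low, training)
  cat_in <- concat_channels(list(h, low))
  if (training)
    model$cache <- list(widths = c(dim(h)[1L], dim(low)[1L]))
  f <- nn_forward(model$fuse, cat_in, training)
  logits <- nn_forward(model$classifier, f, training)
  nn_forward(model$up_final, logits, training)
}

#' Backward pass from the gradient of the loss wrt the output logits
#'
#' Accumulates parameter gradients throughout the network (retrieve them
#' via [nn_params()]; apply with [sgd_step()]) and returns the gradient
#' with respect to the input batch.
#'
#' @param model model previously run with `model_forward(..., training = TRUE)`.
#' @param dlogits gradient array shaped like the logits.
#' @return gradient with respect to the input image batch.
#' @export
model_backward <- function(model, dlogits) {
  g <- nn_backward(model$up_final, dlogits)
  g <- nn_backward(model$classifier, g)
  g <- nn_backward(model$fuse, g)
  parts <- split_channels(g, model$cache$widths)
  model$cache <- NULL
  dlow <- nn_backward(model$low_reduce, parts[[2L]])
  dh <- nn_backward(model$up4, parts[[1L]])
  dh <- nn_backward(model$attention, dh)
  dhigh <- nn_backward(model$neck, dh)
  backbone_backward(model$backbone, dlow, dhigh)
}

#' Per-pixel label prediction from logits
#'
#' Argmax over the class axis; ties are broken toward the smaller class id.
#'
#' @param logits array dim `c(K, H, W, N)` (or `c(K, H, W)`), finite values.
#' @return integer array of 0-based class ids, dim `c(H, W, N)` (or `c(H, W)`).
#' @export
predict_labels <- function(logits) {
  d <- dim(logits)
  if (length(d) == 3L) dim(logits) <- d <- c(d, 1L)
  if (anyNA(logits) || any(!is.finite(logits))) stop("logits must be finite")
  ids <- argmax_channels(logits, d[1L], d[2L], d[3L], d[4L])
  out <- array(ids, d[-1L])
  if (dim(out)[3L] == 1L) dim(out) <- d[2:3]
  out
}

#' All trainable parameters of a model or layer
#' @param model model or layer object.
#' @return named list of parameter records.
#' @export
model_parameters <- function(model) nn_params(model)

#' Count trainable parameters by enumerating tensors
#'
#' Sums the element counts of every trainable tensor in the built network
#' (convolution kernels, biases, normalization scales/shifts). This is the
#' enumeration route; [complexity_report()] computes the same total in
#' closed form from the configuration, and the two must agree.
#'
#' @param model a built model (or any layer object).
#' @return integer total.
#' @export
count_parameters <- function(model) {
  sum(vapply(nn_params(model), n_elements, 1L))
}

#' Save / load model checkpoints
#'
#' Checkpoints store the configuration together with every parameter tensor
#' and normalization running statistic, so a reloaded model reproduces
#' evaluation-mode outputs bit-for-bit.
#' @param model built model.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  ps <- nn_params(model)
  state <- lapply(ps, function(p) p$v)
  bns <- collect_bn(model)
  run <- lapply(bns, function(b) list(mean = b$run_mean, var = b$run_var))
  saveRDS(list(cfg = model$cfg, state = state, run = run), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param seed passed to [build_model()] (weights are overwritten anyway).
#' @export
load_checkpoint <- function(path, seed = 0L) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg, seed = seed)
  ps <- nn_params(model)
  stopifnot(length(ps) == length(ck$state))
  for (i in seq_along(ps)) ps[[i]]$v <- ck$state[[i]]
  bns <- collect_bn(model)
  stopifnot(length(bns) == length(ck$run))
  for (i in seq_along(bns)) {
    bns[[i]]$run_mean <- ck$run[[i]]$mean
    bns[[i]]$run_var <- ck$run[[i]]$var
  }
  model
}

## depth-first collection of batch-normalization layers (all composites
## expose their param-bearing children through $layers)
collect_bn <- function(layer) {
  if (inherits(layer, "nn_bn")) return(list(layer))
  out <- list()
  for (sub in layer$layers %||% list()) out <- c(out, collect_bn(sub))
  out
}
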