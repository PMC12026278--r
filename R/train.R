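# Training loop: cross-entropy loss, SGD with momentum 0.9 and weight decay
# 1e-4, and a polynomial learning-rate decay applied after every iteration
# so the rate reaches exactly 0 at the end of training.

#' Polynomial learning-rate decay
#'
#' `base_lr * (1 - iteration / max_iterations)^power`: strictly decreasing
#' in the iteration index, equal to `base_lr` at iteration 0 and exactly 0
#' at `max_iterations`.
#'
#' @param iteration current iteration, `0 <= iteration <= max_iterations`.
#' @param max_iterations total number of iterations (> 0).
#' @param base_lr initial learning rate (> 0).
#' @param power decay exponent, 0.9 by default.
#' @return the learning rate.
#' @export
poly_lr <- function(iteration, max_iterations, base_lr, power = 0.9) {
  if (max_iterations <= 0) stop("max_iterations must be positive")
  if (base_lr <= 0) stop("base_lr must be positive")
  if (any(iteration < 0 | iteration > max_iterations))
    stop("iteration must lie in [0, max_iterations]")
  base_lr * (1 - iteration / max_iterations)^power
}

#' Training configuration
#'
#' Defaults follow the published recipe: 100 epochs, batch size 8, SGD with
#' momentum 0.9 and weight decay 1e-4, cross-entropy loss, per-iteration
#' polynomial decay at power 0.9, inputs resized to `side` and scaled to
#' `[0, 1]`, random horizontal flips with probability 1/2.
#'
#' @param epochs,batch_size,base_lr,momentum,weight_decay,poly_power,seed
#'   scalars as described above.
#' @param side square input side in pixels (divisible by 16).
#' @param flip_prob probability of a horizontal flip per presented sample.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, base_lr = 0.01,
                         momentum = 0.9, weight_decay = 1e-4,
                         poly_power = 0.9, seed = 0L, side = 512L,
                         flip_prob = 0.5) {
  if (base_lr <= 0) stop("base_lr must be positive")
  if (poly_power <= 0) stop("poly_power must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 momentum = momentum, weight_decay = weight_decay,
                 poly_power = poly_power, seed = as.integer(seed),
                 side = as.integer(side), flip_prob = flip_prob),
            class = "train_config")
}

#' Train a segmentation model on a set of samples
#'
#' Runs `epochs * ceiling(n / batch_size)` optimization steps. Each sample
#' is resized to `cfg$side` (bilinear image / nearest-neighbour labels) and
#' scaled to `[0, 1]` once; per presentation it is horizontally flipped with
#' probability `cfg$flip_prob`. The learning rate is decayed polynomially
#' after every iteration. All randomness (shuffling, flips) derives from
#' `cfg$seed`, so a run is reproducible on one device.
#'
#' @param model a [build_model()] result (attention kind "se" or "none").
#' @param samples list of `seg_sample` objects (see [seg_sample()]).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch mean loss.
#' @return list with `model`, `loss` (per-iteration trace), `lr`
#'   (per-iteration rates used).
#' @export
train_model <- function(model, samples, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(samples) == 0L) stop("empty training set")
  set.seed(cfg$seed)
  prep <- lapply(samples, preprocess, side = cfg$side, training = FALSE)
  n <- length(prep)
  iters_per_epoch <- ceiling(n / cfg$batch_size)
  max_iter <- cfg$epochs * iters_per_epoch
  losses <- numeric(max_iter)
  lrs <- numeric(max_iter)
  params <- nn_params(model)
  it <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (bi in seq_len(iters_per_epoch)) {
      take <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      batch <- assemble_batch(prep[take], cfg$flip_prob)
      lr <- poly_lr(it, max_iter, cfg$base_lr, cfg$poly_power)
      logits <- model_forward(model, batch$x, training = TRUE)
      ce <- softmax_xent(logits, batch$y)
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite loss at iteration %d (lr %.3g): aborting",
                     it, lr))
      model_backward(model, ce$grad)
      sgd_step(params, lr, cfg$momentum, cfg$weight_decay)
      it <- it + 1L
      losses[it] <- ce$loss
      lrs[it] <- lr
    }
    if (verbose)
      message(sprintf("epoch %3d/%d  mean loss %.4f  lr %.5f", ep,
                      cfg$epochs, mean(losses[(it - iters_per_epoch + 1L):it]),
                      lrs[it]))
  }
  list(model = model, loss = losses, lr = lrs)
}

## stack preprocessed (x: (3,S,S,1), y: S x S) pairs into one batch,
## flipping image and labels together
assemble_batch <- function(preps, flip_prob) {
  s <- dim(preps[[1L]]$image)[2L]
  nb <- length(preps)
  x <- array(0, c(3L, s, s, nb))
  y <- array(0L, c(s, s, nb))
  for (j in seq_len(nb)) {
    xi <- preps[[j]]$image
    yi <- preps[[j]]$labels
    if (stats::runif(1) < flip_prob) {
      xi <- xi[, , rev(seq_len(s)), , drop = FALSE]   # mirror columns
      yi <- yi[, rev(seq_len(s))]
    }
    x[, , , j] <- xi
    y[, , j] <- yi
  }
  list(x = x, y = y)
}

#' Evaluate a model on a set of samples
#'
#' Resizes each sample to `side`, predicts labels in evaluation mode and
#' scores them against the (resized) ground truth with [mean_iou()].
#'
#' @param model built (possibly trained) model.
#' @param samples list of `seg_sample` objects.
#' @param side input side (divisible by 16).
#' @param convention passed to [mean_iou()].
#' @param batch_size evaluation batch size.
#' @return an `eval_result` (see [mean_iou()]).
#' @export
evaluate_model <- function(model, samples, side = 512L,
                           convention = "skip", batch_size = 4L) {
  preds <- vector("list", length(samples))
  gts <- vector("list", length(samples))
  i <- 1L
  while (i <= length(samples)) {
    take <- i:min(i + batch_size - 1L, length(samples))
    preps <- lapply(samples[take], preprocess, side = side, training = FALSE)
    x <- array(0, c(3L, side, side, length(take)))
    for (j in seq_along(take)) x[, , , j] <- preps[[j]]$image
    logits <- model_forward(model, x, training = FALSE)
    lab <- predict_labels(logits)
    if (length(dim(lab)) == 2L) dim(lab) <- c(dim(lab), 1L)
    for (j in seq_along(take)) {
      preds[[take[j]]] <- lab[, , j]
      gts[[take[j]]] <- preps[[j]]$labels
    }
    i <- i + batch_size
  }
  mean_iou(gts, preds, num_classes = model$cfg$num_classes,
           convention = convention)
}
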