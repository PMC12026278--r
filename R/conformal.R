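# Post hoc conformal-prediction uncertainty for segmentation.
#
# The softmax output is treated as a multi-label mask: with coverage
# parameter lambda and threshold lambda_hat = 1 - lambda, every class whose
# softmax score exceeds lambda_hat is selected at a pixel (value 1, else 0).
# NL counts the selected labels per pixel; the heatmap V divides each
# selected indicator by NL, giving per-class values in [0, 1] that sum to 1
# wherever at least one label is selected. A scalar display map
# u = 1 - 1/NL (and u = 1 where the selected set is empty) summarizes the
# K planes for visualization.

#' Threshold a softmax stack into a multi-label mask
#'
#' @param probs array dim `c(K, H, W)` or `c(K, H, W, N)` of softmax scores
#'   (values in [0, 1], per-pixel sums approximately 1).
#' @param lambda_hat threshold in [0, 1]; a class is selected where its
#'   score is strictly above it. The published default is 0.01.
#' @return object of class `multilabel_mask`: list with `z` (binary array,
#'   same dim as `probs`), `lambda_hat`, `coverage` (= 1 - lambda_hat).
#' @export
threshold_softmax <- function(probs, lambda_hat = 0.01) {
  if (lambda_hat < 0 || lambda_hat > 1) stop("lambda_hat must be in [0, 1]")
  d <- dim(probs)
  if (is.null(d) || length(d) < 3L) stop("probs must be a (K,H,W[,N]) array")
  if (anyNA(probs) || min(probs) < 0 || max(probs) > 1)
    stop("softmax scores must lie in [0, 1]")
  sums <- apply(probs, seq_along(d)[-1L], sum)
  if (max(abs(sums - 1)) > 1e-6)
    stop("per-pixel softmax scores must sum to 1")
  z <- (probs > lambda_hat) * 1L
  structure(list(z = z, lambda_hat = lambda_hat, coverage = 1 - lambda_hat),
            class = "multilabel_mask")
}

#' Count selected labels per pixel
#'
#' @param mask a [threshold_softmax()] result.
#' @return array dim `c(H, W[, N])` of per-pixel label counts in 0..K.
#' @export
count_labels <- function(mask) {
  stopifnot(inherits(mask, "multilabel_mask"))
  d <- dim(mask$z)
  nl <- apply(mask$z, seq_along(d)[-1L], sum)
  storage.mode(nl) <- "integer"
  nl
}

#' VariASCo uncertainty heatmap
#'
#' `V[k, ij] = z[k, ij] / NL[ij]` (0 where `NL[ij] = 0`), so V lies in
#' [0, 1] and sums to 1 over classes wherever at least one label is
#' selected. The scalar summary is `u = 1 - 1/NL` for `NL >= 1` and
#' `u = 1` for the empty set (maximal uncertainty).
#'
#' @param mask a [threshold_softmax()] result.
#' @param counts matching [count_labels()] output (recomputed if missing).
#' @return object of class `uncertainty_heatmap`: list with `V` (same dim
#'   as the mask), `summary` (per-pixel u), `counts`.
#' @export
variasco <- function(mask, counts = NULL) {
  stopifnot(inherits(mask, "multilabel_mask"))
  if (is.null(counts)) counts <- count_labels(mask)
  d <- dim(mask$z)
  if (!identical(dim(counts), d[-1L]) &&
      !(length(d) == 3L && identical(dim(counts), d[2:3])))
    stop("counts shape does not match the mask")
  denom <- pmax(counts, 1L)
  K <- d[1L]
  V <- mask$z / rep(denom, each = K)
  u <- ifelse(counts == 0L, 1, 1 - 1 / denom)
  structure(list(V = V, summary = u, counts = counts),
            class = "uncertainty_heatmap")
}

#' Calibrate the selection threshold on labelled data
#'
#' Scans a documented grid of thresholds (100 log-spaced values in
#' [1e-4, 0.5]) and returns the largest lambda_hat whose empirical pixel
#' coverage -- the fraction of calibration pixels whose true label is
#' selected -- reaches `target_coverage`. Smaller thresholds select
#' supersets, so coverage is monotone non-increasing in lambda_hat and the
#' returned value is the least conservative admissible grid point. With no
#' calibration data (`cal_probs = NULL`) the published default 0.01 is
#' returned.
#'
#' @param cal_probs list of softmax stacks (`c(K, H, W)` arrays), or NULL.
#' @param cal_labels list of matching H x W integer label maps.
#' @param target_coverage required coverage in (0, 1).
#' @param grid threshold grid (decreasing values are tried from the top).
#' @return lambda_hat.
#' @export
calibrate_lambda <- function(cal_probs = NULL, cal_labels = NULL,
                             target_coverage = 0.99,
                             grid = exp(seq(log(1e-4), log(0.5),
                                            length.out = 100L))) {
  if (is.null(cal_probs)) return(0.01)
  if (length(cal_probs) == 0L) stop("empty calibration set")
  if (target_coverage <= 0 || target_coverage >= 1)
    stop("target_coverage must be in (0, 1)")
  stopifnot(length(cal_probs) == length(cal_labels))
  ## per-pixel true-label scores, pooled over the calibration set
  scores <- unlist(lapply(seq_along(cal_probs), function(i) {
    p <- cal_probs[[i]]
    d <- dim(p)
    lab <- as.integer(cal_labels[[i]])
    npix <- prod(d[-1L])
    p[lab + 1L + (seq_len(npix) - 1L) * d[1L]]
  }))
  grid <- sort(grid, decreasing = TRUE)
  for (lh in grid) {
    if (mean(scores > lh) >= target_coverage) return(lh)
  }
  min(grid)
}

#' Conformal analysis of a batch of images with a model
#'
#' Runs the model in evaluation mode, applies the threshold, and returns
#' the multi-label mask, label counts, heatmap and point prediction.
#'
#' @param model built model.
#' @param x image batch `c(3, S, S, N)`.
#' @param lambda_hat selection threshold.
#' @return list with `probs`, `mask`, `counts`, `heatmap`, `labels`.
#' @export
conformal_predict <- function(model, x, lambda_hat = 0.01) {
  logits <- model_forward(model, x, training = FALSE)
  d <- dim(logits)
  m <- mat_chw(logits)
  m <- m - rep(apply(m, 2L, max), each = d[1L])
  e <- exp(m)
  p <- e / rep(colSums(e), each = d[1L])
  dim(p) <- d
  mask <- threshold_softmax(p, lambda_hat)
  counts <- count_labels(mask)
  list(probs = p, mask = mask, counts = counts,
       heatmap = variasco(mask, counts), labels = predict_labels(logits))
}
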