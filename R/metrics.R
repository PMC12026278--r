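# Per-image mean intersection over union.
#
# The headline score is the double mean
#   mIoU = (1/N) sum_i (1/K_i) sum_k |y_ik  ^ yhat_ik| / |y_ik v yhat_ik|,
# i.e. IoU per class within each image, averaged over the classes of that
# image, then over images. Background (class 0) participates in the class
# average. A class whose union is empty in an image (absent from both the
# ground truth and the prediction) contributes 0/0; three conventions are
# offered for it: "skip" (exclude from that image's average, the default),
# "one" (count as a perfect 1), and "global" (no per-image averaging at
# all: one dataset-level confusion matrix, IoU per class, mean over
# classes).

#' Mean intersection over union
#'
#' @param gt,pred ground-truth and predicted label maps: integer matrices
#'   (H x W, 0-based class ids), 3-D arrays (H x W x N), or lists of
#'   matrices. Shapes must match pairwise.
#' @param num_classes number of classes K; all labels must be `< K`.
#' @param convention treatment of classes with an empty union in an image:
#'   `"skip"`, `"one"`, or `"global"` (see file header).
#' @return object of class `eval_result`: list with `miou`, `per_image`
#'   (N x K matrix of per-class IoU, NA where skipped), `n_images`,
#'   `num_classes`, `convention`.
#' @export
mean_iou <- function(gt, pred, num_classes,
                     convention = c("skip", "one", "global")) {
  convention <- match.arg(convention)
  gt <- as_label_list(gt)
  pred <- as_label_list(pred)
  if (length(gt) == 0L) stop("at least one image is required")
  if (length(gt) != length(pred)) stop("gt and pred differ in length")
  K <- as.integer(num_classes)
  per_image <- matrix(NA_real_, length(gt), K)
  global_inter <- numeric(K)
  global_union <- numeric(K)
  for (i in seq_along(gt)) {
    a <- gt[[i]]; b <- pred[[i]]
    if (!identical(dim(a), dim(b))) stop("image ", i, ": shape mismatch")
    if (max(a, b) >= K || min(a, b) < 0L)
      stop("image ", i, ": labels outside 0..K-1")
    cm <- confusion_counts(a, b, K)
    inter <- diag(cm)
    union <- rowSums(cm) + colSums(cm) - inter
    global_inter <- global_inter + inter
    global_union <- global_union + union
    iou <- ifelse(union > 0, inter / union, NA_real_)
    per_image[i, ] <- iou
  }
  miou <- switch(convention,
    skip = mean(apply(per_image, 1L, function(r) mean(r, na.rm = TRUE))),
    one = mean(apply(per_image, 1L, function(r) {
      r[is.na(r)] <- 1
      mean(r)
    })),
    global = {
      g <- ifelse(global_union > 0, global_inter / global_union, NA_real_)
      mean(g, na.rm = TRUE)
    })
  structure(list(miou = miou, per_image = per_image,
                 n_images = length(gt), num_classes = K,
                 convention = convention),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("mIoU = %.4f over %d images, K = %d (%s convention)\n",
              x$miou, x$n_images, x$num_classes, x$convention))
  invisible(x)
}

as_label_list <- function(x) {
  if (is.list(x)) return(lapply(x, function(m) {
    storage.mode(m) <- "integer"
    m
  }))
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    return(list(x))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    storage.mode(x) <- "integer"
    return(lapply(seq_len(dim(x)[3L]), function(i) x[, , i]))
  }
  stop("expected a matrix, a 3-D array, or a list of matrices")
}

confusion_counts <- function(a, b, K) {
  idx <- as.integer(a) + K * as.integer(b)   # gt + K * pred
  cnt <- tabulate(idx + 1L, nbins = K * K)
  matrix(cnt, K, K)                          # rows gt, cols pred
}
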