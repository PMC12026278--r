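# Parameter / multiply-accumulate profiler.
#
# Parameter totals are exact closed-form sums over the architecture
# definition and are cross-checked in the tests against enumeration of the
# built tensors. MAC totals are convention-dependent; published counts for
# segmentation models differ across profiling tools, so the convention is a
# first-class, recorded part of every report:
#
#   conv            Cin/groups * k^2 * out_elements (biases free)
#   affine norm     4 * input_elements
#   bilinear up     11 * output_elements (module form; functional broadcast 0)
#   adaptive pool   (pooled_area + 1) * output_elements
#   activations     0
#
# Two conventions ship. "full" counts every operation above in every
# submodule. "published" additionally excludes the backbone's convolution
# and pooling operations (backbone normalizations stay counted): the
# published totals for this family of models are reproducible only under
# that convention, which is the footprint a hook-based profiler leaves when
# the backbone implementation wraps its convolutions in custom classes the
# profiler does not recognize. See the methods vignette for the calibration.

#' @rdname complexity_report
#' @export
mac_conventions <- function() c("published", "full")

BN_MACS_PER_ELEM <- 4L
UPSAMPLE_MACS_PER_ELEM <- 11L

#' Complexity report: parameters and MACs with a per-layer breakdown
#'
#' Computes trainable-parameter and multiply-accumulate counts for a model
#' configuration in closed form, at a stated square input size.
#'
#' @param cfg a [model_config()] (a built model's `$cfg` works too).
#' @param side input side in pixels, divisible by 16. Default 512.
#' @param convention "published" (default) or "full"; see Details above.
#' @return object of class `complexity_report`: list with `parameters`,
#'   `macs`, `per_layer` (data.frame name/params/macs), `side`,
#'   `convention`, `num_classes`.
#' @export
complexity_report <- function(cfg, side = 512L, convention = mac_conventions()) {
  stopifnot(inherits(cfg, "foodseg_config"))
  convention <- match.arg(convention)
  side <- as.integer(side)
  if (side %% 16L != 0L || side <= 0L) stop("side must be a positive multiple of 16")
  rows <- rbind(
    backbone_complexity(side, cfg$include_feature_head,
                        count_convs = convention == "full"),
    neck_complexity(cfg$neck, side),
    attention_complexity(cfg$attention, side),
    decoder_complexity(cfg, side)
  )
  structure(list(parameters = sum(rows$params), macs = sum(rows$macs),
                 per_layer = rows, side = side, convention = convention,
                 num_classes = cfg$num_classes),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("Complexity at %dx%d (%s convention, K = %d)\n",
              x$side, x$side, x$convention, x$num_classes))
  cat(sprintf("  parameters: %s\n  MACs: %.2fM\n",
              format(x$parameters, big.mark = ","), x$macs / 1e6))
  invisible(x)
}

#' Count MACs of a built model
#'
#' @param model a [build_model()] result.
#' @inheritParams complexity_report
#' @return numeric MAC count.
#' @export
count_macs <- function(model, side = 512L, convention = mac_conventions()) {
  complexity_report(model$cfg, side = side, convention = convention)$macs
}

row_ <- function(name, params, macs) {
  data.frame(name = name, params = as.numeric(params), macs = as.numeric(macs),
             stringsAsFactors = FALSE)
}

backbone_complexity <- function(side, include_feature_head, count_convs) {
  cfg <- efficientnet_b1_config()
  res <- side %/% 2L
  rows <- row_("stem",
               params = 3 * 32 * 9 + 2 * 32,
               macs = (if (count_convs) 3 * 32 * 9 * res^2 else 0) +
                 BN_MACS_PER_ELEM * 32 * res^2)
  for (s in seq_len(nrow(cfg))) {
    p <- 0; m <- 0
    for (b in seq_len(cfg$repeats[s])) {
      ci <- if (b == 1L) cfg$cin[s] else cfg$cout[s]
      co <- cfg$cout[s]
      st <- if (b == 1L) cfg$stride[s] else 1L
      if (s == 6L && b == 1L) st <- 1L          # dilated in place of stride 32
      E <- ci * cfg$expand[s]; S <- max(1L, ci %/% 4L); k <- cfg$kernel[s]
      rin <- res; rout <- res %/% st
      if (cfg$expand[s] != 1L) {
        p <- p + ci * E + 2 * E
        m <- m + (if (count_convs) ci * E * rin^2 else 0) +
          BN_MACS_PER_ELEM * E * rin^2
      }
      p <- p + k^2 * E + 2 * E                                   # depthwise
      m <- m + (if (count_convs) k^2 * E * rout^2 else 0) +
        BN_MACS_PER_ELEM * E * rout^2
      p <- p + E * S + S + S * E + E                             # SE gate
      m <- m + (if (count_convs) E * S + S * E + (rout^2 + 1) * E else 0)
      p <- p + E * co + 2 * co                                   # project
      m <- m + (if (count_convs) E * co * rout^2 else 0) +
        BN_MACS_PER_ELEM * co * rout^2
      res <- rout
    }
    rows <- rbind(rows, row_(sprintf("backbone_stage%d", s), p, m))
  }
  if (include_feature_head)
    rows <- rbind(rows, row_("backbone_feature_head",
                             params = 320 * 1280 + 2 * 1280, macs = 0))
  rows
}

neck_complexity <- function(mode, side) {
  A <- (side %/% 16L)^2                  # high-level map pixels
  if (mode == "cwaspp") {
    dft <- cwaspp_defaults()
    R <- dft$reduced_channels; B <- dft$branch_channels
    n <- length(dft$rates)
    W <- R + n * B + if (dft$include_image_pooling) B else 0L
    rows <- row_("cwaspp_reduce", 320 * R + R, 320 * R * A)
    rows <- rbind(rows, row_("cwaspp_cascade",
                             (9 * R * B + B) + (n - 1) * (9 * B * B + B),
                             (9 * R * B + (n - 1) * 9 * B * B) * A))
    if (dft$include_image_pooling)
      rows <- rbind(rows, row_("cwaspp_pool", 320 * B + B,
                               (A + 1) * 320 + 320 * B))
    rbind(rows, row_("cwaspp_fuse", W * 256 + 256, W * 256 * A))
  } else {
    bn1 <- BN_MACS_PER_ELEM * 256 * A
    rows <- row_("aspp_1x1", 320 * 256 + 512, 320 * 256 * A + bn1)
    rows <- rbind(rows, row_("aspp_atrous",
                             3 * (9 * 320 + 320 * 256 + 512),
                             3 * ((9 * 320 + 320 * 256) * A + bn1)))
    rows <- rbind(rows, row_("aspp_pool", 320 * 256 + 512,
                             (A + 1) * 320 + 320 * 256 + BN_MACS_PER_ELEM * 256))
    rows <- rbind(rows, row_("aspp_project", 1280 * 256 + 512,
                             1280 * 256 * A + bn1))
    rbind(rows, row_("aspp_post", 9 * 256 + 256 * 256 + 512,
                     (9 * 256 + 256 * 256) * A + bn1))
  }
}

attention_complexity <- function(kind, side) {
  A <- (side %/% 16L)^2
  r16 <- side %/% 16L
  C <- 256L
  macs <- switch(kind,
    none  = 0,
    se    = 2 * C * (C %/% 16) + (A + 1) * C,
    cbam  = 2 * (2 * C * (C %/% 16)) + (A + 1) * C + 98 * A,
    eca   = 5 * C + (A + 1) * C,
    gam   = 2 * C * (C %/% 4) * A + 2 * 50 * A,
    simam = 0,
    tam   = 2 * 98 * C * r16 + 2 * BN_MACS_PER_ELEM * C * r16)
  row_(paste0("attention_", kind), attention_param_contract(kind, C), macs)
}

decoder_complexity <- function(cfg, side) {
  A4 <- (side %/% 4L)^2
  K <- cfg$num_classes
  lo <- cfg$low_channels_reduced; fu <- cfg$fuse_channels
  fin <- 256L + lo
  rbind(
    row_("decoder_upsample", 0, UPSAMPLE_MACS_PER_ELEM * 256 * A4),
    row_("decoder_low_reduce", 24 * lo + 2 * lo,
         24 * lo * A4 + BN_MACS_PER_ELEM * lo * A4),
    row_("decoder_fuse", 9 * fin + fin * fu + 2 * fu,
         (9 * fin + fin * fu) * A4 + BN_MACS_PER_ELEM * fu * A4),
    row_("classifier", fu * K + K, fu * K * A4),
    row_("final_upsample", 0, UPSAMPLE_MACS_PER_ELEM * K * side^2)
  )
}

#' Pareto frontier under (parameters down, MACs down, mIoU up)
#'
#' Returns the subset of points not dominated by any other point: a point is
#' dominated if some other point is no worse on all three objectives and
#' strictly better on at least one. Input order is preserved.
#'
#' @param points data.frame with columns `label`, `params`, `macs`, `miou`.
#' @return the non-dominated rows, in input order.
#' @export
pareto_front <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) >= 1L,
            all(c("params", "macs", "miou") %in% names(points)))
  if (any(!is.finite(points$params) | !is.finite(points$macs) |
          !is.finite(points$miou))) stop("all objective values must be finite")
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      no_worse <- points$params[j] <= points$params[i] &&
        points$macs[j] <= points$macs[i] && points$miou[j] >= points$miou[i]
      better <- points$params[j] < points$params[i] ||
        points$macs[j] < points$macs[i] || points$miou[j] > points$miou[i]
      if (no_worse && better) { keep[i] <- FALSE; break }
    }
  }
  points[keep, , drop = FALSE]
}
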