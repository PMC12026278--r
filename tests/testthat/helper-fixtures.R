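# Shared fixtures: tiny synthetic scenes, random label maps, and independent
# brute-force oracles kept deliberately separate from the package internals.

.cache <- new.env()

cached_model <- function(K = 3L, attention = "se", neck = "cwaspp") {
  key <- paste(K, attention, neck, sep = "_")
  if (is.null(.cache[[key]]))
    .cache[[key]] <- build_model(model_config(K, neck = neck,
                                              attention = attention),
                                 seed = 42)
  .cache[[key]]
}

tiny_samples <- function(n = 4L, K = 3L, side = 96L, seed = 0L) {
  spec <- scene_spec(num_classes = K, seed = seed, canvas_side = side)
  lapply(seq_len(n) - 1L, function(i) generate_scene(spec, i))
}

rand_labels <- function(h, w, K) {
  matrix(sample.int(K, h * w, replace = TRUE) - 1L, h, w)
}

## brute-force per-image mIoU: explicit set arithmetic, one class at a time
brute_miou <- function(gt, pred, K, convention = "skip") {
  scores <- vapply(seq_along(gt), function(i) {
    per_class <- numeric(0)
    for (k in 0:(K - 1L)) {
      a <- gt[[i]] == k
      b <- pred[[i]] == k
      uni <- sum(a | b)
      if (uni == 0) {
        if (convention == "one") per_class <- c(per_class, 1)
      } else {
        per_class <- c(per_class, sum(a & b) / uni)
      }
    }
    mean(per_class)
  }, 1)
  mean(scores)
}

## brute-force Pareto dominance: keep points no other point dominates
brute_pareto <- function(df) {
  n <- nrow(df)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      if (i == j) return(FALSE)
      (df$params[j] <= df$params[i] && df$macs[j] <= df$macs[i] &&
         df$miou[j] >= df$miou[i]) &&
        (df$params[j] < df$params[i] || df$macs[j] < df$macs[i] ||
           df$miou[j] > df$miou[i])
    }, TRUE))
  }, TRUE)
  df[!dominated, , drop = FALSE]
}

softmax_stack <- function(K, h, w) {
  raw <- array(stats::rexp(K * h * w), c(K, h, w))
  sums <- apply(raw, c(2, 3), sum)
  raw / rep(sums, each = K)
}
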