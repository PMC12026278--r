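test_that("closed-form parameter totals match tensor enumeration", {
  for (spec in list(list(3, "cwaspp", "se"), list(3, "cwaspp", "none"),
                    list(5, "aspp", "none"))) {
    cfg <- model_config(spec[[1]], neck = spec[[2]], attention = spec[[3]])
    m <- cached_model(spec[[1]], spec[[3]], spec[[2]])
    expect_equal(complexity_report(cfg)$parameters, count_parameters(m),
                 label = paste(unlist(spec), collapse = "/"))
  }
})

test_that("single-layer MAC closed forms are exact", {
  # bias-free 1x1 conv 256 -> 103: parameter count 26368
  cv <- foodseg:::nn_conv(256L, 103L, 1L)
  expect_equal(length(cv$W$v), 26368)
  # 1x1 conv 256->103 on a 128x128 map: 103*256*128^2 MACs, read from the
  # per-layer breakdown of the published convention
  rep <- complexity_report(model_config(103), side = 512)
  cls <- rep$per_layer[rep$per_layer$name == "classifier", ]
  expect_equal(cls$macs, 103 * 256 * 128^2)
})

test_that("MACs scale with spatial area for the convolutional body", {
  cfg <- model_config(103)
  m512 <- complexity_report(cfg, side = 512)$macs
  m256 <- complexity_report(cfg, side = 256)$macs
  # image-pooling terms are area-independent; everything else scales by 4
  expect_lt(abs(m512 / m256 - 4), 1e-3)
  # the residual constant is exactly the non-spatial pooled-branch work:
  # neck pool tail (320 + 320*48) plus the SE gate's convs and pool tail
  const <- (4 * m256 - m512) / 3
  expect_equal(const, 320 + 320 * 48 + 8192 + 256)
})

test_that("MACs are affine in the class count with the printed-gap slope", {
  cfg <- function(K) model_config(K, attention = "none")
  mk <- vapply(c(11, 74, 103), function(K)
    complexity_report(cfg(K))$macs, 1)
  slope1 <- (mk[3] - mk[1]) / (103 - 11)
  slope2 <- (mk[3] - mk[2]) / (103 - 74)
  expect_equal(slope1, slope2)
  # slope * 92 equals the printed 2.54G - 1.89G gap at printed rounding
  expect_equal(round(slope1 * 92 / 1e7), round((2.54e9 - 1.89e9) / 1e7))
})

test_that("pareto_front matches brute-force dominance enumeration", {
  # one point is its own frontier
  one <- data.frame(label = "a", params = 1, macs = 1, miou = 0.5)
  expect_equal(pareto_front(one), one)
  # total dominance
  two <- data.frame(label = c("a", "b"), params = c(1, 2), macs = c(1, 2),
                    miou = c(0.9, 0.5))
  expect_equal(pareto_front(two)$label, "a")
  # random clouds against the oracle
  set.seed(42)
  for (i in 1:20) {
    pts <- data.frame(label = letters[1:12],
                      params = sample(1:6, 12, TRUE),
                      macs = sample(1:6, 12, TRUE),
                      miou = round(stats::runif(12), 2))
    expect_identical(pareto_front(pts), brute_pareto(pts))
  }
  expect_error(pareto_front(data.frame(label = "a", params = NA_real_,
                                       macs = 1, miou = 1)), "finite")
})

test_that("the attention-variant cloud yields the published-style frontier", {
  base_p <- complexity_report(model_config(103, attention = "none"))$parameters
  base_m <- complexity_report(model_config(103, attention = "none"))$macs
  kinds <- c("none", "cbam", "eca", "gam", "se", "simam", "tam")
  # measured segmentation scores of the variants on one benchmark
  miou <- c(0.6439, 0.6914, 0.6808, 0.6985, 0.6926, 0.6851, 0.6917)
  pts <- data.frame(
    label = kinds,
    params = vapply(kinds, function(k)
      complexity_report(model_config(103, attention = k))$parameters, 1),
    macs = vapply(kinds, function(k)
      complexity_report(model_config(103, attention = k))$macs, 1),
    miou = miou)
  front <- pareto_front(pts)
  expect_identical(front, brute_pareto(pts))
  # the frontier is the SIMAM / TAM / SE / GAM quartet: SIMAM costs exactly
  # as much as the identity but scores higher, so the identity drops out,
  # and CBAM is dominated by SE on all three axes
  expect_setequal(front$label, c("gam", "se", "simam", "tam"))
})

test_that("reports carry their convention and breakdown consistently", {
  rep <- complexity_report(model_config(11), side = 256,
                           convention = "full")
  expect_equal(sum(rep$per_layer$params), rep$parameters)
  expect_equal(sum(rep$per_layer$macs), rep$macs)
  pub <- complexity_report(model_config(11), side = 256)
  expect_gt(rep$macs, pub$macs)   # full counts the backbone convolutions
  expect_equal(rep$parameters, pub$parameters)
  expect_error(complexity_report(model_config(11), side = 100), "multiple")
})
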