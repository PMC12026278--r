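test_that("logits match input resolution for valid sizes", {
  m <- cached_model(3, "se")
  for (side in c(64L, 128L)) {
    x <- array(stats::runif(3 * side * side), c(3, side, side, 1))
    lg <- model_forward(m, x)
    expect_equal(dim(lg), c(3, side, side, 1))
  }
  expect_error(model_forward(m, array(0, c(3, 72, 72, 1))), "divisible")
})

test_that("identical images in one batch give identical logits", {
  m <- cached_model(3, "se")
  set.seed(5)
  x1 <- array(stats::runif(3 * 64 * 64), c(3, 64, 64, 1))
  xb <- array(0, c(3, 64, 64, 2))
  xb[, , , 1] <- x1; xb[, , , 2] <- x1
  lg <- model_forward(m, xb)
  expect_equal(lg[, , , 1], lg[, , , 2], tolerance = 1e-12)
})

test_that("predict_labels is an exact argmax with smallest-id tie break", {
  # one-hot logits
  lg <- array(0, c(4, 3, 3, 1)); lg[2, , , ] <- 5
  expect_true(all(predict_labels(lg) == 1L))
  # all-equal logits -> class 0 everywhere
  expect_true(all(predict_labels(array(1, c(4, 3, 3, 1))) == 0L))
  # random logits against an elementwise brute force
  set.seed(0)
  lg <- array(stats::rnorm(5 * 6 * 7 * 2), c(5, 6, 7, 2))
  got <- predict_labels(lg)
  for (n in 1:2) for (i in 1:6) for (j in 1:7) {
    v <- lg[, i, j, n]
    expect_equal(got[i, j, n], which(v == max(v))[1] - 1L)
  }
  lg[1] <- NaN
  expect_error(predict_labels(lg), "finite")
})

test_that("parameter additivity holds for every attention kind", {
  base <- complexity_report(model_config(103, attention = "none"))$parameters
  for (kind in c("se", "cbam", "eca", "gam", "simam", "tam")) {
    total <- complexity_report(model_config(103, attention = kind))$parameters
    expect_equal(total - base, attention_param_contract(kind, 256L),
                 label = kind)
  }
})

test_that("parameter count is affine in K with slope 257", {
  p11 <- complexity_report(model_config(11))$parameters
  p74 <- complexity_report(model_config(74))$parameters
  p103 <- complexity_report(model_config(103))$parameters
  expect_equal((p103 - p11) / (103 - 11), 257)
  expect_equal((p103 - p74) / (103 - 74), 257)
  # classifier closed form: difference = 92 * (256 + 1)
  expect_equal(p103 - p11, 92 * 257)
})

test_that("checkpoints restore evaluation outputs bit-for-bit", {
  m <- cached_model(3, "se")
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  x <- array(stats::runif(3 * 64 * 64), c(3, 64, 64, 1))
  expect_identical(model_forward(m, x), model_forward(m2, x))
})
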