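test_that("thresholding selects exactly the labels above lambda_hat", {
  # one-hot probabilities: exactly one label per pixel at small lambda_hat
  p <- array(0, c(3, 4, 4)); p[1, , ] <- 1
  mk <- threshold_softmax(p, 0.01)
  expect_true(all(count_labels(mk) == 1L))
  # uniform over K = 3: all three labels selected everywhere
  u <- array(1 / 3, c(3, 5, 5))
  expect_true(all(count_labels(threshold_softmax(u, 0.01)) == 3L))
  # lambda_hat = 1 gives the empty mask
  expect_true(all(threshold_softmax(u, 1)$z == 0))
  expect_error(threshold_softmax(u, 1.2), "\\[0, 1\\]")
  expect_error(threshold_softmax(u * 2, 0.1), "sum to 1")
})

test_that("label counts match a brute-force per-pixel loop", {
  set.seed(0)
  p <- softmax_stack(4, 6, 5)
  mk <- threshold_softmax(p, 0.2)
  nl <- count_labels(mk)
  for (i in 1:6) for (j in 1:5)
    expect_equal(nl[i, j], sum(mk$z[, i, j]))
})

test_that("the heatmap normalizes selected labels per pixel", {
  # one-hot: V equals the mask and the summary is certain (0)
  p <- array(0, c(3, 4, 4)); p[2, , ] <- 1
  mk <- threshold_softmax(p, 0.01)
  hm <- variasco(mk)
  expect_equal(hm$V, mk$z * 1)
  expect_true(all(hm$summary == 0))
  # a pixel with three labels gets V = 1/3 and u = 2/3
  u <- array(1 / 3, c(3, 2, 2))
  hm3 <- variasco(threshold_softmax(u, 0.01))
  expect_true(all(abs(hm3$V - 1 / 3) < 1e-12))
  expect_true(all(abs(hm3$summary - 2 / 3) < 1e-12))
  # empty selection: V = 0, maximal uncertainty
  hm0 <- variasco(threshold_softmax(u, 1))
  expect_true(all(hm0$V == 0))
  expect_true(all(hm0$summary == 1))
})

test_that("conformal invariants hold on random softmax stacks", {
  set.seed(1)
  for (rep in 1:10) {
    p <- softmax_stack(5, 8, 8)
    lh <- stats::runif(1, 0.01, 0.4)
    mk <- threshold_softmax(p, lh)
    nl <- count_labels(mk)
    hm <- variasco(mk, nl)
    # V in [0,1] and sums to 1 where NL > 0
    expect_true(all(hm$V >= 0 & hm$V <= 1))
    vsum <- apply(hm$V, c(2, 3), sum)
    expect_true(all(abs(vsum[nl > 0] - 1) < 1e-12))
    expect_true(all(vsum[nl == 0] == 0))
    # monotonicity: lowering the threshold only adds labels
    mk2 <- threshold_softmax(p, lh / 2)
    expect_true(all(mk2$z >= mk$z))
    expect_true(all(count_labels(mk2) >= nl))
    # the conformal set contains the argmax class when lambda_hat is below
    # the per-pixel maximum
    pmax_map <- apply(p, c(2, 3), max)
    lh3 <- min(pmax_map) * 0.99
    mk3 <- threshold_softmax(p, lh3)
    am <- apply(p, c(2, 3), which.max)
    for (i in 1:8) for (j in 1:8)
      expect_equal(mk3$z[am[i, j], i, j], 1)
  }
})

test_that("lambda calibration covers at the requested level", {
  # default path without calibration data
  expect_equal(calibrate_lambda(NULL), 0.01)
  expect_error(calibrate_lambda(list(), list()), "empty")
  # perfectly confident correct model: the largest admissible grid value
  p <- array(0.001, c(3, 6, 6)); p[1, , ] <- 0.998
  lab <- matrix(0L, 6, 6)
  lh <- calibrate_lambda(list(p), list(lab), target_coverage = 0.95)
  grid <- exp(seq(log(1e-4), log(0.5), length.out = 100))
  expect_equal(lh, max(grid[grid < 0.998]))
  # miscalibrated probabilities: held-out coverage still reached
  set.seed(0)
  make_pair <- function() {
    lab <- rand_labels(8, 8, 4)
    p <- array(stats::runif(4 * 8 * 8, 0.05, 1), c(4, 8, 8))
    for (i in 1:8) for (j in 1:8)
      p[lab[i, j] + 1, i, j] <- stats::runif(1, 0.2, 0.6)  # true label mid-mass
    sums <- apply(p, c(2, 3), sum)
    list(p = p / rep(sums, each = 4), lab = lab)
  }
  cal <- replicate(6, make_pair(), simplify = FALSE)
  lh <- calibrate_lambda(lapply(cal, `[[`, "p"), lapply(cal, `[[`, "lab"),
                         target_coverage = 0.9)
  held <- replicate(6, make_pair(), simplify = FALSE)
  cov <- mean(unlist(lapply(held, function(h) {
    sel <- threshold_softmax(h$p, lh)$z
    vapply(seq_len(64), function(q) {
      i <- (q - 1) %% 8 + 1; j <- (q - 1) %/% 8 + 1
      sel[h$lab[i, j] + 1, i, j] == 1
    }, TRUE)
  })))
  expect_gte(cov, 0.9 - 0.05)   # stochastic margin on the held-out split
})
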