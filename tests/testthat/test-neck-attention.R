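test_that("both necks honour the 32x32x256 shape contract", {
  x <- array(stats::rnorm(320 * 8 * 8 * 2), c(320, 8, 8, 2))
  set.seed(1)
  cw <- build_cwaspp()
  as <- build_aspp()
  expect_equal(dim(nn_forward(cw, x)), c(256, 8, 8, 2))
  expect_equal(dim(nn_forward(as, x)), c(256, 8, 8, 2))
})

test_that("the waterfall cascade is sequential with the calibrated layout", {
  cw <- build_cwaspp()
  dft <- cwaspp_defaults()
  expect_length(cw$stages, length(dft$rates))
  # stage i consumes the previous stage's width
  expect_equal(cw$stages[[1]]$layers[[1]]$cin, dft$reduced_channels)
  for (i in seq_along(cw$stages)) {
    conv <- cw$stages[[i]]$layers[[1]]
    expect_equal(conv$dilation, dft$rates[i])
    expect_equal(conv$cout, dft$branch_channels)
    if (i > 1) expect_equal(conv$cin, dft$branch_channels)
  }
  expect_equal(cw$concat_channels,
               dft$reduced_channels +
                 (length(dft$rates) + 1L) * dft$branch_channels)
  expect_error(build_cwaspp(rates = c(4, 2)), "strictly increasing")
  expect_error(build_aspp(rates = c(-1, 2, 3)), "positive")
})

test_that("atrous branches have the documented effective receptive field", {
  # a 3x3 kernel at dilation r spans 2*r + 1 pixels; padding keeps shape
  for (r in c(6L, 12L, 18L)) {
    dw <- foodseg:::nn_dwconv(4L, 3L, dilation = r)
    expect_equal(dw$pad, r)
    x <- array(stats::rnorm(4 * 40 * 40), c(4, 40, 40, 1))
    expect_equal(dim(nn_forward(dw, x)), dim(x))
  }
})

test_that("attention parameter contracts reproduce the published deltas", {
  contracts <- c(none = 0, se = 8192, cbam = 8290, eca = 5, gam = 32870,
                 simam = 0, tam = 200)
  for (kind in names(contracts)) {
    blk <- build_attention(kind, channels = 256L)
    built <- sum(vapply(nn_params(blk), function(p) length(p$v), 1))
    expect_equal(built, unname(contracts[kind]), label = kind)
    expect_equal(attention_param_contract(kind, 256L),
                 unname(contracts[kind]), label = kind)
  }
  expect_error(build_attention("glam"), "arg")
})

test_that("attention blocks preserve shape and are deterministic in eval", {
  set.seed(3)
  x <- array(stats::rnorm(32 * 6 * 6 * 2), c(32, 6, 6, 2))
  for (kind in c("none", "se", "cbam", "eca", "gam", "simam", "tam")) {
    blk <- build_attention(kind, channels = 32L)
    y1 <- nn_forward(blk, x)
    y2 <- nn_forward(blk, x)
    expect_equal(dim(y1), dim(x), label = kind)
    expect_identical(y1, y2, label = kind)
    expect_true(all(is.finite(y1)), label = kind)
  }
})

test_that("SE gating is a channel-uniform rescale with weights in (0,1)", {
  set.seed(4)
  blk <- build_attention("se", channels = 16L)
  x <- array(abs(stats::rnorm(16 * 5 * 5)) + 0.1, c(16, 5, 5, 1))
  y <- nn_forward(blk, x)
  ratio <- y / x
  # per channel, the ratio is a single scalar in (0,1)
  for (c in 1:16) {
    rc <- ratio[c, , , 1]
    expect_lt(max(rc) - min(rc), 1e-12)
    expect_gt(rc[1], 0)
    expect_lt(rc[1], 1)
  }
  # constant-positive input stays constant per channel
  xc <- array(rep(seq_len(16), 25), c(16, 5, 5, 1))
  yc <- nn_forward(blk, xc)
  expect_lt(max(abs(yc[, 1, 1, 1] - yc[, 3, 4, 1])), 1e-12)
})

test_that("the waterfall neck is strictly cheaper than the pyramid", {
  lw <- complexity_report(model_config(103, neck = "cwaspp",
                                       attention = "none"))
  dl <- complexity_report(model_config(103, neck = "aspp",
                                       attention = "none"))
  expect_lt(lw$parameters, dl$parameters)
  expect_lt(lw$macs, dl$macs)
})
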