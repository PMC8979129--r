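# Residual-network construction, FLOP accounting, freezing protocol.

test_that("the head emits 13 logits and the builder rejects other depths", {
  net <- buildResnet(resnetSpec(18), seed = 1)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  r <- resnetForward(net, x)
  expect_equal(dim(r$logits), c(13, 2))
  p <- resnetPredict(net, x)
  expect_equal(colSums(p), c(1, 1), tolerance = 1e-12)
  expect_error(resnetSpec(50), "depth")
})

test_that("weighted-layer counts equal the nominal depths", {
  # convs (stem + block convs, projections excluded by convention) + fc
  plan18 <- thzQuant:::.resnetPlan(resnetSpec(18))
  expect_equal(sum(plan18$role != "proj") + 1, 18)
  plan152 <- thzQuant:::.resnetPlan(resnetSpec(152))
  expect_equal(sum(plan152$role != "proj") + 1, 152)
  # stage plans: 2-2-2-2 basic, 3-8-36-3 bottleneck
  expect_equal(resnetSpec(18)$blocks, c(2, 2, 2, 2))
  expect_equal(resnetSpec(152)$blocks, c(3, 8, 36, 3))
})

test_that("stage output sides on a 224 input match the architecture table", {
  net <- buildResnet(resnetSpec(18), seed = 1)
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  sides <- c()
  for (ch in net$children) {
    r <- thzQuant:::.fwd(ch, x, FALSE)
    x <- r$out
    if (!is.null(dim(x)) && length(dim(x)) == 4) sides <- c(sides, dim(x)[1])
  }
  # after conv1: 112; after the stride-2 max pool and conv2_x: 56; then
  # 28, 14, 7 at the ends of conv3_x, conv4_x, conv5_x
  expect_equal(sides[1], 112)
  expect_true(all(c(56, 28, 14, 7) %in% sides))
  expect_equal(min(sides), 7)
})

test_that("zeroing every residual branch leaves the shortcut path", {
  set.seed(16)
  blk <- thzQuant:::nnResBlock("basic", 4, 4, 4, 1, "s")
  # zero the second conv and its batch norm: F(x) = 0
  blk$children$conv2$params$W[] <- 0
  blk$children$bn2$params$gamma[] <- 0
  blk$children$bn2$params$beta[] <- 0
  x <- array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))
  out <- thzQuant:::.fwd(blk, x, FALSE)$out
  expect_equal(out, x * (x > 0), tolerance = 1e-12)
})

test_that("analytic FLOP counts match the printed model complexities", {
  g18 <- countFlops(resnetSpec(18)) / 1e9
  g152 <- countFlops(resnetSpec(152)) / 1e9
  expect_lt(abs(g18 - 1.8) / 1.8, 0.03)
  expect_lt(abs(g152 - 11.3) / 11.3, 0.03)
  # counts scale with the head size exactly
  expect_equal(countFlops(resnetSpec(18, headClasses = 1000)) -
                 countFlops(resnetSpec(18)), 512 * 987)
})

test_that("freezing marks exactly the first n macro-layers non-trainable", {
  spec <- resnetSpec(18)
  counts <- vapply(0:5, function(nf) {
    net <- buildResnet(spec, seed = 1)
    fr <- applyFreeze(net, freezePlan(nf))
    paramCounts(fr$net)["trainable"]
  }, 0)
  expect_true(all(diff(counts) < 0))            # strictly fewer trainable
  net <- buildResnet(spec, seed = 1)
  total <- paramCounts(net)["total"]
  f5 <- applyFreeze(net, freezePlan(5))
  pc <- paramCounts(f5$net)
  expect_equal(unname(pc["trainable"] + pc["frozen"]), unname(total))
  # with everything frozen only the head trains
  headParams <- 512 * 13 + 13
  expect_equal(unname(pc["trainable"]), headParams)
  f0 <- applyFreeze(buildResnet(spec, seed = 1), freezePlan(0))
  expect_equal(unname(paramCounts(f0$net)["frozen"]), 0)
  expect_error(freezePlan(6), "0..5")
  expect_error(freezePlan(-1), "0..5")
})

test_that("frozen parameters are bit-identical after a training step", {
  set.seed(17)
  spec <- resnetSpec(18)
  x <- array(rnorm(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  y <- sample(1:13, 8, replace = TRUE)
  net <- buildResnet(spec, seed = 2)
  fr <- applyFreeze(net, freezePlan(5))
  net <- fr$net
  before <- thzQuant:::.collectParams(net, frozenOnly = TRUE)
  opt <- thzQuant:::makeOptimizer("adam", lr = 1e-2)
  r <- thzQuant:::.fwd(net, x, TRUE)
  ce <- thzQuant:::softmaxCrossEntropy(r$out, y)
  b <- thzQuant:::.bwd(r$mod, r$cache, ce$dlogits)
  net2 <- thzQuant:::optStep(opt, r$mod, b$grads)
  after <- thzQuant:::.collectParams(net2, frozenOnly = TRUE)
  expect_identical(before, after)
  # the (always trainable) head did move
  expect_false(identical(net$children[[length(net$children)]]$params$W,
                         net2$children[[length(net2$children)]]$params$W))
})
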