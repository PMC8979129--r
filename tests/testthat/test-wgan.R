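# Wasserstein GAN: losses, weight clipping, per-class training mechanics.

test_that("critic and generator losses follow the Wasserstein forms", {
  expect_equal(criticLoss(c(1, 3), c(0, 2)), -1)
  expect_equal(criticLoss(c(5, 5), c(5, 5)), 0)   # constant critic
  expect_equal(generatorLoss(c(2, 4)), -3)
  expect_equal(generatorLoss(c(0, 0, 0)), 0)
  set.seed(21)
  s <- rnorm(17)
  expect_equal(generatorLoss(s) + mean(s), 0)
  expect_error(criticLoss(numeric(0), 1), "empty")
  expect_error(generatorLoss(numeric(0)), "empty")
})

test_that("weight clipping clamps, is idempotent and preserves interior", {
  critic <- thzQuant:::nnSequential(list(thzQuant:::nnLinear(3, 1)))
  critic$children[[1]]$params$W <- matrix(c(-0.2, 0.005, 0.2), 1, 3)
  critic$children[[1]]$params$b <- 0.009
  c1 <- clipWeights(critic, 0.01)
  expect_equal(as.numeric(c1$children[[1]]$params$W), c(-0.01, 0.005, 0.01))
  expect_equal(c1$children[[1]]$params$b, 0.009)
  expect_identical(clipWeights(c1, 0.01), c1)     # idempotent
  expect_error(clipWeights(critic, 0), "cClip")
})

test_that("wgan training is seed-deterministic and respects the clip bound", {
  set.seed(22)
  px <- array(runif(32 * 32 * 10), c(32, 32, 10))
  cfg <- wganConfig(iterations = 6, batchSize = 4, side = 32,
                    baseChannels = 8, latentDim = 16, seed = 9L)
  f1 <- trainWgan(px, cfg)
  f2 <- trainWgan(px, cfg)
  expect_identical(f1$log, f2$log)
  expect_true(all(is.finite(f1$log$criticLoss)))
  ps <- thzQuant:::.collectParams(f1$critic)
  expect_true(all(vapply(ps, function(p) all(abs(p) <= cfg$cClip + 1e-15),
                         TRUE)))
})

test_that("mixed-class image sets and tiny classes are rejected", {
  imgs <- list(outerImage(runif(8, 1, 2), label = 0L),
               outerImage(runif(8, 1, 2), label = 1L))
  expect_error(trainWgan(imgs, wganConfig(iterations = 1)), "mixed")
  px <- array(runif(32 * 32 * 4), c(32, 32, 4))
  expect_error(trainWgan(px, wganConfig(iterations = 1, side = 32)),
               "at least 8")
})

test_that("generated samples carry the class label and provenance", {
  set.seed(23)
  imgs <- lapply(1:8, function(i)
    outerImage(runif(16, 1, 3), label = 4L, concentration = 0.08,
               specimenId = sprintf("c04_s%03d", i)))
  cfg <- wganConfig(iterations = 4, batchSize = 4, side = 32,
                    baseChannels = 8, latentDim = 16, seed = 2L)
  fit <- trainWgan(imgs, cfg)
  expect_length(generateSamples(fit, 0), 0)
  g <- generateSamples(fit, 5, seed = 5L)
  expect_length(g, 5)
  expect_true(all(vapply(g, imageLabel, 0L) == 4L))
  expect_true(all(vapply(g, imageSource, "") == "generated"))
  expect_true(all(vapply(g, function(im) im@concentration, 0) == 0.08))
  expect_true(all(vapply(g, function(im) all(pixels(im) >= 0 & pixels(im) <= 1),
                         TRUE)))
  expect_equal(dim(pixels(g[[1]])), c(32, 32))
  # seed-reproducible draws
  g2 <- generateSamples(fit, 5, seed = 5L)
  expect_identical(pixels(g[[3]]), pixels(g2[[3]]))
})

test_that("training on one repeated image moves samples toward it", {
  set.seed(24)
  target <- outerImage(sort(runif(32, 0.5, 3)), label = 0L)
  imgs <- rep(list(target), 10)
  cfg <- wganConfig(iterations = 120, batchSize = 8, side = 32,
                    baseChannels = 8, latentDim = 16, seed = 7L)
  fit <- trainWgan(imgs, cfg)
  g <- generateSamples(fit, 4, seed = 11L)
  tpx <- pixels(target)
  sGen <- mean(vapply(g, function(im) ssim(pixels(im), tpx), 0))
  set.seed(25)
  sNoise <- mean(replicate(4, ssim(matrix(runif(1024), 32, 32), tpx)))
  expect_gt(sGen, sNoise)
})
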