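# Classifier training harness: accuracy bookkeeping, leakage guards,
# deterministic traces.

test_that("accuracy equals confusion-matrix trace over total", {
  truth <- c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 1L, 2L, 3L)
  predPerfect <- truth
  cm <- thzQuant:::.confusion(truth, predPerfect, 3)
  expect_equal(sum(diag(cm)) / length(truth), 1.0)
  pred9 <- truth; pred9[10] <- 1L
  cm9 <- thzQuant:::.confusion(truth, pred9, 3)
  expect_equal(sum(diag(cm9)) / length(truth), 0.9)
  # row sums equal per-class counts
  expect_equal(rowSums(cm9), as.numeric(table(factor(truth, levels = 1:3))))
})

makeToySets <- function(nPerClass = 6, seed = 31L, K = 3L, side = 32) {
  # tiny synthetic image task: K classes of outer images from shifted vectors
  set.seed(seed)
  imgs <- list()
  for (cl in 0:(K - 1)) {
    for (i in seq_len(nPerClass)) {
      base <- seq(1, 3, length.out = 16) + cl * c(rep(0, 8), rep(0.8, 8))
      x <- base + rnorm(16, 0, 0.03)
      imgs <- c(imgs, list(outerImage(x, label = cl,
                                      concentration = cl / K,
                                      specimenId = sprintf("c%d_s%03d", cl, i))))
    }
  }
  labs <- vapply(imgs, imageLabel, 0L)
  specs <- vapply(imgs, function(im) im@specimenId, "")
  sp <- splitSpecimens(specs, labs, 2 / 3, seed = seed)
  list(train = imageSet(imgs[sp$train], side = side),
       test = imageSet(imgs[!sp$train], side = side))
}

test_that("specimen leakage and generated test images are rejected", {
  ts <- makeToySets()
  leaky <- ts$test
  leaky$specimen[1] <- ts$train$specimen[1]
  spec <- resnetSpec(18, headClasses = 3)
  expect_error(trainClassifier(ts$train, leaky, spec, freezePlan(0),
                               trainConfig(epochs = 1)), "leakage")
  genTest <- ts$test
  genTest$source[2] <- "generated"
  expect_error(trainClassifier(ts$train, genTest, spec, freezePlan(0),
                               trainConfig(epochs = 1)), "measured")
  missing <- ts$train
  keep <- missing$y != 1L
  missing$x <- missing$x[, , , keep, drop = FALSE]
  missing$y <- missing$y[keep]; missing$specimen <- missing$specimen[keep]
  missing$source <- missing$source[keep]
  expect_error(trainClassifier(missing, ts$test, spec, freezePlan(0),
                               trainConfig(epochs = 1)), "missing")
})

test_that("training learns an easy task and reports coherent bookkeeping", {
  ts <- makeToySets()
  spec <- resnetSpec(18, headClasses = 3)
  cfg <- trainConfig(lr = 3e-4, batchSize = 8, epochs = 6, seed = 5L)
  rep1 <- trainClassifier(ts$train, ts$test, spec, freezePlan(0), cfg)
  expect_s3_class(rep1, "TrainReport")
  expect_lt(tail(rep1$epochLoss, 1), head(rep1$epochLoss, 1))
  expect_equal(dim(rep1$confusion), c(3, 3))
  expect_equal(sum(rep1$confusion), rep1$nTest)
  expect_equal(rep1$accuracy, sum(diag(rep1$confusion)) / rep1$nTest)
  expect_equal(rowSums(rep1$confusion),
               as.numeric(table(factor(ts$test$y, levels = 1:3))))
  expect_gt(rep1$accuracy, 0.5)
  # deterministic loss trace under the same seed
  rep2 <- trainClassifier(ts$train, ts$test, spec, freezePlan(0), cfg)
  expect_identical(rep1$epochLoss, rep2$epochLoss)
  expect_identical(rep1$accuracy, rep2$accuracy)
})

test_that("the frozen-layer sweep returns six controlled runs", {
  ts <- makeToySets(nPerClass = 4)
  spec <- resnetSpec(18, headClasses = 3)
  cfg <- trainConfig(lr = 3e-4, batchSize = 8, epochs = 1, seed = 6L)
  sweep <- frozenLayerSweep(ts$train, ts$test, spec, cfg)
  expect_length(sweep, 6)
  expect_equal(names(sweep), as.character(0:5))
  hashes <- vapply(sweep, `[[`, "", "testHash")
  expect_length(unique(hashes), 1)
  tr <- vapply(sweep, function(r) {
    with(r$census, sum(count[trainable]))
  }, 0)
  expect_true(all(diff(tr) < 0))
})
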