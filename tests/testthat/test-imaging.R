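# Outer-product images, model-input preparation, SSIM.

test_that("outer image of a unit vector matches the hand result", {
  img <- outerImage(c(1, 0))
  # raw outer product [[1,0],[0,0]]; min-max normalization keeps it
  expect_equal(pixels(img), matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(img@normMeta, c(0, 1))
})

test_that("outer images match a double-loop oracle and are rank one", {
  set.seed(4)
  for (i in 1:25) {
    x <- runif(sample(4:12, 1), 0.1, 5)
    P <- naiveOuter(x)
    rng <- range(P)
    img <- outerImage(x)
    expect_equal(pixels(img), (P - rng[1]) / (rng[2] - rng[1]))
    expect_identical(pixels(img), t(pixels(img)))
    # every 2x2 minor of the raw outer product vanishes (rank 1)
    n <- length(x)
    for (k in 1:5) {
      ij <- sample(n, 2); kl <- sample(n, 2)
      minor <- P[ij[1], kl[1]] * P[ij[2], kl[2]] -
        P[ij[1], kl[2]] * P[ij[2], kl[1]]
      expect_lt(abs(minor), 1e-9)
    }
  }
})

test_that("normalized outer images are invariant to positive rescaling", {
  set.seed(5)
  for (i in 1:10) {
    x <- runif(8, 0.5, 3)
    lambda <- runif(1, 0.01, 100)
    expect_equal(pixels(outerImage(x)), pixels(outerImage(lambda * x)),
                 tolerance = 1e-12)
  }
})

test_that("non-finite input and short vectors are rejected", {
  expect_error(outerImage(c(1, NA, 2)), "finite")
  expect_error(outerImage(3), "length")
})

test_that("model input resize is identity at native size and respects nodes", {
  m <- matrix(runif(32 * 32), 32, 32)
  out <- toModelInput(m, side = 32)
  expect_equal(dim(out), c(32, 32, 3))
  for (ch in 1:3) expect_equal(out[, , ch], (m - 0.5) / 0.5, tolerance = 1e-12)
  # constant image stays constant in every channel
  cst <- toModelInput(matrix(0.25, 8, 8), side = 32)
  expect_true(all(abs(cst - (0.25 - 0.5) / 0.5) < 1e-12))
  # integer upscaling preserves values at aligned grid nodes (corner-aligned)
  chk <- matrix(as.numeric((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2), 4, 4)
  up <- thzQuant:::.bilinearResize(chk, 10)     # factor 3 between nodes
  expect_equal(up[seq(1, 10, by = 3), seq(1, 10, by = 3)], chk)
  expect_error(toModelInput(m, side = 16), ">= 32")
})

test_that("ssim is 1 on identical images and symmetric", {
  set.seed(6)
  a <- matrix(runif(24 * 24), 24, 24)
  b <- matrix(runif(24 * 24), 24, 24)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-14)
  expect_error(ssim(a, b[1:20, 1:20]), "shape")
})

test_that("ssim agrees with the naive sliding-window oracle", {
  set.seed(7)
  for (i in 1:5) {
    a <- matrix(runif(16 * 16), 16, 16)
    b <- matrix(runif(16 * 16), 16, 16)
    expect_equal(ssim(a, b), naiveSsim(a, b), tolerance = 1e-6)
  }
})

test_that("ssim of an image against its inversion is low", {
  half <- rbind(matrix(0, 8, 16), matrix(1, 8, 16))
  expect_lt(ssim(half, 1 - half), 0.2)
})

test_that("within-class spectral images are more similar than 0% vs 100%", {
  fx <- deskImages(specimensPerClass = 4)
  labs <- vapply(fx$images, imageLabel, 0L)
  c0 <- fx$images[labs == 0]
  c12 <- fx$images[labs == 12]
  within <- mean(c(ssim(c0[[1]], c0[[2]]), ssim(c0[[2]], c0[[3]]),
                   ssim(c12[[1]], c12[[2]]), ssim(c12[[2]], c12[[3]])))
  between <- mean(c(ssim(c0[[1]], c12[[1]]), ssim(c0[[2]], c12[[2]]),
                    ssim(c0[[3]], c12[[3]])))
  expect_gt(within, between)
})

test_that("PNG export and manifest round-trip within 8-bit quantization", {
  set.seed(8)
  imgs <- list(outerImage(runif(16, 1, 3), label = 2L, concentration = 0.04,
                          specimenId = "c02_s001"),
               outerImage(runif(16, 1, 3), label = 5L, concentration = 0.10,
                          specimenId = "c05_s001"))
  dir <- tempfile("imgstore")
  manifest <- writeSpectralImages(imgs, dir)
  expect_equal(nrow(manifest), 2)
  back <- readSpectralImages(dir)
  expect_equal(length(back), 2)
  expect_identical(imageLabel(back[[1]]), 2L)
  expect_identical(imageSource(back[[2]]), "measured")
  expect_lt(max(abs(pixels(back[[1]]) - pixels(imgs[[1]]))), 1 / 255)
  expect_equal(back[[1]]@normMeta, imgs[[1]]@normMeta)
})
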