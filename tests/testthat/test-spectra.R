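# Inversion: FFT, amplitude/phase ratio, optical-constant extraction.

test_that("FFT places a pure cosine at the nearest frequency bin", {
  dt <- 0.05
  t <- (0:511) * dt
  w <- new("Waveform", time = t, field = cos(2 * pi * 1.0 * t),
           kind = "reference", specimenId = "x", replicateIndex = 1L,
           meta = list())
  sp <- toFrequency(w)
  fpk <- freqTHz(sp)[which.max(sp@amplitude)]
  expect_lt(abs(fpk - 1.0), 1 / (512 * dt))
})

test_that("a delayed pulse produces a linear phase difference of slope tau", {
  cfg <- simConfig(noiseSd = 0)
  g <- thzQuant:::.timeGrid(cfg)
  pulse <- thzQuant:::.referencePulse(g$t)
  tau <- 25 * g$dt                     # delay = integer bins, exact shift
  delayed <- c(rep(0, 25), pulse[1:(length(pulse) - 25)])
  mk <- function(f) new("Waveform", time = g$t, field = f, kind = "sample",
                        specimenId = "x", replicateIndex = 1L, meta = list())
  r <- phaseAmplitudeRatio(toFrequency(mk(delayed)), toFrequency(mk(pulse)))
  sel <- r$valid & r$freq > 0.2 & r$freq < 2
  # phi = phase_ref - phase_sample = +omega tau for a delayed sample
  slope <- coef(lm(r$phi[sel] ~ I(2 * pi * r$freq[sel])))[2]
  expect_equal(unname(slope), tau, tolerance = 1e-6)
})

test_that("zero signal transforms to zero amplitude", {
  t <- (0:63) * 0.1
  w <- new("Waveform", time = t, field = numeric(64), kind = "reference",
           specimenId = "x", replicateIndex = 1L, meta = list())
  expect_true(all(toFrequency(w)@amplitude == 0))
})

test_that("non-uniform time grids are rejected at construction", {
  t <- (0:39) * 0.1
  t[25] <- t[25] + 0.03
  expect_error(new("Waveform", time = t, field = numeric(40),
                   kind = "reference", specimenId = "x",
                   replicateIndex = 1L, meta = list()), "uniform")
})

test_that("sample identical to reference gives unit ratio and zero phase", {
  cfg <- simConfig(noiseSd = 0)
  pair <- forwardTransmit(vacuumMix(), cfg, 0)
  # literally the same spectrum on both ports
  s <- toFrequency(pair$reference)
  r0 <- phaseAmplitudeRatio(s, s)
  expect_true(all(abs(r0$A[r0$valid] - 1) < 1e-15))
  expect_true(all(abs(r0$phi[r0$valid]) < 1e-12))
  # vacuum-transmitted sample against its reference, on the analysis band
  r <- phaseAmplitudeRatio(toFrequency(pair$sample), s)
  sel <- r$valid & r$freq >= 0.4 & r$freq <= 1.4
  expect_true(all(abs(r$A[sel] - 1) < 1e-12))
  expect_true(all(abs(r$phi[sel]) < 1e-9))
})

test_that("slab phase difference matches the closed form at 1 THz", {
  cfg <- simConfig(noiseSd = 0)
  pair <- forwardTransmit(constantSlabMix(0, 1.5), cfg, 1)
  r <- phaseAmplitudeRatio(toFrequency(pair$sample),
                           toFrequency(pair$reference))
  i1 <- which.min(abs(r$freq - 1))
  phiExp <- 0.5 * 2 * pi * r$freq[i1] * 1e12 * 1e-3 / 299792458  # ~10.48 rad
  expect_equal(r$phi[i1], phiExp, tolerance = 1e-9)
})

test_that("low-amplitude reference bins are flagged, not divided through", {
  f <- seq(0.1, 2, by = 0.1)
  amp <- rep(1, length(f)); amp[5] <- 0
  mkcs <- function(a) new("ComplexSpectrum", freq = f, amplitude = a,
                          phase = numeric(length(f)))
  r <- phaseAmplitudeRatio(mkcs(rep(1, length(f))), mkcs(amp))
  expect_false(r$valid[5])
  expect_true(all(r$valid[-5]))
  expect_true(is.na(r$A[5]))
  expect_false(any(is.nan(r$A)))
})

test_that("extraction inverts the vacuum and the constant slab", {
  f <- seq(0.4, 1.4, length.out = 30)
  oc <- extractConstants(rep(1, 30), numeric(30), f, 1)
  expect_true(all(abs(refractiveIndex(oc) - 1) < 1e-12))
  expect_true(all(abs(alphaCm(oc)) < 1e-12))
  # A = exp(-0.5) at every bin, d = 1 mm -> alpha = 10 /cm
  oc2 <- extractConstants(rep(exp(-0.5), 30), numeric(30), f, 1)
  expect_true(all(abs(alphaCm(oc2) - 10) < 1e-9))
  expect_error(extractConstants(rep(1, 30), numeric(30), f, 0), "thicknessD")
})

test_that("Fresnel-corrected extraction subtracts the interface loss", {
  f <- seq(0.4, 1.4, length.out = 10)
  n <- 1.5
  phi <- (n - 1) * 2 * pi * f * 1e12 * 1e-3 / 299792458
  # amplitude carrying both absorption and the Fresnel factor 4n/(n+1)^2
  A <- exp(-0.5) * 4 * n / (n + 1)^2
  oc <- extractConstants(rep(A, 10), phi, f, 1, fresnel = TRUE)
  expect_true(all(abs(alphaCm(oc) - 10) < 1e-9))
  expect_true(all(abs(refractiveIndex(oc) - 1.5) < 1e-12))
})

test_that("simulator and extractor are exact inverses at zero noise", {
  mix <- carbendazimPreset()
  cfg <- simConfig(noiseSd = 0)
  for (conc in c(0, 0.3, 1)) {
    pair <- forwardTransmit(mix, cfg, conc)
    oc <- cropBand(invertPair(pair$sample, pair$reference), 0.4, 1.4)
    f <- freqTHz(oc)
    interior <- f >= 0.45 & f <= 1.35
    nerr <- abs(refractiveIndex(oc) - mixtureIndex(mix, conc, f)) /
      mixtureIndex(mix, conc, f)
    aerr <- abs(alphaCm(oc) - mixtureAlpha(mix, conc, f)) /
      pmax(mixtureAlpha(mix, conc, f), 1e-6)
    expect_lt(max(nerr[interior]), 0.01)
    expect_lt(max(aerr[interior]), 0.02)
  }
})

test_that("replicate averaging is a pointwise mean and validates grids", {
  f <- seq(0.4, 1.4, length.out = 16)
  mk <- function(a) new("OpticalConstants", freq = f, n = rep(1.5, 16),
                        alpha = rep(a, 16), thicknessD = 1)
  avg <- averageReplicates(list(mk(9), mk(10), mk(11)))
  expect_true(all(alphaCm(avg) == 10))
  expect_identical(averageReplicates(list(mk(7))), mk(7))
  same <- averageReplicates(list(mk(5), mk(5), mk(5)))
  expect_equal(same, mk(5))
  bad <- new("OpticalConstants", freq = f + 0.01, n = rep(1.5, 16),
             alpha = rep(1, 16), thicknessD = 1)
  expect_error(averageReplicates(list(mk(1), bad)), "grids")
})

test_that("band cropping keeps in-band bins in order and rejects empty bands", {
  f <- seq(0.1, 2.0, by = 0.05)
  oc <- new("OpticalConstants", freq = f, n = rep(1.5, length(f)),
            alpha = seq_along(f) * 1.0, thicknessD = 1)
  cr <- cropBand(oc, 0.4, 1.4)
  expect_true(all(freqTHz(cr) >= 0.4 & freqTHz(cr) <= 1.4))
  expect_true(!is.unsorted(freqTHz(cr), strictly = TRUE))
  expect_equal(cropBand(oc, 0, 3), oc)
  expect_error(cropBand(oc, 2.5, 3.0), "overlap")
})

test_that("alpha is monotone in the amplitude ratio, n linear in phase", {
  # single-bin extractions at a fixed frequency of 1 THz
  alphaAt <- function(A) alphaCm(extractConstants(A, 1, 1, 1))
  a <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), alphaAt, 0)
  expect_true(all(diff(a) > 0))               # smaller A -> larger alpha
  nAt <- function(phi) refractiveIndex(extractConstants(0.5, phi, 1, 1))
  n <- vapply(1:5, nAt, 0)
  dn <- diff(n)
  expect_true(all(abs(dn - dn[1]) < 1e-12))   # linear in phi at fixed omega, d
})

test_that("extracted peak absorption grows monotonically with concentration", {
  mix <- carbendazimPreset()
  cfg <- simConfig(noiseSd = 1e-3, seed = 21L)
  alphaPk <- vapply(c(0, 0.1, 0.3, 0.5, 1), function(conc) {
    pair <- forwardTransmit(mix, cfg, conc, seed = 77L)
    oc <- cropBand(invertPair(pair$sample, pair$reference), 0.4, 1.4)
    alphaCm(oc)[which.min(abs(freqTHz(oc) - 1.15))]
  }, 0)
  expect_true(all(diff(alphaPk) > 0))
})

test_that("replicate averaging shrinks the alpha variance like 1/m", {
  mix <- constantSlabMix(10, 1.5)
  cfg <- simConfig(noiseSd = 2e-3, nPoints = 16)
  m <- 3
  pick <- function(oc) alphaCm(oc)[8]
  set.seed(98)
  single <- replicate(200, {
    p <- forwardTransmit(mix, cfg, 1, seed = sample.int(1e6, 1))
    pick(cropBand(invertPair(p$sample, p$reference), 0.4, 1.4))
  })
  set.seed(99)
  averaged <- replicate(200, {
    ocs <- lapply(1:m, function(i) {
      p <- forwardTransmit(mix, cfg, 1, seed = sample.int(1e6, 1))
      cropBand(invertPair(p$sample, p$reference), 0.4, 1.4)
    })
    pick(averageReplicates(ocs))
  })
  ratio <- var(averaged) / var(single)
  expect_lt(abs(ratio - 1 / m), 0.3 / m)
})

test_that("optical constants CSV round-trips", {
  f <- seq(0.4, 1.4, length.out = 8)
  oc <- new("OpticalConstants", freq = f, n = 1.5 + f / 10, alpha = f * 3,
            thicknessD = 1.25)
  path <- tempfile(fileext = ".csv")
  writeOpticalConstants(oc, path)
  oc2 <- readOpticalConstants(path)
  expect_equal(freqTHz(oc2), f)
  expect_equal(alphaCm(oc2), oc@alpha)
  expect_equal(oc2@thicknessD, 1.25)
})
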