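# Waveform simulator: presets, forward transfer model, dataset design.

test_that("carbendazim preset has the two analyte peaks inside the band", {
  mix <- carbendazimPreset()
  expect_equal(sort(mix@analyte@peaks[, "center"]), c(1.15, 1.32))
  expect_equal(mix@band, c(0.4, 1.4))
  expect_true(all(mix@analyte@peaks[, "width"] > 0))
  # matrix model is a smooth background: no peaks
  expect_equal(nrow(mix@matrixModel@peaks), 0)
})

test_that("mixture rule: identity at c = 0, monotone peak height in c", {
  mix <- carbendazimPreset()
  f <- seq(0.4, 1.4, length.out = 201)
  expect_equal(mixtureAlpha(mix, 0, f), evalAbsorption(mix@matrixModel, f))
  a_half <- mixtureAlpha(mix, 0.5, 1.15)
  a_full <- mixtureAlpha(mix, 1.0, 1.15)
  expect_gt(a_full, a_half)
  # alpha stays non-negative over the whole simulated bandwidth
  expect_true(all(mixtureAlpha(mix, 0.3, seq(0, 8, by = 0.05)) >= 0))
})

test_that("vacuum slab transmits the reference unchanged at zero noise", {
  cfg <- simConfig(noiseSd = 0)
  pair <- forwardTransmit(vacuumMix(), cfg, 0.5)
  expect_equal(fieldAmplitude(pair$sample), fieldAmplitude(pair$reference),
               tolerance = 1e-12)
})

test_that("constant slab matches the closed-form amplitude ratio and phase", {
  # alpha = 10 /cm, n = 1.5, d = 1 mm: field ratio exp(-alpha d / 2) =
  # exp(-0.5) at every bin; phase delay 0.5 * omega * d / c
  cfg <- simConfig(noiseSd = 0)
  pair <- forwardTransmit(constantSlabMix(10, 1.5), cfg, 1)
  r <- phaseAmplitudeRatio(toFrequency(pair$sample),
                           toFrequency(pair$reference))
  sel <- r$valid & r$freq >= 0.4 & r$freq <= 1.4
  expect_true(all(abs(r$A[sel] - exp(-0.5)) < 1e-9))
  phiExp <- 0.5 * 2 * pi * r$freq[sel] * 1e12 * 1e-3 / 299792458
  expect_true(all(abs(r$phi[sel] - phiExp) < 1e-6))
})

test_that("forward simulation is bit-identical under one seed", {
  cfg <- simConfig(noiseSd = 0.01, seed = 42L)
  p1 <- forwardTransmit(carbendazimPreset(), cfg, 0.2, seed = 42L)
  p2 <- forwardTransmit(carbendazimPreset(), cfg, 0.2, seed = 42L)
  expect_identical(fieldAmplitude(p1$sample), fieldAmplitude(p2$sample))
  expect_identical(fieldAmplitude(p1$reference), fieldAmplitude(p2$reference))
})

test_that("forward simulation rejects invalid concentrations", {
  cfg <- simConfig(noiseSd = 0)
  expect_error(forwardTransmit(carbendazimPreset(), cfg, 1.2), "\\[0, 1\\]")
  expect_error(forwardTransmit(carbendazimPreset(), cfg, -0.1), "\\[0, 1\\]")
})

test_that("dataset reproduces the study design and label balance", {
  mix <- carbendazimPreset()
  # full design: 13 classes x 33 specimens = 429 specimens
  cfg <- simConfig(specimensPerClass = 33)
  nspec <- length(thzConcentrations()) * cfg$specimensPerClass
  expect_equal(nspec, 429)
  # counting at desk scale: 2 classes x 1 specimen x 3 replicates
  cfg2 <- simConfig(specimensPerClass = 1, replicates = 3, nPoints = 8)
  ds <- generateDataset(mix, cfg2, concentrations = c(0, 1))
  expect_equal(nrow(ds$manifest), 6)
  expect_equal(length(ds$records), 6)
  # label histogram uniform across classes
  cfg3 <- simConfig(specimensPerClass = 2, replicates = 2, nPoints = 8)
  ds3 <- generateDataset(mix, cfg3, concentrations = c(0, 0.5, 1))
  expect_true(all(table(ds3$manifest$classIndex) == 4))
  # determinism of the whole dataset
  ds3b <- generateDataset(mix, cfg3, concentrations = c(0, 0.5, 1))
  expect_identical(
    fieldAmplitude(ds3$records[[5]]$sample),
    fieldAmplitude(ds3b$records[[5]]$sample))
})

test_that("duplicate or out-of-range concentrations are rejected", {
  cfg <- simConfig(nPoints = 8)
  expect_error(generateDataset(carbendazimPreset(), cfg, c(0.1, 0.1)),
               "duplicate")
  expect_error(generateDataset(carbendazimPreset(), cfg, c(0.5, 1.5)),
               "\\[0, 1\\]")
})

test_that("waveform text serialization round-trips", {
  cfg <- simConfig(noiseSd = 0.01, seed = 3L, nPoints = 8)
  pair <- forwardTransmit(carbendazimPreset(), cfg, 0.25,
                          specimenId = "c03_s001", replicateIndex = 2L)
  path <- tempfile(fileext = ".txt")
  writeWaveform(pair$sample, path)
  w <- readWaveform(path)
  expect_equal(timePs(w), timePs(pair$sample))
  expect_equal(fieldAmplitude(w), fieldAmplitude(pair$sample))
  expect_identical(w@kind, "sample")
  expect_identical(w@specimenId, "c03_s001")
  expect_identical(w@replicateIndex, 2L)
  expect_equal(w@meta$concentration, 0.25)
})

test_that("dataset directory export writes a manifest and waveform files", {
  cfg <- simConfig(specimensPerClass = 1, replicates = 1, nPoints = 8)
  ds <- generateDataset(carbendazimPreset(), cfg, concentrations = c(0, 1))
  dir <- tempfile("wfds")
  m <- writeDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(file.path(dir, m$sampleFile))))
  w <- readWaveform(file.path(dir, m$sampleFile[1]))
  expect_equal(fieldAmplitude(w), fieldAmplitude(ds$records[[1]]$sample))
})
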