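# thzQuant

Quantifying a pesticide (carbendazim) in a food matrix (rice) from
terahertz time-domain spectroscopy, for chemometricians and
food-safety labs exploring deep learning on scarce spectral data.  The
package implements the full WGAN-ResNet pipeline:

1. **Simulate** paired reference/sample THz waveforms for 13
   concentration classes (0–100 %) with known ground-truth optical
   constants (`carbendazimPreset()`, `generateDataset()`).
2. **Invert** waveform pairs to refractive index and absorption
   coefficient with the thin-slab formulas
   `n(ω) = 1 + c·φ(ω)/(ω d)` and `α(ω) = −(2/d)·ln A(ω)`,
   where `A` is the sample/reference amplitude ratio and `φ` the phase
   difference (`invertPair()`, `extractConstants()`).
3. **Image** each cropped absorption vector `x` as the outer product
   `A = x·xᵀ`, min–max normalized (`outerImage()`), scored with SSIM
   (`ssim()`).
4. **Augment** each class with a Wasserstein GAN whose weight-clipped
   critic scores realism under the Earth-Mover distance; losses
   `E[f(g(z))] − E[f(x)]` (critic) and `−E[f(g(z))]` (generator)
   (`trainWgan()`, `generateSamples()`).
5. **Classify** with 18- or 152-layer residual networks (`F(x) + x`
   blocks, 2-2-2-2 basic / 3-8-36-3 bottleneck stage plans, 13-way
   head), optionally freezing the first *n* of the five macro-layers
   conv1…conv5_x (`trainClassifier()`, `frozenLayerSweep()`), and
   compare with SVM (GA/PSO-tuned), KNN, naive Bayes and a random
   forest on identical splits (`runBaseline()`).

The networks run on a self-contained CPU engine (RcppArmadillo GEMM
kernels, analytic backpropagation, Adam/RMSprop); no external
deep-learning framework is required.

## Worked example

```r
library(thzQuant)

mix <- carbendazimPreset()            # peaks at 1.15 / 1.32 THz
cfg <- simConfig(specimensPerClass = 2, seed = 1)
pair <- forwardTransmit(mix, cfg, conc = 0.5, specimenId = "demo")
oc <- cropBand(invertPair(pair$sample, pair$reference), 0.4, 1.4)
oc
#> OpticalConstants: 64 bins, 0.406-1.391 THz, d = 1 mm
#>   n in [1.547, 1.553], alpha in [2.88, 26.36] 1/cm

img <- outerImage(alphaCm(oc), label = 6L, concentration = 0.5,
                  specimenId = "demo")
img
#> SpectralImage 64x64 [measured] class 6 (c = 0.5)

countFlops(resnetSpec(18)) / 1e9      # multiply-adds at 224x224 input
#> [1] 1.813568
countFlops(resnetSpec(152)) / 1e9
#> [1] 11.28039
```

The inverted trace recovers the mixture's constant index (1.55 at 50 %
analyte, up to measurement noise) and an absorption curve rising from
~3 to ~26 1/cm across the band with the analyte peaks superimposed; at
zero noise the round trip
is exact to machine precision (see the physics tests).  The FLOP
counter reports the analytic multiply-add counts of the two
architectures at their reference input size.

An end-to-end run (simulate → invert → image → augment → train →
baselines) is one call:

```r
res <- runPipeline(runConfig("desk", seed = 1), dir = "run1")
res$summary                           # one accuracy per method
```

or from a shell: `Rscript inst/cli/thzquant.R --scale desk --seed 1
--out run1` (add `--no-augment` for the plain ResNet arm).

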