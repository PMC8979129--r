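# Shared fixtures and independent oracles for the suite.

# mixture whose two components are identical constant slabs (flat alpha,
# constant n): closed-form transmission for derived-value tests
constantSlabMix <- function(alpha0 = 10, n0 = 1.5) {
  m <- new("AbsorptionModel",
           peaks = matrix(numeric(0), 0, 3),
           baseline = c(alpha0, 0, 0), nConst = n0)
  new("MixtureSpec", analyte = m, matrixModel = m, band = c(0.4, 1.4))
}

# vacuum: no absorption, unit index
vacuumMix <- function() constantSlabMix(0, 1)

# small simulated image cache shared across tests (built once per run)
.fixtureEnv <- new.env(parent = emptyenv())

deskImages <- function(specimensPerClass = 4, noiseSd = 1e-3, seed = 11L) {
  key <- paste0("imgs_", specimensPerClass, "_", noiseSd, "_", seed)
  if (is.null(.fixtureEnv[[key]])) {
    mix <- carbendazimPreset()
    cfg <- simConfig(noiseSd = noiseSd, specimensPerClass = specimensPerClass,
                     seed = seed)
    ds <- generateDataset(mix, cfg)
    inv <- invertDataset(ds)
    .fixtureEnv[[key]] <- list(ds = ds, inv = inv,
                               images = imagesFromConstants(inv))
  }
  .fixtureEnv[[key]]
}

# independent SSIM oracle: literal sliding-window formula, double loop
naiveSsim <- function(a, b, windowSize = 11, sigma = 1.5, K1 = 0.01,
                      K2 = 0.03, L = 1) {
  k <- windowSize
  g1 <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  w <- outer(g1, g1)
  w <- w / sum(w)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - k + 1)) {
    for (j in seq_len(ncol(a) - k + 1)) {
      wa <- a[i:(i + k - 1), j:(j + k - 1)]
      wb <- b[i:(i + k - 1), j:(j + k - 1)]
      mua <- sum(w * wa); mub <- sum(w * wb)
      va <- sum(w * wa^2) - mua^2
      vb <- sum(w * wb^2) - mub^2
      cab <- sum(w * wa * wb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                        ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# brute-force outer-product oracle
naiveOuter <- function(x) {
  n <- length(x)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) P[i, j] <- x[i] * x[j]
  P
}

# numerical gradient of a scalar function of an array
numGrad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
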