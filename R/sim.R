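#' Evaluate an absorption model on a frequency grid
#'
#' Baseline plus Lorentzian peaks: each peak contributes
#' \code{amp * hwhm^2 / ((f - center)^2 + hwhm^2)} so its height at the
#' center equals \code{amp}.
#'
#' @param model an \linkS4class{AbsorptionModel}
#' @param freq frequencies in THz
#' @return absorption coefficient in 1/cm, same length as \code{freq}
#' @export
evalAbsorption <- function(model, freq) {
  stopifnot(is(model, "AbsorptionModel"))
  b <- model@baseline
  a <- b[1] + b[2] * freq + b[3] * freq^2
  p <- model@peaks
  if (nrow(p) > 0) {
    for (i in seq_len(nrow(p)))
      a <- a + p[i, 3] * p[i, 2]^2 / ((freq - p[i, 1])^2 + p[i, 2]^2)
  }
  a
}

#' Mixture absorption and refractive index at a concentration
#'
#' Pointwise linear mixing: \code{c * analyte + (1 - c) * matrix}.
#'
#' @param mix a \linkS4class{MixtureSpec}
#' @param conc concentration fraction in [0, 1]
#' @param freq frequencies in THz
#' @return for \code{mixtureAlpha}, absorption in 1/cm; for
#'   \code{mixtureIndex}, the (constant) refractive index
#' @export
mixtureAlpha <- function(mix, conc, freq) {
  stopifnot(is(mix, "MixtureSpec"), conc >= 0, conc <= 1)
  conc * evalAbsorption(mix@analyte, freq) +
    (1 - conc) * evalAbsorption(mix@matrixModel, freq)
}

#' @rdname mixtureAlpha
#' @export
mixtureIndex <- function(mix, conc, freq) {
  stopifnot(is(mix, "MixtureSpec"), conc >= 0, conc <= 1)
  rep(conc * mix@analyte@nConst + (1 - conc) * mix@matrixModel@nConst,
      length(freq))
}

#' Carbendazim-in-rice mixture preset
#'
#' Analyte model with two Lorentzian absorption peaks at 1.15 and 1.32 THz
#' over a gently rising background; matrix (rice) model with a smooth,
#' featureless background and no peaks.  Band 0.4-1.4 THz.  Peak widths and
#' amplitudes are preset parameters chosen to resemble pressed-pellet
#' spectra qualitatively (peak heights a few tens of 1/cm); the
#' concentration dependence of the peaks follows from linear mixing.
#'
#' @return a \linkS4class{MixtureSpec}
#' @export
carbendazimPreset <- function() {
  analyte <- new("AbsorptionModel",
    peaks = cbind(center = c(1.15, 1.32),
                  width = c(0.045, 0.055),
                  amplitude = c(35, 25)),
    baseline = c(1.0, 6.0, 0.0), nConst = 1.60)
  matrixModel <- new("AbsorptionModel",
    peaks = matrix(numeric(0), 0, 3,
                   dimnames = list(NULL, c("center", "width", "amplitude"))),
    baseline = c(0.5, 3.0, 2.0), nConst = 1.50)
  new("MixtureSpec", analyte = analyte, matrixModel = matrixModel,
      band = c(0.4, 1.4))
}

#' The 13-level concentration grid
#'
#' Mass fractions 0, 2, 4, 6, 8, 10, 15, 20, 25, 30, 40, 50 and 100
#' percent, as fractions in [0, 1].
#'
#' @return numeric vector of length 13
#' @export
thzConcentrations <- function() {
  c(0, 2, 4, 6, 8, 10, 15, 20, 25, 30, 40, 50, 100) / 100
}

#' Simulation configuration
#'
#' @param band (f_min, f_max) in THz; the analysis band.
#' @param nPoints number of frequency bins the band should contain (the
#'   frequency resolution is set to \code{diff(band)/nPoints}); >= 8.
#' @param thicknessD slab thickness in mm.
#' @param noiseSd additive time-domain field noise, standard deviation as a
#'   fraction of the reference peak amplitude.
#' @param replicates measurements per specimen (>= 1).
#' @param specimensPerClass specimens simulated per concentration class.
#' @param seed integer random seed.
#' @return a validated list of class \code{"SimConfig"}
#' @export
simConfig <- function(band = c(0.4, 1.4), nPoints = 64, thicknessD = 1,
                      noiseSd = 1e-3, replicates = 3,
                      specimensPerClass = 33, seed = 1L) {
  stopifnot(length(band) == 2, band[1] < band[2], nPoints >= 8,
            thicknessD > 0, noiseSd >= 0, replicates >= 1,
            specimensPerClass >= 1)
  structure(list(band = as.numeric(band), nPoints = as.integer(nPoints),
                 thicknessD = as.numeric(thicknessD),
                 noiseSd = as.numeric(noiseSd),
                 replicates = as.integer(replicates),
                 specimensPerClass = as.integer(specimensPerClass),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Time grid conjugate to the requested band resolution: df = width/nPoints
# (THz), record length N a power of two covering at least 4x the upper band
# edge in bandwidth, dt = 1/(N df) ps.
.timeGrid <- function(cfg) {
  df <- diff(cfg$band) / cfg$nPoints
  fnyq <- max(4 * cfg$band[2], 5)
  N <- 2^ceiling(log2(2 * fnyq / df))
  dt <- 1 / (N * df)
  list(t = (0:(N - 1)) * dt, dt = dt, df = df, N = N)
}

# Differentiated-Gaussian reference pulse, peak amplitude normalized to 1.
.referencePulse <- function(t, t0 = 10, sigma = 0.12) {
  e <- -(t - t0) / sigma^2 * exp(-(t - t0)^2 / (2 * sigma^2))
  e / max(abs(e))
}

#' Simulate a reference/sample waveform pair
#'
#' Forward model: a differentiated-Gaussian reference pulse is multiplied in
#' the frequency domain by the thin-slab transfer function
#' \code{H(omega) = exp(-alpha(omega) d / 2) * exp(-i (n(omega) - 1) omega d / c)}
#' (power-absorption convention, no Fresnel or etalon terms), inverse
#' transformed, and white Gaussian noise is added independently to the
#' reference and sample time traces.  This makes the simulator the exact
#' inverse of \code{\link{extractConstants}} in its default (no-Fresnel)
#' mode at zero noise.
#'
#' @param mix a \linkS4class{MixtureSpec}
#' @param cfg a \code{\link{simConfig}}
#' @param conc concentration fraction in [0, 1]
#' @param seed seed for the noise draws (default \code{cfg$seed})
#' @param specimenId,replicateIndex provenance labels stored on the waveforms
#' @return list with elements \code{reference} and \code{sample}, both
#'   \linkS4class{Waveform}s on the same time grid
#' @export
forwardTransmit <- function(mix, cfg, conc, seed = cfg$seed,
                            specimenId = "sim", replicateIndex = 1L) {
  stopifnot(is(mix, "MixtureSpec"), inherits(cfg, "SimConfig"))
  if (!is.finite(conc) || conc < 0 || conc > 1)
    stop("concentration must lie in [0, 1]")
  g <- .timeGrid(cfg)
  pulse <- .referencePulse(g$t)
  N <- g$N
  # frequency of each FFT bin, signed (THz)
  k <- 0:(N - 1)
  fs <- ifelse(k <= N / 2, k, k - N) * g$df
  fa <- abs(fs)
  alpha <- mixtureAlpha(mix, conc, fa)           # 1/cm at |f|
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("absorption model produced non-finite or negative alpha")
  nidx <- mixtureIndex(mix, conc, fa)
  d_m <- .mm_to_m(cfg$thicknessD)
  att <- exp(-.percm_to_perm(alpha) * d_m / 2)
  phi <- (nidx - 1) * .omega(fa) * d_m / .C_LIGHT
  H <- att * exp(-1i * sign(fs) * phi)           # Hermitian-symmetric
  samp <- Re(fft(fft(pulse) * H, inverse = TRUE)) / N
  if (cfg$noiseSd > 0) {
    set.seed(seed)
    ref <- pulse + rnorm(N, 0, cfg$noiseSd)
    samp <- samp + rnorm(N, 0, cfg$noiseSd)
  } else ref <- pulse
  meta <- list(thickness_mm = cfg$thicknessD, concentration = conc)
  list(
    reference = new("Waveform", time = g$t, field = ref, kind = "reference",
                    specimenId = specimenId,
                    replicateIndex = as.integer(replicateIndex), meta = meta),
    sample = new("Waveform", time = g$t, field = samp, kind = "sample",
                 specimenId = specimenId,
                 replicateIndex = as.integer(replicateIndex), meta = meta))
}

#' Generate a labeled synthetic dataset of waveform pairs
#'
#' Reproduces the study design at configurable scale: for each
#' concentration class, \code{cfg$specimensPerClass} specimens each
#' measured \code{cfg$replicates} times (reference re-measured alongside
#' every sample trace).  Record seeds are derived deterministically from
#' \code{cfg$seed}, so the whole dataset is reproducible.
#'
#' @param mix a \linkS4class{MixtureSpec}
#' @param cfg a \code{\link{simConfig}}
#' @param concentrations distinct concentration fractions (default the
#'   13-level grid of \code{\link{thzConcentrations}})
#' @return list of class \code{"ThzDataset"} with elements \code{records}
#'   (list of reference/sample pairs) and \code{manifest} (data.frame with
#'   record, specimenId, classIndex, concentration, replicate)
#' @export
generateDataset <- function(mix, cfg, concentrations = thzConcentrations()) {
  stopifnot(length(concentrations) >= 1)
  if (anyDuplicated(concentrations))
    stop("duplicate concentration values")
  if (any(concentrations < 0 | concentrations > 1))
    stop("concentrations must lie in [0, 1]")
  records <- list()
  rows <- list()
  idx <- 0L
  for (ci in seq_along(concentrations)) {
    conc <- concentrations[ci]
    for (sp in seq_len(cfg$specimensPerClass)) {
      sid <- sprintf("c%02d_s%03d", ci - 1L, sp)
      for (rep_i in seq_len(cfg$replicates)) {
        idx <- idx + 1L
        sd_i <- .deriveSeed(cfg$seed, sprintf("%s/r%d", sid, rep_i))
        pair <- forwardTransmit(mix, cfg, conc, seed = sd_i,
                                specimenId = sid, replicateIndex = rep_i)
        pair$sample@meta$classIndex <- ci - 1L
        records[[idx]] <- pair
        rows[[idx]] <- data.frame(record = idx, specimenId = sid,
                                  classIndex = ci - 1L, concentration = conc,
                                  replicate = rep_i)
      }
    }
  }
  structure(list(records = records, manifest = do.call(rbind, rows),
                 config = cfg, concentrations = concentrations),
            class = "ThzDataset")
}

#' @export
print.ThzDataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("ThzDataset: %d records, %d classes, %d specimens, %d replicate(s)\n",
              nrow(m), length(unique(m$classIndex)),
              length(unique(m$specimenId)), max(m$replicate)))
  invisible(x)
}

#' Waveform text serialization
#'
#' Canonical on-disk form: two-column whitespace-delimited text
#' (time_ps, field) preceded by '#'-prefixed header lines carrying kind,
#' specimen, replicate, thickness and concentration.
#'
#' @param w a \linkS4class{Waveform}
#' @param path output file
#' @export
writeWaveform <- function(w, path) {
  stopifnot(is(w, "Waveform"))
  hdr <- c(sprintf("# kind: %s", w@kind),
           sprintf("# specimen: %s", w@specimenId),
           sprintf("# replicate: %d", w@replicateIndex),
           sprintf("# d_mm: %.17g", w@meta$thickness_mm %||% NA_real_),
           sprintf("# concentration: %.17g", w@meta$concentration %||% NA_real_))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.17g %.17g", w@time, w@field), con)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname writeWaveform
#' @param path input file
#' @return \code{readWaveform}: the reconstructed \linkS4class{Waveform}
#' @export
readWaveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(sprintf("^# %s: ", key), "", grep(
    sprintf("^# %s:", key), hdr, value = TRUE)[1])
  body <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  new("Waveform", time = m[, 1], field = m[, 2], kind = getv("kind"),
      specimenId = getv("specimen"),
      replicateIndex = as.integer(getv("replicate")),
      meta = list(thickness_mm = as.numeric(getv("d_mm")),
                  concentration = as.numeric(getv("concentration"))))
}

#' Write a dataset's waveforms and manifest to a directory
#'
#' @param ds a \code{ThzDataset}
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest data.frame including file paths
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- ds$manifest
  m$referenceFile <- sprintf("rec%04d_ref.txt", m$record)
  m$sampleFile <- sprintf("rec%04d_smp.txt", m$record)
  for (i in seq_len(nrow(m))) {
    writeWaveform(ds$records[[m$record[i]]]$reference,
                  file.path(dir, m$referenceFile[i]))
    writeWaveform(ds$records[[m$record[i]]]$sample,
                  file.path(dir, m$sampleFile[i]))
  }
  write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}
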