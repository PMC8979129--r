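# Thin-slab THz-TDS inversion: FFT, amplitude ratio / phase difference,
# optical-constant extraction, replicate averaging, band cropping.

# one-dimensional phase unwrapping (cumulative 2*pi correction)
.unwrapPhase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  corr <- cumsum(-2 * pi * round(d / (2 * pi)))
  p + c(0, corr)
}

#' Fourier transform a waveform to a one-sided complex spectrum
#'
#' @param w a \linkS4class{Waveform} on a uniform time grid (>= 8 points)
#' @param zeroPad integer padding factor >= 1 (record length multiplied)
#' @param window \code{"rectangular"} (default) or \code{"hann"}
#' @return a \linkS4class{ComplexSpectrum}; frequencies in THz, phase
#'   unwrapped along frequency
#' @export
toFrequency <- function(w, zeroPad = 1, window = c("rectangular", "hann")) {
  stopifnot(is(w, "Waveform"))
  window <- match.arg(window)
  x <- w@field
  N <- length(x)
  dt <- diff(w@time[1:2])
  if (max(abs(diff(diff(w@time)))) > 1e-9 * dt)
    stop("non-uniform time grid")
  if (window == "hann")
    x <- x * 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1)))
  Np <- as.integer(round(zeroPad)) * N
  if (Np > N) x <- c(x, numeric(Np - N))
  X <- fft(x)
  half <- 0:(Np %/% 2)
  freq <- half / (Np * dt)                 # ps grid -> THz
  amp <- Mod(X[half + 1])
  ph <- .unwrapPhase(Arg(X[half + 1]))
  new("ComplexSpectrum", freq = freq, amplitude = amp, phase = ph)
}

#' Amplitude ratio and phase difference of sample vs reference
#'
#' \code{A = amplitude_sample / amplitude_reference};
#' \code{phi = phase_reference - phase_sample}, so an optically denser
#' (slower) sample yields \code{phi >= 0}.  The phase difference is
#' re-unwrapped along frequency and anchored by removing the 2*pi*k offset
#' closest to the intercept of a linear fit through the low-frequency
#' points, so that phi extrapolates to 0 at omega = 0.  Bins where the
#' reference amplitude falls below \code{epsRel * max(reference amplitude)}
#' are flagged invalid (values set to NA) rather than divided through.
#'
#' @param sample,reference \linkS4class{ComplexSpectrum}s on one grid
#' @param epsRel relative low-amplitude guard (default 1e-6)
#' @param anchorBelow upper frequency (THz) of the anchoring fit window
#' @return list with \code{freq}, \code{A}, \code{phi}, \code{valid}
#' @export
phaseAmplitudeRatio <- function(sample, reference, epsRel = 1e-6,
                                anchorBelow = 0.5) {
  stopifnot(is(sample, "ComplexSpectrum"), is(reference, "ComplexSpectrum"))
  if (length(sample@freq) != length(reference@freq) ||
      max(abs(sample@freq - reference@freq)) > 1e-9)
    stop("sample and reference must share the frequency grid")
  eps <- epsRel * max(reference@amplitude)
  valid <- reference@amplitude >= eps & sample@amplitude > 0
  A <- rep(NA_real_, length(valid))
  A[valid] <- sample@amplitude[valid] / reference@amplitude[valid]
  phi <- rep(NA_real_, length(valid))
  phi[valid] <- .unwrapPhase((reference@phase - sample@phase)[valid])
  # anchor: linear fit through low-frequency valid bins, remove 2*pi*k offset
  f <- sample@freq
  sel <- valid & f > 0 & f <= anchorBelow
  if (sum(sel) < 5) sel <- valid & f > 0 & seq_along(f) <= (which(valid)[1] + 7)
  if (sum(sel) >= 2) {
    fit <- stats::lm.fit(cbind(1, f[sel]), phi[sel])
    phi[valid] <- phi[valid] - 2 * pi * round(fit$coefficients[1] / (2 * pi))
  }
  list(freq = f, A = A, phi = phi, valid = valid)
}

#' Extract refractive index and absorption coefficient
#'
#' Thin-slab formulas: \code{n(omega) = 1 + c * phi(omega) / (omega d)} and
#' \code{alpha(omega) = -(2/d) ln A(omega)} (power absorption; field ratio
#' carries \code{exp(-alpha d / 2)}).  With \code{fresnel = TRUE} the
#' amplitude ratio is first corrected for the air/slab interface losses:
#' \code{alpha = -(2/d) ln[A (n + 1)^2 / (4 n)]}.  The default no-Fresnel
#' convention is the exact inverse of \code{\link{forwardTransmit}}.
#'
#' @param A amplitude ratio per bin (NA allowed at flagged bins)
#' @param phi phase difference per bin, rad
#' @param freq frequency grid, THz
#' @param thicknessD slab thickness, mm (> 0)
#' @param fresnel apply the interface correction (default FALSE)
#' @return an \linkS4class{OpticalConstants} over the bins where both A and
#'   phi are finite (flagged bins dropped)
#' @export
extractConstants <- function(A, phi, freq, thicknessD, fresnel = FALSE) {
  if (thicknessD <= 0) stop("thicknessD must be > 0 (mm)")
  keep <- is.finite(A) & is.finite(phi) & freq > 0
  if (!any(keep)) stop("no usable bins")
  f <- freq[keep]; A <- A[keep]; phi <- phi[keep]
  if (any(A <= 0)) stop("amplitude ratio must be > 0 on retained bins")
  d_m <- .mm_to_m(thicknessD)
  n <- 1 + .C_LIGHT * phi / (.omega(f) * d_m)
  Aeff <- if (fresnel) A * (n + 1)^2 / (4 * n) else A
  alpha_m <- -(2 / d_m) * log(Aeff)
  new("OpticalConstants", freq = f, n = n, alpha = .perm_to_percm(alpha_m),
      thicknessD = thicknessD)
}

#' Invert one reference/sample waveform pair
#'
#' Convenience wrapper: FFT both waveforms, form the guarded amplitude
#' ratio and anchored phase difference, and extract optical constants.
#'
#' @param sample,reference \linkS4class{Waveform}s
#' @param thicknessD slab thickness in mm (default from the sample's
#'   metadata)
#' @inheritParams toFrequency
#' @inheritParams extractConstants
#' @return an \linkS4class{OpticalConstants}
#' @export
invertPair <- function(sample, reference,
                       thicknessD = sample@meta$thickness_mm,
                       zeroPad = 1, window = "rectangular",
                       fresnel = FALSE) {
  ss <- toFrequency(sample, zeroPad, window)
  rs <- toFrequency(reference, zeroPad, window)
  r <- phaseAmplitudeRatio(ss, rs)
  extractConstants(r$A, r$phi, r$freq, thicknessD, fresnel)
}

#' Average optical constants over replicate measurements
#'
#' @param ocs list of \linkS4class{OpticalConstants} on identical grids
#' @return pointwise arithmetic mean (single input returned unchanged)
#' @export
averageReplicates <- function(ocs) {
  stopifnot(length(ocs) >= 1)
  if (length(ocs) == 1) return(ocs[[1]])
  f0 <- ocs[[1]]@freq
  for (oc in ocs[-1])
    if (length(oc@freq) != length(f0) || max(abs(oc@freq - f0)) > 1e-9)
      stop("mismatched frequency grids")
  n <- Reduce(`+`, lapply(ocs, function(o) o@n)) / length(ocs)
  a <- Reduce(`+`, lapply(ocs, function(o) o@alpha)) / length(ocs)
  new("OpticalConstants", freq = f0, n = n, alpha = a,
      thicknessD = ocs[[1]]@thicknessD)
}

#' Crop optical constants to an analysis band
#'
#' Retains bins with \code{fMin <= f <= fMax} in order; the resulting
#' length is the side length of the outer-product image built from the
#' cropped absorption vector.
#'
#' @param oc an \linkS4class{OpticalConstants}
#' @param fMin,fMax band edges in THz
#' @return the cropped \linkS4class{OpticalConstants}
#' @export
cropBand <- function(oc, fMin, fMax) {
  stopifnot(fMin < fMax)
  keep <- oc@freq >= fMin & oc@freq <= fMax
  if (!any(keep)) stop("band does not overlap the frequency grid")
  new("OpticalConstants", freq = oc@freq[keep], n = oc@n[keep],
      alpha = oc@alpha[keep], thicknessD = oc@thicknessD)
}

#' Write / read optical constants as CSV
#'
#' Columns freq_THz, n, alpha_cm1 with a '#' metadata header line carrying
#' the thickness.
#'
#' @param oc an \linkS4class{OpticalConstants}
#' @param path file path
#' @export
writeOpticalConstants <- function(oc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# d_mm: %.17g", oc@thicknessD), con)
  writeLines("freq_THz,n,alpha_cm1", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", oc@freq, oc@n, oc@alpha), con)
}

#' @rdname writeOpticalConstants
#' @export
readOpticalConstants <- function(path) {
  lines <- readLines(path)
  d <- as.numeric(sub("^# d_mm: ", "", lines[1]))
  m <- read.csv(text = lines[-1])
  new("OpticalConstants", freq = m$freq_THz, n = m$n, alpha = m$alpha_cm1,
      thicknessD = d)
}
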