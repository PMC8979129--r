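#' Absorption model of one material
#'
#' Parametric model of a material's terahertz response: a monotone quadratic
#' baseline absorption plus Lorentzian peaks, and a constant real refractive
#' index.  Absorption is in 1/cm, frequencies in THz.
#'
#' @slot peaks numeric matrix with columns \code{center} (THz),
#'   \code{width} (half-width at half-maximum, THz) and \code{amplitude}
#'   (peak height above baseline, 1/cm); zero rows allowed.
#' @slot baseline numeric length-3 coefficients \code{(a0, a1, a2)} of the
#'   background \code{a0 + a1*f + a2*f^2} (1/cm, f in THz); all
#'   non-negative so the background is monotone non-decreasing over f > 0.
#' @slot nConst real refractive-index level (dimensionless, >= 1).
#' @exportClass AbsorptionModel
setClass("AbsorptionModel",
  representation(peaks = "matrix", baseline = "numeric", nConst = "numeric"))

setValidity("AbsorptionModel", function(object) {
  p <- object@peaks
  if (ncol(p) != 3) return("peaks must have 3 columns (center, width, amplitude)")
  if (nrow(p) > 0) {
    if (any(!is.finite(p))) return("peak parameters must be finite")
    if (any(p[, 2] <= 0)) return("peak widths must be > 0")
    if (any(p[, 3] < 0)) return("peak amplitudes must be >= 0")
  }
  if (length(object@baseline) != 3) return("baseline needs 3 coefficients")
  if (any(object@baseline < 0)) return("baseline coefficients must be >= 0 (monotone background)")
  if (length(object@nConst) != 1 || object@nConst < 1) return("nConst must be a scalar >= 1")
  TRUE
})

#' Two-material mixture specification
#'
#' Analyte and matrix absorption models plus the simulated frequency band.
#' At concentration c the mixture absorbs
#' \code{c * alpha_analyte + (1 - c) * alpha_matrix} pointwise, and its
#' refractive index blends linearly the same way.
#'
#' @slot analyte,matrixModel \linkS4class{AbsorptionModel} objects.
#' @slot band numeric length 2, (f_min, f_max) in THz.
#' @exportClass MixtureSpec
setClass("MixtureSpec",
  representation(analyte = "AbsorptionModel", matrixModel = "AbsorptionModel",
                 band = "numeric"))

setValidity("MixtureSpec", function(object) {
  if (length(object@band) != 2 || object@band[1] >= object@band[2])
    return("band must be (f_min, f_max) with f_min < f_max")
  ctr <- object@analyte@peaks[, 1]
  if (length(ctr) && any(ctr <= object@band[1] | ctr >= object@band[2]))
    return("analyte peak centers must lie strictly inside the band")
  ctr <- object@matrixModel@peaks[, 1]
  if (length(ctr) && any(ctr <= object@band[1] | ctr >= object@band[2]))
    return("matrix peak centers must lie strictly inside the band")
  TRUE
})

#' Time-domain terahertz waveform
#'
#' One trace of the time-domain electric field, either the reference (dry
#' air) or a sample measurement, with acquisition metadata.
#'
#' @slot time numeric, ps, strictly increasing uniform grid.
#' @slot field numeric, field amplitude (a.u.), finite.
#' @slot kind \code{"reference"} or \code{"sample"}.
#' @slot specimenId character scalar.
#' @slot replicateIndex integer scalar >= 1.
#' @slot meta named list (thickness_mm, concentration, classIndex, ...).
#' @exportClass Waveform
setClass("Waveform",
  representation(time = "numeric", field = "numeric", kind = "character",
                 specimenId = "character", replicateIndex = "integer",
                 meta = "list"))

setValidity("Waveform", function(object) {
  t <- object@time
  if (length(t) < 8) return("need at least 8 samples")
  dt <- diff(t)
  if (any(dt <= 0)) return("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(dt)) return("time step must be uniform")
  if (length(object@field) != length(t)) return("field and time lengths differ")
  if (any(!is.finite(object@field))) return("field must be finite")
  if (!object@kind %in% c("reference", "sample")) return("kind must be reference or sample")
  TRUE
})

#' One-sided complex spectrum of a waveform
#'
#' Amplitude and unwrapped phase on a strictly increasing frequency grid,
#' as produced by \code{\link{toFrequency}}.
#'
#' @slot freq numeric, THz, strictly increasing.
#' @slot amplitude numeric, >= 0 (a.u.).
#' @slot phase numeric, rad, unwrapped along frequency.
#' @exportClass ComplexSpectrum
setClass("ComplexSpectrum",
  representation(freq = "numeric", amplitude = "numeric", phase = "numeric"))

setValidity("ComplexSpectrum", function(object) {
  if (any(diff(object@freq) <= 0)) return("freq must be strictly increasing")
  if (length(object@amplitude) != length(object@freq) ||
      length(object@phase) != length(object@freq))
    return("freq, amplitude, phase must have equal length")
  if (any(object@amplitude < 0, na.rm = TRUE)) return("amplitude must be >= 0")
  TRUE
})

#' Extracted optical constants of a slab
#'
#' Per-frequency refractive index and power absorption coefficient, with the
#' slab thickness used in the extraction.
#'
#' @slot freq numeric, THz.
#' @slot n numeric, dimensionless.
#' @slot alpha numeric, 1/cm (power absorption; the field ratio carries
#'   \code{exp(-alpha d / 2)}).
#' @slot thicknessD numeric scalar, mm, > 0.
#' @exportClass OpticalConstants
setClass("OpticalConstants",
  representation(freq = "numeric", n = "numeric", alpha = "numeric",
                 thicknessD = "numeric"))

setValidity("OpticalConstants", function(object) {
  m <- length(object@freq)
  if (length(object@n) != m || length(object@alpha) != m)
    return("freq, n, alpha must have equal length")
  if (any(diff(object@freq) <= 0)) return("freq must be strictly increasing")
  if (length(object@thicknessD) != 1 || object@thicknessD <= 0)
    return("thicknessD must be a positive scalar (mm)")
  TRUE
})

#' Outer-product spectral image
#'
#' The n x n image \code{x x^T} of an absorption-coefficient vector x,
#' min-max normalized to [0, 1], with its concentration label and
#' provenance (measured vs GAN-generated).
#'
#' @slot pixels numeric square matrix with entries in [0, 1].
#' @slot label integer concentration class index (0-based, NA allowed).
#' @slot concentration numeric fraction in [0, 1] (NA allowed).
#' @slot source \code{"measured"} or \code{"generated"}.
#' @slot normMeta numeric length 2: the (min, max) of the raw outer product
#'   used for the intensity mapping.
#' @slot specimenId character scalar (provenance; "" for generated).
#' @exportClass SpectralImage
setClass("SpectralImage",
  representation(pixels = "matrix", label = "integer", concentration = "numeric",
                 source = "character", normMeta = "numeric",
                 specimenId = "character"))

setValidity("SpectralImage", function(object) {
  p <- object@pixels
  if (nrow(p) != ncol(p)) return("pixels must be square")
  if (any(!is.finite(p))) return("pixels must be finite")
  if (min(p) < -1e-12 || max(p) > 1 + 1e-12) return("pixels must lie in [0, 1]")
  if (!object@source %in% c("measured", "generated"))
    return("source must be measured or generated")
  if (length(object@normMeta) != 2) return("normMeta must be (min, max)")
  TRUE
})

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform [%s] %s rep %d: %d points, %.3f-%.3f ps\n",
              object@kind, object@specimenId, object@replicateIndex,
              length(object@time), min(object@time), max(object@time)))
})

setMethod("show", "OpticalConstants", function(object) {
  cat(sprintf("OpticalConstants: %d bins, %.3f-%.3f THz, d = %.3g mm\n",
              length(object@freq), min(object@freq), max(object@freq),
              object@thicknessD))
  cat(sprintf("  n in [%.3f, %.3f], alpha in [%.2f, %.2f] 1/cm\n",
              min(object@n), max(object@n), min(object@alpha), max(object@alpha)))
})

setMethod("show", "SpectralImage", function(object) {
  cat(sprintf("SpectralImage %dx%d [%s] class %s (c = %s)\n",
              nrow(object@pixels), ncol(object@pixels), object@source,
              ifelse(is.na(object@label), "NA", object@label),
              ifelse(is.na(object@concentration), "NA",
                     format(object@concentration))))
})

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf("MixtureSpec: band %.2f-%.2f THz; analyte %d peak(s), matrix %d peak(s)\n",
              object@band[1], object@band[2], nrow(object@analyte@peaks),
              nrow(object@matrixModel@peaks)))
})

# ---- accessors ----

#' @describeIn OpticalConstants-class frequency grid in THz
#' @param object an object of the documented class
#' @export
setGeneric("freqTHz", function(object) standardGeneric("freqTHz"))
setMethod("freqTHz", "OpticalConstants", function(object) object@freq)
setMethod("freqTHz", "ComplexSpectrum", function(object) object@freq)

#' @describeIn OpticalConstants-class absorption coefficient in 1/cm
#' @export
setGeneric("alphaCm", function(object) standardGeneric("alphaCm"))
setMethod("alphaCm", "OpticalConstants", function(object) object@alpha)

#' @describeIn OpticalConstants-class refractive index
#' @export
setGeneric("refractiveIndex", function(object) standardGeneric("refractiveIndex"))
setMethod("refractiveIndex", "OpticalConstants", function(object) object@n)

#' @describeIn SpectralImage-class pixel matrix
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
setMethod("pixels", "SpectralImage", function(object) object@pixels)

#' @describeIn SpectralImage-class class label (0-based integer)
#' @export
setGeneric("imageLabel", function(object) standardGeneric("imageLabel"))
setMethod("imageLabel", "SpectralImage", function(object) object@label)

#' @describeIn SpectralImage-class provenance ("measured" or "generated")
#' @export
setGeneric("imageSource", function(object) standardGeneric("imageSource"))
setMethod("imageSource", "SpectralImage", function(object) object@source)

#' @describeIn Waveform-class field amplitude vector
#' @export
setGeneric("fieldAmplitude", function(object) standardGeneric("fieldAmplitude"))
setMethod("fieldAmplitude", "Waveform", function(object) object@field)

#' @describeIn Waveform-class time grid in ps
#' @export
setGeneric("timePs", function(object) standardGeneric("timePs"))
setMethod("timePs", "Waveform", function(object) object@time)
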