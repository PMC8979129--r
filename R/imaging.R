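# Outer-product spectral images, classifier input preparation, SSIM.

#' Outer-product image of an absorption vector
#'
#' Builds the rank-1 matrix \code{x x^T} from a spectrum vector x and
#' min-max normalizes its intensities to [0, 1], recording the (min, max)
#' used so the mapping is invertible.  Because the outer product scales as
#' \code{lambda^2 x x^T} under \code{x -> lambda x}, the normalized pixels
#' are invariant to any positive global rescaling of x.
#'
#' @param x finite numeric vector, length >= 2
#' @param label concentration class index (0-based integer, NA allowed)
#' @param concentration concentration fraction (NA allowed)
#' @param source provenance, \code{"measured"} (default) or
#'   \code{"generated"}
#' @param specimenId provenance id
#' @return a \linkS4class{SpectralImage}
#' @export
outerImage <- function(x, label = NA_integer_, concentration = NA_real_,
                       source = "measured", specimenId = "") {
  if (length(x) < 2) stop("need a vector of length >= 2")
  if (any(!is.finite(x))) stop("non-finite entries in x")
  P <- outer(x, x)
  rng <- range(P)
  pix <- if (rng[2] > rng[1]) (P - rng[1]) / (rng[2] - rng[1])
         else matrix(0, nrow(P), ncol(P))
  new("SpectralImage", pixels = pix, label = as.integer(label),
      concentration = as.numeric(concentration), source = source,
      normMeta = rng, specimenId = specimenId)
}

# Bilinear resize with corner-aligned sampling: target node i maps to
# source coordinate (i-1)*(n-1)/(m-1), so integer upscaling factors
# reproduce source values exactly at aligned nodes.
.bilinearResize <- function(mat, side) {
  n <- nrow(mat)
  if (side == n) return(mat)
  pos <- if (side == 1) (n + 1) / 2 else 1 + (0:(side - 1)) * (n - 1) / (side - 1)
  lo <- pmin(floor(pos), n - 1)
  fr <- pos - lo
  # rows then columns (separable)
  R <- mat[lo, , drop = FALSE] * (1 - fr) + mat[lo + 1, , drop = FALSE] * fr
  t(t(R)[lo, , drop = FALSE] * (1 - fr) + t(R)[lo + 1, , drop = FALSE] * fr)
}

#' Prepare a spectral image for the network
#'
#' Bilinear resize to \code{side x side}, replicate the single channel to 3
#' channels, and standardize each channel with fixed constants
#' \code{(value - mean) / sd}.
#'
#' @param img a \linkS4class{SpectralImage} (or plain matrix in [0,1])
#' @param side target side length, >= 32
#' @param mean,sd per-channel standardization constants, length 1 or 3;
#'   defaults 0.5/0.5 (scratch training); use the ImageNet constants when
#'   feeding a pretrained base
#' @return numeric array dim \code{c(side, side, 3)}
#' @export
toModelInput <- function(img, side = 224, mean = 0.5, sd = 0.5) {
  if (side < 32) stop("side must be >= 32")
  m <- if (is(img, "SpectralImage")) img@pixels else img
  r <- .bilinearResize(m, side)
  mean <- rep_len(mean, 3); sd <- rep_len(sd, 3)
  out <- array(0, c(side, side, 3))
  for (ch in 1:3) out[, , ch] <- (r - mean[ch]) / sd[ch]
  out
}

#' ImageNet channel standardization constants
#' @return list with \code{mean} and \code{sd}, each length 3
#' @export
imagenetStats <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

#' Structural similarity index of two images
#'
#' Standard SSIM with a sliding Gaussian window (default 11 x 11,
#' sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic range L = 1), averaged over
#' all fully-contained (valid-mode) window positions.  Symmetric in its
#' arguments; equals 1 iff the images are identical.
#'
#' @param a,b numeric matrices of equal shape, at least the window size
#' @param windowSize odd window side (default 11)
#' @param sigma Gaussian window standard deviation (default 1.5)
#' @param K1,K2 stabilization constants (defaults 0.01, 0.03)
#' @param L dynamic range of the pixel values (default 1)
#' @return scalar in [-1, 1]
#' @export
ssim <- function(a, b, windowSize = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 L = 1) {
  if (is(a, "SpectralImage")) a <- a@pixels
  if (is(b, "SpectralImage")) b <- b@pixels
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  n <- nrow(a); m <- ncol(a)
  k <- windowSize
  if (n < k || m < k) stop("image smaller than the SSIM window")
  g <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  # valid-mode separable Gaussian filtering via banded matrices
  band <- function(len) {
    B <- matrix(0, len - k + 1, len)
    for (i in seq_len(len - k + 1)) B[i, i:(i + k - 1)] <- g
    B
  }
  Br <- band(n); Bc <- t(band(m))
  filt <- function(X) Br %*% X %*% Bc
  mu_a <- filt(a); mu_b <- filt(b)
  var_a <- filt(a * a) - mu_a^2
  var_b <- filt(b * b) - mu_b^2
  cov_ab <- filt(a * b) - mu_a * mu_b
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(s)
}

#' Export spectral images as 8-bit PNGs with a manifest
#'
#' Writes each image as a lossless 8-bit grayscale PNG plus a sidecar CSV
#' manifest (path, label, concentration, source, specimen, norm_min,
#' norm_max).  Pixels are kept as float internally throughout the pipeline;
#' quantization to 8 bits happens only here, at export.
#'
#' @param images list of \linkS4class{SpectralImage}
#' @param dir output directory
#' @return invisibly, the manifest data.frame
#' @export
writeSpectralImages <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    fn <- sprintf("img%05d.png", i)
    png::writePNG(im@pixels, file.path(dir, fn))
    data.frame(path = fn, label = im@label,
               concentration = im@concentration, source = im@source,
               specimen = im@specimenId, norm_min = im@normMeta[1],
               norm_max = im@normMeta[2])
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "images.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname writeSpectralImages
#' @return \code{readSpectralImages}: list of \linkS4class{SpectralImage}
#' @export
readSpectralImages <- function(dir) {
  manifest <- read.csv(file.path(dir, "images.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    px <- png::readPNG(file.path(dir, manifest$path[i]))
    if (length(dim(px)) == 3) px <- px[, , 1]
    new("SpectralImage", pixels = px,
        label = as.integer(manifest$label[i]),
        concentration = as.numeric(manifest$concentration[i]),
        source = as.character(manifest$source[i]),
        normMeta = c(manifest$norm_min[i], manifest$norm_max[i]),
        specimenId = as.character(manifest$specimen[i]))
  })
}
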