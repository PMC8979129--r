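# Per-class Wasserstein GAN with a weight-clipped critic.

#' WGAN configuration
#'
#' Defaults follow the original weight-clipping recipe: clip bound 0.01,
#' five critic updates per generator update, RMSprop at 5e-5.  At full
#' scale \code{perClassSamples} is 3495 generated images per concentration
#' class; scale it down for desk runs.
#'
#' @param latentDim latent dimension of the generator input (default 100)
#' @param cClip weight clip bound (> 0)
#' @param nCritic critic steps per generator step (>= 1)
#' @param lr RMSprop learning rate
#' @param batchSize minibatch size
#' @param iterations generator updates to run
#' @param perClassSamples images to generate per class (>= 1)
#' @param side image side the GAN operates at (must be 4 * 2^k)
#' @param baseChannels channel width of the smallest feature maps
#' @param seed integer seed
#' @return list of class \code{"WganConfig"}
#' @export
wganConfig <- function(latentDim = 100, cClip = 0.01, nCritic = 5,
                       lr = 5e-5, batchSize = 16, iterations = 500,
                       perClassSamples = 3495, side = 32,
                       baseChannels = 32, seed = 1L) {
  stopifnot(nCritic >= 1, cClip > 0, perClassSamples >= 1, batchSize >= 1)
  k <- log2(side / 4)
  if (k < 1 || k != round(k)) stop("side must be 4 * 2^k, k >= 1")
  structure(list(latentDim = as.integer(latentDim), cClip = cClip,
                 nCritic = as.integer(nCritic), lr = lr,
                 batchSize = as.integer(batchSize),
                 iterations = as.integer(iterations),
                 perClassSamples = as.integer(perClassSamples),
                 side = as.integer(side),
                 baseChannels = as.integer(baseChannels),
                 seed = as.integer(seed)),
            class = "WganConfig")
}

#' Critic and generator losses
#'
#' The critic minimizes \code{mean(fake) - mean(real)} (its negative
#' estimates the Wasserstein-1 distance under the Lipschitz constraint);
#' the generator minimizes \code{-mean(fake)}.
#'
#' @param realScores,fakeScores numeric score batches (non-empty)
#' @return scalar loss
#' @export
criticLoss <- function(realScores, fakeScores) {
  if (!length(realScores) || !length(fakeScores)) stop("empty score batch")
  mean(fakeScores) - mean(realScores)
}

#' @rdname criticLoss
#' @export
generatorLoss <- function(fakeScores) {
  if (!length(fakeScores)) stop("empty score batch")
  -mean(fakeScores)
}

#' Clamp every critic parameter into [-cClip, cClip]
#'
#' The crude Lipschitz surrogate of the weight-clipping WGAN: after each
#' critic update, every parameter is clamped to the bound.
#'
#' @param critic a critic network module
#' @param cClip clip bound (> 0)
#' @return the clipped critic
#' @export
clipWeights <- function(critic, cClip) {
  stopifnot(cClip > 0)
  .mapParams(critic, function(p) pmin(pmax(p, -cClip), cClip))
}

# DCGAN-style generator: z -> 4x4 feature map -> k transposed-conv
# doublings -> 1-channel image in [0, 1] via scaled tanh
.buildGenerator <- function(cfg) {
  k <- as.integer(log2(cfg$side / 4))
  ch <- cfg$baseChannels * 2^k           # channels at 4x4
  layers <- list(nnLinear(cfg$latentDim, ch * 16, initSd = 0.02),
                 nnReshape(c(4, 4, ch)))
  for (i in seq_len(k)) {
    cout <- if (i == k) 1L else as.integer(ch / 2)
    layers <- c(layers, list(nnBatchNorm(ch), nnReLU(),
                             nnConvT(4, 4, ch, cout, stride = 2, pad = 1)))
    ch <- cout
  }
  layers <- c(layers, list(nnTanh01()))
  nnSequential(layers)
}

# convolutional critic: k stride-2 conv halvings then an affine score head
# (no sigmoid; the score is unbounded)
.buildCritic <- function(cfg) {
  k <- as.integer(log2(cfg$side / 4))
  layers <- list()
  cin <- 1L
  ch <- cfg$baseChannels
  for (i in seq_len(k)) {
    layers <- c(layers, list(nnConv(4, 4, cin, ch, stride = 2, pad = 1,
                                    bias = TRUE, initSd = 0.02),
                             nnLeakyReLU(0.2)))
    cin <- ch; ch <- ch * 2L
  }
  layers <- c(layers, list(nnFlatten(), nnLinear(cin * 16, 1, initSd = 0.02)))
  nnSequential(layers)
}

.genForward <- function(gen, z, training = TRUE) .fwd(gen, z, training)

#' Train a Wasserstein GAN on one concentration class
#'
#' Alternating optimization: \code{nCritic} critic updates (each followed
#' by weight clipping) per generator update, RMSprop on both networks.
#' All randomness is governed by \code{cfg$seed}; non-finite losses abort
#' with a diagnostic.  Images of mixed classes are rejected: one
#' independent WGAN is trained per class.
#'
#' @param images list of \linkS4class{SpectralImage} of a single class
#'   (>= 8), or a (side, side, N) array of pixels in [0, 1]
#' @param cfg a \code{\link{wganConfig}}
#' @return list of class \code{"WganFit"}: \code{generator},
#'   \code{critic}, \code{log} (iteration, criticLoss, genLoss),
#'   \code{label}, \code{concentration}, \code{cfg}
#' @export
trainWgan <- function(images, cfg = wganConfig()) {
  if (is.list(images)) {
    labs <- unique(vapply(images, function(im) im@label, 0L))
    if (length(labs) > 1) stop("images of mixed classes; train one WGAN per class")
    label <- labs[1]
    conc <- images[[1]]@concentration
    px <- vapply(images, function(im) .bilinearResize(im@pixels, cfg$side),
                 matrix(0, cfg$side, cfg$side))
  } else {
    px <- images
    label <- NA_integer_; conc <- NA_real_
  }
  N <- dim(px)[3]
  if (N < 8) stop("need at least 8 images of the class")
  real <- array(px, c(cfg$side, cfg$side, 1, N))
  set.seed(cfg$seed)
  gen <- .buildGenerator(cfg)
  critic <- .buildCritic(cfg)
  optG <- makeOptimizer("rmsprop", lr = cfg$lr)
  optC <- makeOptimizer("rmsprop", lr = cfg$lr)
  log_ <- data.frame(iteration = seq_len(cfg$iterations),
                     criticLoss = NA_real_, genLoss = NA_real_)
  B <- cfg$batchSize
  for (it in seq_len(cfg$iterations)) {
    closs <- NA_real_
    for (ci in seq_len(cfg$nCritic)) {
      idx <- sample.int(N, B, replace = N < B)
      xr <- real[, , , idx, drop = FALSE]
      z <- matrix(rnorm(cfg$latentDim * B), cfg$latentDim, B)
      gf <- .genForward(gen, z, training = TRUE)
      gen <- gf$mod
      xf <- gf$out
      fr <- .fwd(critic, xr, TRUE); critic <- fr$mod
      ff <- .fwd(critic, xf, TRUE); critic <- ff$mod
      closs <- criticLoss(fr$out, ff$out)
      if (!is.finite(closs)) stop("WGAN diverged: non-finite critic loss at iteration ", it)
      nr <- length(fr$out); nf <- length(ff$out)
      br <- .bwd(critic, fr$cache, array(-1 / nr, dim(fr$out)))
      bf <- .bwd(critic, ff$cache, array(1 / nf, dim(ff$out)))
      critic <- optStep(optC, critic, .addGrads(br$grads, bf$grads))
      critic <- clipWeights(critic, cfg$cClip)
    }
    # generator update
    z <- matrix(rnorm(cfg$latentDim * B), cfg$latentDim, B)
    gf <- .genForward(gen, z, training = TRUE)
    gen <- gf$mod
    ff <- .fwd(critic, gf$out, TRUE); critic <- ff$mod
    gloss <- generatorLoss(ff$out)
    if (!is.finite(gloss)) stop("WGAN diverged: non-finite generator loss at iteration ", it)
    bf <- .bwd(critic, ff$cache, array(-1 / length(ff$out), dim(ff$out)))
    bg <- .bwd(gen, gf$cache, bf$dx)
    gen <- optStep(optG, gen, bg$grads)
    log_$criticLoss[it] <- closs
    log_$genLoss[it] <- gloss
  }
  # freeze generator batch-norm statistics on fresh latent batches
  gen <- .resetBnStats(gen)
  set.seed(.deriveSeed(cfg$seed, "bncal"))
  for (i in 1:8) {
    z <- matrix(rnorm(cfg$latentDim * B), cfg$latentDim, B)
    gen <- .fwd(gen, z, training = "calibrate")$mod
  }
  gen <- .finalizeBnStats(gen)
  structure(list(generator = gen, critic = critic, log = log_,
                 label = label, concentration = conc, cfg = cfg),
            class = "WganFit")
}

#' Sample images from a trained generator
#'
#' @param fit a \code{WganFit} from \code{\link{trainWgan}}
#' @param k number of images (0 allowed)
#' @param seed integer seed for the latent draws
#' @return list of \code{k} \linkS4class{SpectralImage}s with
#'   \code{source = "generated"} and the class's label
#' @export
generateSamples <- function(fit, k, seed = fit$cfg$seed) {
  stopifnot(inherits(fit, "WganFit"), k >= 0)
  if (k == 0) return(list())
  set.seed(seed)
  out <- vector("list", k)
  done <- 0L
  while (done < k) {
    B <- min(64L, k - done)
    z <- matrix(rnorm(fit$cfg$latentDim * B), fit$cfg$latentDim, B)
    imgs <- .genForward(fit$generator, z, training = FALSE)$out
    for (j in seq_len(B)) {
      px <- pmin(pmax(imgs[, , 1, j], 0), 1)
      out[[done + j]] <- new("SpectralImage", pixels = px,
                             label = fit$label,
                             concentration = fit$concentration,
                             source = "generated",
                             normMeta = c(0, 1), specimenId = "")
    }
    done <- done + B
  }
  out
}
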