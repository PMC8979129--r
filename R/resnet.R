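# Residual-network construction, analytic FLOP accounting, and the
# macro-layer freezing protocol.

#' Residual network specification
#'
#' The two stage plans: depth 18 uses 2-2-2-2 basic blocks (two 3x3 convs,
#' 64/128/256/512 channels); depth 152 uses 3-8-36-3 bottleneck blocks
#' (1x1, 3x3, 1x1 with 4x channel expansion).  Down-sampling happens at
#' the first block of conv3_x, conv4_x and conv5_x with stride 2 (placed
#' on the block's first convolution), and in conv2_x via the 3x3 stride-2
#' max pool after the 7x7 stride-2 stem.  The head is global average
#' pooling plus an affine layer with \code{headClasses} outputs (softmax
#' at inference).
#'
#' @param depth 18 or 152
#' @param headClasses number of output classes (default 13)
#' @return list of class \code{"ResNetSpec"}
#' @export
resnetSpec <- function(depth = 18, headClasses = 13) {
  if (!depth %in% c(18, 152)) stop("unsupported depth (18 or 152)")
  if (depth == 18)
    spec <- list(depth = 18, kind = "basic", blocks = c(2, 2, 2, 2),
                 widths = c(64, 128, 256, 512), expansion = 1)
  else
    spec <- list(depth = 152, kind = "bottleneck", blocks = c(3, 8, 36, 3),
                 widths = c(64, 128, 256, 512), expansion = 4)
  spec$headClasses <- as.integer(headClasses)
  structure(spec, class = "ResNetSpec")
}

# Flat conv/fc plan shared by the builder and the FLOP counter.  Each row:
# stage, kh, kw, cin, cout, stride, role.  Spatial sizes are derived during
# counting/building from the input side.
.resnetPlan <- function(spec) {
  rows <- list(data.frame(stage = "conv1", kh = 7, kw = 7, cin = 3,
                          cout = 64, stride = 2, role = "stem"))
  cin <- 64
  for (s in 1:4) {
    stage <- paste0("conv", s + 1, "_x")
    width <- spec$widths[s]
    cout <- width * spec$expansion
    for (b in seq_len(spec$blocks[s])) {
      stride <- if (s > 1 && b == 1) 2 else 1
      # projection listed before the block's convs so the counter sees the
      # stage input side
      if (stride != 1 || cin != cout)
        rows <- c(rows, list(
          data.frame(stage = stage, kh = 1, kw = 1, cin = cin, cout = cout,
                     stride = stride, role = "proj")))
      if (spec$kind == "basic") {
        rows <- c(rows, list(
          data.frame(stage = stage, kh = 3, kw = 3, cin = cin, cout = width,
                     stride = stride, role = "conv"),
          data.frame(stage = stage, kh = 3, kw = 3, cin = width, cout = cout,
                     stride = 1, role = "conv")))
      } else {
        rows <- c(rows, list(
          data.frame(stage = stage, kh = 1, kw = 1, cin = cin, cout = width,
                     stride = stride, role = "conv"),
          data.frame(stage = stage, kh = 3, kw = 3, cin = width, cout = width,
                     stride = 1, role = "conv"),
          data.frame(stage = stage, kh = 1, kw = 1, cin = width, cout = cout,
                     stride = 1, role = "conv")))
      }
      cin <- cout
    }
  }
  do.call(rbind, rows)
}

#' Analytic FLOP count of a residual network
#'
#' Counts one multiply-add as one FLOP over all convolutions (including
#' projection shortcuts) and the affine head at the given input side,
#' following the counting convention of the architecture literature
#' (batch norm, activations and pooling excluded).
#'
#' @param spec a \code{\link{resnetSpec}}
#' @param inputSide input spatial side in pixels (default 224)
#' @return total multiply-add count (numeric scalar)
#' @export
countFlops <- function(spec, inputSide = 224) {
  plan <- .resnetPlan(spec)
  side <- inputSide
  total <- 0
  laststage <- ""
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    if (p$stage == "conv2_x" && laststage == "conv1")
      side <- floor((side + 2 - 3) / 2) + 1          # stem max pool
    inside <- side
    if (p$role == "proj") {
      outside <- floor((inside - 1) / p$stride) + 1
    } else {
      pad <- (p$kh - 1) / 2
      outside <- floor((inside + 2 * pad - p$kh) / p$stride) + 1
      side <- outside
    }
    total <- total + p$kh * p$kw * p$cin * p$cout * outside^2
    laststage <- p$stage
  }
  total + spec$widths[4] * spec$expansion * spec$headClasses
}

#' Build a residual network
#'
#' Instantiates the plan of \code{\link{resnetSpec}} as a trainable module
#' on the package's network engine.  On a 224 x 224 input the per-stage
#' output sides are 112, 56, 28, 14 and 7.  Every module is tagged with
#' its macro-layer (conv1, conv2_x ... conv5_x, fc) for the freezing
#' protocol.
#'
#' @param spec a \code{\link{resnetSpec}}
#' @param seed seed for the weight initialization
#' @return a network module (engine representation)
#' @export
buildResnet <- function(spec, seed = 1L) {
  set.seed(seed)
  ex <- spec$expansion
  layers <- list(
    nnConv(7, 7, 3, 64, stride = 2, pad = 3, stage = "conv1"),
    nnBatchNorm(64, stage = "conv1"),
    nnReLU(),
    nnMaxPool(3, 2, 1))
  cin <- 64
  for (s in 1:4) {
    stage <- paste0("conv", s + 1, "_x")
    width <- spec$widths[s]
    cout <- width * ex
    for (b in seq_len(spec$blocks[s])) {
      stride <- if (s > 1 && b == 1) 2 else 1
      layers <- c(layers, list(nnResBlock(spec$kind, cin, width, cout,
                                          stride, stage)))
      cin <- cout
    }
  }
  layers <- c(layers, list(nnGlobalAvgPool(),
                           nnLinear(cin, spec$headClasses, stage = "fc")))
  net <- nnSequential(layers)
  net$spec <- spec
  net
}

#' Forward pass returning class logits
#'
#' @param net a built network
#' @param x input array (side, side, 3, N)
#' @param training batch-norm mode
#' @return list with the updated \code{net}, \code{logits} (classes x N)
#'   and the backward \code{cache}
#' @export
resnetForward <- function(net, x, training = FALSE) {
  r <- .fwd(net, x, training)
  list(net = r$mod, logits = r$out, cache = r$cache)
}

#' Class probabilities for a batch of images
#'
#' @param net a built network
#' @param x input array (side, side, 3, N)
#' @return matrix (classes x N) of softmax probabilities
#' @export
resnetPredict <- function(net, x) {
  logits <- .fwd(net, x, training = FALSE)$out
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  sweep(ez, 2, colSums(ez), "/")
}

#' Freezing plan over the five macro-layers
#'
#' @param nFrozen how many of conv1, conv2_x, conv3_x, conv4_x, conv5_x to
#'   freeze, starting from conv1 (0..5)
#' @param pretrained whether the base weights are a pretrained snapshot
#' @return list of class \code{"FreezePlan"}
#' @export
freezePlan <- function(nFrozen = 0, pretrained = FALSE) {
  if (nFrozen < 0 || nFrozen > 5) stop("nFrozen must be in 0..5")
  structure(list(nFrozen = as.integer(nFrozen),
                 pretrained = isTRUE(pretrained)),
            class = "FreezePlan")
}

.MACRO_LAYERS <- c("conv1", "conv2_x", "conv3_x", "conv4_x", "conv5_x")

#' Apply a freezing plan to a network
#'
#' Marks the first \code{plan$nFrozen} macro-layers non-trainable; the
#' remaining macro-layers and the head stay trainable (the head always is,
#' since its shape differs from any pretrained base).
#'
#' @param net a built network
#' @param plan a \code{\link{freezePlan}}
#' @return list with the updated \code{net} and a \code{census} data.frame
#'   (stage, trainable, parameter count)
#' @export
applyFreeze <- function(net, plan) {
  stopifnot(inherits(plan, "FreezePlan"))
  frozen <- .MACRO_LAYERS[seq_len(plan$nFrozen)]
  net <- .freezeStages(net, frozen)
  census <- .paramCensus(net)
  census <- aggregate(count ~ stage + trainable, census, sum)
  list(net = net, census = census)
}

#' Parameter counts by trainability
#'
#' @param net a built network
#' @return named vector with \code{trainable}, \code{frozen}, \code{total}
#' @export
paramCounts <- function(net) {
  census <- .paramCensus(net)
  tr <- sum(census$count[census$trainable])
  fz <- sum(census$count[!census$trainable])
  c(trainable = tr, frozen = fz, total = tr + fz)
}
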