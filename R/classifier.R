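# Classifier training: cross-entropy over concentration classes, Adam,
# specimen-level splits, freeze protocol, sweep.

#' Training configuration for the residual classifier
#'
#' Defaults follow the study protocol: Adam, learning rate 1e-4, batch
#' size 128.
#'
#' @param optimizer \code{"adam"}
#' @param lr learning rate
#' @param batchSize minibatch size
#' @param epochs training epochs
#' @param seed integer seed governing initialization and batch shuffling
#' @param augmentation \code{"none"} or \code{"wgan"} (recorded in reports)
#' @param weightDecay L2 penalty on weight matrices (0 = off)
#' @param lrDecay multiplicative learning-rate drop applied for the final
#'   quarter of the epochs (1 = constant rate)
#' @param tailAverage average the network weights over the final-quarter
#'   epochs (stochastic weight averaging; FALSE = use the last iterate)
#' @return list of class \code{"TrainConfig"}
#' @export
trainConfig <- function(optimizer = "adam", lr = 1e-4, batchSize = 128,
                        epochs = 30, seed = 1L, augmentation = "none",
                        weightDecay = 0, lrDecay = 1, tailAverage = FALSE) {
  stopifnot(lr > 0, batchSize >= 1, epochs >= 1, weightDecay >= 0,
            lrDecay > 0, lrDecay <= 1)
  structure(list(optimizer = optimizer, lr = lr,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augmentation = augmentation, weightDecay = weightDecay,
                 lrDecay = lrDecay, tailAverage = isTRUE(tailAverage)),
            class = "TrainConfig")
}

#' Assemble a model-ready image set
#'
#' Converts a list of \linkS4class{SpectralImage} into the network input
#' tensor plus label/provenance vectors.
#'
#' @param images list of \linkS4class{SpectralImage}
#' @param side network input side (>= 32)
#' @param mean,sd channel standardization constants (see
#'   \code{\link{toModelInput}})
#' @return list with \code{x} (side, side, 3, N), \code{y} (1-based class
#'   integers), \code{label0} (0-based labels), \code{specimen},
#'   \code{source}
#' @export
imageSet <- function(images, side = 32, mean = 0.5, sd = 0.5) {
  N <- length(images)
  stopifnot(N >= 1)
  x <- array(0, c(side, side, 3, N))
  for (i in seq_len(N)) x[, , , i] <- toModelInput(images[[i]], side, mean, sd)
  label0 <- vapply(images, function(im) im@label, 0L)
  list(x = x, y = label0 + 1L, label0 = label0,
       specimen = vapply(images, function(im) im@specimenId, ""),
       source = vapply(images, function(im) im@source, ""))
}

# accuracy and confusion matrix (K x K, rows = truth, cols = prediction)
.confusion <- function(truth, pred, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

#' Train the residual classifier
#'
#' Trains with softmax cross-entropy and reports held-out accuracy
#' (correct / total), the confusion matrix, the per-epoch loss trace and a
#' parameter census.  Specimen-level leakage between train and test is
#' rejected, as are generated images in the test set.
#'
#' @param train,test image sets from \code{\link{imageSet}}; the test set
#'   must contain measured images only, from specimens absent in train
#' @param spec a \code{\link{resnetSpec}}
#' @param plan a \code{\link{freezePlan}}
#' @param cfg a \code{\link{trainConfig}}
#' @param baseWeights optional network whose weights initialize the base
#'   (the "task A" snapshot for the freeze protocol); NULL trains from
#'   scratch
#' @return a \code{TrainReport} list: \code{accuracy}, \code{confusion},
#'   \code{epochLoss}, \code{census}, \code{flops}, \code{config},
#'   \code{nTrain}, \code{nTest}
#' @export
trainClassifier <- function(train, test, spec = resnetSpec(18),
                            plan = freezePlan(0), cfg = trainConfig(),
                            baseWeights = NULL) {
  K <- spec$headClasses
  if (any(test$source == "generated"))
    stop("test set must contain measured images only")
  leak <- intersect(unique(train$specimen[train$specimen != ""]),
                    unique(test$specimen))
  if (length(leak))
    stop("specimen leakage between train and test: ", paste(head(leak), collapse = ", "))
  if (length(setdiff(seq_len(K), unique(train$y))) > 0)
    stop("class missing from the training set")
  net <- buildResnet(spec, seed = .deriveSeed(cfg$seed, "init"))
  if (!is.null(baseWeights)) net <- .copyBaseWeights(net, baseWeights)
  fr <- applyFreeze(net, plan)
  net <- fr$net
  opt <- makeOptimizer(cfg$optimizer, lr = cfg$lr,
                       weightDecay = cfg$weightDecay %||% 0)
  N <- length(train$y)
  set.seed(.deriveSeed(cfg$seed, "shuffle"))
  epochLoss <- numeric(cfg$epochs)
  decayAt <- ceiling(0.75 * cfg$epochs) + 1L
  swaNet <- NULL; swaK <- 0
  for (ep in seq_len(cfg$epochs)) {
    if (ep == decayAt && (cfg$lrDecay %||% 1) < 1)
      opt$lr <- opt$lr * cfg$lrDecay
    ord <- sample.int(N)
    losses <- c()
    for (b0 in seq(1, N, by = cfg$batchSize)) {
      idx <- ord[b0:min(b0 + cfg$batchSize - 1, N)]
      xb <- train$x[, , , idx, drop = FALSE]
      fwd <- .fwd(net, xb, training = TRUE)
      net <- fwd$mod
      ce <- softmaxCrossEntropy(fwd$out, train$y[idx])
      if (!is.finite(ce$loss)) stop("training diverged (non-finite loss)")
      bwd <- .bwd(net, fwd$cache, ce$dlogits)
      net <- optStep(opt, net, bwd$grads)
      losses <- c(losses, ce$loss)
    }
    epochLoss[ep] <- mean(losses)
    if (isTRUE(cfg$tailAverage) && ep >= decayAt - 1L) {
      # running mean of the weights over the tail epochs (averaged iterate)
      swaK <- swaK + 1
      swaNet <- if (swaK == 1) net
                else .zipParams(swaNet, net,
                                function(a, b) a + (b - a) / swaK)
    }
  }
  if (isTRUE(cfg$tailAverage) && !is.null(swaNet))
    net <- .zipParams(net, swaNet, function(a, b) b)
  # exact batch-norm statistics over the training set before evaluation
  net <- calibrateBatchNorm(net, train$x)
  # held-out evaluation in minibatches
  pred <- integer(length(test$y))
  for (b0 in seq(1, length(test$y), by = 64)) {
    idx <- b0:min(b0 + 63, length(test$y))
    p <- resnetPredict(net, test$x[, , , idx, drop = FALSE])
    pred[idx] <- apply(p, 2, which.max)
  }
  cm <- .confusion(test$y, pred, K)
  rep_ <- list(accuracy = sum(diag(cm)) / length(test$y), confusion = cm,
               epochLoss = epochLoss, census = fr$census,
               flops = countFlops(spec),
               config = list(train = unclass(cfg), plan = unclass(plan),
                             depth = spec$depth),
               nTrain = N, nTest = length(test$y))
  class(rep_) <- "TrainReport"
  attr(rep_, "net") <- net
  rep_
}

#' @export
print.TrainReport <- function(x, ...) {
  what <- if (!is.null(x$method)) x$method
          else sprintf("ResNet depth %s", x$config$depth)
  cat(sprintf("TrainReport [%s]: accuracy %.3f (n test = %d, n train = %d)\n",
              what, x$accuracy, x$nTest, x$nTrain))
  invisible(x)
}

# copy parameters (not the head) from a same-shape base network
.copyBaseWeights <- function(net, base) {
  for (i in seq_along(net$children)) {
    if (identical(net$children[[i]]$stage, "fc")) next
    src <- base$children[[i]]
    net$children[[i]] <- .copyModParams(net$children[[i]], src)
  }
  net
}
.copyModParams <- function(dst, src) {
  if (length(dst$params)) {
    for (nm in names(dst$params))
      if (!is.null(src$params[[nm]]) &&
          identical(dim(src$params[[nm]]), dim(dst$params[[nm]])) &&
          length(src$params[[nm]]) == length(dst$params[[nm]]))
        dst$params[[nm]] <- src$params[[nm]]
  }
  if (length(dst$buffers)) dst$buffers <- src$buffers
  if (length(dst$children))
    for (i in seq_along(dst$children))
      dst$children[[i]] <- .copyModParams(dst$children[[i]], src$children[[i]])
  dst
}

#' Sweep the number of frozen macro-layers
#'
#' Runs six trainings with identical data, seeds and configuration,
#' differing only in \code{nFrozen} = 0..5.  All runs share the same base
#' weights and the same test manifest.
#'
#' @inheritParams trainClassifier
#' @param pretrained whether \code{baseWeights} is a pretrained snapshot
#' @return list of 6 \code{TrainReport}s (names "0".."5"), each carrying
#'   the shared \code{testHash}
#' @export
frozenLayerSweep <- function(train, test, spec = resnetSpec(18),
                             cfg = trainConfig(), baseWeights = NULL,
                             pretrained = !is.null(baseWeights)) {
  if (is.null(baseWeights))
    baseWeights <- buildResnet(spec, seed = .deriveSeed(cfg$seed, "base"))
  testHash <- .hashObject(list(test$specimen, test$y))
  out <- list()
  for (nf in 0:5) {
    r <- trainClassifier(train, test, spec, freezePlan(nf, pretrained), cfg,
                         baseWeights = baseWeights)
    r$testHash <- testHash
    attr(r, "net") <- NULL
    out[[as.character(nf)]] <- r
  }
  out
}

#' Stratified specimen-level train/test split
#'
#' Splits specimens (not images) within each class, so replicates of one
#' specimen never straddle the split.
#'
#' @param specimen character vector of specimen ids per image
#' @param label0 0-based class labels per image
#' @param trainFrac fraction of specimens per class assigned to train
#' @param seed integer seed
#' @return list with logical \code{train} mask, \code{hash} of the test
#'   manifest, and the specimen assignment table
#' @export
splitSpecimens <- function(specimen, label0, trainFrac = 0.8, seed = 1L) {
  sp <- unique(data.frame(specimen = specimen, label0 = label0))
  set.seed(seed)
  trainSpec <- character(0)
  for (cl in unique(sp$label0)) {
    ids <- sp$specimen[sp$label0 == cl]
    ntr <- max(1, round(trainFrac * length(ids)))
    if (ntr >= length(ids)) ntr <- length(ids) - 1
    trainSpec <- c(trainSpec, sample(ids, max(ntr, 1)))
  }
  mask <- specimen %in% trainSpec
  list(train = mask,
       hash = .hashObject(sort(setdiff(sp$specimen, trainSpec))),
       assignment = transform(sp, train = sp$specimen %in% trainSpec))
}
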