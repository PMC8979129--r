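# Shallow-learning comparators on flattened cropped absorption vectors,
# run on the identical split manifest as the deep models.

#' Baseline configuration
#'
#' @param method one of \code{"svm_ga"}, \code{"svm_pso"}, \code{"knn"},
#'   \code{"naive_bayes"}, \code{"ensemble"}
#' @param cRange,gammaRange SVM search space (RBF kernel), on the raw
#'   scale; searched in log2 space
#' @param k neighbours for KNN
#' @param popSize,generations GA population and generation counts
#' @param particles,psoIters,inertia PSO swarm size, iterations, inertia
#' @param cvFolds folds of the cross-validated fitness
#' @param nTree trees of the random forest standing in for "ensemble
#'   learning"
#' @param seed integer seed
#' @return list of class \code{"BaselineConfig"}
#' @export
baselineConfig <- function(method = c("svm_ga", "svm_pso", "knn",
                                      "naive_bayes", "ensemble"),
                           cRange = c(2^-3, 2^7),
                           gammaRange = c(2^-7, 2^3), k = 5,
                           popSize = 20, generations = 15,
                           particles = 20, psoIters = 15, inertia = 0.72,
                           cvFolds = 5, nTree = 200, seed = 1L) {
  method <- match.arg(method)
  structure(list(method = method, cRange = cRange, gammaRange = gammaRange,
                 k = as.integer(k), popSize = as.integer(popSize),
                 generations = as.integer(generations),
                 particles = as.integer(particles),
                 psoIters = as.integer(psoIters), inertia = inertia,
                 cvFolds = as.integer(cvFolds), nTree = as.integer(nTree),
                 seed = as.integer(seed)),
            class = "BaselineConfig")
}

# k-fold CV accuracy of an RBF SVM at (C, gamma); the searched fitness
.svmCvAccuracy <- function(x, y, C, gamma, folds, seed) {
  set.seed(seed)
  n <- length(y)
  fold <- sample(rep_len(seq_len(folds), n))
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) return(0)
    fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr]), cost = C,
                      gamma = gamma, kernel = "radial", scale = FALSE)
    acc[f] <- mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }
  mean(acc)
}

# GA over (log2 C, log2 gamma): tournament selection, uniform crossover,
# Gaussian mutation
.gaSearch <- function(x, y, cfg) {
  lo <- log2(c(cfg$cRange[1], cfg$gammaRange[1]))
  hi <- log2(c(cfg$cRange[2], cfg$gammaRange[2]))
  set.seed(.deriveSeed(cfg$seed, "ga"))
  P <- cfg$popSize
  pop <- cbind(runif(P, lo[1], hi[1]), runif(P, lo[2], hi[2]))
  evalOne <- function(g, i)
    .svmCvAccuracy(x, y, 2^g[1], 2^g[2], cfg$cvFolds,
                   .deriveSeed(cfg$seed, "cv"))
  fit <- vapply(seq_len(P), function(i) evalOne(pop[i, ]), 0)
  trace <- data.frame(generation = 0, C = 2^pop[, 1], gamma = 2^pop[, 2],
                      fitness = fit)
  for (g in seq_len(cfg$generations)) {
    newpop <- matrix(0, P, 2)
    for (i in seq_len(P)) {
      t1 <- sample.int(P, 3); p1 <- pop[t1[which.max(fit[t1])], ]
      t2 <- sample.int(P, 3); p2 <- pop[t2[which.max(fit[t2])], ]
      child <- ifelse(runif(2) < 0.5, p1, p2)           # uniform crossover
      mut <- runif(2) < 0.2
      child[mut] <- child[mut] + rnorm(sum(mut), 0, 0.5)
      newpop[i, ] <- pmin(pmax(child, lo), hi)
    }
    # elitism: keep the best individual
    newpop[1, ] <- pop[which.max(fit), ]
    pop <- newpop
    fit <- vapply(seq_len(P), function(i) evalOne(pop[i, ]), 0)
    trace <- rbind(trace, data.frame(generation = g, C = 2^pop[, 1],
                                     gamma = 2^pop[, 2], fitness = fit))
  }
  best <- pop[which.max(fit), ]
  list(C = 2^best[1], gamma = 2^best[2], trace = trace)
}

# canonical PSO with inertia and two acceleration terms
.psoSearch <- function(x, y, cfg) {
  lo <- log2(c(cfg$cRange[1], cfg$gammaRange[1]))
  hi <- log2(c(cfg$cRange[2], cfg$gammaRange[2]))
  set.seed(.deriveSeed(cfg$seed, "pso"))
  P <- cfg$particles
  pos <- cbind(runif(P, lo[1], hi[1]), runif(P, lo[2], hi[2]))
  vel <- matrix(0, P, 2)
  evalOne <- function(g)
    .svmCvAccuracy(x, y, 2^g[1], 2^g[2], cfg$cvFolds,
                   .deriveSeed(cfg$seed, "cv"))
  fit <- apply(pos, 1, evalOne)
  pbest <- pos; pbestFit <- fit
  gbest <- pos[which.max(fit), ]; gbestFit <- max(fit)
  trace <- data.frame(iteration = 0, C = 2^pos[, 1], gamma = 2^pos[, 2],
                      fitness = fit)
  c1 <- 1.49; c2 <- 1.49
  for (it in seq_len(cfg$psoIters)) {
    r1 <- matrix(runif(P * 2), P); r2 <- matrix(runif(P * 2), P)
    vel <- cfg$inertia * vel + c1 * r1 * (pbest - pos) +
           c2 * r2 * (matrix(gbest, P, 2, byrow = TRUE) - pos)
    pos <- pos + vel
    pos[, 1] <- pmin(pmax(pos[, 1], lo[1]), hi[1])
    pos[, 2] <- pmin(pmax(pos[, 2], lo[2]), hi[2])
    fit <- apply(pos, 1, evalOne)
    upd <- fit > pbestFit
    pbest[upd, ] <- pos[upd, ]; pbestFit[upd] <- fit[upd]
    if (max(fit) > gbestFit) {
      gbestFit <- max(fit); gbest <- pos[which.max(fit), ]
    }
    trace <- rbind(trace, data.frame(iteration = it, C = 2^pos[, 1],
                                     gamma = 2^pos[, 2], fitness = fit))
  }
  list(C = 2^gbest[1], gamma = 2^gbest[2], trace = trace)
}

#' Run a shallow-learning baseline on a fixed split
#'
#' Fits the requested method on the training rows of the split and
#' reports plain accuracy and the confusion matrix on the test rows, in
#' the same report schema as the deep classifier.  SVM hyperparameters
#' are searched by GA or PSO with cross-validated accuracy as fitness,
#' and the full evaluation trace is returned for audit.
#'
#' @param features numeric matrix (observations x features): the cropped
#'   absorption vectors
#' @param labels integer class labels (1-based)
#' @param split logical vector, TRUE = training row (as produced by
#'   \code{\link{splitSpecimens}})
#' @param cfg a \code{\link{baselineConfig}}
#' @return a \code{TrainReport}-style list with \code{accuracy},
#'   \code{confusion}, \code{method}, \code{hyper}, \code{hyperTrace},
#'   \code{splitHash}
#' @export
runBaseline <- function(features, labels, split, cfg = baselineConfig()) {
  stopifnot(nrow(features) == length(labels), length(split) == length(labels))
  if (!any(split) || all(split)) stop("split must contain both train and test rows")
  xtr <- features[split, , drop = FALSE]; ytr <- labels[split]
  xte <- features[!split, , drop = FALSE]; yte <- labels[!split]
  if (any(table(factor(ytr, levels = sort(unique(labels)))) == 0))
    stop("empty class in the training rows")
  K <- max(labels)
  hyper <- NULL; hyperTrace <- NULL
  set.seed(.deriveSeed(cfg$seed, cfg$method))
  pred <- switch(cfg$method,
    svm_ga = , svm_pso = {
      s <- if (cfg$method == "svm_ga") .gaSearch(xtr, ytr, cfg)
           else .psoSearch(xtr, ytr, cfg)
      hyper <- list(C = s$C, gamma = s$gamma); hyperTrace <- s$trace
      fit <- e1071::svm(xtr, factor(ytr), cost = s$C, gamma = s$gamma,
                        kernel = "radial", scale = FALSE)
      as.integer(as.character(predict(fit, xte)))
    },
    knn = as.integer(as.character(
      class::knn(xtr, xte, factor(ytr), k = min(cfg$k, nrow(xtr))))),
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, factor(ytr))
      as.integer(as.character(predict(fit, xte)))
    },
    ensemble = {
      fit <- randomForest::randomForest(xtr, factor(ytr), ntree = cfg$nTree)
      as.integer(as.character(predict(fit, xte)))
    })
  cm <- .confusion(yte, pred, K)
  structure(list(accuracy = sum(diag(cm)) / length(yte), confusion = cm,
                 method = cfg$method, hyper = hyper,
                 hyperTrace = hyperTrace,
                 splitHash = .hashObject(which(!split)),
                 nTrain = sum(split), nTest = sum(!split)),
            class = "TrainReport")
}
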