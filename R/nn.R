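# Minimal CPU network engine used by the WGAN and the residual classifier.
#
# A module is a plain list: type, params (named arrays), buffers, cfg,
# trainable flag, stage tag, children.  Forward passes return the updated
# module (batch-norm running stats), the output, and a cache consumed by
# the backward pass.  Tensors are (H, W, C, N) arrays; vector features are
# (F, N) matrices.

.mod <- function(type, params = list(), buffers = list(), cfg = list(),
                 children = list(), stage = NA_character_) {
  list(type = type, params = params, buffers = buffers, cfg = cfg,
       children = children, stage = stage, trainable = TRUE)
}

.heConv <- function(kh, kw, cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (kh * kw * cin))
  array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout))
}

nnConv <- function(kh, kw, cin, cout, stride = 1, pad = 0, bias = FALSE,
                   stage = NA_character_, initSd = NULL) {
  p <- list(W = .heConv(kh, kw, cin, cout, initSd))
  if (bias) p$b <- numeric(cout)
  .mod("conv", p, cfg = list(stride = stride, pad = pad), stage = stage)
}

# transposed convolution; weight dims (kh, kw, cout, cin)
nnConvT <- function(kh, kw, cin, cout, stride = 2, pad = 1, bias = TRUE,
                    stage = NA_character_, initSd = 0.02) {
  p <- list(W = array(rnorm(kh * kw * cout * cin, 0, initSd),
                      c(kh, kw, cout, cin)))
  if (bias) p$b <- numeric(cout)
  .mod("convT", p, cfg = list(stride = stride, pad = pad), stage = stage)
}

nnBatchNorm <- function(c, stage = NA_character_, momentum = 0.1,
                        eps = 1e-5) {
  .mod("bn", params = list(gamma = rep(1, c), beta = numeric(c)),
       buffers = list(rmean = numeric(c), rvar = rep(1, c)),
       cfg = list(momentum = momentum, eps = eps), stage = stage)
}

nnReLU <- function() .mod("relu")
nnLeakyReLU <- function(slope = 0.2) .mod("lrelu", cfg = list(slope = slope))
nnTanh01 <- function() .mod("tanh01")
nnMaxPool <- function(k, stride, pad = 0)
  .mod("maxpool", cfg = list(k = k, stride = stride, pad = pad))
nnGlobalAvgPool <- function() .mod("gap")
nnFlatten <- function() .mod("flatten")
nnReshape <- function(shape) .mod("reshape", cfg = list(shape = shape))
nnLinear <- function(nin, nout, stage = NA_character_, initSd = NULL) {
  if (is.null(initSd)) initSd <- sqrt(2 / nin)
  .mod("linear",
       params = list(W = matrix(rnorm(nout * nin, 0, initSd), nout, nin),
                     b = numeric(nout)), stage = stage)
}
nnSequential <- function(...) {
  ch <- list(...)
  if (length(ch) == 1 && is.null(ch[[1]]$type)) ch <- ch[[1]]
  .mod("seq", children = ch)
}

# residual block; kind "basic" (3x3, 3x3) or "bottleneck" (1x1, 3x3, 1x1 x4)
nnResBlock <- function(kind, cin, cmid, cout, stride, stage) {
  ch <- if (kind == "basic") list(
    conv1 = nnConv(3, 3, cin, cmid, stride, 1, stage = stage),
    bn1 = nnBatchNorm(cmid, stage),
    conv2 = nnConv(3, 3, cmid, cout, 1, 1, stage = stage),
    bn2 = nnBatchNorm(cout, stage))
  else list(
    conv1 = nnConv(1, 1, cin, cmid, stride, 0, stage = stage),
    bn1 = nnBatchNorm(cmid, stage),
    conv2 = nnConv(3, 3, cmid, cmid, 1, 1, stage = stage),
    bn2 = nnBatchNorm(cmid, stage),
    conv3 = nnConv(1, 1, cmid, cout, 1, 0, stage = stage),
    bn3 = nnBatchNorm(cout, stage))
  if (stride != 1 || cin != cout) {
    ch$downConv <- nnConv(1, 1, cin, cout, stride, 0, stage = stage)
    ch$downBn <- nnBatchNorm(cout, stage)
  }
  .mod("block", cfg = list(kind = kind), children = ch, stage = stage)
}

.chSum <- function(x) {
  d <- dim(x)
  rs <- rowSums(matrix(x, nrow = d[1] * d[2] * d[3]))
  colSums(matrix(rs, nrow = d[1] * d[2]))
}

# multiply per-channel vector into (H,W,C,N) array
.chMul <- function(x, v) {
  d <- dim(x)
  x * rep(v, each = d[1] * d[2])
}
.chAdd <- function(x, v) {
  d <- dim(x)
  x + rep(v, each = d[1] * d[2])
}

.fwd <- function(mod, x, training = TRUE) {
  switch(mod$type,
    conv = {
      d <- dim(x)
      wd <- dim(mod$params$W)
      b <- mod$params$b %||% numeric(0)
      # caching the im2col matrix for the filter gradient costs more in
      # allocation churn than the recompute saves; recompute instead
      keepK <- FALSE
      if (keepK) {
        r <- .conv2d_fwd_k(x, mod$params$W, b, mod$cfg$stride, mod$cfg$pad)
        list(mod = mod, out = r$out,
             cache = list(K = r$K, hin = d[1], win = d[2]))
      } else {
        out <- .conv2d_fwd(x, mod$params$W, b, mod$cfg$stride, mod$cfg$pad)
        list(mod = mod, out = out, cache = list(x = x, hin = d[1], win = d[2]))
      }
    },
    convT = {
      d <- dim(x); wd <- dim(mod$params$W); s <- mod$cfg$stride; p <- mod$cfg$pad
      ho <- (d[1] - 1) * s - 2 * p + wd[1]
      wo <- (d[2] - 1) * s - 2 * p + wd[2]
      out <- .conv2d_bwd_data(x, mod$params$W, s, p, ho, wo)
      if (!is.null(mod$params$b)) out <- .chAdd(out, mod$params$b)
      list(mod = mod, out = out, cache = list(x = x))
    },
    bn = {
      d <- dim(x); m <- d[1] * d[2] * d[4]
      calibrate <- identical(training, "calibrate")
      if (isTRUE(training) || calibrate) {
        r <- .bn_fwd(x, mod$params$gamma, mod$params$beta, mod$cfg$eps)
        ub <- if (m > 1) m / (m - 1) else 1
        if (calibrate) {
          # accumulate exact dataset statistics (finalized by the caller)
          mod$buffers$rmean <- mod$buffers$rmean + r$mu
          mod$buffers$rvar <- mod$buffers$rvar + r$var * ub
          mod$buffers$calibCount <- (mod$buffers$calibCount %||% 0) + 1
        } else {
          mom <- mod$cfg$momentum
          mod$buffers$rmean <- (1 - mom) * mod$buffers$rmean + mom * r$mu
          mod$buffers$rvar <- (1 - mom) * mod$buffers$rvar + mom * r$var * ub
        }
        return(list(mod = mod, out = r$out,
                    cache = list(xhat = r$xhat, invstd = r$invstd, m = m,
                                 training = TRUE)))
      }
      mu <- mod$buffers$rmean; v <- mod$buffers$rvar
      invstd <- 1 / sqrt(v + mod$cfg$eps)
      xhat <- .chMul(.chAdd(x, -mu), invstd)
      out <- .chAdd(.chMul(xhat, mod$params$gamma), mod$params$beta)
      list(mod = mod, out = out,
           cache = list(xhat = xhat, invstd = invstd, m = m,
                        training = FALSE))
    },
    relu = { out <- x * (x > 0); list(mod = mod, out = out, cache = list(mask = x > 0)) },
    lrelu = {
      s <- mod$cfg$slope
      scale <- s + (1 - s) * (x > 0)
      list(mod = mod, out = x * scale, cache = list(scale = scale))
    },
    tanh01 = { th <- tanh(x); list(mod = mod, out = (th + 1) / 2, cache = list(th = th)) },
    maxpool = {
      d <- dim(x)
      r <- .maxpool_fwd(x, mod$cfg$k, mod$cfg$stride, mod$cfg$pad)
      list(mod = mod, out = r$out,
           cache = list(argmax = r$argmax, hin = d[1], win = d[2]))
    },
    gap = {
      d <- dim(x)
      out <- matrix(colSums(matrix(x, nrow = d[1] * d[2])) / (d[1] * d[2]),
                    d[3], d[4])
      list(mod = mod, out = out, cache = list(d = d))
    },
    flatten = {
      d <- dim(x)
      out <- x; dim(out) <- c(prod(d[1:3]), d[4])
      list(mod = mod, out = out, cache = list(d = d))
    },
    reshape = {
      n <- ncol(x)
      out <- array(x, c(mod$cfg$shape, n))
      list(mod = mod, out = out, cache = list(f = nrow(x)))
    },
    linear = {
      out <- mod$params$W %*% x + mod$params$b
      list(mod = mod, out = out, cache = list(x = x))
    },
    seq = {
      caches <- vector("list", length(mod$children))
      for (i in seq_along(mod$children)) {
        r <- .fwd(mod$children[[i]], x, training)
        mod$children[[i]] <- r$mod
        x <- r$out
        caches[[i]] <- r$cache
      }
      list(mod = mod, out = x, cache = caches)
    },
    block = {
      ch <- mod$children; cc <- list()
      run <- function(name, inp) {
        r <- .fwd(ch[[name]], inp, training)
        ch[[name]] <<- r$mod; cc[[name]] <<- r$cache
        r$out
      }
      h <- run("conv1", x); h <- run("bn1", h)
      cc$m1 <- h > 0; h <- h * cc$m1
      h <- run("conv2", h); h <- run("bn2", h)
      if (mod$cfg$kind == "bottleneck") {
        cc$m2 <- h > 0; h <- h * cc$m2
        h <- run("conv3", h); h <- run("bn3", h)
      }
      sc <- if (!is.null(ch$downConv)) run("downBn", run("downConv", x)) else x
      y <- h + sc
      cc$mout <- y > 0
      mod$children <- ch
      list(mod = mod, out = y * cc$mout, cache = cc)
    },
    stop("unknown module type ", mod$type))
}

.bwd <- function(mod, cache, dout) {
  switch(mod$type,
    conv = {
      W <- mod$params$W; wd <- dim(W)
      g <- list(W = if (!is.null(cache$K))
                      .conv2d_bwd_filter_k(cache$K, dout, wd[1], wd[2], wd[3])
                    else .conv2d_bwd_filter(cache$x, dout, wd[1], wd[2],
                                            mod$cfg$stride, mod$cfg$pad))
      if (!is.null(mod$params$b)) g$b <- .chSum(dout)
      dx <- .conv2d_bwd_data(dout, W, mod$cfg$stride, mod$cfg$pad,
                             cache$hin, cache$win)
      list(dx = dx, grads = list(params = g))
    },
    convT = {
      W <- mod$params$W; wd <- dim(W)
      g <- list(W = .conv2d_bwd_filter(dout, cache$x, wd[1], wd[2],
                                       mod$cfg$stride, mod$cfg$pad))
      if (!is.null(mod$params$b)) g$b <- .chSum(dout)
      dx <- .conv2d_fwd(dout, W, numeric(0), mod$cfg$stride, mod$cfg$pad)
      list(dx = dx, grads = list(params = g))
    },
    bn = {
      if (cache$training) {
        r <- .bn_bwd(dout, cache$xhat, cache$invstd, mod$params$gamma)
        list(dx = r$dx,
             grads = list(params = list(gamma = r$dgamma, beta = r$dbeta)))
      } else {
        dgamma <- .chSum(dout * cache$xhat)
        dbeta <- .chSum(dout)
        dx <- .chMul(dout, mod$params$gamma * cache$invstd)
        list(dx = dx,
             grads = list(params = list(gamma = dgamma, beta = dbeta)))
      }
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    lrelu = list(dx = dout * cache$scale, grads = list()),
    tanh01 = list(dx = dout * (1 - cache$th^2) / 2, grads = list()),
    maxpool = list(dx = .maxpool_bwd(dout, cache$argmax, cache$hin, cache$win),
                   grads = list()),
    gap = {
      d <- cache$d
      dx <- array(rep(as.vector(dout) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx, grads = list())
    },
    flatten = { dim(dout) <- cache$d; list(dx = dout, grads = list()) },
    reshape = list(dx = matrix(dout, cache$f), grads = list()),
    linear = {
      g <- list(W = dout %*% t(cache$x), b = rowSums(dout))
      list(dx = t(mod$params$W) %*% dout, grads = list(params = g))
    },
    seq = {
      n <- length(mod$children)
      gch <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- .bwd(mod$children[[i]], cache[[i]], dout)
        dout <- r$dx
        gch[[i]] <- r$grads
      }
      list(dx = dout, grads = list(children = gch))
    },
    block = {
      ch <- mod$children; gch <- list()
      back <- function(name, d) {
        r <- .bwd(ch[[name]], cache[[name]], d)
        gch[[name]] <<- r$grads
        r$dx
      }
      dy <- dout * cache$mout
      # shortcut branch
      dsc <- if (!is.null(ch$downConv)) back("downConv", back("downBn", dy)) else dy
      # residual branch
      d <- dy
      if (mod$cfg$kind == "bottleneck") {
        d <- back("bn3", d); d <- back("conv3", d)
        d <- d * cache$m2
      }
      d <- back("bn2", d); d <- back("conv2", d)
      d <- d * cache$m1
      d <- back("bn1", d); d <- back("conv1", d)
      list(dx = d + dsc, grads = list(children = gch))
    },
    stop("unknown module type ", mod$type))
}

# walk a module and its gradients in parallel, applying fun(key, p, g) to
# every trainable parameter; returns the updated module
.applyGrads <- function(mod, grads, fun, path = "root", frozen = FALSE) {
  frozen <- frozen || !isTRUE(mod$trainable)
  if (!frozen && length(mod$params)) {
    for (nm in names(mod$params)) {
      g <- grads$params[[nm]]
      if (!is.null(g))
        mod$params[[nm]] <- fun(paste0(path, ".", nm), mod$params[[nm]], g)
    }
  }
  if (length(mod$children)) {
    idx <- if (is.null(names(mod$children))) seq_along(mod$children)
           else names(mod$children)
    for (i in idx) {
      gc_i <- grads$children[[i]]
      if (!is.null(gc_i))
        mod$children[[i]] <- .applyGrads(mod$children[[i]], gc_i, fun,
                                         paste0(path, ".", i), frozen)
    }
  }
  mod
}

# accumulate gradients elementwise across two gradient trees
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    keys <- union(names(a), names(b))
    if (is.null(names(a)) && is.null(names(b)))
      keys <- seq_len(max(length(a), length(b)))
    out <- if (is.null(names(a)) && is.null(names(b))) vector("list", length(keys)) else list()
    for (k in keys) out[[k]] <- .addGrads(a[[k]], b[[k]])
    return(out)
  }
  a + b
}

#' Create an optimizer for the network engine
#'
#' @param type \code{"adam"} or \code{"rmsprop"}
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer
#' @param alpha RMSprop smoothing constant
#' @return an optimizer environment consumed by \code{optStep}
#' @keywords internal
makeOptimizer <- function(type = c("adam", "rmsprop"), lr = 1e-4,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          alpha = 0.99, weightDecay = 0) {
  type <- match.arg(type)
  e <- new.env(parent = emptyenv())
  e$type <- type; e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2
  e$eps <- eps; e$alpha <- alpha; e$wd <- weightDecay
  e$t <- 0L; e$state <- list()
  e
}

optStep <- function(opt, mod, grads) {
  opt$t <- opt$t + 1L
  if (opt$type == "adam") {
    b1 <- opt$beta1; b2 <- opt$beta2; t <- opt$t
    corr <- sqrt(1 - b2^t) / (1 - b1^t)
    fun <- function(key, p, g) {
      s <- opt$state[[key]]
      if (is.null(s)) {
        s <- list(m = numeric(length(p)), v = numeric(length(p)))
        opt$state[[key]] <- s
      }
      # L2 decay on weight matrices only (not biases or norm parameters)
      if (opt$wd > 0 && endsWith(key, ".W")) g <- g + opt$wd * p
      # .adam_step updates the m/v buffers in place
      .adam_step(p, s$m, s$v, g, opt$lr, b1, b2, opt$eps, corr)
    }
  } else {
    fun <- function(key, p, g) {
      s <- opt$state[[key]]
      if (is.null(s)) {
        s <- numeric(length(p))
        opt$state[[key]] <- s
      }
      .rmsprop_step(p, s, g, opt$lr, opt$alpha, opt$eps)
    }
  }
  .applyGrads(mod, grads, fun)
}

# Batch-norm recalibration: after training, replace the exponentially
# smoothed running statistics with exact averages over the training data
# (forward passes in "calibrate" mode), which is far more reliable for the
# short training schedules of desk-scale runs.
.resetBnStats <- function(mod) {
  if (mod$type == "bn")
    mod$buffers <- list(rmean = 0 * mod$buffers$rmean,
                        rvar = 0 * mod$buffers$rvar, calibCount = 0)
  if (length(mod$children))
    mod$children <- lapply(mod$children, .resetBnStats)
  mod
}

.finalizeBnStats <- function(mod) {
  if (mod$type == "bn") {
    k <- mod$buffers$calibCount %||% 0
    if (k > 0)
      mod$buffers <- list(rmean = mod$buffers$rmean / k,
                          rvar = mod$buffers$rvar / k)
    else mod$buffers <- list(rmean = mod$buffers$rmean,
                             rvar = mod$buffers$rvar + 1)
  }
  if (length(mod$children))
    mod$children <- lapply(mod$children, .finalizeBnStats)
  mod
}

calibrateBatchNorm <- function(net, x, batchSize = 64) {
  net <- .resetBnStats(net)
  N <- dim(x)[4]
  for (b0 in seq(1, N, by = batchSize)) {
    idx <- b0:min(b0 + batchSize - 1, N)
    if (length(idx) < 2) next
    net <- .fwd(net, x[, , , idx, drop = FALSE], training = "calibrate")$mod
  }
  .finalizeBnStats(net)
}

# softmax cross-entropy on logits (K, N) with integer labels 1..K
softmaxCrossEntropy <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  idx <- cbind(labels, seq_len(N))
  pidx <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(pidx, 1e-300)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / N, probs = p)
}

# parameter census by stage; counts every parameter element
.paramCensus <- function(mod, frozen = FALSE, stage = NA_character_) {
  frozen <- frozen || !isTRUE(mod$trainable)
  if (!is.na(mod$stage)) stage <- mod$stage
  rows <- list()
  if (length(mod$params)) {
    n <- sum(vapply(mod$params, length, 0L))
    rows[[1]] <- data.frame(stage = stage %||% NA_character_,
                            trainable = !frozen, count = n)
  }
  for (ch in mod$children)
    rows <- c(rows, list(.paramCensus(ch, frozen, stage)))
  do.call(rbind, rows)
}

# set trainable = FALSE on every module tagged with one of the stages
.freezeStages <- function(mod, stages) {
  if (!is.na(mod$stage) && mod$stage %in% stages) mod$trainable <- FALSE
  if (length(mod$children))
    mod$children <- lapply(mod$children, .freezeStages, stages = stages)
  mod
}

# collect all parameter arrays (flat named list, for clip/serialize/compare)
.collectParams <- function(mod, path = "root", frozenOnly = FALSE,
                           frozen = FALSE) {
  frozen <- frozen || !isTRUE(mod$trainable)
  out <- list()
  if (length(mod$params) && (!frozenOnly || frozen)) {
    for (nm in names(mod$params))
      out[[paste0(path, ".", nm)]] <- mod$params[[nm]]
  }
  if (length(mod$children)) {
    idx <- if (is.null(names(mod$children))) seq_along(mod$children)
           else names(mod$children)
    for (i in idx)
      out <- c(out, .collectParams(mod$children[[i]], paste0(path, ".", i),
                                   frozenOnly, frozen))
  }
  out
}

# combine the parameters of two structurally identical modules with
# f(a, b) -> array; structure (cfg, buffers, flags) comes from `a`
.zipParams <- function(a, b, f) {
  if (length(a$params))
    for (nm in names(a$params)) a$params[[nm]] <- f(a$params[[nm]],
                                                    b$params[[nm]])
  if (length(a$children))
    for (i in seq_along(a$children))
      a$children[[i]] <- .zipParams(a$children[[i]], b$children[[i]], f)
  a
}

# transform every parameter in place with f(array) -> array
.mapParams <- function(mod, f) {
  if (length(mod$params)) mod$params <- lapply(mod$params, f)
  if (length(mod$children)) mod$children <- lapply(mod$children, .mapParams, f = f)
  mod
}
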