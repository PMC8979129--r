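# End-to-end orchestration: simulate -> invert -> image -> augment ->
# train -> compare, with reproducible run directories.

#' Assemble the run configuration
#'
#' Nested configuration of every stage with all sub-seeds derived
#' deterministically from one global seed.  The \code{"desk"} preset keeps
#' every stage CPU-friendly (32-pixel model input, bounded WGAN
#' iterations and epochs); \code{"full"} uses the study-scale settings
#' (224-pixel input, 3495 generated images per class).
#'
#' @param scale \code{"desk"} or \code{"full"}
#' @param seed global integer seed
#' @param concentrations concentration grid (default the 13 levels)
#' @param augment train the WGAN and augment the training set
#' @param depth residual network depth (18 or 152)
#' @param nFrozen frozen macro-layers (0..5)
#' @param ... overrides for individual fields of the nested configs
#'   (\code{sim}, \code{wgan}, \code{train} as named lists)
#' @return list of class \code{"RunConfig"}
#' @export
runConfig <- function(scale = c("desk", "full"), seed = 1L,
                      concentrations = thzConcentrations(),
                      augment = TRUE, depth = 18, nFrozen = 0, ...) {
  scale <- match.arg(scale)
  ov <- list(...)
  if (scale == "desk") {
    sim <- simConfig(specimensPerClass = 6, seed = .deriveSeed(seed, "sim"))
    wgan <- wganConfig(iterations = 300, perClassSamples = 24, side = 32,
                       batchSize = 8, baseChannels = 16,
                       seed = .deriveSeed(seed, "wgan"))
    train <- trainConfig(lr = 3e-4, batchSize = 32, epochs = 28,
                         lrDecay = 0.1, tailAverage = TRUE,
                         seed = .deriveSeed(seed, "train"))
    side <- 32
  } else {
    sim <- simConfig(seed = .deriveSeed(seed, "sim"))
    wgan <- wganConfig(iterations = 2000, perClassSamples = 3495, side = 64,
                       batchSize = 64, seed = .deriveSeed(seed, "wgan"))
    train <- trainConfig(seed = .deriveSeed(seed, "train"))
    side <- 224
  }
  for (nm in intersect(names(ov), c("sim", "wgan", "train")))
    for (f in names(ov[[nm]]))
      assign(nm, `[[<-`(get(nm), f, ov[[nm]][[f]]))
  structure(list(scale = scale, seed = as.integer(seed), sim = sim,
                 wgan = wgan, train = train, side = side,
                 concentrations = concentrations, augment = isTRUE(augment),
                 depth = depth, nFrozen = nFrozen),
            class = "RunConfig")
}

#' Invert a simulated dataset to per-specimen optical constants
#'
#' FFTs every reference/sample pair, extracts optical constants, averages
#' the replicates of each specimen, and crops to the analysis band.
#'
#' @param ds a \code{ThzDataset} from \code{\link{generateDataset}}
#' @param average average the replicates of each specimen (default TRUE);
#'   with FALSE every replicate yields its own spectrum (useful when data
#'   are deliberately scarce and each measurement must count as a sample)
#' @return list with \code{constants} (one \linkS4class{OpticalConstants}
#'   per specimen, or per record when \code{average = FALSE}) and
#'   \code{info} (data.frame: specimenId, classIndex, concentration,
#'   replicate)
#' @export
invertDataset <- function(ds, average = TRUE) {
  m <- ds$manifest
  band <- ds$config$band
  # crop each replicate to the band before averaging: out-of-band bins can
  # fall below the low-amplitude guard on some noise draws, and only the
  # in-band grid is guaranteed common to all replicates
  invOne <- function(r)
    cropBand(invertPair(ds$records[[r]]$sample, ds$records[[r]]$reference),
             band[1], band[2])
  if (average) {
    specs <- unique(m$specimenId)
    constants <- vector("list", length(specs))
    rows <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      rs <- which(m$specimenId == specs[i])
      constants[[i]] <- averageReplicates(lapply(rs, invOne))
      rows[[i]] <- data.frame(specimenId = specs[i],
                              classIndex = m$classIndex[rs[1]],
                              concentration = m$concentration[rs[1]],
                              replicate = NA_integer_)
    }
  } else {
    constants <- lapply(seq_len(nrow(m)), invOne)
    rows <- lapply(seq_len(nrow(m)), function(r)
      data.frame(specimenId = m$specimenId[r], classIndex = m$classIndex[r],
                 concentration = m$concentration[r],
                 replicate = m$replicate[r]))
  }
  list(constants = constants, info = do.call(rbind, rows))
}

#' Build outer-product images from inverted constants
#'
#' @param inv result of \code{\link{invertDataset}}
#' @return list of \linkS4class{SpectralImage} (source "measured")
#' @export
imagesFromConstants <- function(inv) {
  lapply(seq_along(inv$constants), function(i)
    outerImage(alphaCm(inv$constants[[i]]),
               label = inv$info$classIndex[i],
               concentration = inv$info$concentration[i],
               specimenId = inv$info$specimenId[i]))
}

#' Train per-class WGANs and generate augmentation images
#'
#' One independent WGAN per concentration class, trained only on that
#' class's measured training images (isolation asserted), generating
#' \code{cfg$perClassSamples} images per class.
#'
#' @param images measured training images (list of
#'   \linkS4class{SpectralImage})
#' @param cfg a \code{\link{wganConfig}}
#' @return list with \code{generated} (list of images) and \code{fits}
#' @export
augmentWithWgan <- function(images, cfg) {
  labs <- vapply(images, function(im) im@label, 0L)
  fits <- list(); generated <- list()
  for (cl in sort(unique(labs))) {
    cls <- images[labs == cl]
    stopifnot(all(vapply(cls, function(im) im@label, 0L) == cl))
    ccfg <- cfg
    ccfg$seed <- .deriveSeed(cfg$seed, paste0("class", cl))
    fit <- trainWgan(cls, ccfg)
    fits[[as.character(cl)]] <- fit
    generated <- c(generated,
                   generateSamples(fit, cfg$perClassSamples,
                                   seed = .deriveSeed(cfg$seed,
                                                      paste0("gen", cl))))
  }
  list(generated = generated, fits = fits)
}

#' Run the full pipeline
#'
#' Simulate the dataset, invert to optical constants, build images, split
#' at specimen level, optionally augment the training arm with per-class
#' WGAN samples, train the residual classifier, run every baseline on the
#' identical split, and write all artifacts and a summary to a run
#' directory.
#'
#' @param cfg a \code{\link{runConfig}}
#' @param dir output directory (default a temporary directory)
#' @param mix mixture preset (default \code{\link{carbendazimPreset}})
#' @param baselines character vector of baseline methods to run
#' @return list with \code{summary} (data.frame of method accuracies),
#'   \code{report} (deep-model TrainReport), \code{baselineReports},
#'   \code{dir}, \code{splitHash}
#' @export
runPipeline <- function(cfg, dir = tempfile("thzrun"),
                        mix = carbendazimPreset(),
                        baselines = c("svm_ga", "knn", "naive_bayes",
                                      "ensemble")) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(configHash = .hashObject(unclass(cfg)), stages = list())
  stamp <- function(stage, ...) {
    prov$stages[[stage]] <<- list(..., done = TRUE)
  }
  ds <- generateDataset(mix, cfg$sim, cfg$concentrations)
  write.csv(ds$manifest, file.path(dir, "dataset_manifest.csv"),
            row.names = FALSE)
  stamp("simulate", records = nrow(ds$manifest))
  inv <- invertDataset(ds)
  dir.create(file.path(dir, "constants"), showWarnings = FALSE)
  for (i in seq_along(inv$constants))
    writeOpticalConstants(inv$constants[[i]],
                          file.path(dir, "constants",
                                    paste0(inv$info$specimenId[i], ".csv")))
  stamp("invert", specimens = length(inv$constants))
  images <- imagesFromConstants(inv)
  writeSpectralImages(images, file.path(dir, "images"))
  stamp("image", images = length(images))

  labs <- vapply(images, function(im) im@label, 0L)
  specs <- vapply(images, function(im) im@specimenId, "")
  split <- splitSpecimens(specs, labs, trainFrac = 0.8,
                          seed = .deriveSeed(cfg$seed, "split"))
  trainImgs <- images[split$train]
  testImgs <- images[!split$train]
  write.csv(split$assignment, file.path(dir, "split.csv"), row.names = FALSE)

  if (cfg$augment) {
    aug <- augmentWithWgan(trainImgs, cfg$wgan)
    trainImgs <- c(trainImgs, aug$generated)
    stamp("augment", generated = length(aug$generated))
  }
  trainSet <- imageSet(trainImgs, side = cfg$side)
  testSet <- imageSet(testImgs, side = cfg$side)
  spec <- resnetSpec(cfg$depth, headClasses = length(cfg$concentrations))
  tcfg <- cfg$train
  tcfg$augmentation <- if (cfg$augment) "wgan" else "none"
  report <- trainClassifier(trainSet, testSet, spec,
                            freezePlan(cfg$nFrozen), tcfg)
  attr(report, "net") <- NULL
  stamp("train", accuracy = report$accuracy)

  # baselines on the flattened cropped absorption vectors, same split
  feats <- t(vapply(inv$constants, alphaCm,
                    numeric(length(freqTHz(inv$constants[[1]])))))
  blabels <- inv$info$classIndex + 1L
  bsplit <- inv$info$specimenId %in% specs[split$train]
  baselineReports <- list()
  for (m in baselines) {
    bcfg <- baselineConfig(m, popSize = 8, generations = 5, particles = 8,
                           psoIters = 5,
                           seed = .deriveSeed(cfg$seed, paste0("bl_", m)))
    baselineReports[[m]] <- runBaseline(feats, blabels, bsplit, bcfg)
  }
  stamp("baseline", methods = baselines)

  deepName <- sprintf("%sResNet_%d", if (cfg$augment) "WGAN-" else "",
                      cfg$depth)
  summary <- data.frame(
    method = c(deepName, names(baselineReports)),
    accuracy = c(report$accuracy,
                 vapply(baselineReports, `[[`, 0, "accuracy")))
  write.csv(summary, file.path(dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(summary = summary, provenance = prov,
                            splitHash = split$hash),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  list(summary = summary, report = report,
       baselineReports = baselineReports, dir = dir,
       splitHash = split$hash)
}
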