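## End-to-end orchestration of the four segmentation methods:
##   cv          plain Chan-Vese, cold start per frame
##   tcv         temporally linked Chan-Vese
##   stdiff      standardization -> spatio-temporal diffusion -> Parzen edge
##               map -> watershed -> threshold/likelihood classification
##   stdiff_tcv  stdiff on every k-th frame to (re)initialize a temporally
##               linked Chan-Vese refinement of all frames
## All methods operate on standardized frames (0-255), rescaled to [0,1]
## for the level-set stages.

#' Default pipeline configuration
#'
#' Nested per-module settings with the package defaults. Any subset can be
#' overridden via `...` (named nested lists) or a YAML file through
#' [readSegConfig()].
#'
#' @param ... named nested lists overriding individual entries, e.g.
#'   `diffusion = list(k = 20)`
#' @return nested configuration list of class `SegConfig`
#' @export
segConfig <- function(...) {
  cfg <- list(
    standardization = list(nBins = 256L, irefMode = "quantile",
                           irefQuantile = 0.8,
                           irefValue = NULL, lminMode = "window",
                           medianFilter = FALSE),
    diffusion = list(lambdaS = 0.2, tsRatio = 1, k = 15, nIter = 10L,
                     gForm = "rational",
                     temporalTerm = "diffusivity_weighted"),
    edge = list(h = 8, window = 7L),
    delineation = list(useLikelihoods = TRUE,
                       areaMean = c(NA, NA), areaSd = c(NA, NA),
                       intensityMean = c(NA, NA), intensitySd = c(NA, NA),
                       priors = c(0.5, 0.5), hMinima = 0,
                       minSelfEstimate = 3L),
    levelset = list(mu = 0.05, nu = 0, lambda1 = 1, lambda2 = 1,
                    epsilon = 1, dt = 5, tol = 1e-4, maxIter = 500L,
                    refineMaxIter = 60L, refineNu = NULL,
                    reinitEvery = 20L,
                    initMode = "intensity", reinitOnHandoff = TRUE),
    kModulo = 5L
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], ov[[nm]])
    else cfg[[nm]] <- ov[[nm]]
  }
  class(cfg) <- "SegConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys keep their defaults from [segConfig()].
#'
#' @param path YAML file with nested per-module sections
#' @return a `SegConfig`
#' @export
readSegConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(segConfig, yaml::read_yaml(path))
}

#' Signed field from a binary mask
#'
#' Either a plain +1/-1 indicator or an approximate signed Euclidean
#' distance (positive inside), used to hand a delineation result to the
#' level-set refinement.
#'
#' @param mask logical or 0/1 matrix
#' @param redistance compute signed distances instead of +/-1
#' @return numeric matrix
#' @export
maskToPhi <- function(mask, redistance = TRUE) {
  m <- mask > 0
  if (all(m) || !any(m))      # constant mask: distances are undefined
    return(matrix(if (all(m)) 1 else -1, nrow(mask), ncol(mask)))
  if (!redistance) return(matrix(ifelse(m, 1, -1), nrow(mask)))
  dIn <- EBImage::imageData(EBImage::distmap(EBImage::as.Image(m * 1)))
  dOut <- EBImage::imageData(EBImage::distmap(EBImage::as.Image((!m) * 1)))
  dIn - dOut
}

## standardized triplet (plus window metadata) for the centre frame t
.standardizedWindow <- function(sequence, model, t, scfg) {
  tr <- frameTriplet(sequence, t)
  if (isTRUE(scfg$medianFilter)) {
    mf <- function(m) EBImage::imageData(
      EBImage::medianFilter(EBImage::as.Image(m / 65536), size = 1L)) * 65536
    tr <- new("FrameTriplet", prev = mf(tr@prev), center = mf(tr@center),
              nxt = mf(tr@nxt), paddedPrev = tr@paddedPrev,
              paddedNext = tr@paddedNext, frameIndex = tr@frameIndex)
  }
  standardizeTriplet(tr, model, lminMode = scfg$lminMode)
}

## one frame of the diffusion->edge->watershed->classification chain
.stdiffFrame <- function(std, cfg) {
  dp <- diffusionParams(lambdaS = cfg$diffusion$lambdaS,
                        tsRatio = cfg$diffusion$tsRatio,
                        k = cfg$diffusion$k, nIter = cfg$diffusion$nIter,
                        gForm = cfg$diffusion$gForm,
                        temporalTerm = cfg$diffusion$temporalTerm)
  dif <- diffuseTriplet(std$triplet, dp)
  em <- edgeIndexMap(dif@center, h = cfg$edge$h, window = cfg$edge$window)
  labels <- watershedRegions(em, hMinima = cfg$delineation$hMinima)
  dl <- cfg$delineation
  rm_ <- regionModel(tRef = std$tRef, areaMean = dl$areaMean,
                     areaSd = dl$areaSd, intensityMean = dl$intensityMean,
                     intensitySd = dl$intensitySd, priors = dl$priors,
                     useLikelihoods = FALSE)
  mask0 <- classifyRegions(labels, dif@center, rm_)
  if (isTRUE(dl$useLikelihoods)) {
    ## with explicit class parameters, apply the MAP filter directly; with
    ## none given, estimate the cell class from the threshold candidates
    ## (needs a minimum number of candidate regions for a meaningful fit)
    explicit <- any(!is.na(c(dl$areaMean, dl$areaSd, dl$intensityMean,
                             dl$intensitySd)))
    cand <- sort(unique(mask0[mask0 > 0L]))
    if (explicit) {
      rm_$useLikelihoods <- TRUE
      mask0 <- classifyRegions(labels, dif@center, rm_)
    } else if (length(cand) >= dl$minSelfEstimate) {
      ## fit both classes from the current partition: cells from the
      ## threshold candidates, background from the remaining basins
      rmeans <- vapply(split(as.vector(dif@center), as.vector(labels)),
                       mean, numeric(1))
      rareas <- tabulate(labels, nbins = max(labels))
      candRegions <- sort(unique(labels[mask0 > 0L]))
      bgRegions <- setdiff(seq_len(max(labels)), candRegions)
      nm <- as.character(candRegions); bm <- as.character(bgRegions)
      guard <- function(s, lo) max(s, lo, na.rm = TRUE)
      am <- mean(rareas[candRegions])
      asd <- guard(sd(rareas[candRegions]), 0.25 * am)
      im <- mean(rmeans[nm]); isd <- guard(sd(rmeans[nm]), 5)
      abm <- mean(rareas[bgRegions])
      absd <- guard(sd(rareas[bgRegions]), 0.25 * abm)
      ibm <- mean(rmeans[bm]); ibsd <- guard(sd(rmeans[bm]), 5)
      rm2 <- regionModel(tRef = std$tRef, areaMean = c(abm, am),
                         areaSd = c(absd, asd),
                         intensityMean = c(ibm, im),
                         intensitySd = c(ibsd, isd), priors = dl$priors,
                         useLikelihoods = TRUE)
      mask0 <- classifyRegions(labels, dif@center, rm2)
    }
  }
  list(mask = mask0, edgeMap = em, diffused = dif@center, tRef = std$tRef)
}

#' Segment a time-lapse sequence
#'
#' Runs one of the four methods over the whole sequence and returns
#' per-frame instance masks. All methods standardize intensities first;
#' the level-set stages run on frames rescaled to \[0,1\].
#'
#' @param sequence a [FrameSequence-class]
#' @param method "stdiff_tcv" (default), "stdiff", "tcv" or "cv"
#' @param config a `SegConfig` from [segConfig()] / [readSegConfig()]
#' @param verbose print per-frame progress
#' @return list with `masks` (instance label matrices, one per frame),
#'   `method`, and `details` (per-frame tRef, level-set iteration counts)
#' @export
segmentSequence <- function(sequence,
                            method = c("stdiff_tcv", "stdiff", "tcv", "cv"),
                            config = segConfig(), verbose = FALSE) {
  stopifnot(is(sequence, "FrameSequence"))
  method <- match.arg(method)
  n <- nFrames(sequence)
  model <- learnStandardization(
    sequence, iRefValue = config$standardization$irefValue,
    iRefMode = config$standardization$irefMode,
    iRefQuantile = config$standardization$irefQuantile,
    nBins = config$standardization$nBins)
  ## standardized centre frames (all methods consume them)
  stds <- lapply(seq_len(n) - 1L, function(t)
    .standardizedWindow(sequence, model, t, config$standardization))
  centers <- lapply(stds, function(s) s$triplet@center)
  lw <- config$levelset
  ## the refinement stage may use its own area pressure: a constant
  ## inward force rests the contour higher on a blob's intensity shoulder
  ## (trimming the dim halo) without ever expelling a strongly fitting
  ## bright core, which an inflated lambda1 would
  refNu <- if (is.null(lw$refineNu)) lw$nu else lw$refineNu
  wRefine <- cvWeights(mu = lw$mu, nu = refNu, lambda1 = lw$lambda1,
                       lambda2 = lw$lambda2, epsilon = lw$epsilon,
                       dt = lw$dt, tol = lw$tol,
                       maxIter = lw$refineMaxIter,
                       reinitEvery = lw$reinitEvery)
  wFull <- cvWeights(mu = lw$mu, nu = lw$nu, lambda1 = lw$lambda1,
                     lambda2 = lw$lambda2, epsilon = lw$epsilon,
                     dt = lw$dt, tol = lw$tol, maxIter = lw$maxIter,
                     reinitEvery = lw$reinitEvery)
  masks <- vector("list", n)
  details <- list(tRef = vapply(stds, `[[`, numeric(1), "tRef"),
                  iFinal = rep(NA_integer_, n))
  if (method == "cv" || method == "tcv") {
    ph <- initialPhi(frameDims(sequence), mode = lw$initMode,
                     image = centers[[1L]] / 255)
    for (t in seq_len(n)) {
      img <- centers[[t]] / 255
      init <- if (method == "cv") initialPhi(frameDims(sequence),
                                             mode = lw$initMode,
                                             image = img) else ph
      fld <- tryCatch(cvEvolve(init, img, wFull),
                      error = function(e)
                        stop("frame ", t - 1L, ": ", conditionMessage(e)))
      masks[[t]] <- .label8(fld@phi >= 0)
      details$iFinal[t] <- fld@iFinal
      ph <- fld@phi
      if (verbose) message("frame ", t - 1L, ": iFinal = ", fld@iFinal)
    }
  } else if (method == "stdiff") {
    for (t in seq_len(n)) {
      res <- tryCatch(.stdiffFrame(stds[[t]], config),
                      error = function(e)
                        stop("frame ", t - 1L, ": ", conditionMessage(e)))
      masks[[t]] <- res$mask
      if (verbose) message("frame ", t - 1L, ": ",
                           max(res$mask), " instance(s)")
    }
  } else {  # stdiff_tcv
    k <- max(1L, as.integer(config$kModulo))
    ph <- NULL
    for (t in seq_len(n)) {
      if ((t - 1L) %% k == 0L || is.null(ph)) {
        res <- tryCatch(.stdiffFrame(stds[[t]], config),
                        error = function(e)
                          stop("frame ", t - 1L, ": ", conditionMessage(e)))
        ph <- maskToPhi(res$mask, redistance = lw$reinitOnHandoff)
      }
      img <- centers[[t]] / 255
      fld <- tryCatch(cvEvolve(ph, img, wRefine),
                      error = function(e)
                        stop("frame ", t - 1L, ": ", conditionMessage(e)))
      masks[[t]] <- .label8(fld@phi >= 0)
      details$iFinal[t] <- fld@iFinal
      ph <- fld@phi   # exact temporal carry-over
      if (verbose) message("frame ", t - 1L, ": iFinal = ", fld@iFinal,
                           ", ", max(masks[[t]]), " instance(s)")
    }
  }
  list(masks = masks, method = method, details = details)
}
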