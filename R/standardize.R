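## Frame intensity standardization by histogram transformation.
##
## Training: pool all frames of the sequence, build the empirical CDF F_AF
## and record the cumulative probability F_AF(I_ref) at a reference
## background-threshold intensity I_ref. Testing: for each three-frame
## window, find the intensity I_test whose window CDF value is closest to
## F_AF(I_ref), then map every pixel by two affine transforms
##   T1(I) = (I_ref - G_Min)/(I_test - L_Min) * (I - G_Min) + G_Min
##   T2(I) = 255 * (I - G_Min) / (G_Max - G_Min)
## so all windows end up on a common [0, 255] scale with backgrounds of the
## same order of magnitude.

#' Empirical CDF over equal-width bins
#'
#' Histogram-based cumulative distribution over `nBins` equal-width bins on
#' `range`. Bins are right-closed; out-of-range values are clipped into the
#' end bins.
#'
#' @param pixels numeric vector of intensities
#' @param nBins number of bins (default 256)
#' @param range c(lo, hi) intensity range covered by the bins
#' @return list with `binEdges` (length nBins+1), `binMids`, `cdf`
#'   (nondecreasing, ends at 1)
#' @export
empiricalCDF <- function(pixels, nBins = 256L, range = NULL) {
  if (length(pixels) == 0L) stop("empty pixel collection")
  if (is.null(range)) range <- c(min(pixels), max(pixels))
  lo <- range[1L]; hi <- range[2L]
  if (!(lo < hi)) stop("degenerate range: lo must be < hi")
  nBins <- as.integer(nBins)
  edges <- seq(lo, hi, length.out = nBins + 1L)
  idx <- findInterval(pixels, edges, left.open = TRUE, all.inside = TRUE)
  ## findInterval with left.open gives right-closed bins (lo excluded from
  ## bin 1 only at exactly lo; all.inside clips out-of-range into end bins)
  counts <- tabulate(idx, nbins = nBins)
  cdf <- cumsum(counts) / length(pixels)
  list(binEdges = edges,
       binMids = (edges[-1L] + edges[-(nBins + 1L)]) / 2,
       cdf = cdf)
}

.cdfAt <- function(cdfTable, x) {
  ## cumulative probability of the bin containing x (right-closed bins)
  edges <- cdfTable$binEdges
  n <- length(cdfTable$cdf)
  i <- findInterval(x, edges, left.open = TRUE, all.inside = TRUE)
  cdfTable$cdf[pmin(pmax(i, 1L), n)]
}

#' Learn the global intensity-standardization model
#'
#' Pools every pixel of the sequence, builds the all-frames CDF on
#' \[globalMin, globalMax\] and evaluates it at the reference
#' background-threshold intensity. `iRef` marks the tail of the background
#' intensity distribution; if not given explicitly it is taken at a
#' configurable quantile of the pooled intensities (default 0.8).
#'
#' @param sequence a [FrameSequence-class]
#' @param iRefValue explicit reference intensity (overrides `iRefMode`)
#' @param iRefMode "quantile" places the reference at `iRefQuantile` of the
#'   pooled intensities (the tail of the background distribution, keeping
#'   dim moving cells above threshold); "otsu" places it at the Otsu
#'   cell/background split of the pooled histogram (tight delineations on
#'   well-contrasted data)
#' @param iRefQuantile pooled-intensity quantile for the quantile mode
#' @param nBins histogram bins (default 256)
#' @return a [StandardizationModel-class]
#' @export
learnStandardization <- function(sequence, iRefValue = NULL,
                                 iRefMode = c("quantile", "otsu"),
                                 iRefQuantile = 0.8, nBins = 256L) {
  stopifnot(is(sequence, "FrameSequence"))
  iRefMode <- match.arg(iRefMode)
  px <- unlist(frames(sequence), use.names = FALSE)
  gr <- globalRange(sequence)
  cdf <- empiricalCDF(px, nBins = nBins, range = gr)
  iRef <- if (!is.null(iRefValue)) {
    iRefValue
  } else if (iRefMode == "otsu") {
    EBImage::otsu(EBImage::as.Image(matrix((px - gr[1L]) / diff(gr),
                                           ncol = 1L)),
                  range = c(0, 1), levels = as.integer(nBins)) *
      diff(gr) + gr[1L]
  } else {
    unname(quantile(px, iRefQuantile, type = 7))
  }
  if (iRef < gr[1L] || iRef > gr[2L])
    stop("iRef outside the global intensity range")
  fRef <- .cdfAt(cdf, iRef)
  new("StandardizationModel", iRef = iRef, fRef = fRef,
      gMin = gr[1L], gMax = gr[2L], nBins = as.integer(nBins), cdf = cdf)
}

#' Find the window intensity matching a reference cumulative probability
#'
#' Returns the bin-centre intensity minimizing |F_window(I) - fRef| over
#' the bins that contain observations (the argmin runs over the window's
#' pixel intensities, so empty bins are not candidates); ties are broken
#' by the smallest intensity.
#'
#' @param windowCDF a CDF table from [empiricalCDF()]
#' @param fRef target cumulative probability in \[0,1\]
#' @return matched intensity (a bin centre)
#' @export
findITest <- function(windowCDF, fRef) {
  stopifnot(fRef >= 0, fRef <= 1)
  mass <- diff(c(0, windowCDF$cdf))
  d <- abs(windowCDF$cdf - fRef)
  d[mass <= 0] <- Inf
  windowCDF$binMids[which.min(d)]   # which.min takes the first (smallest) tie
}

#' Standardize a three-frame window against the learned model
#'
#' Builds the window CDF over the global range, matches `iTest` to the
#' model's reference probability, applies T1 then T2 to every pixel of all
#' three frames and clips to \[0, 255\]. Output stays floating point.
#'
#' @param triplet a [FrameTriplet-class]
#' @param model a [StandardizationModel-class] learned on the same sequence
#' @param lminMode "window" uses the minimum over the three frames for
#'   L_Min; "global" uses the sequence minimum
#' @return list with `triplet` (standardized [FrameTriplet-class]), `iTest`,
#'   `lMin`, and `tRef`: the reference threshold on the standardized scale,
#'   T2(iRef). The matching construction sends iTest to iRef under T1 (when
#'   lMin equals the global minimum), so the window's cumulative
#'   probability at tRef approximates the model's fRef.
#' @export
standardizeTriplet <- function(triplet, model,
                               lminMode = c("window", "global")) {
  stopifnot(is(triplet, "FrameTriplet"), is(model, "StandardizationModel"))
  lminMode <- match.arg(lminMode)
  px <- c(triplet@prev, triplet@center, triplet@nxt)
  wcdf <- empiricalCDF(px, nBins = model@nBins,
                       range = c(model@gMin, model@gMax))
  iTest <- findITest(wcdf, model@fRef)
  lMin <- if (lminMode == "window") min(px) else model@gMin
  if (abs(iTest - lMin) < .Machine$double.eps * 256)
    stop("degenerate window contrast (iTest equals lMin)")
  tmap <- function(I) {
    t1 <- (model@iRef - model@gMin) / (iTest - lMin) * (I - model@gMin) +
      model@gMin
    t2 <- 255 * (t1 - model@gMin) / (model@gMax - model@gMin)
    pmin(pmax(t2, 0), 255)
  }
  out <- new("FrameTriplet",
             prev = matrix(tmap(triplet@prev), nrow(triplet@prev)),
             center = matrix(tmap(triplet@center), nrow(triplet@center)),
             nxt = matrix(tmap(triplet@nxt), nrow(triplet@nxt)),
             paddedPrev = triplet@paddedPrev,
             paddedNext = triplet@paddedNext,
             frameIndex = triplet@frameIndex)
  tRef <- 255 * (model@iRef - model@gMin) / (model@gMax - model@gMin)
  list(triplet = out, iTest = iTest, lMin = lMin,
       tRef = min(max(tRef, 0), 255))
}
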