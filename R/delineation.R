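## Cell delineation: the edge-occurrence map is read as a topographic
## surface (valleys = homogeneous areas, peaks = discontinuities). The
## inverted surface is flooded from its regional minima by the watershed
## transform; every basin becomes a candidate region. Regions are then
## classified into cell/background by comparing their mean intensity with
## the standardized reference threshold T(I_ref), optionally filtered by
## Gaussian area/intensity likelihoods, and adjacent cell regions are
## merged into instances.

## 8-connected labelling of a logical mask by iterative min-label
## propagation (converges in at most the component diameter).
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- matrix(seq_along(mask), nrow(mask))
  lab[mask] <- idx[mask]
  repeat {
    nb <- lab
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      s <- .shift(lab, di, dj)
      upd <- mask & s > 0L & (nb == 0L | s < nb)
      nb[upd] <- s[upd]
    }
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  ids <- sort(unique(lab[lab > 0L]))
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask] <- match(lab[mask], ids)
  out
}

#' Watershed regions of an edge-occurrence map
#'
#' Inverts the stochastic map (so homogeneous valleys become peaks), floods
#' from the regional minima of the original surface and partitions the
#' frame into basins. Every pixel is assigned; labels are contiguous
#' 1..nRegions.
#'
#' @param edgeMap an [EdgeMap-class] (or numeric matrix in \[0,1\])
#' @param hMinima minima-depth tolerance passed to the flooding: minima
#'   shallower than this are merged with their neighbours (default 0)
#' @return integer matrix of region labels, with attribute `nRegions`
#' @export
watershedRegions <- function(edgeMap, hMinima = 0) {
  v <- if (is(edgeMap, "EdgeMap")) values2d(edgeMap) else edgeMap
  stopifnot(is.matrix(v))
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    stop("edge map values must lie in [0, 1]")
  ## EBImage floods from local maxima of its input and treats values <= 0
  ## as background, so feed it the positive-shifted inverted map.
  surf <- (1 - v) + 0.01
  w <- EBImage::watershed(EBImage::as.Image(surf), tolerance = hMinima,
                          ext = 1)
  lab <- EBImage::imageData(w)
  storage.mode(lab) <- "integer"
  ## unassigned pixels cannot occur (surf > 0 everywhere), but relabel to
  ## contiguous ids for the partition contract
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0L]
  out <- matrix(match(lab, ids), nrow(lab))
  storage.mode(out) <- "integer"
  attr(out, "nRegions") <- length(ids)
  out
}

#' Region classification model
#'
#' Gaussian class-conditional models p(area|c) and p(I|c) for the two
#' classes background/cell with priors, used as an optional filter on top
#' of the T(I_ref) threshold rule. Means/sds of NA disable the
#' corresponding factor.
#'
#' @param tRef standardized reference threshold T(I_ref)
#' @param areaMean,areaSd Gaussian area model per class,
#'   c(background, cell)
#' @param intensityMean,intensitySd Gaussian intensity model per class
#' @param priors class priors c(background, cell), summing to 1
#' @param useLikelihoods logical, apply the MAP filter
#' @return validated list of class `RegionModel`
#' @export
regionModel <- function(tRef, areaMean = c(NA, NA), areaSd = c(NA, NA),
                        intensityMean = c(NA, NA), intensitySd = c(NA, NA),
                        priors = c(0.5, 0.5), useLikelihoods = FALSE) {
  if (useLikelihoods) {
    if (any(!is.na(areaSd) & areaSd <= 0) ||
        any(!is.na(intensitySd) & intensitySd <= 0))
      stop("class model sds must be positive")
    if (abs(sum(priors) - 1) > 1e-9) stop("priors must sum to 1")
  }
  structure(list(tRef = tRef, areaMean = areaMean, areaSd = areaSd,
                 intensityMean = intensityMean, intensitySd = intensitySd,
                 priors = priors, useLikelihoods = useLikelihoods),
            class = "RegionModel")
}

## Gaussian MAP log scores over the two classes for one region. A factor
## (area or intensity) modeled in both classes enters as a proper density
## comparison; a factor modeled in a single class acts as a z-score gate:
## |z| > 3 vetoes that class (how speck/giant artifacts are rejected when
## only cell-class priors are configured).
.classScores <- function(area, intensity, model, zCut = 3) {
  s <- log(model$priors)
  for (f in list(c(area, 1), c(intensity, 2))) {
    x <- f[1L]
    mns <- if (f[2L] == 1) model$areaMean else model$intensityMean
    sds <- if (f[2L] == 1) model$areaSd else model$intensitySd
    has <- !is.na(mns)
    if (all(has)) {
      s <- s + dnorm(x, mns, sds, log = TRUE)
    } else if (any(has)) {
      cls <- which(has)
      if (abs((x - mns[cls]) / sds[cls]) > zCut) s[cls] <- -Inf
    }
  }
  s
}

#' Classify watershed regions and merge adjacent cells into instances
#'
#' A region is foreground when its mean intensity exceeds the standardized
#' reference threshold `tRef`; with `useLikelihoods` the Gaussian MAP rule
#' over area and intensity must additionally prefer the cell class.
#' Adjacent (8-connected) foreground regions are merged into one instance
#' each.
#'
#' @param labels watershed label matrix from [watershedRegions()]
#' @param frame standardized intensity frame (same shape)
#' @param model a `RegionModel` from [regionModel()]
#' @return integer instance label mask (0 = background)
#' @export
classifyRegions <- function(labels, frame, model) {
  stopifnot(identical(dim(labels), dim(frame)),
            inherits(model, "RegionModel"))
  nr <- max(labels)
  if (nr < 1L) stop("empty region set")
  means <- vapply(split(as.vector(frame), as.vector(labels)), mean,
                  numeric(1))
  areas <- tabulate(labels, nbins = nr)
  fg <- means[as.character(seq_len(nr))] > model$tRef
  if (model$useLikelihoods) {
    for (rg in which(fg)) {
      sc <- .classScores(areas[rg], means[as.character(rg)], model)
      if (sc[2L] < sc[1L]) fg[rg] <- FALSE
    }
  }
  mask <- matrix(fg[labels], nrow(labels))
  mask[is.na(mask)] <- FALSE
  .label8(mask)
}
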