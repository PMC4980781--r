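## Coupled spatio-temporal nonlinear diffusion over a three-frame window,
## solved by explicit finite differences. Spatial fluxes follow the
## Perona-Malik scheme with the diffusivity evaluated at the gradient
## magnitude of shifted positions; temporal fluxes couple the centre frame
## to both neighbours (PF = I_{t-1} - I_t, NF = I_{t+1} - I_t) and the
## neighbour frames back to the centre with a factor -2. Spatial boundaries
## use replicate padding (zero gradient).

#' Edge-stopping diffusivity function
#'
#' The rational form 1/(1 + x^2/k^2) favours region-oriented smoothing; the
#' exponential form exp(-x^2/k^2) favours high-contrast edges. Both equal 1
#' at x = 0 and decrease monotonically.
#'
#' @param x gradient magnitude(s), nonnegative
#' @param k conductance parameter (> 0): the contrast scale separating
#'   gradients treated as noise (diffused) from edges (preserved)
#' @param form "rational" or "exponential"
#' @return diffusivity value(s) in (0, 1]
#' @examples
#' diffusivity(0, 10)            # 1
#' diffusivity(10, 10)           # 0.5
#' diffusivity(10, 10, "exponential")  # exp(-1)
#' @export
diffusivity <- function(x, k, form = c("rational", "exponential")) {
  form <- match.arg(form)
  if (k <= 0) stop("conductance k must be positive")
  switch(form,
         rational = 1 / (1 + (x / k)^2),
         exponential = exp(-(x / k)^2))
}

#' Diffusion solver parameters
#'
#' @param lambdaS spatial step, in (0, 0.25] for explicit stability
#' @param tsRatio ratio of temporal to spatial step: lambdaT =
#'   tsRatio * lambdaS (the previous/next-frame steps equal lambdaT)
#' @param k conductance parameter on the standardized 0-255 scale
#' @param nIter number of explicit scale steps
#' @param gForm diffusivity form, "rational" or "exponential"
#' @param temporalTerm "diffusivity_weighted" weights the temporal
#'   differences by g(|PF|), g(|NF|) (preserves temporal discontinuities);
#'   "literal_gradmag" multiplies them by the spatial gradient magnitude of
#'   the neighbour frame instead
#' @return validated parameter list of class `DiffusionParams`
#' @export
diffusionParams <- function(lambdaS = 0.2, tsRatio = 1, k = 15,
                            nIter = 10L,
                            gForm = c("rational", "exponential"),
                            temporalTerm = c("diffusivity_weighted",
                                             "literal_gradmag")) {
  gForm <- match.arg(gForm)
  temporalTerm <- match.arg(temporalTerm)
  if (lambdaS <= 0 || lambdaS > 0.25)
    stop("lambdaS must lie in (0, 0.25] (explicit 4-neighbour stability)")
  if (tsRatio < 0) stop("tsRatio must be nonnegative")
  if (k <= 0) stop("conductance k must be positive")
  if (nIter < 1L) stop("nIter must be >= 1")
  structure(list(lambdaS = lambdaS, tsRatio = tsRatio, k = k,
                 nIter = as.integer(nIter), gForm = gForm,
                 temporalTerm = temporalTerm),
            class = "DiffusionParams")
}

## shift a matrix by (di, dj) with replicate padding
.shift <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

## central-difference gradient magnitude with replicate padding
.gradMag <- function(m) {
  gx <- (.shift(m, 1L, 0L) - .shift(m, -1L, 0L)) / 2
  gy <- (.shift(m, 0L, 1L) - .shift(m, 0L, -1L)) / 2
  sqrt(gx^2 + gy^2)
}

## replicate-pad by one pixel on every side
.pad1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
}

## One spatial Perona-Malik flux term: sum of g(neighbour grad mag) * diff.
## As printed in the update equations the North difference (toward i-1) is
## weighted by g at i+1, the South difference by g at i-1, and likewise
## for East/West. The diffusivity arguments are gradient magnitudes of the
## replicate-padded image, so positions just outside the border carry a
## zero normal gradient; gmp is that padded-size gradient-magnitude map.
.spatialFlux <- function(m, gmp, k, gForm) {
  nr <- nrow(m); nc <- ncol(m)
  N <- .shift(m, -1L, 0L) - m     # I_{i-1,j} - I_{i,j}
  S <- .shift(m,  1L, 0L) - m     # I_{i+1,j} - I_{i,j}
  E <- .shift(m, 0L,  1L) - m     # I_{i,j+1} - I_{i,j}
  W <- .shift(m, 0L, -1L) - m     # I_{i,j-1} - I_{i,j}
  gN <- gmp[3:(nr + 2L), 2:(nc + 1L)]   # |grad I| at (i+1, j)
  gS <- gmp[1:nr,        2:(nc + 1L)]   # |grad I| at (i-1, j)
  gE <- gmp[2:(nr + 1L), 3:(nc + 2L)]   # |grad I| at (i, j+1)
  gW <- gmp[2:(nr + 1L), 1:nc]          # |grad I| at (i, j-1)
  diffusivity(gN, k, gForm) * N +
  diffusivity(gS, k, gForm) * S +
  diffusivity(gE, k, gForm) * E +
  diffusivity(gW, k, gForm) * W
}

#' Solve the coupled spatio-temporal diffusion system on a frame triplet
#'
#' Runs `nIter` explicit finite-difference steps of the three coupled
#' equations: each frame diffuses spatially under the edge-stopping
#' diffusivity while the centre frame exchanges intensity with both
#' temporal neighbours (steps lambdaT) and the neighbours couple back to
#' the centre with steps -2*lambdaT. Background regions are smoothed out
#' while spatio-temporal discontinuities -- moving cells -- are preserved.
#'
#' @param triplet a [FrameTriplet-class] (floating-point frames)
#' @param params a parameter list from [diffusionParams()]
#' @return the diffused [FrameTriplet-class]
#' @export
diffuseTriplet <- function(triplet, params = diffusionParams()) {
  stopifnot(is(triplet, "FrameTriplet"),
            inherits(params, "DiffusionParams"))
  P <- triplet@prev; C <- triplet@center; Nx <- triplet@nxt
  lS <- params$lambdaS
  lT <- params$tsRatio * lS
  k <- params$k; gf <- params$gForm
  for (s in seq_len(params$nIter)) {
    gmP <- .gradMag(.pad1(P)); gmC <- .gradMag(.pad1(C))
    gmN <- .gradMag(.pad1(Nx))
    PF <- P - C
    NF <- Nx - C
    if (params$temporalTerm == "diffusivity_weighted") {
      tPF <- diffusivity(abs(PF), k, gf) * PF
      tNF <- diffusivity(abs(NF), k, gf) * NF
    } else {
      core <- function(g) g[2:(nrow(g) - 1L), 2:(ncol(g) - 1L)]
      tPF <- core(gmP) * PF
      tNF <- core(gmN) * NF
    }
    Cn <- C + lS * .spatialFlux(C, gmC, k, gf) + lT * (tPF + tNF)
    Pn <- P + lS * .spatialFlux(P, gmP, k, gf) - 2 * lT * tPF
    Nn <- Nx + lS * .spatialFlux(Nx, gmN, k, gf) - 2 * lT * tNF
    P <- Pn; C <- Cn; Nx <- Nn
  }
  new("FrameTriplet", prev = P, center = C, nxt = Nx,
      paddedPrev = triplet@paddedPrev, paddedNext = triplet@paddedNext,
      frameIndex = triplet@frameIndex)
}
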