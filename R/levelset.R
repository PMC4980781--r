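## Region-based Chan-Vese level-set model with temporal linking. The
## two-phase piecewise-constant energy
##   F(phi, c1, c2) = mu*length{phi=0} + nu*area{phi>=0}
##                  + lambda1*int_{phi>=0} (I-c1)^2 + lambda2*int_{phi<0} (I-c2)^2
## is minimized by gradient descent on phi with the regularized Heaviside
## H_eps(z) = (1 + (2/pi) atan(z/eps))/2 and delta_eps(z) = eps/(pi(eps^2+z^2)).
## Temporal linking initializes each frame with the converged field of the
## previous frame, a warm start near the previous optimum.
##
## Weights are calibrated for images on a [0,1] intensity scale; the
## pipeline rescales standardized (0-255) frames accordingly.

#' Chan-Vese energy weights and descent controls
#'
#' @param mu contour-length weight (default 0.05 on a \[0,1\] image scale;
#'   larger values over-smooth objects of radius below ~1/mu px)
#' @param nu area weight (default 0)
#' @param lambda1,lambda2 inside/outside fitting weights (default 1)
#' @param epsilon Heaviside/Dirac regularization scale in phi units
#' @param dt base gradient-descent step; each iteration backtracks (halves
#'   the step) until the energy does not increase, so the trace is
#'   nonincreasing by construction
#' @param tol relative energy-change convergence tolerance
#' @param maxIter iteration cap
#' @param reinitEvery rebuild phi as the signed distance of its current
#'   mask every this many iterations (0 disables). The rebuild is guarded:
#'   it is only accepted when it does not raise the energy, so the descent
#'   stays monotone while phi stays well conditioned over long evolutions
#'   (a carried field steepens over frames and can otherwise stall)
#' @return validated list of class `CVWeights`
#' @export
cvWeights <- function(mu = 0.05, nu = 0, lambda1 = 1, lambda2 = 1,
                      epsilon = 1, dt = 5, tol = 1e-4, maxIter = 500L,
                      reinitEvery = 20L) {
  if (mu < 0 || nu < 0) stop("mu and nu must be nonnegative")
  if (lambda1 <= 0 || lambda2 <= 0) stop("lambda1/lambda2 must be positive")
  if (epsilon <= 0 || dt <= 0 || tol <= 0) stop("epsilon, dt, tol must be positive")
  if (reinitEvery < 0) stop("reinitEvery must be nonnegative")
  structure(list(mu = mu, nu = nu, lambda1 = lambda1, lambda2 = lambda2,
                 epsilon = epsilon, dt = dt, tol = tol,
                 maxIter = as.integer(maxIter),
                 reinitEvery = as.integer(reinitEvery)),
            class = "CVWeights")
}

.heaviside <- function(z, eps) 0.5 * (1 + (2 / pi) * atan(z / eps))
.dirac <- function(z, eps) eps / (pi * (eps^2 + z^2))
.diracPrime <- function(z, eps) -2 * eps * z / (pi * (eps^2 + z^2)^2)

#' Chan-Vese energy of a level-set field
#'
#' Region means c1/c2 are the regularized-Heaviside-weighted means inside
#' and outside the zero level set; the length and area terms use the
#' regularized Dirac and Heaviside. When one phase is (numerically) empty
#' its mean falls back to the global image mean and the result carries the
#' attribute `degenerate = TRUE`.
#'
#' @param phi a [LevelSetField-class] or numeric matrix
#' @param image numeric matrix, same shape
#' @param w weights from [cvWeights()]
#' @return list with `energy`, `c1`, `c2`
#' @export
cvEnergy <- function(phi, image, w = cvWeights()) {
  ph <- if (is(phi, "LevelSetField")) phi@phi else phi
  stopifnot(identical(dim(ph), dim(image)), inherits(w, "CVWeights"))
  H <- .heaviside(ph, w$epsilon)
  ## a phase holding less than half a pixel of Heaviside mass is treated
  ## as empty: its mean falls back to the global image mean
  sH <- sum(H); sHc <- sum(1 - H)
  degenerate <- sH < 0.5 || sHc < 0.5
  c1 <- if (sH >= 0.5) sum(image * H) / sH else mean(image)
  c2 <- if (sHc >= 0.5) sum(image * (1 - H)) / sHc else mean(image)
  gx <- (.shift(ph, 1L, 0L) - .shift(ph, -1L, 0L)) / 2
  gy <- (.shift(ph, 0L, 1L) - .shift(ph, 0L, -1L)) / 2
  len <- sum(.dirac(ph, w$epsilon) * sqrt(gx^2 + gy^2))
  area <- sum(H)
  energy <- w$mu * len + w$nu * area +
    w$lambda1 * sum((image - c1)^2 * H) +
    w$lambda2 * sum((image - c2)^2 * (1 - H))
  out <- list(energy = energy, c1 = c1, c2 = c2)
  attr(out, "degenerate") <- degenerate
  out
}

## curvature div(grad phi / |grad phi|) by central differences with a
## small positive stabilizer in the denominator
.curvature <- function(ph, eta = 1e-8) {
  px <- (.shift(ph, 1L, 0L) - .shift(ph, -1L, 0L)) / 2
  py <- (.shift(ph, 0L, 1L) - .shift(ph, 0L, -1L)) / 2
  pxx <- .shift(ph, 1L, 0L) - 2 * ph + .shift(ph, -1L, 0L)
  pyy <- .shift(ph, 0L, 1L) - 2 * ph + .shift(ph, 0L, -1L)
  pxy <- (.shift(.shift(ph, 1L, 0L), 0L, 1L) -
          .shift(.shift(ph, 1L, 0L), 0L, -1L) -
          .shift(.shift(ph, -1L, 0L), 0L, 1L) +
          .shift(.shift(ph, -1L, 0L), 0L, -1L)) / 4
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
    (px^2 + py^2 + eta)^1.5
}

#' Default cold-start level-set initialization
#'
#' A sinusoidal checkerboard of small foreground discs covering the frame
#' (the descent can create or remove contours anywhere), a single centred
#' circle, or an intensity-based start phi0 = image - Otsu threshold that
#' breaks the c1/c2 symmetry immediately on sparse scenes.
#'
#' @param dims c(rows, cols)
#' @param mode "checkerboard", "circle" or "intensity"
#' @param period checkerboard period in pixels
#' @param image required for mode "intensity": the frame to be segmented
#' @return numeric matrix phi0
#' @export
initialPhi <- function(dims, mode = c("checkerboard", "circle", "intensity"),
                       period = 10, image = NULL) {
  mode <- match.arg(mode)
  if (mode == "intensity") {
    if (is.null(image)) stop("mode 'intensity' needs the image")
    rng <- range(image)
    if (diff(rng) == 0) return(matrix(0, dims[1L], dims[2L]))
    thr <- EBImage::otsu(EBImage::as.Image((image - rng[1L]) / diff(rng)),
                         range = c(0, 1)) * diff(rng) + rng[1L]
    return(image - thr)
  }
  r <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  if (mode == "checkerboard") {
    sin(pi * r / (period / 2)) * sin(pi * cc / (period / 2))
  } else {
    rad <- min(dims) / 3
    rad - sqrt((r - (dims[1L] + 1) / 2)^2 + (cc - (dims[2L] + 1) / 2)^2)
  }
}

#' Evolve a Chan-Vese level set to convergence
#'
#' Gradient descent on the regularized energy with replicate-padded
#' (Neumann) boundaries: the fitting and area forces enter as
#' delta_eps(phi) * (-nu - lambda1 (I-c1)^2 + lambda2 (I-c2)^2) and the
#' length term as the exact negative gradient of its discretization (the
#' curvature flow delta * mu * div(grad phi/|grad phi|) in the continuum).
#' The step backtracks (halving dt) whenever it would raise the energy, so
#' the energy trace is nonincreasing. Stops when the relative energy
#' change stays below `tol` for 5 consecutive iterations, when no descent
#' step exists (a local minimum), or at `maxIter`.
#'
#' @param phi0 initial field: numeric matrix or [LevelSetField-class]
#' @param image numeric matrix on a \[0,1\]-like scale
#' @param w weights from [cvWeights()]
#' @return a [LevelSetField-class] with `iFinal` and `energyTrace`
#' @export
cvEvolve <- function(phi0, image, w = cvWeights()) {
  ph <- if (is(phi0, "LevelSetField")) phi0@phi else phi0
  stopifnot(identical(dim(ph), dim(image)), all(is.finite(ph)))
  ## normalize the initial field to a unit-slope signed distance with the
  ## same zero set: a field carried through earlier evolutions can be
  ## arbitrarily steep at the interface, which freezes the contour (the
  ## Dirac window shrinks as |grad phi| grows)
  ph <- maskToPhi(ph >= 0, redistance = TRUE)
  trace <- numeric(0)
  stable <- 0L
  i <- 0L
  while (i < w$maxIter) {
    i <- i + 1L
    e <- cvEnergy(ph, image, w)
    dlt <- .dirac(ph, w$epsilon)
    descent <- dlt * (w$mu * .curvature(ph) - w$nu -
                        w$lambda1 * (image - e$c1)^2 +
                        w$lambda2 * (image - e$c2)^2)
    dt <- w$dt
    collapsed <- FALSE
    repeat {
      cand <- ph + dt * descent
      eNew <- cvEnergy(cand, image, w)$energy
      if (eNew <= e$energy + 1e-12 * max(1, abs(e$energy))) break
      dt <- dt / 2
      if (dt < w$dt / 2^25) { collapsed <- TRUE; cand <- ph; break }
    }
    ## energy-guarded redistancing: same zero set, unit-slope field,
    ## accepted only when it does not raise the energy
    tryReinit <- (w$reinitEvery > 0L && i %% w$reinitEvery == 0L) ||
      collapsed
    if (tryReinit) {
      sd <- maskToPhi(cand >= 0, redistance = TRUE)
      eSd <- cvEnergy(sd, image, w)$energy
      eRef <- cvEnergy(cand, image, w)$energy
      if (eSd <= eRef + 1e-12 * max(1, abs(eRef))) {
        cand <- sd
        collapsed <- FALSE
      }
    }
    trace <- c(trace, e$energy)
    if (collapsed) break   # no descent step exists: local minimum reached
    n <- length(trace)
    if (n > 1L) {
      rel <- abs(trace[n] - trace[n - 1L]) / max(abs(trace[n - 1L]), 1e-12)
      stable <- if (rel < w$tol) stable + 1L else 0L
      if (stable >= 5L) break
    }
    ph <- cand
  }
  new("LevelSetField", phi = ph, iFinal = i, energyTrace = trace)
}

#' Temporally linked Chan-Vese segmentation of a sequence
#'
#' Frame 1 starts from `phiInit` (default checkerboard); every following
#' frame starts from the converged field of its predecessor, carried over
#' exactly. Per-frame masks are the 8-connected components of
#' \{phi >= 0\}.
#'
#' @param sequence a [FrameSequence-class]; frames are rescaled to \[0,1\]
#'   by the sequence global range before evolution
#' @param phiInit optional initial field for the first frame
#' @param w weights from [cvWeights()]
#' @return list with `masks` (instance label matrices) and `fields`
#'   (final [LevelSetField-class] per frame)
#' @export
tcvSequence <- function(sequence, phiInit = NULL, w = cvWeights()) {
  stopifnot(is(sequence, "FrameSequence"))
  gr <- globalRange(sequence)
  d <- frameDims(sequence)
  ph <- if (is.null(phiInit)) initialPhi(d) else
    if (is(phiInit, "LevelSetField")) phiInit@phi else phiInit
  masks <- vector("list", nFrames(sequence))
  fields <- vector("list", nFrames(sequence))
  for (t in seq_len(nFrames(sequence))) {
    img <- (frameAt(sequence, t) - gr[1L]) / (gr[2L] - gr[1L])
    fld <- cvEvolve(ph, img, w)
    fields[[t]] <- fld
    masks[[t]] <- .label8(fld@phi >= 0)
    ph <- fld@phi   # exact carry-over to the next frame
  }
  list(masks = masks, fields = fields)
}
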