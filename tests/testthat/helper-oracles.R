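## Independent oracles and small constructors shared across tests. These
## deliberately use plain double loops / direct formulas, not the package's
## vectorized internals.

## clamped accessor = replicate padding
.at <- function(M, i, j) {
  M[min(max(i, 1L), nrow(M)), min(max(j, 1L), ncol(M))]
}

## central-difference gradient magnitude with replicate padding
.oracleGradMag <- function(M, i, j) {
  gx <- (.at(M, i + 1L, j) - .at(M, i - 1L, j)) / 2
  gy <- (.at(M, i, j + 1L) - .at(M, i, j - 1L)) / 2
  sqrt(gx^2 + gy^2)
}

## one literal explicit step of the coupled spatio-temporal system:
## spatial 4-neighbour fluxes weighted by the diffusivity at the shifted
## positions exactly as the update equations pair them, temporal couplings
## PF/NF with the factor -2 on the neighbour frames
oracleDiffuseStep <- function(P, C, N, lambdaS, tsRatio, k,
                              form = "rational") {
  g <- function(x) if (form == "rational") 1 / (1 + (x / k)^2) else
    exp(-(x / k)^2)
  lambdaT <- tsRatio * lambdaS
  outP <- P; outC <- C; outN <- N
  for (i in seq_len(nrow(C))) for (j in seq_len(ncol(C))) {
    spat <- function(M) {
      Nd <- .at(M, i - 1L, j) - M[i, j]
      Sd <- .at(M, i + 1L, j) - M[i, j]
      Ed <- .at(M, i, j + 1L) - M[i, j]
      Wd <- .at(M, i, j - 1L) - M[i, j]
      g(.oracleGradMag(M, i + 1L, j)) * Nd +
        g(.oracleGradMag(M, i - 1L, j)) * Sd +
        g(.oracleGradMag(M, i, j + 1L)) * Ed +
        g(.oracleGradMag(M, i, j - 1L)) * Wd
    }
    PF <- P[i, j] - C[i, j]
    NF <- N[i, j] - C[i, j]
    outC[i, j] <- C[i, j] + lambdaS * spat(C) +
      lambdaT * (g(abs(PF)) * PF + g(abs(NF)) * NF)
    outP[i, j] <- P[i, j] + lambdaS * spat(P) - 2 * lambdaT * g(abs(PF)) * PF
    outN[i, j] <- N[i, j] + lambdaS * spat(N) - 2 * lambdaT * g(abs(NF)) * NF
  }
  list(prev = outP, center = outC, nxt = outN)
}

## direct double-loop Chan-Vese energy with the arctan Heaviside
oracleCVEnergy <- function(ph, img, mu, nu, lambda1, lambda2, eps) {
  H <- function(z) 0.5 * (1 + (2 / pi) * atan(z / eps))
  dlt <- function(z) eps / (pi * (eps^2 + z^2))
  sH <- 0; sHI <- 0; sHc <- 0; sHcI <- 0
  for (i in seq_len(nrow(ph))) for (j in seq_len(ncol(ph))) {
    h <- H(ph[i, j])
    sH <- sH + h; sHI <- sHI + img[i, j] * h
    sHc <- sHc + (1 - h); sHcI <- sHcI + img[i, j] * (1 - h)
  }
  c1 <- sHI / sH; c2 <- sHcI / sHc
  E <- 0
  for (i in seq_len(nrow(ph))) for (j in seq_len(ncol(ph))) {
    gx <- (.at(ph, i + 1L, j) - .at(ph, i - 1L, j)) / 2
    gy <- (.at(ph, i, j + 1L) - .at(ph, i, j - 1L)) / 2
    h <- H(ph[i, j])
    E <- E + mu * dlt(ph[i, j]) * sqrt(gx^2 + gy^2) + nu * h +
      lambda1 * (img[i, j] - c1)^2 * h +
      lambda2 * (img[i, j] - c2)^2 * (1 - h)
  }
  list(energy = E, c1 = c1, c2 = c2)
}

## separable Gaussian convolution with mirror (half-sample symmetric)
## padding, the image-method boundary matching a zero-flux heat equation;
## kernel truncated at 4 sigma
oracleGaussBlur <- function(M, sigma) {
  r <- ceiling(4 * sigma)
  kern <- dnorm(-r:r, 0, sigma)
  kern <- kern / sum(kern)
  pad <- function(v, n) c(rev(v[1:n]), v, rev(v[(length(v) - n + 1L):length(v)]))
  conv1 <- function(v) {
    vp <- pad(v, r)
    vapply(seq_along(v), function(i) sum(vp[i:(i + 2L * r)] * kern),
           numeric(1))
  }
  M1 <- apply(M, 2L, conv1)
  t(apply(M1, 1L, conv1))
}

## sharp-edged disk image
makeDisk <- function(dims, center, radius, fg = 200, bg = 20) {
  r <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  inside <- sqrt((r - center[1L])^2 + (cc - center[2L])^2) <= radius
  list(img = ifelse(inside, fg, bg), mask = inside)
}

## random frame triplet on the 0-255 scale
randomTriplet <- function(seed, dims = c(16L, 16L), lo = 0, hi = 255) {
  set.seed(seed)
  mats <- lapply(1:3, function(i) matrix(runif(prod(dims), lo, hi), dims[1L]))
  new("FrameTriplet", prev = mats[[1L]], center = mats[[2L]],
      nxt = mats[[3L]], paddedPrev = FALSE, paddedNext = FALSE,
      frameIndex = 1L)
}
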