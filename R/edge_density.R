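## Detection of spatio-temporal discontinuities by Parzen density
## estimation. In each pixel's neighbourhood we estimate the local
## intensity PDF with Gaussian Parzen kernels and evaluate the likelihood
## of the neighbourhood mean: region interiors have a unimodal local PDF
## (mean likelihood high), windows straddling an edge have a bimodal PDF
## whose valley sits near the mean (mean likelihood low). One minus the
## normalized mean-likelihood is the edge-occurrence index.

#' Parzen (kernel) density estimate at query points
#'
#' f_h(x) = 1/(n h) * sum_i K((x - x_i)/h) with a Gaussian kernel K.
#'
#' @param samples numeric vector of observations
#' @param h kernel bandwidth (> 0)
#' @param query numeric vector of evaluation points
#' @return density values at `query`
#' @examples
#' parzenDensity(0, 1, 0)   # 1/sqrt(2*pi)
#' @export
parzenDensity <- function(samples, h, query) {
  if (length(samples) == 0L) stop("empty sample collection")
  if (h <= 0) stop("bandwidth h must be positive")
  vapply(query, function(q) mean(dnorm((q - samples) / h)) / h, numeric(1))
}

#' Edge-occurrence index map of a frame
#'
#' For every pixel, the intensities of the surrounding `window` x `window`
#' neighbourhood (replicate-padded at the borders) form the Parzen sample;
#' the density is evaluated at the neighbourhood mean and the index is
#' 1 - f_h(mean)/max(f_h(mean)) over the frame. Values near 1 flag bimodal
#' neighbourhoods, i.e. edges of moving regions.
#'
#' @param frame numeric matrix (typically the diffused centre frame)
#' @param h Parzen bandwidth on the standardized 0-255 scale (default 8)
#' @param window odd neighbourhood side length (default 7)
#' @return an [EdgeMap-class]
#' @export
edgeIndexMap <- function(frame, h = 8, window = 7L) {
  stopifnot(is.matrix(frame))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (h <= 0) stop("bandwidth h must be positive")
  if (window > min(dim(frame))) stop("window larger than frame")
  r <- (window - 1L) %/% 2L
  offsets <- expand.grid(di = -r:r, dj = -r:r)
  n <- nrow(offsets)
  shifted <- vector("list", n)
  acc <- matrix(0, nrow(frame), ncol(frame))
  for (o in seq_len(n)) {
    shifted[[o]] <- .shift(frame, offsets$di[o], offsets$dj[o])
    acc <- acc + shifted[[o]]
  }
  mu <- acc / n                       # neighbourhood mean per pixel
  dens <- matrix(0, nrow(frame), ncol(frame))
  for (o in seq_len(n)) {
    dens <- dens + dnorm((mu - shifted[[o]]) / h)
  }
  dens <- dens / (n * h)              # f_h(mean) per pixel
  fmax <- max(dens)
  vals <- if (fmax > 0) 1 - dens / fmax else matrix(0, nrow(frame), ncol(frame))
  new("EdgeMap", values = vals, h = h, window = window)
}
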