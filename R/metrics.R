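## Validation and image-quality measures: Dice overlap between binary
## masks, and SNR/CNR of a frame given its cell mask.

#' Dice similarity coefficient
#'
#' 2|A . B| / (|A| + |B|) between two binary masks. Two empty masks agree
#' perfectly and score 1.
#'
#' @param a,b logical (or 0/1, or instance-labelled) matrices of one shape;
#'   instance labels are binarized as label > 0
#' @return Dice coefficient in \[0, 1\]
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Signal-to-noise ratio of a frame, in dB
#'
#' 20 log10(mean cell intensity / mean background intensity) given the
#' binary cell mask.
#'
#' @param frame numeric matrix
#' @param cells logical (or labelled) cell mask of the same shape
#' @return SNR in decibels
#' @export
snr <- function(frame, cells) {
  if (!identical(dim(frame), dim(cells))) stop("shape mismatch")
  cells <- cells > 0
  if (!any(cells)) stop("empty cell set")
  if (all(cells)) stop("empty background set")
  uC <- mean(frame[cells]); uB <- mean(frame[!cells])
  if (uB <= 0) stop("nonpositive background mean")
  20 * log10(uC / uB)
}

#' Contrast-to-noise ratio of a frame
#'
#' |mean cell - mean background| / sd(background), with the population
#' (divide-by-N) standard deviation so values are reproducible.
#'
#' @inheritParams snr
#' @return CNR (dimensionless)
#' @export
cnr <- function(frame, cells) {
  if (!identical(dim(frame), dim(cells))) stop("shape mismatch")
  cells <- cells > 0
  if (!any(cells)) stop("empty cell set")
  bg <- frame[!cells]
  if (length(bg) < 2L) stop("background must have at least 2 pixels")
  sB <- sqrt(mean((bg - mean(bg))^2))
  if (sB == 0) stop("zero background deviation")
  abs(mean(frame[cells]) - mean(bg)) / sB
}

#' Per-frame Dice evaluation of a predicted segmentation
#'
#' @param pred,ref lists of masks (instance-labelled or binary), same
#'   length and shapes; compared after binarization
#' @return data.frame with columns `frame` (0-based) and `dice`, plus
#'   attributes `mean` and `sd` (over frames)
#' @export
evaluateSegmentation <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("sequence length mismatch")
  d <- vapply(seq_along(pred),
              function(i) diceCoefficient(pred[[i]], ref[[i]]), numeric(1))
  out <- data.frame(frame = seq_along(pred) - 1L, dice = d)
  attr(out, "mean") <- mean(d)
  attr(out, "sd") <- if (length(d) > 1L) sd(d) else 0
  out
}
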