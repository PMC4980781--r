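## Sequence and mask I/O. Frames come in either as one multi-page TIFF or a
## directory of numbered single-frame TIFF/PNG files; label masks go out as
## 16-bit TIFFs using the Cell Tracking Challenge "man_seg{TTT}.tif" naming.

#' Construct a FrameSequence from in-memory matrices
#'
#' @param frames list of numeric matrices (identical dims), time-ordered
#' @param bitDepth nominal bit depth of the data (8 or 16)
#' @return a [FrameSequence-class] object
#' @examples
#' fs <- frameSequence(list(matrix(runif(64, 0, 255), 8, 8),
#'                          matrix(runif(64, 0, 255), 8, 8)))
#' nFrames(fs)
#' @export
frameSequence <- function(frames, bitDepth = 8L) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  px <- unlist(frames, use.names = FALSE)
  new("FrameSequence", frames = frames, bitDepth = as.integer(bitDepth),
      globalMin = min(px), globalMax = max(px))
}

## decode one TIFF/PNG page to a raw-scale intensity matrix.
## tiff/png return values in [0,1]; as.is=TRUE keeps raw integers for TIFF.
.readFramePage <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.(tif|tiff)$", lower)) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  } else if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)   # [0,1]; infer source depth from quantization
    img <- img * 65535
    if (all(abs(img / 257 - round(img / 257)) < 1e-6)) {
      img <- round(img / 257)       # 8-bit source
    } else {
      img <- round(img)             # 16-bit source
    }
  } else {
    stop("unsupported frame format: ", path)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L &&
        !all(abs(img[, , 1L] - img[, , pmin(2L, dim(img)[3L])]) < 1e-9))
      stop("non-grayscale input: ", path)
    img <- img[, , 1L]
  }
  if (length(dim(img)) != 2L)
    stop("frame is not a 2D grayscale image: ", path)
  depth <- attr(img, "bits.per.sample")
  out <- matrix(as.double(img), nrow(img))
  attr(out, "depth") <- if (!is.null(depth)) as.integer(depth) else
    if (max(out) > 255) 16L else 8L
  out
}

#' Read a time-lapse frame sequence
#'
#' Accepts either a single multi-page TIFF file or a directory of numbered
#' single-frame TIFF/PNG files. Frames are ordered by the numeric part of
#' their file names (multi-page TIFFs keep page order), promoted to doubles
#' and validated for shape consistency.
#'
#' @param path multi-page TIFF file or directory of frames
#' @param pattern regular expression selecting frame files in a directory
#' @param bitDepth bit depth; by default inferred from the maximum intensity
#' @return a [FrameSequence-class]
#' @export
readFrameSequence <- function(path, pattern = "\\.(tif|tiff|png)$",
                              bitDepth = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = pattern, full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0L) stop("zero frames found in ", path)
    ## numeric-aware ordering: sort on the last integer in each file name
    nums <- suppressWarnings(as.numeric(sub(
      ".*?(\\d+)\\D*$", "\\1", basename(files))))
    files <- files[order(nums, basename(files))]
    mats <- lapply(files, .readFramePage)
    depth <- max(vapply(mats, attr, integer(1), "depth"))
  } else {
    if (!grepl("\\.(tif|tiff)$", tolower(path)))
      stop("single-file input must be a (multi-page) TIFF: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    depth <- max(vapply(pages, function(p) {
      d <- attr(p, "bits.per.sample")
      if (is.null(d)) 8L else as.integer(d)
    }, integer(1)))
    mats <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      matrix(as.double(p), nrow(p))
    })
  }
  dims <- vapply(mats, dim, integer(2))
  if (!all(dims == dims[, 1L])) stop("inconsistent frame shapes")
  mats <- lapply(mats, function(m) { attr(m, "depth") <- NULL; m })
  if (is.null(bitDepth)) bitDepth <- depth
  frameSequence(mats, bitDepth = bitDepth)
}

#' Write instance label masks as 16-bit TIFFs
#'
#' One file per frame, named by `sprintf(naming, frameIndex)` with 0-based
#' frame indices, following the Cell Tracking Challenge mask convention.
#' Values round-trip bit-exactly through [readLabelMasks()].
#'
#' @param masks list of nonnegative integer matrices (0 = background)
#' @param path output directory (created if missing)
#' @param naming sprintf template for file names
#' @return invisibly, the vector of files written
#' @export
writeLabelMasks <- function(masks, path, naming = "man_seg%03d.tif") {
  if (length(masks) == 0L) stop("empty mask list")
  dims <- vapply(masks, dim, integer(2))
  if (!all(dims == dims[, 1L])) stop("inconsistent mask shapes")
  mx <- max(unlist(masks, use.names = FALSE))
  if (mx > 65535) stop("label exceeds 16-bit range")
  if (min(unlist(masks, use.names = FALSE)) < 0) stop("negative label value")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- character(length(masks))
  for (i in seq_along(masks)) {
    f <- file.path(path, sprintf(naming, i - 1L))
    tiff::writeTIFF(masks[[i]] / 65535, f, bits.per.sample = 16L,
                    compression = "none")
    files[i] <- f
  }
  invisible(files)
}

#' Read instance label masks written by [writeLabelMasks()]
#'
#' @param path directory of 16-bit TIFF label masks
#' @param pattern regular expression selecting mask files
#' @return list of integer matrices, ordered by the numeric part of the names
#' @export
readLabelMasks <- function(path, pattern = "\\.(tif|tiff)$") {
  if (!dir.exists(path)) stop("path does not exist: ", path)
  files <- list.files(path, pattern = pattern, full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L) stop("zero masks found in ", path)
  nums <- suppressWarnings(as.numeric(sub(
    ".*?(\\d+)\\D*$", "\\1", basename(files))))
  files <- files[order(nums, basename(files))]
  lapply(files, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    storage.mode(m) <- "integer"
    m
  })
}

#' Extract the three-frame window centred on a time point
#'
#' At the first and last frames the missing temporal neighbour is replicated
#' from the centre frame (zero temporal gradient), and flagged.
#'
#' @param sequence a [FrameSequence-class]
#' @param t 0-based centre frame index
#' @return a [FrameTriplet-class]
#' @export
frameTriplet <- function(sequence, t) {
  n <- nFrames(sequence)
  if (t < 0L || t > n - 1L) stop("frame index out of range")
  center <- frameAt(sequence, t + 1L)
  paddedPrev <- t == 0L
  paddedNext <- t == n - 1L
  prev <- if (paddedPrev) center else frameAt(sequence, t)
  nxt  <- if (paddedNext) center else frameAt(sequence, t + 2L)
  new("FrameTriplet", prev = prev, center = center, nxt = nxt,
      paddedPrev = paddedPrev, paddedNext = paddedNext,
      frameIndex = as.integer(t))
}
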