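# Bead isolation: grayscale -> (optional) histogram equalization ->
# threshold -> morphological open/close -> connected components ->
# component selection.  Intensity statistics are always measured on the
# raw (non-equalized) grayscale.

.GRAY_WEIGHTS <- c(R = 0.299, G = 0.587, B = 0.114)  # Rec. 601 luma

#' Convert an RGB frame to 8-bit grayscale
#'
#' Fixed Rec. 601 luminance weighting `0.299 R + 0.587 G + 0.114 B`,
#' rounded to integers.  Deterministic; a pure-gray input (all channels
#' equal) is returned unchanged.
#'
#' @param fr a [Frame-class] (3-channel 8-bit).
#' @return integer matrix `height x width`, values 0-255.
#' @export
toGray <- function(fr) {
  if (!is(fr, "Frame")) stop("format error: expected a Frame", call. = FALSE)
  px <- framePixels(fr)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("format error: frame must have exactly 3 channels", call. = FALSE)
  g <- .GRAY_WEIGHTS[1] * px[, , 1] + .GRAY_WEIGHTS[2] * px[, , 2] +
    .GRAY_WEIGHTS[3] * px[, , 3]
  g <- round(g)
  storage.mode(g) <- "integer"
  g
}

#' Histogram equalization of an 8-bit grayscale image
#'
#' Classic cumulative-histogram remapping: with `F(v)` the empirical CDF
#' of pixel values and `Fmin` the CDF at the lowest level present, each
#' level maps to `round(255 * (F(v) - Fmin) / (1 - Fmin))`.  The mapping
#' preserves the rank order of distinct pixel values and never shrinks the
#' dynamic range.  A constant image (degenerate histogram) is returned
#' unchanged.
#'
#' @param img integer matrix with values 0-255.
#' @return equalized integer matrix of the same dimensions.
#' @export
enhanceContrast <- function(img) {
  v <- as.integer(img)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(v)
  fmin <- min(cdf[counts > 0])
  if (fmin >= 1) return(img)  # single-valued histogram
  map <- as.integer(round(255 * (cdf - fmin) / (1 - fmin)))
  out <- matrix(map[v + 1L], nrow = nrow(img), ncol = ncol(img))
  storage.mode(out) <- "integer"
  out
}

#' Construct a segmentation configuration
#'
#' @param equalize `"auto"`, `"always"` or `"never"`; auto equalizes when
#'   the grayscale dynamic range (p99 - p1) is below `contrastTrigger`.
#' @param contrastTrigger dynamic-range trigger in levels (default 40).
#' @param thresholdMethod `"otsu"` (default) or `"fixed"`.
#' @param fixedThreshold threshold 0-255; required iff method is fixed.
#' @param minArea minimum surviving component area, px.
#' @param morphRadius disk radius for morphological open/close; 0 disables.
#' @param centerBias prefer the component nearest the image centre.
#' @param minContrast minimum foreground-background separation (levels) on
#'   the working image for a component to count as a detection.
#' @return a [SegmentationConfig-class].
#' @export
segmentationConfig <- function(equalize = c("auto", "always", "never"),
                               contrastTrigger = 40,
                               thresholdMethod = c("otsu", "fixed"),
                               fixedThreshold = NA_real_,
                               minArea = 500, morphRadius = 2L,
                               centerBias = TRUE, minContrast = 30) {
  new("SegmentationConfig",
      equalize = match.arg(equalize), contrastTrigger = contrastTrigger,
      thresholdMethod = match.arg(thresholdMethod),
      fixedThreshold = as.numeric(fixedThreshold),
      minArea = minArea, morphRadius = as.integer(morphRadius),
      centerBias = centerBias, minContrast = minContrast)
}

#' Isolate the bead in a frame as a binary mask
#'
#' The bead-isolation pipeline: grayscale conversion, histogram
#' equalization per the config (transparent beads against the dark
#' background need the contrast boost to separate from it), Otsu or fixed
#' thresholding, morphological open then close with a disk brush,
#' connected-component labelling, removal of components below `minArea`,
#' a minimum-contrast detection guard on the working image, and selection
#' of the component nearest the image centre (or the largest).  Mask
#' coordinates refer to the original frame.  Finding nothing is a result
#' (`found = FALSE`), not an error.
#'
#' @param fr a [Frame-class].
#' @param cfg a [SegmentationConfig-class].
#' @return a [BeadMask-class].
#' @seealso [measureIntensity()]
#' @export
segmentBead <- function(fr, cfg = segmentationConfig()) {
  gray <- toGray(fr)
  doEq <- switch(cfg@equalize,
    always = TRUE, never = FALSE,
    auto = diff(quantile(gray, c(0.01, 0.99), names = FALSE)) <
      cfg@contrastTrigger)
  work <- if (doEq) enhanceContrast(gray) else gray

  th <- if (cfg@thresholdMethod == "fixed") cfg@fixedThreshold
    else 255 * otsu(work / 255, range = c(0, 1), levels = 256)
  m <- work > th

  if (cfg@morphRadius > 0L) {
    br <- makeBrush(2L * cfg@morphRadius + 1L, "disc")
    m <- closing(opening(m, br), br) > 0
  }

  labels <- bwlabel(m)
  ncomp <- max(labels)
  notFound <- new("BeadMask",
                  mask = matrix(FALSE, nrow(gray), ncol(gray)),
                  area = 0, centroid = c(NA_real_, NA_real_), found = FALSE)
  if (ncomp == 0L) return(notFound)

  areas <- tabulate(labels[labels > 0], nbins = ncomp)
  keep <- which(areas >= cfg@minArea)
  if (!length(keep)) return(notFound)

  # detection guard: component must stand out from the background on the
  # working image by at least minContrast levels
  bgPix <- work[labels == 0]
  bgMean <- if (length(bgPix)) mean(bgPix) else Inf
  keep <- keep[vapply(keep, function(k)
    mean(work[labels == k]) - bgMean >= cfg@minContrast, logical(1))]
  if (!length(keep)) return(notFound)

  centroids <- lapply(keep, function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  })
  sel <- if (cfg@centerBias) {
    ctr <- c(ncol(gray) / 2, nrow(gray) / 2)
    which.min(vapply(centroids, function(ct)
      sum((ct - ctr)^2), numeric(1)))
  } else which.max(areas[keep])

  mask <- labels == keep[sel]
  new("BeadMask", mask = matrix(as.logical(mask), nrow(gray), ncol(gray)),
      area = areas[keep[sel]], centroid = unname(centroids[[sel]]),
      found = TRUE)
}

#' Pixel-intensity statistics within a bead mask
#'
#' Statistics are computed on the raw (non-equalized) grayscale of the
#' original frame restricted to the mask, on the 8-bit 0-255 scale:
#' equalization serves only mask finding, because only pre-equalization
#' values carry the opacity interpretation.
#'
#' @param fr a [Frame-class].
#' @param mask a [BeadMask-class] with `found = TRUE` and matching
#'   dimensions.
#' @return one-row data.frame: `mean`, `sd`, `nPixels`, `p5`, `p25`,
#'   `p50`, `p75`, `p95`.
#' @export
measureIntensity <- function(fr, mask) {
  if (!is(mask, "BeadMask") || !mask@found)
    stop("measurement error: no bead", call. = FALSE)
  gray <- toGray(fr)
  if (!all(dim(gray) == dim(mask@mask)))
    stop("measurement error: mask dimensions do not match frame",
         call. = FALSE)
  px <- as.numeric(gray[mask@mask])
  q <- quantile(px, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  data.frame(mean = mean(px), sd = if (length(px) > 1L) sd(px) else 0,
             nPixels = length(px),
             p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5])
}
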