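# Resize, affine enhancement, Otsu threshold selection, and grey-level-
# preserving threshold segmentation: pixels below the threshold are zeroed,
# pixels at or above it keep their original value (the tumor region stays at
# its native intensities rather than being flattened to white).

#' Resize an image to a square
#'
#' Bilinear interpolation; aspect ratio is not preserved (the output is
#' forced square, matching the classifier's fixed input size).
#'
#' @param img 1- or 3-channel image.
#' @param side output side in pixels (default 144).
#' @return `side` x `side` image.
#' @export
resize_image <- function(img, side = 144) {
  assert_image(img)
  if (side < 1) stop("`side` must be >= 1", call. = FALSE)
  if (nrow(img) == side && ncol(img) == side) return(img)
  out <- EBImage::resize(img, w = side, h = side)
  clip8(floor(as.numeric_array(out) + 0.5))
}

# EBImage returns Image objects; strip back to plain matrix/array
as.numeric_array <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) matrix(as.numeric(x), d[1], d[2])
  else array(as.numeric(x), d)
}

#' Affine brightness/contrast enhancement
#'
#' `pixel <- clip(round(alpha * pixel + beta), 0, 255)`. Widens the gap
#' between bright (suspect) and dark (normal) tissue ahead of thresholding.
#'
#' @param img 1-channel image.
#' @param alpha contrast gain (> 0), default 1.3.
#' @param beta brightness offset in grey levels, default 10.
#' @return enhanced image.
#' @export
enhance <- function(img, alpha = 1.3, beta = 10) {
  assert_image(img, channels = 1L)
  if (!is.numeric(alpha) || alpha <= 0) {
    stop("`alpha` must be > 0", call. = FALSE)
  }
  clip8(floor(alpha * img + beta + 0.5))
}

#' Otsu threshold of an image histogram
#'
#' Returns the grey level maximizing the between-class variance of the
#' 256-bin histogram (ties resolved to the smallest qualifying level). The
#' returned value `t` is meant to be used as in [segment()]: background is
#' `pixel < t`, foreground `pixel >= t`.
#'
#' @param img 1-channel image with at least two distinct grey levels.
#' @return integer threshold in \[0, 255\].
#' @export
compute_threshold <- function(img) {
  assert_image(img, channels = 1L)
  v <- as.integer(round(img))
  if (length(unique(v)) < 2L) {
    degenerate_hist_error("constant image: histogram has a single grey level")
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  p <- counts / n
  levels <- 0:255
  omega <- cumsum(p)              # class-0 probability for threshold t = level+1
  mu <- cumsum(p * levels)        # partial mean
  mu_t <- mu[256]
  # candidate thresholds t: background < t, foreground >= t; evaluate
  # sigma_b^2(t) for t = 1..255 using cumulative stats up to level t-1
  w0 <- omega[1:255]
  m0 <- mu[1:255]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  as.integer(which.max(sigma_b))  # smallest maximizer; t in 1..255
}

#' Grey-level-preserving threshold segmentation
#'
#' Pixels below `threshold` are set to 0; pixels at or above keep their
#' original intensity (the operation is idempotent and never raises a pixel).
#'
#' @param img 1-channel image.
#' @param threshold grey level in \[0, 255\].
#' @return segmented image.
#' @export
segment <- function(img, threshold) {
  assert_image(img, channels = 1L)
  img * (img >= threshold)
}

#' Resize + enhance + threshold + segment in one call
#'
#' The full segmentation stage applied to a cropped brain image: bilinear
#' resize to `side` x `side`, affine enhancement, Otsu threshold selection
#' (or a fixed manual threshold), then grey-level-preserving segmentation.
#'
#' The default enhancement here is a bright-end window (`alpha = 3`,
#' `beta = -420`: grey levels at or below 140 map to 0, at or above 225 to
#' 255). On a cropped brain the histogram has three modes — background,
#' normal tissue, hyperintense (suspect) tissue — and a mild affine gain
#' leaves the background/brain split dominating the between-class variance,
#' so Otsu would "segment" the whole brain. The window compresses
#' background and normal tissue together, after which the threshold lands
#' in the brain/tumor gap and the surviving pixels are the bright lesion.
#'
#' @param img cropped 1-channel brain image.
#' @param alpha,beta enhancement parameters, see [enhance()].
#' @param side output side (default 144).
#' @param threshold optional fixed threshold; when `NULL` (default) the
#'   threshold is computed from the enhanced image via [compute_threshold()].
#' @return list with `image` (segmented `side` x `side` image) and
#'   `threshold` (the grey level used).
#' @export
segment_pipeline <- function(img, alpha = 3, beta = -420, side = 144,
                             threshold = NULL) {
  assert_image(img, channels = 1L)
  resized <- resize_image(img, side)
  enhanced <- enhance(resized, alpha, beta)
  t <- if (is.null(threshold)) compute_threshold(enhanced) else threshold
  list(image = segment(enhanced, t), threshold = t)
}
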