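# Brain contour cropping: grayscale -> Gaussian smoothing -> binarization ->
# morphological cleanup -> external contour retrieval -> largest-contour
# bounding box -> crop of the ORIGINAL image. The crop isolates the brain
# blob (the "large white portion within the black area") before any
# segmentation or classification.

#' Convert a 3-channel image to grayscale
#'
#' Uses BT.601 luma weights (0.299, 0.587, 0.114), rounded half up and
#' clipped to \[0, 255\]. A 1-channel input passes through unchanged.
#'
#' @param img H x W x 3 array (or H x W matrix) of 8-bit values.
#' @return H x W matrix of 8-bit values.
#' @export
to_grayscale <- function(img) {
  assert_image(img)
  if (is.matrix(img)) return(img)
  if (dim(img)[3L] != 3L) {
    stop("expected a 3-channel image, got ", dim(img)[3L], " channels",
         call. = FALSE)
  }
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  clip8(floor(g + 0.5))
}

gaussian_kernel <- function(kernel_size, sigma) {
  half <- (kernel_size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Convolves with a normalized Gaussian kernel (borders handled by edge
#' replication) and re-quantizes to 8 bits. `sigma`, when omitted, follows
#' the usual kernel-size heuristic `0.3 * ((size - 1)/2 - 1) + 0.8`.
#'
#' @param img 1-channel image.
#' @param kernel_size odd window side in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed 1-channel image.
#' @export
gaussian_smooth <- function(img, kernel_size = 5,
                            sigma = 0.3 * ((kernel_size - 1) / 2 - 1) + 0.8) {
  assert_image(img, channels = 1L)
  if (kernel_size < 1 || kernel_size %% 2 == 0) {
    stop("`kernel_size` must be odd and >= 1", call. = FALSE)
  }
  if (kernel_size == 1) return(img)
  k <- gaussian_kernel(kernel_size, sigma)
  out <- EBImage::filter2(img, k, boundary = "replicate")
  clip8(floor(out + 0.5))
}

#' Binarize an image at a global threshold
#'
#' Pixels below `T` become 0, pixels at or above `T` become 255.
#'
#' @param img 1-channel image.
#' @param T threshold grey level.
#' @return binary mask over \{0, 255\}.
#' @export
binarize <- function(img, T) {
  assert_image(img, channels = 1L)
  (img >= T) * 255
}

#' Morphological parameters
#'
#' @param kernel_size side of the square structuring element (default 3).
#' @param erode_iterations,dilate_iterations repetition counts (>= 0).
#' @return a `morph_params` list.
#' @export
morph_params <- function(kernel_size = 3, erode_iterations = 2,
                         dilate_iterations = 2) {
  if (erode_iterations < 0 || dilate_iterations < 0) {
    stop("iteration counts must be >= 0", call. = FALSE)
  }
  structure(list(kernel_size = as.integer(kernel_size),
                 erode_iterations = as.integer(erode_iterations),
                 dilate_iterations = as.integer(dilate_iterations)),
            class = "morph_params")
}

#' Morphological cleanup of a binary mask
#'
#' Applies `erode_iterations` erosions then `dilate_iterations` dilations
#' with a square structuring element (an opening when the counts match);
#' removes specks and smooths blob boundaries before contour retrieval.
#'
#' @param mask binary mask over \{0, 255\}.
#' @param params a [morph_params()].
#' @return cleaned binary mask.
#' @export
morph_clean <- function(mask, params = morph_params()) {
  assert_mask(mask)
  m <- mask / 255
  kern <- EBImage::makeBrush(params$kernel_size, shape = "box")
  for (i in seq_len(params$erode_iterations))  m <- EBImage::erode(m, kern)
  for (i in seq_len(params$dilate_iterations)) m <- EBImage::dilate(m, kern)
  matrix(as.numeric(m), nrow(mask), ncol(mask)) * 255
}

# 8-connected component labeling (two-pass, union-find). EBImage's bwlabel
# is 4-connected, which splits diagonal bridges the contour retrieval must
# keep together.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nxt <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (mask[i, j] == 0) next
      nb <- integer(0)
      if (i > 1           && lab[i - 1, j]     > 0) nb <- c(nb, lab[i - 1, j])
      if (j > 1) {
        if (lab[i, j - 1] > 0)                      nb <- c(nb, lab[i, j - 1])
        if (i > 1 && lab[i - 1, j - 1] > 0)         nb <- c(nb, lab[i - 1, j - 1])
        if (i < h && lab[i + 1, j - 1] > 0)         nb <- c(nb, lab[i + 1, j - 1])
      }
      if (length(nb) == 0L) {
        nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r <- min(roots)
        lab[i, j] <- r
        for (x in roots) parent[x] <- r
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relab <- integer(nxt)
  relab[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- which(lab > 0)
  lab[pos] <- relab[roots[lab[pos]]]
  lab
}

# Moore-neighbour boundary tracing of one labeled component; returns the
# closed outer boundary as (row, col) points in trace order.
trace_boundary <- function(lab, id) {
  h <- nrow(lab); w <- ncol(lab)
  inside <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && lab[i, j] == id
  # start: first foreground pixel in column-major scan (top of leftmost column)
  start <- which(lab == id)[1]
  si <- (start - 1) %% h + 1; sj <- (start - 1) %/% h + 1
  # clockwise Moore neighbourhood, starting west
  di <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dj <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  pts <- matrix(c(si, sj), 1, 2)
  if (!any(vapply(1:8, function(k) inside(si + di[k], sj + dj[k]), logical(1)))) {
    return(pts)  # isolated pixel
  }
  ci <- si; cj <- sj; backtrack <- 1L  # scan starts toward the west
  k1 <- NA_integer_                    # direction of the very first move
  cap <- 4L * h * w
  repeat {
    k <- NA_integer_
    for (s in 0:7) {
      kk <- (backtrack - 1L + s) %% 8L + 1L
      if (inside(ci + di[kk], cj + dj[kk])) { k <- kk; break }
    }
    if (is.na(k)) break
    # Jacob's stopping criterion: back at the start pixel, about to repeat
    # the initial move — the outer boundary is complete.
    if (!is.na(k1) && ci == si && cj == sj && k == k1) break
    ci <- ci + di[k]; cj <- cj + dj[k]
    if (is.na(k1)) k1 <- k
    pts <- rbind(pts, c(ci, cj))
    backtrack <- (k + 4L) %% 8L + 1L
    if (nrow(pts) > cap) break  # safety net
  }
  # drop a trailing revisit of the start pixel, if present
  n <- nrow(pts)
  if (n > 1L && pts[n, 1] == si && pts[n, 2] == sj) pts <- pts[-n, , drop = FALSE]
  pts
}

# Collapse collinear runs (horizontal, vertical, diagonal) to their
# endpoints — the simple chain approximation.
chain_approx_simple <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n); keep[1] <- TRUE; keep[n] <- TRUE
  for (i in 2:(n - 1)) {
    d1 <- pts[i, ] - pts[i - 1, ]
    d2 <- pts[i + 1, ] - pts[i, ]
    keep[i] <- !all(d1 == d2)
  }
  pts[keep, , drop = FALSE]
}

#' Retrieve external contours of a binary mask
#'
#' One contour per 8-connected foreground component: only the outermost
#' boundary is traced (interior holes are ignored), stored with collinear
#' runs collapsed to their endpoints. Each contour carries the filled pixel
#' area of its component.
#'
#' @param mask binary mask over \{0, 255\}.
#' @return list of contours, each a list with `points` (n x 2 matrix of
#'   1-based (row, col) boundary coordinates) and `area` (filled pixel
#'   count). Empty mask gives an empty list.
#' @export
find_external_contours <- function(mask) {
  assert_mask(mask)
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  areas <- tabulate(lab[lab > 0], nbins = n)
  # report in scan order of first appearance (column-major first pixel)
  first <- vapply(seq_len(n), function(id) which(lab == id)[1], integer(1))
  ord <- order(first)
  lapply(ord, function(id) {
    pts <- chain_approx_simple(trace_boundary(lab, id))
    list(points = pts, area = areas[id])
  })
}

#' Bounding box of the largest contour
#'
#' Selects the contour with maximum filled area (ties broken by scan order)
#' and returns the inclusive bounding box of its boundary points.
#'
#' @param contours list as returned by [find_external_contours()].
#' @return list with `row_min`, `col_min`, `row_max`, `col_max` (1-based,
#'   inclusive).
#' @export
largest_contour_bbox <- function(contours) {
  if (length(contours) == 0L) {
    no_contour_error("no contours found: preprocessing produced a blank mask")
  }
  areas <- vapply(contours, `[[`, numeric(1), "area")
  best <- contours[[which.max(areas)]]
  pts <- best$points
  list(row_min = min(pts[, 1]), col_min = min(pts[, 2]),
       row_max = max(pts[, 1]), col_max = max(pts[, 2]))
}

#' Crop an image to a bounding box
#'
#' @param img image (1- or 3-channel).
#' @param box inclusive bounding box as from [largest_contour_bbox()].
#' @return cropped image of shape
#'   `(row_max - row_min + 1) x (col_max - col_min + 1)`.
#' @export
crop_image <- function(img, box) {
  assert_image(img)
  h <- nrow(img); w <- ncol(img)
  if (box$row_min < 1 || box$col_min < 1 || box$row_max > h || box$col_max > w ||
      box$row_min > box$row_max || box$col_min > box$col_max) {
    stop("bounding box out of image bounds", call. = FALSE)
  }
  if (is.matrix(img)) {
    img[box$row_min:box$row_max, box$col_min:box$col_max, drop = FALSE]
  } else {
    img[box$row_min:box$row_max, box$col_min:box$col_max, , drop = FALSE]
  }
}

#' Brain extraction by largest-contour cropping
#'
#' The composite preprocessing stage: grayscale conversion, Gaussian
#' smoothing, global binarization, morphological opening, external contour
#' retrieval, then cropping the ORIGINAL (pre-binarization) image to the
#' bounding box of the largest blob. Parameters follow the conventional
#' brain-contour-cropping recipe and are all overridable.
#'
#' @param img input image (1- or 3-channel, 8-bit).
#' @param threshold binarization threshold (default 45).
#' @param kernel_size Gaussian window side (default 5).
#' @param sigma Gaussian sd; default derived from `kernel_size`.
#' @param morph a [morph_params()] (default 2 erosions, 2 dilations, 3x3).
#' @param verbose emit a per-image QC line (contour count, selected area,
#'   box) via `message()`.
#' @return cropped image (same channel count as the input), with the
#'   selected bounding box attached as attribute `"bbox"`.
#' @export
extract_brain <- function(img, threshold = 45, kernel_size = 5,
                          sigma = 0.3 * ((kernel_size - 1) / 2 - 1) + 0.8,
                          morph = morph_params(), verbose = FALSE) {
  assert_image(img)
  gray <- to_grayscale(img)
  smooth <- gaussian_smooth(gray, kernel_size, sigma)
  mask <- binarize(smooth, threshold)
  mask <- morph_clean(mask, morph)
  contours <- find_external_contours(mask)
  box <- largest_contour_bbox(contours)
  if (verbose) {
    areas <- vapply(contours, `[[`, numeric(1), "area")
    message(sprintf("extract_brain: %d contour(s), selected area %d, box [%d:%d, %d:%d]",
                    length(contours), max(areas),
                    box$row_min, box$row_max, box$col_min, box$col_max))
  }
  structure(crop_image(img, box), bbox = box)
}
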