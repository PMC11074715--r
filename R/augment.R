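# Deterministic geometric augmentation: rotations (exact permutations at
# right angles, bilinear with zero fill otherwise), horizontal/vertical
# flips, and centre zooms, composed into fixed expansion plans (x8, x36)
# that multiply a manifest by an exact factor.

#' Rotate an image about its centre
#'
#' Right-angle rotations (`theta` a multiple of 90) are exact pixel
#' permutations; other angles use bilinear resampling with zero (background)
#' fill. The output shape always equals the input shape.
#'
#' @param img 1- or 3-channel image.
#' @param theta rotation angle in degrees, counter-clockwise, in \[0, 360).
#' @return rotated image.
#' @export
rotate_image <- function(img, theta) {
  assert_image(img)
  theta <- theta %% 360
  if (theta == 0) return(img)
  per_channel(img, function(m) rotate_matrix(m, theta))
}

rotate_matrix <- function(m, theta) {
  if (theta == 90)  return(t(m)[rev(seq_len(ncol(m))), , drop = FALSE])
  if (theta == 180) return(m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE])
  if (theta == 270) return(t(m)[, rev(seq_len(nrow(m))), drop = FALSE])
  out <- EBImage::rotate(m, theta, filter = "bilinear",
                         output.dim = dim(m), bg.col = 0)
  clip8(floor(as.numeric_array(out) + 0.5))
}

per_channel <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  res <- lapply(seq_len(dim(img)[3L]), function(c) f(img[, , c]))
  array(unlist(res), dim = c(dim(res[[1]]), length(res)))
}

#' Flip an image
#'
#' A vertical flip negates the row (Y) coordinate, i.e. reverses rows; a
#' horizontal flip negates the column (X) coordinate, i.e. reverses columns.
#' Both are exact pixel permutations and involutions.
#'
#' @param img 1- or 3-channel image.
#' @param axis `"vertical"` or `"horizontal"`.
#' @return flipped image.
#' @export
flip_image <- function(img, axis = c("vertical", "horizontal")) {
  assert_image(img)
  axis <- match.arg(axis)
  per_channel(img, function(m) {
    if (axis == "vertical") m[rev(seq_len(nrow(m))), , drop = FALSE]
    else m[, rev(seq_len(ncol(m))), drop = FALSE]
  })
}

#' Centre zoom
#'
#' Zoom-in (`factor > 1`): the central `1/factor` crop is resized back to
#' the original shape. Zoom-out (`factor < 1`): the image is scaled down and
#' zero-padded back to the original shape. The output shape always equals
#' the input shape.
#'
#' @param img 1- or 3-channel image.
#' @param factor zoom factor (> 0).
#' @return zoomed image.
#' @export
zoom_image <- function(img, factor) {
  assert_image(img)
  if (factor <= 0) stop("`factor` must be > 0", call. = FALSE)
  if (factor == 1) return(img)
  h <- nrow(img); w <- ncol(img)
  if (factor > 1) {
    ch <- floor(h / factor); cw <- floor(w / factor)
    if (ch < 1 || cw < 1) stop("zoom factor too large for image size", call. = FALSE)
    r0 <- floor((h - ch) / 2) + 1L; c0 <- floor((w - cw) / 2) + 1L
    per_channel(img, function(m) {
      crop <- m[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
      resize_rect(crop, h, w)
    })
  } else {
    sh <- max(1L, round(h * factor)); sw <- max(1L, round(w * factor))
    r0 <- floor((h - sh) / 2) + 1L; c0 <- floor((w - sw) / 2) + 1L
    per_channel(img, function(m) {
      small <- resize_rect(m, sh, sw)
      out <- matrix(0, h, w)
      out[r0:(r0 + sh - 1L), c0:(c0 + sw - 1L)] <- small
      out
    })
  }
}

resize_rect <- function(m, h, w) {
  out <- EBImage::resize(m, w = w, h = h)
  clip8(floor(as.numeric_array(out) + 0.5))
}

#' A single augmentation operation
#'
#' Operations compose rotate -> flip -> zoom; elementary ops set the unused
#' components to their identities.
#'
#' @param theta rotation in degrees (0 = none).
#' @param flip `"none"`, `"h"` or `"v"`.
#' @param factor zoom factor (1 = none).
#' @return an `augment_op` list with a canonical `name`.
#' @export
augment_op <- function(theta = 0, flip = c("none", "h", "v"), factor = 1) {
  flip <- match.arg(flip)
  if (theta < 0 || theta >= 360) stop("`theta` must lie in [0, 360)", call. = FALSE)
  if (factor <= 0) stop("`factor` must be > 0", call. = FALSE)
  name <- if (theta == 0 && flip == "none" && factor == 1) "identity" else {
    parts <- character(0)
    if (theta != 0) parts <- c(parts, sprintf("rot%g", theta))
    if (flip != "none") parts <- c(parts, paste0("flip_", flip))
    if (factor != 1) parts <- c(parts, sprintf("zoom%g", factor))
    paste(parts, collapse = "_")
  }
  structure(list(theta = theta, flip = flip, factor = factor, name = name),
            class = "augment_op")
}

#' Apply one augmentation operation
#'
#' @param img image.
#' @param op an [augment_op()].
#' @return transformed image (same shape).
#' @export
apply_op <- function(img, op) {
  out <- img
  if (op$theta != 0) out <- rotate_image(out, op$theta)
  if (op$flip == "h") out <- flip_image(out, "horizontal")
  if (op$flip == "v") out <- flip_image(out, "vertical")
  if (op$factor != 1) out <- zoom_image(out, op$factor)
  out
}

#' Fixed expansion plans
#'
#' The two plan sizes implied by the study's dataset arithmetic: a 3000-image
#' collection expanded to 24000 needs an 8-op plan; a 253-image collection
#' expanded to 9108 needs a 36-op plan (and the same 8-op plan over 253
#' images yields the 2024-image unseen test set).
#'
#' * `k = 8`: identity, rotations 90/180/270, horizontal and vertical flips,
#'   zoom 1.25 and zoom 0.8.
#' * `k = 36`: the cartesian product of rotations \{0, 90, 180, 270, 15,
#'   345\} x flips \{none, h, v\} x zooms \{1, 1.25\}, identity first.
#'
#' @param k plan size, 8 or 36.
#' @return an `augmentation_plan` list with `ops` (list of [augment_op()],
#'   identity first, pairwise distinct) and `name` (`"x8"`/`"x36"`).
#' @export
standard_plan <- function(k) {
  if (!k %in% c(8L, 36L)) stop("supported plan sizes are 8 and 36", call. = FALSE)
  ops <- if (k == 8L) {
    list(augment_op(),
         augment_op(theta = 90), augment_op(theta = 180), augment_op(theta = 270),
         augment_op(flip = "h"), augment_op(flip = "v"),
         augment_op(factor = 1.25), augment_op(factor = 0.8))
  } else {
    grid <- expand.grid(factor = c(1, 1.25), flip = c("none", "h", "v"),
                        theta = c(0, 90, 180, 270, 15, 345),
                        stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(i) {
      augment_op(theta = grid$theta[i], flip = grid$flip[i],
                 factor = grid$factor[i])
    })
  }
  structure(list(ops = ops, name = paste0("x", k)), class = "augmentation_plan")
}

#' Expand a manifest through an augmentation plan
#'
#' Applies every op of `plan` to every image of `manifest`, writing the
#' results as PNGs under `out_dir`. Output row count is exactly
#' `nrow(manifest) * length(plan$ops)`; labels are inherited from the source
#' image, and each output row records its `source` path and `op` name.
#'
#' @param manifest data.frame with columns `path`, `label`.
#' @param plan an [standard_plan()] (or any `augmentation_plan`).
#' @param out_dir output directory (created if missing).
#' @return augmented manifest (`path`, `label`, `source`, `op`), also written
#'   to `file.path(out_dir, "manifest.csv")`.
#' @export
apply_plan <- function(manifest, plan, out_dir) {
  validate_manifest(manifest)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  nops <- length(plan$ops)
  n <- nrow(manifest)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    src <- manifest$path[i]
    if (!file.exists(src)) stop("cannot read image: ", src, call. = FALSE)
    img <- read_image(src)
    base <- tools::file_path_sans_ext(basename(src))
    rows <- vector("list", nops)
    for (j in seq_len(nops)) {
      op <- plan$ops[[j]]
      dst <- file.path(out_dir, sprintf("%s__%s.png", base, op$name))
      write_image(apply_op(img, op), dst)
      rows[[j]] <- data.frame(path = dst, label = manifest$label[i],
                              source = src, op = op$name,
                              stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  write_manifest(res, file.path(out_dir, "manifest.csv"))
  res
}
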