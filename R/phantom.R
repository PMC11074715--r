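# Synthetic brain-phantom generator: a bright ellipse ("brain") on a dark
# background, optionally containing a brighter disc ("tumor"), plus additive
# Gaussian noise. Every downstream stage (cropping, segmentation,
# augmentation, training, evaluation) is exercised on these phantoms, so the
# suite needs no external image data.

#' Specify a synthetic brain phantom
#'
#' @param height,width image size in pixels.
#' @param brain_axes length-2 numeric, ellipse semi-axes (row, col) in pixels.
#' @param brain_intensity mean grey level of the brain ellipse (0-255).
#' @param tumor_present logical; place a tumor disc?
#' @param tumor_radius tumor disc radius in pixels; must fit strictly inside
#'   the brain ellipse (`tumor_radius < min(brain_axes)`).
#' @param tumor_intensity mean grey level of the tumor disc; must exceed
#'   `brain_intensity`, which must exceed `background_intensity`.
#' @param noise_sd standard deviation of additive Gaussian noise (grey levels).
#' @param background_intensity mean grey level outside the brain.
#' @return a `phantom_spec` list.
#' @examples
#' sp <- phantom_spec(tumor_present = TRUE)
#' ph <- generate_phantom(sp, seed = 1)
#' table(ph$label)
#' @export
phantom_spec <- function(height = 200, width = 200,
                         brain_axes = c(70, 60),
                         brain_intensity = 120,
                         tumor_present = FALSE,
                         tumor_radius = 20,
                         tumor_intensity = 210,
                         noise_sd = 3,
                         background_intensity = 10) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               brain_axes = as.numeric(brain_axes),
               brain_intensity = brain_intensity,
               tumor_present = isTRUE(tumor_present),
               tumor_radius = tumor_radius,
               tumor_intensity = tumor_intensity,
               noise_sd = noise_sd,
               background_intensity = background_intensity)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (height < 8 || width < 8) stop("phantom must be at least 8 x 8", call. = FALSE)
    if (length(brain_axes) != 2L || any(brain_axes <= 0))
      stop("`brain_axes` must be two positive semi-axes", call. = FALSE)
    ints <- c(background_intensity, brain_intensity, tumor_intensity)
    if (any(ints < 0) || any(ints > 255))
      stop("intensities must lie in [0, 255]", call. = FALSE)
    if (!(tumor_intensity > brain_intensity && brain_intensity > background_intensity))
      stop("intensity ordering violated: need tumor > brain > background",
           call. = FALSE)
    if (tumor_present && tumor_radius >= min(brain_axes))
      stop("`tumor_radius` must be smaller than min(brain_axes)", call. = FALSE)
    if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  })
  invisible(spec)
}

#' Generate one labeled phantom image
#'
#' Deterministic for a given `(spec, seed)` pair. The brain ellipse centre is
#' jittered uniformly within +/-5% of the image size (so cropping is
#' non-trivial); when `tumor_present`, the tumor disc is placed strictly
#' inside the ellipse and returned as `tumor_mask`.
#'
#' @param spec a [phantom_spec()].
#' @param seed non-negative integer seed.
#' @return list with `image` (H x W matrix, 0-255), `label` (0/1) and
#'   `tumor_mask` (logical matrix, or `NULL` when no tumor).
#' @export
generate_phantom <- function(spec, seed) {
  validate_phantom_spec(spec)
  with_seed(seed, {
    h <- spec$height; w <- spec$width
    cy <- h / 2 + stats::runif(1, -0.05, 0.05) * h
    cx <- w / 2 + stats::runif(1, -0.05, 0.05) * w
    ry <- spec$brain_axes[1]; rx <- spec$brain_axes[2]

    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    brain <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1

    img <- matrix(spec$background_intensity, h, w)
    img[brain] <- spec$brain_intensity

    tumor_mask <- NULL
    if (spec$tumor_present) {
      # offset the tumor centre so the whole disc stays inside the ellipse:
      # shrink the ellipse by the tumor radius and sample a point within it
      margin_y <- ry - spec$tumor_radius
      margin_x <- rx - spec$tumor_radius
      repeat {
        oy <- stats::runif(1, -0.7, 0.7) * margin_y
        ox <- stats::runif(1, -0.7, 0.7) * margin_x
        if ((oy / margin_y)^2 + (ox / margin_x)^2 <= 1) break
      }
      ty <- cy + oy; tx <- cx + ox
      tumor_mask <- (rows - ty)^2 + (cols - tx)^2 <= spec$tumor_radius^2
      img[tumor_mask] <- spec$tumor_intensity
    }

    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    img <- round(clip8(img))

    list(image = img,
         label = as.integer(spec$tumor_present),
         tumor_mask = tumor_mask)
  })
}

#' Default phantom parameter ranges
#'
#' The ranges [generate_phantom_dataset()] samples from when none are given:
#' image sides 180-260 px, brain semi-axes 30-42% of the half-side, brain
#' intensity 110-150, tumor 80-110 grey levels above the brain, background
#' 10, tumor radius 15-35% of the smaller brain axis, noise_sd 3. These
#' emulate collections of modest-resolution axial slices of varying size.
#'
#' @return named list of length-2 numeric ranges.
#' @export
phantom_ranges <- function() {
  list(side = c(180, 260),
       axis_frac = c(0.30, 0.42),
       brain_intensity = c(110, 150),
       tumor_delta = c(80, 110),
       tumor_radius_frac = c(0.15, 0.35),
       noise_sd = c(3, 3),
       background_intensity = c(10, 10))
}

sample_phantom_spec <- function(ranges, tumor_present) {
  r <- function(nm) stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
  h <- round(r("side")); w <- round(r("side"))
  axes <- c(r("axis_frac") * h / 2, r("axis_frac") * w / 2)
  bi <- r("brain_intensity")
  phantom_spec(height = h, width = w, brain_axes = axes,
               brain_intensity = bi,
               tumor_present = tumor_present,
               tumor_radius = max(3, r("tumor_radius_frac") * min(axes)),
               tumor_intensity = min(255, bi + r("tumor_delta")),
               noise_sd = r("noise_sd"),
               background_intensity = r("background_intensity"))
}

#' Generate a labeled phantom dataset on disk
#'
#' Writes `n_tumor + n_normal` PNG files under `out_dir` plus a CSV manifest
#' (`manifest.csv`, columns `path,label`). Per-image specs are drawn from
#' `spec_ranges`; the whole dataset is reproducible under `seed` (identical
#' file bytes on repeated calls).
#'
#' @param n_tumor,n_normal class counts (label 1 / label 0).
#' @param out_dir output directory (created if missing).
#' @param seed non-negative integer seed.
#' @param spec_ranges parameter ranges as in [phantom_ranges()].
#' @return the manifest data.frame, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_phantom_dataset <- function(n_tumor, n_normal, out_dir, seed,
                                     spec_ranges = phantom_ranges()) {
  if (n_tumor < 0 || n_normal < 0) stop("class counts must be >= 0", call. = FALSE)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  labels <- c(rep(1L, n_tumor), rep(0L, n_normal))
  n <- length(labels)
  paths <- character(n)
  for (i in seq_len(n)) {
    base <- stage_seed(seed, "phantoms")
    spec <- with_seed((base + 2 * i) %% 2147483647,
                      sample_phantom_spec(spec_ranges, labels[i] == 1L))
    ph <- generate_phantom(spec, seed = (base + 2 * i + 1) %% 2147483647)
    nm <- sprintf("phantom_%s_%04d.png", ifelse(labels[i] == 1L, "yes", "no"), i)
    paths[i] <- file.path(out_dir, nm)
    write_image(ph$image, paths[i])
  }
  manifest <- data.frame(path = paths, label = labels, stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
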