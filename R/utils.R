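#' @keywords internal
"_PACKAGE"

# Shared helpers: 8-bit image conventions, conditions, seeded RNG scoping.
#
# Image convention used throughout the package: a 1-channel image is an
# integer-valued numeric matrix (rows = image rows, cols = image columns)
# with values in [0, 255]; a 3-channel image is an H x W x 3 array. Binary
# masks take values in {0, 255}. Coordinates are (row, col), 1-based in R
# code; bounding boxes are inclusive.

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; metric tables conventionally round
#' half up. Used only when formatting reported values, never in intermediate
#' arithmetic.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_image <- function(img) {
  is.numeric(img) && (is.matrix(img) || (is.array(img) && length(dim(img)) == 3L))
}

n_channels <- function(img) {
  if (is.matrix(img)) 1L else dim(img)[3L]
}

assert_image <- function(img, channels = NULL, arg = "img") {
  if (!is_image(img)) {
    stop(sprintf("`%s` must be a numeric matrix or H x W x C array", arg),
         call. = FALSE)
  }
  if (any(img < 0) || any(img > 255)) {
    stop(sprintf("`%s` has values outside [0, 255]", arg), call. = FALSE)
  }
  if (!is.null(channels) && !n_channels(img) %in% channels) {
    stop(sprintf("`%s` must have %s channel(s), got %d",
                 arg, paste(channels, collapse = " or "), n_channels(img)),
         call. = FALSE)
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  assert_image(mask, channels = 1L, arg = arg)
  if (!all(mask %in% c(0, 255))) {
    stop(sprintf("`%s` must be binary with values in {0, 255}", arg),
         call. = FALSE)
  }
  invisible(mask)
}

# Classed conditions so callers can distinguish pipeline failure modes.
stop_condition <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

no_contour_error       <- function(msg) stop_condition("contourtl_no_contour", msg)
degenerate_hist_error  <- function(msg) stop_condition("contourtl_degenerate_histogram", msg)
leakage_error          <- function(msg) stop_condition("contourtl_leakage", msg)
solver_error           <- function(msg) stop_condition("contourtl_solve_confusion", msg)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb unrelated randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# One top-level seed deterministically derives per-stage seeds; keeps every
# derived value a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  offsets <- c(phantoms = 101L, augment = 211L, split = 307L,
               train = 401L, model = 503L, generic = 601L)
  off <- offsets[[match.arg(stage, names(offsets))]]
  as.integer((as.numeric(seed) * 613 + off) %% 2147483647)
}

#' Read a PNG or JPEG file as an 8-bit image
#'
#' @param path file path (PNG; the phantom pipeline writes PNG only).
#' @return numeric matrix (grayscale) or H x W x 3 array, values 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- png::readPNG(path)
  x <- round(x * 255)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] >= 3L) x <- x[, , 1:3, drop = FALSE] else x <- x[, , 1L]
  }
  x
}

#' Write an 8-bit image to PNG
#'
#' @param img image matrix/array with values in [0, 255].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read / write a dataset manifest CSV
#'
#' Manifests are plain CSV files with at least columns `path` and `label`
#' (0 = no tumor, 1 = tumor); augmented manifests add `source` and `op`,
#' partitioned manifests add `split`.
#'
#' @param path CSV path.
#' @return data.frame with character `path` and integer `label`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  if (!is.data.frame(m) || !all(c("path", "label") %in% names(m))) {
    stop("manifest must be a data.frame with columns `path` and `label`",
         call. = FALSE)
  }
  if (!all(m$label %in% c(0L, 1L))) {
    stop("manifest labels must be 0 (no tumor) or 1 (tumor)", call. = FALSE)
  }
  invisible(m)
}
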