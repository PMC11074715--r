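# Train/validation/test partitioning. Two schemes from the study design:
# 80/20(+20%-of-pool): test = 20% of total, validation = 20% of the
# remaining training pool; and the unseen-case 70/30 scheme, where one
# dataset supplies train/validation and a wholly disjoint dataset is the
# test set. Counts use ceiling rounding on test and validation (the only
# rule consistent with the published split tables).

#' Split specification
#'
#' @param test_fraction fraction of the total rows assigned to test.
#' @param val_fraction fraction of the post-test training pool assigned to
#'   validation.
#' @param stratified preserve per-class proportions (default TRUE).
#' @param group_by_source keep all augmented variants of one source image in
#'   the same split (default TRUE; prevents leakage through augmented
#'   near-duplicates). Set FALSE for exact row-level counts.
#' @param seed shuffle seed.
#' @return a `split_spec` list.
#' @export
split_spec <- function(test_fraction = 0.2, val_fraction = 0.2,
                       stratified = TRUE, group_by_source = TRUE,
                       seed = 0) {
  if (test_fraction < 0 || test_fraction >= 1 ||
      val_fraction < 0 || val_fraction >= 1) {
    stop("fractions must lie in [0, 1)", call. = FALSE)
  }
  structure(list(test_fraction = test_fraction, val_fraction = val_fraction,
                 stratified = isTRUE(stratified),
                 group_by_source = isTRUE(group_by_source),
                 seed = seed),
            class = "split_spec")
}

#' Partition sizes under the ceiling-rounding rule
#'
#' `test = ceil(test_fraction * total)`; `val = ceil(val_fraction * (total -
#' test))`; `train` takes the remainder. This reproduces the published split
#' tables, e.g. 3000 rows at 20/20 give (1920, 480, 600) and 9108 rows give
#' (5828, 1458, 1822).
#'
#' @param total row count (>= 0).
#' @param spec a [split_spec()].
#' @return named integer vector `c(train=, val=, test=)`.
#' @export
partition_sizes <- function(total, spec = split_spec()) {
  if (total < 0) stop("`total` must be >= 0", call. = FALSE)
  test <- as.integer(ceiling(spec$test_fraction * total))
  pool <- total - test
  val <- as.integer(ceiling(spec$val_fraction * pool))
  train <- as.integer(pool - val)
  c(train = train, val = val, test = test)
}

# proportional integer allocation by largest remainder; sums exactly to `k`
allocate_counts <- function(sizes, k) {
  if (sum(sizes) == 0) return(integer(length(sizes)))
  q <- k * sizes / sum(sizes)
  base <- floor(q)
  rem <- k - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split a manifest into train/validation/test
#'
#' Assignment is by seeded shuffle; with `stratified`, per-class proportions
#' match the overall fractions to within one row per class; with
#' `group_by_source`, whole source-image groups are assigned together (split
#' sizes then match the target to within one group). Deterministic under
#' `(manifest order, seed)`.
#'
#' @param manifest data.frame with columns `path`, `label` (and optionally
#'   `source`).
#' @param spec a [split_spec()].
#' @return a `partition` list with data.frames `train`, `validation`, `test`.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  validate_manifest(manifest)
  if (nrow(manifest) == 0L) stop("manifest is empty", call. = FALSE)

  group <- if (spec$group_by_source && "source" %in% names(manifest)) {
    manifest$source
  } else {
    manifest$path
  }
  units <- unique(group)
  unit_label <- manifest$label[match(units, group)]
  unit_size <- as.integer(table(factor(group, levels = units)))

  sizes <- partition_sizes(nrow(manifest), spec)

  # scale row targets to unit (group) counts; for ungrouped manifests a
  # unit is a single row and this is exact
  n_units <- length(units)
  mean_size <- nrow(manifest) / n_units
  test_units <- as.integer(ceiling(sizes[["test"]] / mean_size - 1e-9))
  pool_units <- n_units - test_units
  val_units <- as.integer(ceiling(sizes[["val"]] / mean_size - 1e-9))
  if (test_units + val_units > n_units) {
    val_units <- n_units - test_units
  }

  assign_units <- character(n_units)
  names(assign_units) <- units
  strata <- if (spec$stratified) split(seq_len(n_units), unit_label)
            else list(seq_len(n_units))
  # per-stratum quotas by largest remainder, so totals are exact
  s_sizes <- vapply(strata, length, integer(1))
  te_q <- allocate_counts(s_sizes, test_units)
  va_q <- allocate_counts(s_sizes - te_q, val_units)
  with_seed(spec$seed, {
    for (s in seq_along(strata)) {
      idx <- strata[[s]]
      idx <- idx[sample.int(length(idx))]
      te <- utils::head(idx, te_q[s])
      va <- utils::head(setdiff(idx, te), va_q[s])
      tr <- setdiff(idx, c(te, va))
      assign_units[te] <- "test"; assign_units[va] <- "validation"
      assign_units[tr] <- "train"
    }
  })

  split_of_row <- assign_units[match(group, units)]
  out <- list(train      = manifest[split_of_row == "train", , drop = FALSE],
              validation = manifest[split_of_row == "validation", , drop = FALSE],
              test       = manifest[split_of_row == "test", , drop = FALSE])
  rownames(out$train) <- rownames(out$validation) <- rownames(out$test) <- NULL
  structure(out, class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: train %d / validation %d / test %d rows\n",
              nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Build the unseen-case evaluation scenario
#'
#' Train and validation rows are drawn from `train_manifest` (70/30 by
#' default, via `spec`); the test set is the ENTIRE `test_manifest`, which
#' must share no paths and no source images with the training collection —
#' any overlap raises a leakage error.
#'
#' @param train_manifest manifest supplying train/validation rows.
#' @param test_manifest wholly disjoint manifest used as the test set.
#' @param spec a [split_spec()]; default `test_fraction = 0`,
#'   `val_fraction = 0.3`.
#' @return a `partition` list.
#' @export
build_unseen_scenario <- function(train_manifest, test_manifest,
                                  spec = split_spec(test_fraction = 0,
                                                    val_fraction = 0.3)) {
  validate_manifest(train_manifest)
  if (nrow(test_manifest) > 0) validate_manifest(test_manifest)
  key <- function(m) {
    k <- m$path
    if ("source" %in% names(m)) k <- c(k, m$source)
    unique(k)
  }
  overlap <- intersect(key(train_manifest), key(test_manifest))
  if (length(overlap) > 0L) {
    leakage_error(paste0("train/test contamination: ",
                         length(overlap), " shared path(s)/source(s), e.g. ",
                         overlap[1]))
  }
  if (spec$test_fraction != 0) {
    spec$test_fraction <- 0
  }
  p <- split_dataset(train_manifest, spec)
  p$test <- test_manifest
  rownames(p$test) <- NULL
  p
}
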