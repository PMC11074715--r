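# Confusion-matrix algebra and the seven-metric report: sensitivity,
# specificity, precision (PPV), NPV, accuracy, F1 (as percentages, reported
# to 2 decimals, half-up) and ROC-AUC (a fraction in [0, 1]). Positive
# class = tumor present (label 1). Includes an exhaustive confusion-matrix
# reconstruction solver for validating printed metric rows.

#' Confusion matrix from binary labels
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels (1 = tumor).
#' @return a `confusion_matrix` list with counts `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("`y_true` and `y_pred` must have equal length >= 1", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  confusion_matrix(TP = sum(y_true == 1 & y_pred == 1),
                   FP = sum(y_true == 0 & y_pred == 1),
                   TN = sum(y_true == 0 & y_pred == 0),
                   FN = sum(y_true == 1 & y_pred == 0))
}

#' @rdname confusion
#' @param TP,FP,TN,FN non-negative counts.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("counts must be non-negative with at least one observation",
         call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
              dimnames = list(truth = c("tumor", "normal"),
                              predicted = c("tumor", "normal")))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Six-metric report from a confusion matrix
#'
#' Percentages rounded half-up to 2 decimals at reporting time only (all
#' intermediate arithmetic is exact): sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, NPV `TN/(TN+FN)`, accuracy
#' `(TP+TN)/N`, and F1 as the harmonic mean of precision and sensitivity.
#' A metric with a zero denominator is reported as `NA` (undefined), with a
#' warning, rather than silently as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_report` list of percentages.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sens <- 100 * safe_ratio(cm$TP, cm$TP + cm$FN, "sensitivity")
  spec <- 100 * safe_ratio(cm$TN, cm$TN + cm$FP, "specificity")
  prec <- 100 * safe_ratio(cm$TP, cm$TP + cm$FP, "precision")
  npv  <- 100 * safe_ratio(cm$TN, cm$TN + cm$FN, "npv")
  acc  <- 100 * (cm$TP + cm$TN) / (cm$TP + cm$FP + cm$TN + cm$FN)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    if (!is.na(prec) && !is.na(sens)) {
      warning("f1 undefined: precision + sensitivity is zero", call. = FALSE)
    }
    NA_real_
  } else 2 * prec * sens / (prec + sens)
  structure(lapply(list(sensitivity = sens, specificity = spec,
                        precision = prec, npv = npv,
                        accuracy = acc, f1 = f1),
                   round_half_up, digits = 2),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x)) {
    val <- if (is.na(x[[nm]])) "undefined" else {
      if (nm == "roc_auc") sprintf("%.4f", x[[nm]]) else sprintf("%.2f%%", x[[nm]])
    }
    cat(sprintf("%-12s %s\n", nm, val))
  }
  invisible(x)
}

#' ROC-AUC by the rank (Mann-Whitney) formula
#'
#' The probability that a uniformly random positive receives a higher score
#' than a uniformly random negative, ties counted one half — equal to the
#' trapezoidal area under the ROC curve.
#'
#' @param y_true 0/1 labels; both classes must be present.
#' @param scores numeric scores (probability of the positive class).
#' @return AUC fraction in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("`y_true` and `scores` must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute ROC-AUC", call. = FALSE)
  }
  r <- rank(scores)  # average ranks give ties weight 1/2
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Reconstruct a confusion matrix from printed metric values
#'
#' Exhaustively searches `TP` in `[0, n_pos]`, `TN` in `[0, n_neg]` for the
#' matrix whose metrics, rounded half-up to 2 decimals, match every supplied
#' printed value. Used to recover count-level results from published metric
#' rows. Errors if no matrix, or more than one, matches.
#'
#' @param n_pos,n_neg class totals (`TP + FN = n_pos`, `TN + FP = n_neg`).
#' @param printed named list/vector of printed percentages; any subset of
#'   `sensitivity`, `specificity`, `precision`, `npv`, `accuracy`, `f1`.
#' @return the unique matching [confusion_matrix()].
#' @export
solve_confusion <- function(n_pos, n_neg, printed) {
  if (n_pos < 1 || n_neg < 1) stop("class totals must be >= 1", call. = FALSE)
  printed <- as.list(printed)
  known <- intersect(names(printed),
                     c("sensitivity", "specificity", "precision", "npv",
                       "accuracy", "f1"))
  if (length(known) == 0L) stop("no usable printed metrics supplied", call. = FALSE)

  TP <- rep(0:n_pos, times = n_neg + 1L)
  TN <- rep(0:n_neg, each = n_pos + 1L)
  FN <- n_pos - TP
  FP <- n_neg - TN
  r2 <- function(x) round_half_up(x, 2)
  ok <- rep(TRUE, length(TP))
  for (nm in known) {
    v <- printed[[nm]]
    m <- switch(nm,
                sensitivity = 100 * TP / n_pos,
                specificity = 100 * TN / n_neg,
                precision   = 100 * TP / (TP + FP),
                npv         = 100 * TN / (TN + FN),
                accuracy    = 100 * (TP + TN) / (n_pos + n_neg),
                f1          = 100 * 2 * TP / (2 * TP + FP + FN))
    ok <- ok & !is.na(m) & r2(m) == r2(v)
  }
  hits <- which(ok)
  if (length(hits) == 0L) {
    solver_error("no confusion matrix reproduces the printed metrics")
  }
  if (length(hits) > 1L) {
    solver_error(sprintf("ambiguous: %d confusion matrices reproduce the printed metrics",
                         length(hits)))
  }
  confusion_matrix(TP = TP[hits], FP = FP[hits], TN = TN[hits], FN = FN[hits])
}
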