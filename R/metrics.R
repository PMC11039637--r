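# Pixel- and sample-level evaluation metrics.
#
# All percentage-valued metrics follow the standard textbook definitions.
# The published formulation this package accompanies prints several of
# them with typographical slips (an accuracy denominator missing FP,
# precision/sensitivity duplicating specificity, a nonstandard MCC
# numerator); `as_printed = TRUE` reproduces those literal formulas for
# auditing, while the default computes the standard quantities, which are
# the only ones consistent with reported results in this literature.

#' Confusion counts for binary masks or label vectors
#'
#' Tallies true/false positives and negatives between a prediction and a
#' reference.  Inputs may be binary masks (matrices) or equal-length
#' binary vectors; values must be 0/1 (or logical).
#'
#' @param pred predicted binary mask/labels.
#' @param truth reference binary mask/labels.
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `tp`, `tn`, `fp`, `fn`.
#' @examples
#' truth <- matrix(c(1, 1, 0, 0), 2)
#' pred  <- matrix(c(1, 0, 0, 0), 2)
#' confusion(pred, truth)
#' @export
confusion <- function(pred, truth) {
  pred <- as_binary_array(pred, "pred")
  truth <- as_binary_array(truth, "truth")
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    lf_stop(sprintf(
      "shape mismatch: pred is %s, truth is %s",
      paste(dim(pred) %||% length(pred), collapse = "x"),
      paste(dim(truth) %||% length(truth), collapse = "x")
    ))
  }
  p <- as.logical(pred)
  t <- as.logical(truth)
  counts <- list(
    tp = sum(p & t), tn = sum(!p & !t),
    fp = sum(p & !t), fn = sum(!p & t)
  )
  structure(counts, class = "confusion_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_binary_array <- function(x, name) {
  if (is.logical(x)) x <- x * 1L
  if (!is.numeric(x)) lf_check(FALSE, name, "must be numeric or logical")
  if (any(!x %in% c(0, 1))) lf_check(FALSE, name, "values must be binary (0/1)")
  x
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "confusion counts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
    x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn
  ))
  invisible(x)
}

as_confusion <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  lf_check(
    is.list(c) && all(c("tp", "tn", "fp", "fn") %in% names(c)),
    "c", "must be a confusion_counts object or list with tp/tn/fp/fn"
  )
  structure(c[c("tp", "tn", "fp", "fn")], class = "confusion_counts")
}

undefined_metric <- function(metric, reason) {
  lf_stop(sprintf("metric `%s` undefined: %s", metric, reason),
          class = "lesionforge_undefined_metric")
}

#' Pixel/sample accuracy (percent)
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`.  With `as_printed = TRUE`
#' the denominator omits FP, reproducing the literal published formula.
#'
#' @param c a [confusion()] result.
#' @param as_printed reproduce the literal (typographically flawed)
#'   published formula instead of the standard definition.
#' @return accuracy in percent.
#' @export
accuracy <- function(c, as_printed = FALSE) {
  c <- as_confusion(c)
  den <- if (as_printed) c$tp + c$tn + c$fn else c$tp + c$tn + c$fp + c$fn
  if (den <= 0) undefined_metric("accuracy", "zero denominator")
  100 * (c$tp + c$tn) / den
}

#' Specificity, sensitivity and precision (percent)
#'
#' Standard definitions: specificity `TN/(TN+FP)`, sensitivity (recall)
#' `TP/(TP+FN)`, precision `TP/(TP+FP)`, each scaled by 100.  With
#' `as_printed = TRUE`, `sensitivity()` and `precision()` return the
#' literal published formula, which duplicates specificity.
#'
#' @inheritParams accuracy
#' @return the metric in percent.
#' @export
specificity <- function(c, as_printed = FALSE) {
  c <- as_confusion(c)
  if (c$tn + c$fp <= 0) undefined_metric("specificity", "TN + FP is zero")
  100 * c$tn / (c$tn + c$fp)
}

#' @rdname specificity
#' @export
sensitivity <- function(c, as_printed = FALSE) {
  c <- as_confusion(c)
  if (as_printed) return(specificity(c))
  if (c$tp + c$fn <= 0) undefined_metric("sensitivity", "TP + FN is zero")
  100 * c$tp / (c$tp + c$fn)
}

#' @rdname specificity
#' @export
precision <- function(c, as_printed = FALSE) {
  c <- as_confusion(c)
  if (as_printed) return(specificity(c))
  if (c$tp + c$fp <= 0) undefined_metric("precision", "TP + FP is zero")
  100 * c$tp / (c$tp + c$fp)
}

#' F1 score (percent)
#'
#' Harmonic mean of precision and sensitivity, scaled to percent:
#' `2 * P * S / (P + S)` with `P`, `S` already in percent.
#'
#' @inheritParams accuracy
#' @return F1 in percent.
#' @export
f1 <- function(c, as_printed = FALSE) {
  c <- as_confusion(c)
  p <- precision(c, as_printed)
  s <- sensitivity(c, as_printed)
  if (p + s <= 0) undefined_metric("f1", "precision + sensitivity is zero")
  2 * p * s / (p + s)
}

#' Matthews correlation coefficient (percent scale)
#'
#' Standard MCC `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' scaled by 100 so it lies in \[-100, 100\].  If any marginal sum is
#' zero the coefficient is undefined; by documented convention 0 is
#' returned with a warning.  `as_printed = TRUE` uses the literal
#' published numerator `TP*TN - TP*FN`.
#'
#' @inheritParams accuracy
#' @return MCC on the percent scale.
#' @export
mcc <- function(c, as_printed = FALSE) {
  c <- as_confusion(c)
  m <- c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn)
  if (any(m == 0)) {
    warning("MCC undefined (zero marginal sum); returning 0 by convention")
    return(0)
  }
  num <- if (as_printed) c$tp * c$tn - c$tp * c$fn else c$tp * c$tn - c$fp * c$fn
  # products of marginals can overflow integers on large masks
  100 * num / sqrt(prod(as.numeric(m)))
}

#' Smoothed Jaccard and Dice coefficients
#'
#' For binary masks `pred` and `truth` with intersection `I`,
#' `jaccard = (eps + I) / (eps + |pred| + |truth| - I)` and
#' `dice = (2 I + eps) / (|pred| + |truth| + eps)`.  With `eps = 0`
#' these are the classical set overlap ratios; a positive `eps` is the
#' smoothing used by the segmentation fitness so that empty masks do not
#' produce 0/0.
#'
#' @param pred,truth binary masks of identical shape.
#' @param eps nonnegative smoothing constant (default 0).
#' @return a proportion in \[0, 1\].
#' @export
jaccard <- function(pred, truth, eps = 0) {
  s <- overlap_sums(pred, truth)
  (eps + s$inter) / (eps + s$np + s$nt - s$inter)
}

#' @rdname jaccard
#' @export
dice <- function(pred, truth, eps = 0) {
  s <- overlap_sums(pred, truth)
  (2 * s$inter + eps) / (s$np + s$nt + eps)
}

overlap_sums <- function(pred, truth) {
  pred <- as_binary_array(pred, "pred")
  truth <- as_binary_array(truth, "truth")
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    lf_stop("shape mismatch between pred and truth")
  }
  list(inter = sum(pred * truth), np = sum(pred), nt = sum(truth))
}

#' Ranking AUC for probability scores
#'
#' Area under the ROC curve computed by the rank statistic
#' (Mann-Whitney).  Provided for the package's own models.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as_binary_array(labels, "labels")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) undefined_metric("auc", "one class absent")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Tabulate segmentation metrics for sets of masks
#'
#' Computes per-image accuracy, sensitivity, specificity, Jaccard and
#' Dice plus a summary row (mean and sd), the report shape used by the
#' pipeline.
#'
#' @param preds,truths lists of binary masks.
#' @param eps smoothing constant for Jaccard/Dice (default 0).
#' @return a data.frame, one row per image plus `mean` and `sd` rows.
#' @export
metric_table <- function(preds, truths, eps = 0) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  rows <- lapply(seq_along(preds), function(i) {
    cc <- confusion(preds[[i]], truths[[i]])
    data.frame(
      image = i,
      accuracy = accuracy(cc),
      sensitivity = if (cc$tp + cc$fn > 0) sensitivity(cc) else NA_real_,
      specificity = if (cc$tn + cc$fp > 0) specificity(cc) else NA_real_,
      jaccard = jaccard(preds[[i]], truths[[i]], eps),
      dice = dice(preds[[i]], truths[[i]], eps)
    )
  })
  tab <- do.call(rbind, rows)
  num <- tab[, -1, drop = FALSE]
  summary <- data.frame(
    image = c(NA, NA),
    rbind(colMeans(num, na.rm = TRUE), apply(num, 2, sd, na.rm = TRUE))
  )
  rownames(summary) <- NULL
  out <- rbind(cbind(stat = "image", tab), cbind(stat = c("mean", "sd"), summary))
  rownames(out) <- NULL
  out
}
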