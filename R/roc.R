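#' Binary labels from ground-truth classes
#'
#' Only biopsy-proven malignant cases count as positive; benign and normal
#' cases are pooled as negative.
#'
#' @param cases A case table with a `truth_class` column, or a
#'   character/factor vector of truth classes.
#' @return Integer vector of 1 (malignant) and 0 (benign or normal).
#' @export
#' @examples
#' binary_labels(c("malignant", "benign", "normal"))
binary_labels <- function(cases) {
  cls <- if (is.data.frame(cases)) cases$truth_class else cases
  cls <- as_truth(cls)
  as.integer(cls == "malignant")
}

check_binary <- function(scores, labels, call = rlang::caller_env()) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length.", call = call)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    abort("`labels` must be binary (0/1).", call = call)
  }
  if (anyNA(scores) || anyNA(labels)) abort("Missing values are not supported.", call = call)
  if (sum(labels == 1L) == 0) abort("No positive (malignant) cases in input.", call = call)
  if (sum(labels == 0L) == 0) abort("No negative (benign/normal) cases in input.", call = call)
  labels
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC of a continuous score against binary truth,
#' with one operating point per distinct score value (a case is called
#' positive when its score is at or above the threshold; ties collapse to
#' a single point) plus the two trivial endpoints at thresholds -Inf and
#' +Inf. Higher scores mean more suspicion.
#'
#' @param scores Numeric score vector.
#' @param labels Binary truth vector (1 = malignant), e.g. from
#'   [binary_labels()].
#' @return An object of class `roc_curve`: operating points
#'   (`threshold`, `sensitivity`, `specificity`) plus positive/negative
#'   counts. Sensitivity is non-increasing and specificity non-decreasing
#'   in the threshold.
#' @export
#' @examples
#' empirical_roc(c(0.9, 0.1, 0.4), c(1, 0, 0))
empirical_roc <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  thr <- sort(unique(scores))
  points <- tibble::tibble(
    threshold = c(-Inf, thr, Inf),
    sensitivity = vapply(c(-Inf, thr, Inf), function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(c(-Inf, thr, Inf), function(t) mean(neg < t), numeric(1))
  )
  structure(
    list(points = points, n_pos = length(pos), n_neg = length(neg)),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> %d operating points, %d positives / %d negatives, AUC %.4f\n",
    nrow(x$points), x$n_pos, x$n_neg, roc_curve_area(x)
  ))
  invisible(x)
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve A `roc_curve`.
#' @return The trapezoidal AUC; equal to the Mann-Whitney estimate of
#'   [roc_auc()] for the same data.
#' @export
roc_curve_area <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fpr <- 1 - curve$points$specificity
  tpr <- curve$points$sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Mann-Whitney AUC
#'
#' The empirical AUC as the Mann-Whitney statistic: the proportion of
#' (positive, negative) case pairs in which the positive scores higher,
#' counting ties as half. Computed via midranks in O(n log n).
#'
#' @inheritParams empirical_roc
#' @return The AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
roc_auc <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Maximum-Youden operating point
#'
#' Finds the operating point maximizing Youden's index
#' J = sensitivity + specificity - 1. Ties are broken toward higher
#' specificity, then lower threshold. A curve consisting only of the two
#' trivial endpoints carries no usable operating point and returns a J = 0
#' point with a warning.
#'
#' @param curve A `roc_curve` from [empirical_roc()].
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
#' @examples
#' curve <- empirical_roc(c(0.9, 0.7, 0.3, 0.2), c(1, 1, 0, 0))
#' max_youden(curve)
max_youden <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- dplyr::mutate(curve$points, youden_j = .data$sensitivity + .data$specificity - 1)
  interior <- dplyr::filter(pts, is.finite(.data$threshold))
  if (nrow(interior) == 0) {
    warn("Degenerate ROC curve (endpoints only); returning a J = 0 operating point.")
    return(tibble::tibble(threshold = Inf, sensitivity = 0, specificity = 1, youden_j = 0))
  }
  best <- dplyr::arrange(
    pts,
    dplyr::desc(.data$youden_j), dplyr::desc(.data$specificity), .data$threshold
  )[1, ]
  tibble::as_tibble(best)
}

#' Youden's index from a sensitivity/specificity pair
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @return J = sensitivity + specificity - 1.
#' @export
#' @examples
#' youden_index(0.761, 0.889)  # 0.650
youden_index <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}
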