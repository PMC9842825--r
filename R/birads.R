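#' BI-RADS assessment vocabulary
#'
#' The seven ordinal BI-RADS assessment categories used by simulated readers,
#' ordered by increasing suspicion: 1 (negative), 2 (benign), 3 (probably
#' benign), 4a/4b/4c (suspicious, low/moderate/high), 5 (highly suggestive of
#' malignancy).
#'
#' @return Character vector of the seven category labels, least to most
#'   suspicious.
#' @export
#' @examples
#' birads_levels()
birads_levels <- function() {
  c("1", "2", "3", "4a", "4b", "4c", "5")
}

#' Coerce to an ordered BI-RADS factor
#'
#' @param x Character or factor vector of category labels.
#' @return Ordered factor over [birads_levels()].
#' @export
as_birads <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), birads_levels())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown BI-RADS category label(s): %s (expected one of %s)",
      paste(bad, collapse = ", "), paste(birads_levels(), collapse = ", ")
    ))
  }
  factor(x, levels = birads_levels(), ordered = TRUE)
}

#' Truth-class vocabulary
#'
#' @return The three ground-truth classes, in reporting order.
#' @export
truth_levels <- function() {
  c("malignant", "benign", "normal")
}

as_truth <- function(x) {
  x <- tolower(as.character(x))
  bad <- setdiff(unique(x[!is.na(x)]), truth_levels())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown truth class label(s): %s (expected one of %s, matched case-insensitively)",
      paste(bad, collapse = ", "), paste(truth_levels(), collapse = ", ")
    ))
  }
  factor(x, levels = truth_levels())
}
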