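#' Min-max normalization to \[0, 1\]
#'
#' Affine map sending the observed minimum to 0 and maximum to 1. Order
#' (and hence any ROC quantity) is preserved. The scale is taken from the
#' full vector, i.e. the whole analyzed cohort.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @param range Optional fixed scale bounds `c(min, max)` to use instead of
#'   the observed extremes (e.g. `c(1, 100)` for a score reported on a
#'   1-100 scale).
#' @return Numeric vector in \[0, 1\] (values outside a fixed `range` are
#'   clipped).
#' @export
#' @examples
#' minmax_normalize(c(10, 20, 30))
minmax_normalize <- function(scores, range = NULL) {
  if (anyNA(scores)) abort("Missing scores are not supported.")
  if (is.null(range)) {
    range <- base::range(scores)
  } else {
    stopifnot(length(range) == 2)
  }
  if (range[2] <= range[1]) {
    abort("Normalization undefined: scores are constant (no distinct values).")
  }
  pmin(pmax((scores - range[1]) / (range[2] - range[1]), 0), 1)
}

#' Weighted average of two normalized modality scores
#'
#' Case-level late fusion: `w_dm * norm_dm + (1 - w_dm) * norm_abus`. The
#' two weights sum to one; with inputs in \[0, 1\] the fused suspicion
#' score stays in \[0, 1\].
#'
#' @param norm_dm,norm_abus Normalized score vectors aligned on cases.
#' @param w_dm Mammography weight in \[0, 1\]; the ultrasound weight is
#'   `1 - w_dm`.
#' @return Fused score vector.
#' @export
#' @examples
#' fuse_scores(0.4, 0.8, w_dm = 0.25)  # 0.7
fuse_scores <- function(norm_dm, norm_abus, w_dm) {
  if (length(norm_dm) != length(norm_abus)) {
    abort("Modality score vectors must be aligned: equal lengths required.")
  }
  stopifnot(length(w_dm) == 1, w_dm >= 0, w_dm <= 1)
  w_dm * norm_dm + (1 - w_dm) * norm_abus
}

#' Fusion weight sweep
#'
#' Normalizes both modality scores to \[0, 1\], fuses them at every weight
#' on a grid (default 0.01 to 0.99 in steps of 0.01, weights summing to 1),
#' and records the AUC against malignant-vs-rest truth at each grid point.
#' The optimum is the weight with maximal AUC; exact ties are broken toward
#' the weight closest to 0.5, then toward the smaller weight. The selection
#' is in-sample: the same cohort supplies the normalization scale, the AUC
#' profile and the argmax.
#'
#' @param cases Case table with `truth_class`, `score_dm`, `score_abus`.
#' @param grid_start,grid_stop,grid_step Weight grid for the mammography
#'   weight.
#' @param range_dm,range_abus Optional fixed normalization bounds per
#'   modality (see [minmax_normalize()]); default uses cohort min/max.
#' @return An object of class `fusion_result`: the `weight`/`auc` sweep
#'   profile, the optimal weight pair, the AUC at the optimum, and the
#'   fused scores at the optimum.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(30, 30, 60, seed = 5))
#' ws <- weight_sweep(cohort)
#' ws$optimal_weight_dm
weight_sweep <- function(cases, grid_start = 0.01, grid_stop = 0.99,
                         grid_step = 0.01, range_dm = NULL, range_abus = NULL) {
  stopifnot(grid_start > 0, grid_stop < 1, grid_start <= grid_stop, grid_step > 0)
  for (col in c("score_dm", "score_abus")) {
    if (!col %in% names(cases)) abort(sprintf("Case table lacks the `%s` column.", col))
  }
  labels <- check_binary(cases$score_dm, binary_labels(cases))
  norm_dm <- tryCatch(
    minmax_normalize(cases$score_dm, range = range_dm),
    error = function(e) abort(paste0("Modality `dm`: ", conditionMessage(e)))
  )
  norm_abus <- tryCatch(
    minmax_normalize(cases$score_abus, range = range_abus),
    error = function(e) abort(paste0("Modality `abus`: ", conditionMessage(e)))
  )
  grid <- seq(grid_start, grid_stop, by = grid_step)
  aucs <- vapply(grid, function(w) {
    roc_auc(fuse_scores(norm_dm, norm_abus, w), labels)
  }, numeric(1))
  best_auc <- max(aucs)
  tied <- which(aucs == best_auc)
  # ties: closest to 0.5, then smaller weight
  tied <- tied[order(abs(grid[tied] - 0.5), grid[tied])]
  opt <- tied[1]
  structure(
    list(
      sweep = tibble::tibble(weight_dm = grid, auc = aucs),
      optimal_weight_dm = grid[opt],
      optimal_weight_abus = 1 - grid[opt],
      optimal_auc = aucs[opt],
      fused_scores = fuse_scores(norm_dm, norm_abus, grid[opt]),
      norm_dm = norm_dm, norm_abus = norm_abus,
      n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)
    ),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("Fusion weight sweep\n")
  cat(sprintf("  grid: %d weights in [%.2f, %.2f]\n",
              nrow(x$sweep), min(x$sweep$weight_dm), max(x$sweep$weight_dm)))
  cat(sprintf("  optimum: w_dm = %.2f, w_abus = %.2f, fused AUC = %.4f\n",
              x$optimal_weight_dm, x$optimal_weight_abus, x$optimal_auc))
  invisible(x)
}
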