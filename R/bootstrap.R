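#' Stratified percentile bootstrap confidence interval
#'
#' Case-level resampling with replacement, stratified by `truth_class` so
#' that every replicate keeps the cohort's class composition, with the
#' percentile interval at the requested level. If the metric fails or
#' returns a non-finite value on a replicate (possible only without
#' stratification, e.g. a resample with no positives), the replicate is
#' redrawn and the redraw counted.
#'
#' @param cases A case table (must contain `truth_class` when
#'   `stratify = TRUE`).
#' @param metric A function taking a case table and returning a single
#'   number.
#' @param n_replicates Number of bootstrap replicates (default 2000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param seed Integer seed; the same seed reproduces the same interval.
#' @param stratify Resample within truth classes (default `TRUE`).
#' @return An object of class `interval_estimate`: `point` (metric on the
#'   original table), `lower`, `upper`, `level`, `n_replicates`,
#'   `n_redraws`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(25, 25, 50, seed = 3))
#' bootstrap_ci(cohort, function(d) roc_auc(d$score_dm, binary_labels(d)),
#'              n_replicates = 200, seed = 9)
bootstrap_ci <- function(cases, metric, n_replicates = 2000, level = 0.95,
                         seed = 1L, stratify = TRUE) {
  stopifnot(is.function(metric), n_replicates >= 1, level > 0, level < 1)
  point <- metric(cases)
  if (length(point) != 1 || !is.finite(point)) {
    abort("`metric` must return a single finite number on the input table.")
  }
  idx_by_stratum <- if (stratify) {
    split(seq_len(nrow(cases)), as.character(cases$truth_class))
  } else {
    list(seq_len(nrow(cases)))
  }
  n_redraws <- 0L
  stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_replicates), function(b) {
      for (attempt in seq_len(1000L)) {
        idx <- unlist(lapply(idx_by_stratum, function(ix) {
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
        val <- tryCatch(metric(cases[idx, , drop = FALSE]), error = function(e) NA_real_)
        if (length(val) == 1 && is.finite(val)) return(val)
        n_redraws <<- n_redraws + 1L
      }
      abort("Metric failed on 1000 consecutive bootstrap resamples.")
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7))
  structure(
    list(
      point = point, lower = ci[1], upper = ci[2],
      level = level, n_replicates = as.integer(n_replicates),
      n_redraws = n_redraws, seed = as.integer(seed)
    ),
    class = "interval_estimate"
  )
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.4f  [%g%% CI: %.4f, %.4f]  (%d bootstrap replicates%s)\n",
              x$point, 100 * x$level, x$lower, x$upper, x$n_replicates,
              if (x$n_redraws > 0) sprintf(", %d redraws", x$n_redraws) else ""))
  invisible(x)
}
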