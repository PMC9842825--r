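#' Plot an empirical ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot: sensitivity against 1 - specificity with the chance
#'   diagonal.
#' @export
autoplot.roc_curve <- function(object, ...) {
  pts <- dplyr::arrange(object$points, 1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Empirical ROC (AUC = %.3f)", roc_curve_area(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fusion weight sweep
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot of AUC against the mammography weight, with the
#'   selected optimum marked.
#' @export
autoplot.fusion_result <- function(object, ...) {
  ggplot2::ggplot(object$sweep, ggplot2::aes(x = .data$weight_dm, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimal_weight_dm,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::annotate(
      "point", x = object$optimal_weight_dm, y = object$optimal_auc, size = 2
    ) +
    ggplot2::labs(
      x = "Mammography weight (ultrasound weight = 1 - w)",
      y = "Fused AUC",
      title = sprintf("Fusion sweep: optimum w_dm = %.2f (AUC = %.3f)",
                      object$optimal_weight_dm, object$optimal_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Study ROC overlay with reader operating points
#'
#' Overlays the empirical ROC curves of the three arms (mammography,
#' ultrasound, fused) with the operating points of any reader strategies
#' in the report, mirroring the standard presentation of an AI-vs-readers
#' benchmarking study.
#'
#' @param report A `study_report` from [run_study()].
#' @param subcohort Plot on the observer subcohort (default `TRUE`, where
#'   reader strategies live) instead of the full cohort.
#' @return A ggplot.
#' @export
plot_study_roc <- function(report, subcohort = TRUE) {
  stopifnot(inherits(report, "study_report"))
  cases <- if (subcohort) {
    # subcohort rows are recoverable from the stored case table via the
    # composition and seed recorded in the report
    report$cases[report$cases$case_id %in% subcohort_ids(report), , drop = FALSE]
  } else {
    report$cases
  }
  labels <- binary_labels(cases)
  arms <- c(dm = "score_dm", abus = "score_abus", fused = "score_fused")
  curves <- purrr::imap_dfr(arms, function(col, arm) {
    dplyr::mutate(empirical_roc(cases[[col]], labels)$points, arm = arm)
  })
  curves <- dplyr::arrange(curves, .data$arm, 1 - .data$specificity, .data$sensitivity)
  p <- ggplot2::ggplot(
    curves, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity, colour = .data$arm)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = "Arm") +
    ggplot2::theme_minimal()
  if (!is.null(report$readers)) {
    p <- p + ggplot2::geom_point(
      data = report$readers,
      mapping = ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity,
                             shape = .data$strategy),
      inherit.aes = FALSE, size = 2
    ) +
      ggplot2::labs(shape = "Reader strategy")
  }
  p
}

# case ids of the observer subcohort implied by the report's stored cases
# and subcohort composition (all malignant; benign/normal resampled with
# the report's seed offset, matching run_study)
subcohort_ids <- function(report) {
  sub <- subsample_observer_cohort(
    report$cases,
    n_benign = report$subcohort_summary$n[report$subcohort_summary$truth_class == "benign"],
    n_normal = report$subcohort_summary$n[report$subcohort_summary$truth_class == "normal"],
    seed = report$provenance$seed + 3L
  )
  sub$case_id
}
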