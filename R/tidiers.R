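#' Tidy an ROC curve
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return Tibble of operating points (`threshold`, `sensitivity`,
#'   `specificity`).
#' @export
tidy.roc_curve <- function(x, ...) {
  x$points
}

#' @rdname tidy.roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(
    auc = roc_curve_area(x),
    n_points = nrow(x$points),
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}

#' Tidy a DeLong paired test result
#'
#' @param x A `delong_result`.
#' @param ... Unused.
#' @return One-row tibble with the two AUCs, their difference, variances,
#'   covariance, z and two-sided p-value.
#' @export
tidy.delong_result <- function(x, ...) {
  tibble::tibble(
    arm_a = x$names[1], arm_b = x$names[2],
    auc_a = x$auc_a, auc_b = x$auc_b,
    auc_diff = x$auc_a - x$auc_b,
    var_a = x$var_a, var_b = x$var_b, cov_ab = x$cov_ab,
    z = x$z, p_value = x$p_value,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname tidy.delong_result
#' @export
glance.delong_result <- tidy.delong_result

#' Tidy a fusion weight sweep
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return `tidy()`: the weight/AUC profile, one row per grid weight.
#'   `glance()`: one row with the optimal weight pair and AUC.
#' @export
tidy.fusion_result <- function(x, ...) {
  x$sweep
}

#' @rdname tidy.fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  tibble::tibble(
    optimal_weight_dm = x$optimal_weight_dm,
    optimal_weight_abus = x$optimal_weight_abus,
    optimal_auc = x$optimal_auc,
    n_weights = nrow(x$sweep),
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}

#' Tidy an interval estimate
#'
#' @param x An `interval_estimate` from [bootstrap_ci()].
#' @param ... Unused.
#' @return One-row tibble: point, lower, upper, level, replicate count.
#' @export
tidy.interval_estimate <- function(x, ...) {
  tibble::tibble(
    point = x$point, lower = x$lower, upper = x$upper,
    level = x$level, n_replicates = x$n_replicates, n_redraws = x$n_redraws
  )
}

#' Tidy a study report
#'
#' @param x A `study_report` from [run_study()].
#' @param ... Unused.
#' @return `tidy()`: the per-arm AUC table with confidence intervals.
#'   `glance()`: one row with the headline quantities (per-arm AUCs,
#'   optimal weights, DeLong p-values).
#' @export
tidy.study_report <- function(x, ...) {
  x$aucs
}

#' @rdname tidy.study_report
#' @export
glance.study_report <- function(x, ...) {
  auc_of <- function(arm) x$aucs$auc[x$aucs$arm == arm]
  tibble::tibble(
    n_cases = x$provenance$n_cases,
    auc_dm = auc_of("dm"),
    auc_abus = auc_of("abus"),
    auc_fused = auc_of("fused"),
    optimal_weight_dm = x$fusion$optimal_weight_dm,
    optimal_weight_abus = x$fusion$optimal_weight_abus,
    p_fused_vs_dm = x$delong$fused_vs_dm$p_value,
    p_fused_vs_abus = x$delong$fused_vs_abus$p_value
  )
}
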