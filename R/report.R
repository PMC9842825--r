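# printed-precision conventions: AUC and Youden J to 3 decimals,
# percentages to 1 decimal
fmt3 <- function(x) sprintf("%.3f", x)
fmt_pct <- function(x) sprintf("%.1f", 100 * x)
fmt_ci_pct <- function(lo, hi) sprintf("[%.1f, %.1f]", 100 * lo, 100 * hi)

#' Render a study report to files
#'
#' Writes the report as plain-text and delimited outputs: a cohort
#' composition table, the per-arm AUC summary with confidence intervals,
#' the DeLong comparisons, the maximum-Youden operating points, the full
#' fusion weight/AUC sweep profile (for plotting), the reader strategy
#' table (one row per strategy with sensitivity, specificity and CIs), and
#' a machine-readable provenance block. AUC and Youden values print with 3
#' decimals and percentages with 1 decimal. When the report carries no
#' reader strategies the reader table is omitted with a notice.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @param format `"text"`, `"delimited"`, or both (default).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, dir, format = c("text", "delimited")) {
  stopifnot(inherits(report, "study_report"))
  format <- match.arg(format, several.ok = TRUE)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", dir))
  }
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  if ("delimited" %in% format) {
    wr(report$cohort_summary, "cohort_composition.csv")
    wr(report$aucs, "auc_summary.csv")
    wr(purrr::map_dfr(report$delong, tidy, .id = "comparison"), "delong_tests.csv")
    wr(report$youden, "youden_points.csv")
    wr(report$fusion$sweep, "fusion_sweep.csv")
    wr(glance(report$fusion), "fusion_summary.csv")
    wr(report$subcohort_aucs, "subcohort_auc.csv")
    if (!is.null(report$readers)) {
      wr(report$readers, "reader_strategies.csv")
    } else {
      inform("No reader scores in the cohort; reader strategy table omitted.")
    }
  }
  if ("text" %in% format) {
    p <- file.path(dir, "report.txt")
    writeLines(format_study_report(report), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

format_study_report <- function(x) {
  comp <- x$cohort_summary
  lines <- c(
    "Multi-modal AI screening evaluation",
    "===================================",
    "",
    sprintf("Cohort: %s (total %d)",
            paste(sprintf("%d %s", comp$n, as.character(comp$truth_class)), collapse = ", "),
            sum(comp$n)),
    "",
    "AUC (malignant vs benign+normal)",
    purrr::pmap_chr(x$aucs, function(arm, auc, lower, upper, level) {
      sprintf("  %-6s %s  [%g%% CI: %s, %s]", arm, fmt3(auc), 100 * level,
              fmt3(lower), fmt3(upper))
    }),
    "",
    "DeLong paired comparisons",
    purrr::map_chr(x$delong, function(d) {
      sprintf("  %s vs %s: dAUC %+0.3f, z = %.3f, p = %.3f",
              d$names[1], d$names[2], d$auc_a - d$auc_b, d$z, d$p_value)
    }),
    "",
    "Maximum-Youden operating points",
    purrr::pmap_chr(x$youden, function(arm, threshold, sensitivity, specificity, youden_j) {
      sprintf("  %-6s J = %s  (sensitivity %s%%, specificity %s%%)",
              arm, fmt3(youden_j), fmt_pct(sensitivity), fmt_pct(specificity))
    }),
    "",
    sprintf("Fusion optimum: w_dm = %.2f, w_abus = %.2f, fused AUC = %s",
            x$fusion$optimal_weight_dm, x$fusion$optimal_weight_abus,
            fmt3(x$fusion$optimal_auc)),
    "",
    sprintf("Observer subcohort: %s (total %d)",
            paste(sprintf("%d %s", x$subcohort_summary$n,
                          as.character(x$subcohort_summary$truth_class)), collapse = ", "),
            sum(x$subcohort_summary$n)),
    purrr::pmap_chr(x$subcohort_aucs, function(arm, auc) {
      sprintf("  subcohort AUC %-6s %s", arm, fmt3(auc))
    }),
    sprintf("  subcohort fused max-Youden: sensitivity %s%%, specificity %s%%",
            fmt_pct(x$subcohort_youden$sensitivity),
            fmt_pct(x$subcohort_youden$specificity))
  )
  if (!is.null(x$readers)) {
    lines <- c(
      lines, "",
      sprintf("Reader strategies (recall at BI-RADS >= %s)", x$readers$threshold[1]),
      "  strategy                       sens (%)  spec (%)",
      purrr::pmap_chr(x$readers, function(label, strategy, readers, threshold,
                                          sensitivity, specificity,
                                          sens_lower, sens_upper,
                                          spec_lower, spec_upper, level) {
        sprintf("  %-28s %6s %s  %6s %s",
                label, fmt_pct(sensitivity), fmt_ci_pct(sens_lower, sens_upper),
                fmt_pct(specificity), fmt_ci_pct(spec_lower, spec_upper))
      })
    )
  }
  c(lines, "",
    sprintf("seed %d | config %s | mmroc %s",
            x$provenance$seed, x$provenance$config_hash, x$provenance$package_version))
}
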