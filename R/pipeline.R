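#' Study configuration
#'
#' Bundles everything a full study run needs: the input source (either a
#' case-table file or a simulation setup), the fusion weight grid, the
#' bootstrap settings, the recall rule and the output directory. Exactly
#' one input source is used: a file path, or a cohort configuration plus
#' generative model (with optional simulated readers).
#'
#' All randomness in [run_study()] derives from the single `seed` by fixed
#' offsets (cohort draw: `seed`; reader scores: `seed + 1`; bootstrap:
#' `seed + 2` onwards; observer subsample: `seed + 3`), so a config
#' reproduces a report bit-identically and each component is independently
#' reproducible.
#'
#' @param input_path Optional path to a case-table file (see
#'   [read_case_table()]). When given, the simulation fields are unused.
#' @param cohort A [cohort_config()] (its seed is overridden by `seed`).
#' @param model A [binormal_model()].
#' @param reader_profiles Named list of [reader_profile()]s simulated onto
#'   the cohort, or `NULL` for no readers.
#' @param grid_start,grid_stop,grid_step Fusion weight grid
#'   (see [weight_sweep()]).
#' @param n_replicates,level Bootstrap replicate count (>= 1) and
#'   confidence level.
#' @param recall_threshold BI-RADS recall threshold for reader strategies.
#' @param vote_on Panel voting order (see [evaluate_strategy()]).
#' @param observer_n_benign,observer_n_normal Observer-subcohort sampling:
#'   all malignant cases plus this many randomly chosen benign and normal
#'   cases (defaults 30 and 80).
#' @param seed Root seed for the whole run.
#' @param output_dir Optional directory; when set, [run_study()] writes
#'   the rendered report there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(input_path = NULL,
                         cohort = cohort_config(),
                         model = default_binormal_model(),
                         reader_profiles = default_reader_profiles(),
                         grid_start = 0.01, grid_stop = 0.99, grid_step = 0.01,
                         n_replicates = 2000, level = 0.95,
                         recall_threshold = "3",
                         vote_on = c("category", "recall"),
                         observer_n_benign = 30, observer_n_normal = 80,
                         seed = 1L, output_dir = NULL) {
  if (!is.null(input_path) && !missing(cohort)) {
    abort("Specify exactly one input source: `input_path` or a simulated `cohort`.")
  }
  stopifnot(n_replicates >= 1, level > 0, level < 1)
  if (is.null(input_path)) {
    stopifnot(inherits(cohort, "cohort_config"))
    cohort$seed <- as.integer(seed)
    model <- binormal_model(model)
  }
  structure(
    list(
      input_path = input_path,
      cohort = if (is.null(input_path)) cohort else NULL,
      model = if (is.null(input_path)) model else NULL,
      reader_profiles = if (is.null(input_path)) reader_profiles else NULL,
      grid_start = grid_start, grid_stop = grid_stop, grid_step = grid_step,
      n_replicates = as.integer(n_replicates), level = level,
      recall_threshold = as.character(recall_threshold),
      vote_on = match.arg(vote_on),
      observer_n_benign = as.integer(observer_n_benign),
      observer_n_normal = as.integer(observer_n_normal),
      seed = as.integer(seed),
      output_dir = output_dir
    ),
    class = "study_config"
  )
}

#' Observer-study subcohort
#'
#' All malignant cases plus a seeded random sample of benign and normal
#' cases — the enrichment scheme of a reader study that keeps every cancer
#' and downsamples the rest (default 30 benign and 80 normal, giving a
#' 152-case subcohort under the default composition).
#'
#' @param cases Case table.
#' @param n_benign,n_normal Number of benign / normal cases to sample
#'   (capped at availability).
#' @param seed Integer sampling seed.
#' @return The subcohort, in original row order.
#' @export
subsample_observer_cohort <- function(cases, n_benign = 30, n_normal = 80, seed = 1L) {
  cls <- as.character(as_truth(cases$truth_class))
  keep_mal <- which(cls == "malignant")
  idx_b <- which(cls == "benign")
  idx_n <- which(cls == "normal")
  withr::with_seed(as.integer(seed), {
    keep_b <- if (length(idx_b) > 0) sort(sample(idx_b, min(n_benign, length(idx_b)))) else integer(0)
    keep_n <- if (length(idx_n) > 0) sort(sample(idx_n, min(n_normal, length(idx_n)))) else integer(0)
  })
  cases[sort(c(keep_mal, keep_b, keep_n)), , drop = FALSE]
}

#' Run the full multi-modal evaluation study
#'
#' End-to-end pipeline: obtain the cohort (file or simulation), run the
#' fusion weight sweep, estimate per-arm AUCs with stratified-bootstrap
#' confidence intervals, compare the fused arm against each single
#' modality with the DeLong paired test, locate maximum-Youden operating
#' points, and — when reader scores are available — evaluate single,
#' either-recall-pair and four-reader-majority strategies on the enriched
#' observer subcohort alongside the AI arms. Deterministic given the
#' config (all randomness is derived from its seed).
#'
#' @param config A [study_config()].
#' @return An object of class `study_report`; see [render_report()] for
#'   the file outputs. If `config$output_dir` is set the report is also
#'   written there.
#' @export
#' @examples
#' cfg <- study_config(cohort = cohort_config(30, 30, 60),
#'                     n_replicates = 50, seed = 7)
#' report <- run_study(cfg)
#' report$aucs
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed

  cases <- if (!is.null(config$input_path)) {
    read_case_table(config$input_path)
  } else {
    cohort <- generate_cohort(config$cohort, config$model)
    if (!is.null(config$reader_profiles)) {
      cohort <- generate_reader_scores(cohort, config$reader_profiles, seed = seed + 1L)
    }
    cohort
  }
  labels <- binary_labels(cases)
  if (sum(labels) == 0) abort("Cohort contains no malignant cases; nothing to evaluate.")
  if (sum(labels == 0L) == 0) abort("Cohort contains no benign/normal cases; nothing to evaluate.")

  cohort_summary <- dplyr::count(
    tibble::tibble(truth_class = as_truth(cases$truth_class)), .data$truth_class,
    name = "n", .drop = FALSE
  )

  fusion <- weight_sweep(cases, config$grid_start, config$grid_stop, config$grid_step)
  cases$score_fused <- fusion$fused_scores

  arms <- c(dm = "score_dm", abus = "score_abus", fused = "score_fused")
  auc_metric <- function(col) function(d) roc_auc(d[[col]], binary_labels(d))
  aucs <- purrr::imap_dfr(arms, function(col, arm) {
    ci <- bootstrap_ci(cases, auc_metric(col),
                       n_replicates = config$n_replicates, level = config$level,
                       seed = seed + 2L + match(arm, names(arms)))
    tibble::tibble(arm = arm, auc = ci$point, lower = ci$lower, upper = ci$upper,
                   level = config$level)
  })

  delong <- list(
    fused_vs_dm = delong_test(cases$score_fused, cases$score_dm, labels,
                              names = c("fused", "dm")),
    fused_vs_abus = delong_test(cases$score_fused, cases$score_abus, labels,
                                names = c("fused", "abus"))
  )

  youden <- purrr::imap_dfr(arms, function(col, arm) {
    dplyr::mutate(max_youden(empirical_roc(cases[[col]], labels)), arm = arm, .before = 1)
  })

  rd_cols <- reader_columns(cases)
  readers <- NULL
  subcohort_aucs <- NULL
  subcohort_youden <- NULL
  subcohort <- subsample_observer_cohort(
    cases, config$observer_n_benign, config$observer_n_normal, seed = seed + 3L
  )
  sub_labels <- binary_labels(subcohort)
  subcohort_aucs <- purrr::imap_dfr(arms, function(col, arm) {
    tibble::tibble(arm = arm, auc = roc_auc(subcohort[[col]], sub_labels))
  })
  subcohort_youden <- dplyr::mutate(
    max_youden(empirical_roc(subcohort$score_fused, sub_labels)),
    arm = "fused", .before = 1
  )
  if (length(rd_cols) > 0) {
    readers <- reader_strategy_table(
      subcohort, rd_cols,
      threshold = config$recall_threshold, vote_on = config$vote_on,
      n_replicates = config$n_replicates, level = config$level, seed = seed + 100L
    )
  }

  report <- structure(
    list(
      cohort_summary = cohort_summary,
      aucs = aucs,
      delong = delong,
      youden = youden,
      fusion = fusion,
      readers = readers,
      subcohort_summary = dplyr::count(
        tibble::tibble(truth_class = as_truth(subcohort$truth_class)),
        .data$truth_class, name = "n", .drop = FALSE
      ),
      subcohort_aucs = subcohort_aucs,
      subcohort_youden = subcohort_youden,
      cases = cases,
      provenance = list(
        seed = seed,
        config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
        package_version = as.character(utils::packageVersion("mmroc")),
        n_cases = nrow(cases)
      )
    ),
    class = "study_report"
  )
  if (!is.null(config$output_dir)) render_report(report, config$output_dir)
  report
}

# Table-2-style strategy sweep given 4 reader columns ordered
# (dm, dm, abus, abus); fewer columns -> singles only.
reader_strategy_table <- function(subcohort, rd_cols, threshold, vote_on,
                                  n_replicates, level, seed) {
  jobs <- purrr::imap(rd_cols, function(col, i) {
    list(strategy = "single", readers = col, label = paste0("single_", col))
  })
  if (length(rd_cols) == 4) {
    pairs <- list(
      list(strategy = "pair_either_recall", readers = rd_cols[c(1, 2)],
           label = "double_dm"),
      list(strategy = "pair_either_recall", readers = rd_cols[c(3, 4)],
           label = "double_abus"),
      list(strategy = "pair_either_recall", readers = rd_cols[c(1, 3)],
           label = "double_multimodal_pair_1"),
      list(strategy = "pair_either_recall", readers = rd_cols[c(1, 4)],
           label = "double_multimodal_pair_2"),
      list(strategy = "pair_either_recall", readers = rd_cols[c(2, 3)],
           label = "double_multimodal_pair_3"),
      list(strategy = "pair_either_recall", readers = rd_cols[c(2, 4)],
           label = "double_multimodal_pair_4"),
      list(strategy = "panel_majority", readers = rd_cols, label = "panel_of_4")
    )
    jobs <- c(jobs, pairs)
  }
  purrr::imap_dfr(jobs, function(job, i) {
    res <- evaluate_strategy(
      subcohort, job$strategy, job$readers,
      threshold = threshold, vote_on = vote_on,
      n_replicates = n_replicates, level = level, seed = seed + 2L * i
    )
    dplyr::mutate(res, label = job$label, .before = 1)
  })
}

#' @export
print.study_report <- function(x, ...) {
  writeLines(format_study_report(x))
  invisible(x)
}
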