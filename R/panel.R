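#' Recall decisions from ordinal BI-RADS categories
#'
#' A case is recalled when its assessment category ranks at or above the
#' threshold in the suspicion order 1 < 2 < 3 < 4a < 4b < 4c < 5. The
#' default threshold of category 3 reflects enriched-study reading, where
#' "probably benign" already triggers workup.
#'
#' @param categories Vector of BI-RADS category labels (coerced via
#'   [as_birads()]; unknown labels are an error naming the label).
#' @param threshold Threshold category label (default `"3"`).
#' @return Integer recall vector (1 = recalled).
#' @export
#' @examples
#' recall_vector(c("1", "3", "4a", "5"), threshold = "4a")
recall_vector <- function(categories, threshold = "3") {
  cats <- as_birads(categories)
  thr <- as_birads(threshold)
  if (length(thr) != 1 || is.na(thr)) abort("`threshold` must be a single BI-RADS label.")
  as.integer(cats >= thr)
}

#' Either-recall combination of two readers
#'
#' Double-reading rule in which one recall suffices: the case is recalled
#' if either reader recalled it (element-wise OR). Commutative and
#' idempotent; relative to either single reader it can only add recalls,
#' so sensitivity never decreases and specificity never increases.
#'
#' @param recalls_a,recalls_b Binary recall vectors aligned on cases.
#' @return Binary recall vector.
#' @export
#' @examples
#' pair_either_recall(c(1, 0, 0), c(0, 0, 1))
pair_either_recall <- function(recalls_a, recalls_b) {
  if (length(recalls_a) != length(recalls_b)) {
    abort("Recall vectors must be aligned: equal lengths required.")
  }
  as.integer(as.integer(recalls_a) | as.integer(recalls_b))
}

#' Majority-vote consensus category of a four-reader panel
#'
#' Per case, the consensus BI-RADS category of exactly four readers:
#' a category held by a strict majority (3 or 4 readers) wins; with a 2-2
#' split between two categories the more suspicious of the two modal
#' categories is assigned (screening-conservative); a lone 2-vote mode
#' wins over two singletons; when all four categories differ, the more
#' suspicious member of the median pair (the third category in suspicion
#' order) is assigned. The consensus is always one of the four input
#' categories and does not depend on reader order.
#'
#' @param categories_by_reader A list of exactly 4 BI-RADS category
#'   vectors, or a data frame with 4 such columns.
#' @return Ordered-factor vector of consensus categories.
#' @export
#' @examples
#' panel_majority(list(c("2", "3"), c("2", "3"), c("2", "4a"), c("5", "4a")))
panel_majority <- function(categories_by_reader) {
  if (is.data.frame(categories_by_reader)) {
    categories_by_reader <- as.list(categories_by_reader)
  }
  if (length(categories_by_reader) != 4) {
    abort("The panel has exactly 4 readers; got a different number of vectors.")
  }
  cols <- lapply(categories_by_reader, function(x) as.integer(as_birads(x)))
  n <- unique(vapply(cols, length, integer(1)))
  if (length(n) != 1) abort("Reader vectors must be aligned: equal lengths required.")
  votes <- matrix(unlist(cols), nrow = n, ncol = 4)
  consensus <- vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    tab <- tabulate(v, nbins = 7)
    top <- max(tab)
    if (top == 1) {
      sort(v)[3]                       # all distinct: median pair, suspicious member
    } else {
      max(which(tab == top))           # modal set: most suspicious mode
    }
  }, integer(1))
  factor(birads_levels()[consensus], levels = birads_levels(), ordered = TRUE)
}

#' Operating point of a reading strategy
#'
#' Computes sensitivity and specificity of a reading strategy on a case
#' table carrying ordinal reader columns, with stratified-bootstrap
#' confidence intervals. Sensitivity is the recalled fraction of malignant
#' cases; specificity the non-recalled fraction of benign and normal cases
#' pooled. Strategies: `single` (one reader), `pair_either_recall` (two
#' readers, recalled if either recalls), `panel_majority` (exactly four
#' readers; by default the panel's consensus BI-RADS category is formed by
#' majority vote and then thresholded; `vote_on = "recall"` instead
#' thresholds each reader and recalls when at least half the panel does).
#'
#' @param cases Case table with `truth_class` and the named reader columns.
#' @param strategy One of `"single"`, `"pair_either_recall"`,
#'   `"panel_majority"`.
#' @param readers Character vector of reader column names (1, 2 or 4 of
#'   them depending on the strategy).
#' @param threshold Recall threshold category (default `"3"`).
#' @param vote_on For the panel: `"category"` (vote, then threshold) or
#'   `"recall"` (threshold, then vote).
#' @param n_replicates,level,seed Bootstrap settings passed to
#'   [bootstrap_ci()]; `n_replicates = 0` skips the intervals.
#' @return One-row tibble of class `panel_result`: strategy, readers,
#'   threshold, sensitivity and specificity with their CI bounds.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(20, 15, 40, seed = 2))
#' cohort <- generate_reader_scores(cohort, default_reader_profiles(), seed = 4)
#' evaluate_strategy(cohort, "pair_either_recall", c("reader_1", "reader_2"),
#'                   n_replicates = 100)
evaluate_strategy <- function(cases,
                              strategy = c("single", "pair_either_recall", "panel_majority"),
                              readers,
                              threshold = "3",
                              vote_on = c("category", "recall"),
                              n_replicates = 2000, level = 0.95, seed = 1L) {
  strategy <- match.arg(strategy)
  vote_on <- match.arg(vote_on)
  missing_cols <- setdiff(readers, names(cases))
  if (length(missing_cols) > 0) {
    abort(sprintf("Case table lacks reader column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  n_needed <- c(single = 1L, pair_either_recall = 2L, panel_majority = 4L)[[strategy]]
  if (length(readers) != n_needed) {
    abort(sprintf("Strategy '%s' needs exactly %d reader(s); got %d.",
                  strategy, n_needed, length(readers)))
  }

  strategy_recalls <- function(tbl) {
    switch(strategy,
      single = recall_vector(tbl[[readers[1]]], threshold),
      pair_either_recall = pair_either_recall(
        recall_vector(tbl[[readers[1]]], threshold),
        recall_vector(tbl[[readers[2]]], threshold)
      ),
      panel_majority = if (vote_on == "category") {
        recall_vector(panel_majority(tbl[readers]), threshold)
      } else {
        rec <- vapply(readers, function(r) recall_vector(tbl[[r]], threshold),
                      integer(nrow(tbl)))
        as.integer(rowSums(rec) >= 2)   # >= half the panel, ties recalled
      }
    )
  }
  sens_of <- function(tbl) {
    pos <- binary_labels(tbl) == 1L
    if (!any(pos)) abort("No malignant cases.")
    mean(strategy_recalls(tbl)[pos])
  }
  spec_of <- function(tbl) {
    neg <- binary_labels(tbl) == 0L
    if (!any(neg)) abort("No benign/normal cases.")
    mean(1 - strategy_recalls(tbl)[neg])
  }

  res <- tibble::tibble(
    strategy = strategy,
    readers = paste(readers, collapse = "+"),
    threshold = as.character(threshold),
    sensitivity = sens_of(cases),
    specificity = spec_of(cases),
    sens_lower = NA_real_, sens_upper = NA_real_,
    spec_lower = NA_real_, spec_upper = NA_real_,
    level = level
  )
  if (n_replicates >= 1) {
    ci_sens <- bootstrap_ci(cases, sens_of, n_replicates, level, seed)
    ci_spec <- bootstrap_ci(cases, spec_of, n_replicates, level, seed + 1L)
    res$sens_lower <- ci_sens$lower; res$sens_upper <- ci_sens$upper
    res$spec_lower <- ci_spec$lower; res$spec_upper <- ci_spec$upper
  }
  class(res) <- c("panel_result", class(res))
  res
}
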