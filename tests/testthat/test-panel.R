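test_that("recall decisions follow the ordinal threshold", {
  expect_equal(recall_vector(c("1", "3", "4a", "5"), threshold = "4a"),
               c(0L, 0L, 1L, 1L))
  expect_equal(recall_vector(c("2", "4c", "1"), threshold = "1"), c(1L, 1L, 1L))
  expect_error(recall_vector(c("1", "6"), threshold = "3"), "6")
})

test_that("either-recall is an element-wise OR with its monotone consequences", {
  expect_equal(pair_either_recall(c(1, 0, 0), c(0, 0, 1)), c(1L, 0L, 1L))
  expect_error(pair_either_recall(c(1, 0), c(1, 0, 1)), "aligned")

  set.seed(22)
  a <- rbinom(500, 1, 0.3)
  b <- rbinom(500, 1, 0.5)
  expect_equal(pair_either_recall(a, b), pair_either_recall(b, a))      # commutative
  expect_equal(pair_either_recall(a, a), as.integer(a))                 # idempotent
  both <- pair_either_recall(a, b)
  expect_true(all(both >= a) && all(both >= b))  # union only adds recalls
})

test_that("pair metrics dominate singles in sensitivity and are dominated in specificity", {
  cohort <- generate_cohort(cohort_config(60, 40, 100, seed = 23))
  cohort <- generate_reader_scores(cohort, default_reader_profiles(), seed = 24)
  single_1 <- evaluate_strategy(cohort, "single", "reader_1", n_replicates = 0)
  single_2 <- evaluate_strategy(cohort, "single", "reader_2", n_replicates = 0)
  pair <- evaluate_strategy(cohort, "pair_either_recall",
                            c("reader_1", "reader_2"), n_replicates = 0)
  expect_gte(pair$sensitivity, max(single_1$sensitivity, single_2$sensitivity))
  expect_lte(pair$specificity, min(single_1$specificity, single_2$specificity))
})

test_that("panel majority follows the documented vote rules", {
  expect_equal(as.character(panel_majority(list("2", "2", "2", "5"))), "2")
  expect_equal(as.character(panel_majority(list("3", "3", "4a", "4a"))), "4a")
  expect_equal(as.character(panel_majority(list("5", "5", "5", "5"))), "5")
  expect_equal(as.character(panel_majority(list("1", "4b", "4b", "2"))), "4b")
  expect_equal(as.character(panel_majority(list("1", "2", "4c", "5"))), "4c")
  expect_error(panel_majority(list("1", "2", "3")), "exactly 4")
  expect_error(panel_majority(list("1", "2", "3", "4a", "5")), "exactly 4")
})

test_that("panel majority is exhaustively sane over all 2401 vote patterns", {
  lev <- birads_levels()
  grid <- expand.grid(r1 = lev, r2 = lev, r3 = lev, r4 = lev,
                      stringsAsFactors = FALSE)
  consensus <- panel_majority(as.list(grid))
  # consensus always equals one of the four input categories
  matches_input <- mapply(
    function(c0, a, b, c, d) c0 %in% c(a, b, c, d),
    as.character(consensus), grid$r1, grid$r2, grid$r3, grid$r4
  )
  expect_true(all(matches_input))
  # and never depends on reader order
  for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    expect_equal(panel_majority(as.list(grid[, perm])), consensus)
  }
})

test_that("strategy operating points are exact class-denominator fractions", {
  cohort <- generate_cohort(cohort_config(42, 30, 80, seed = 25))
  cohort <- generate_reader_scores(cohort, default_reader_profiles(), seed = 26)
  res <- evaluate_strategy(cohort, "panel_majority", paste0("reader_", 1:4),
                           n_replicates = 0)
  expect_true(res$sensitivity >= 0 && res$sensitivity <= 1)
  expect_true(res$specificity >= 0 && res$specificity <= 1)
  expect_equal(res$sensitivity * 42, round(res$sensitivity * 42), tolerance = 1e-9)
  expect_equal(res$specificity * 110, round(res$specificity * 110), tolerance = 1e-9)
})

test_that("degenerate readers give the expected trivial operating points", {
  cohort <- generate_cohort(cohort_config(10, 5, 15, seed = 27))
  cohort$reader_1 <- as_birads(ifelse(cohort$truth_class == "malignant", "5", "1"))
  perfect <- evaluate_strategy(cohort, "single", "reader_1", n_replicates = 0)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  cohort$reader_2 <- as_birads(rep("5", nrow(cohort)))
  recall_all <- evaluate_strategy(cohort, "single", "reader_2", n_replicates = 0)
  expect_equal(recall_all$sensitivity, 1)
  expect_equal(recall_all$specificity, 0)

  expect_error(evaluate_strategy(cohort, "single", "reader_9", n_replicates = 0),
               "reader_9")
})

test_that("majority voting is stricter than union recall on specificity", {
  # four readers at sens 0.85 / spec 0.40 on the enriched 42/30/80 cohort:
  # the panel's consensus recalls fewer healthy cases than an either-recall
  # pair in nearly every replicate
  profs <- replicate(4, reader_profile_from_operating_point(0.85, 0.40),
                     simplify = FALSE)
  names(profs) <- paste0("reader_", 1:4)
  base <- generate_cohort(cohort_config(42, 30, 80, seed = 28))
  neg <- binary_labels(base) == 0L
  wins <- vapply(seq_len(500), function(r) {
    tbl <- generate_reader_scores(base, profs, seed = 30000 + r)
    pair <- pair_either_recall(recall_vector(tbl$reader_1),
                               recall_vector(tbl$reader_2))
    pan <- recall_vector(panel_majority(tbl[paste0("reader_", 1:4)]))
    mean(1 - pan[neg]) > mean(1 - pair[neg])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("the alternative vote-then-threshold order is exposed and coherent", {
  cohort <- generate_cohort(cohort_config(30, 20, 50, seed = 29))
  cohort <- generate_reader_scores(cohort, default_reader_profiles(), seed = 30)
  by_cat <- evaluate_strategy(cohort, "panel_majority", paste0("reader_", 1:4),
                              vote_on = "category", n_replicates = 0)
  by_rec <- evaluate_strategy(cohort, "panel_majority", paste0("reader_", 1:4),
                              vote_on = "recall", n_replicates = 0)
  for (res in list(by_cat, by_rec)) {
    expect_true(res$sensitivity >= 0 && res$sensitivity <= 1)
    expect_true(res$specificity >= 0 && res$specificity <= 1)
  }
})
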