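test_that("generated cohorts have exactly the configured class counts", {
  cohort <- generate_cohort(cohort_config(42, 114, 274, seed = 1))
  expect_equal(nrow(cohort), 430)
  counts <- table(cohort$truth_class)
  expect_equal(unname(counts[["malignant"]]), 42)
  expect_equal(unname(counts[["benign"]]), 114)
  expect_equal(unname(counts[["normal"]]), 274)
  expect_false(anyDuplicated(cohort$case_id) > 0)

  empty_classes <- generate_cohort(cohort_config(0, 0, 5, seed = 2))
  expect_equal(nrow(empty_classes), 5)
  expect_true(all(empty_classes$truth_class == "normal"))
})

test_that("cohort generation is deterministic in (config, model)", {
  cfg <- cohort_config(10, 10, 10, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other_seed <- generate_cohort(cohort_config(10, 10, 10, seed = 100))
  expect_false(identical(generate_cohort(cfg)$score_dm, other_seed$score_dm))
})

test_that("invalid model parameters are rejected naming the offender", {
  bad_sd <- tibble::tibble(
    truth_class = c("malignant", "benign", "normal"),
    mean_dm = 0, sd_dm = c(1, -1, 1), mean_abus = 0, sd_abus = 1, rho = 0
  )
  expect_error(binormal_model(bad_sd), "benign.*dm")
  bad_rho <- tibble::tibble(
    truth_class = c("malignant", "benign", "normal"),
    mean_dm = 0, sd_dm = 1, mean_abus = 0, sd_abus = 1, rho = c(0, 0, 1.2)
  )
  expect_error(binormal_model(bad_rho), "normal")
  expect_error(cohort_config(-1, 5, 5), "non-negative")
  expect_error(cohort_config(0, 0, 0), ">= 1")
})

test_that("class-conditional moments and correlation converge to the model", {
  model <- binormal_model(tibble::tibble(
    truth_class = c("malignant", "benign", "normal"),
    mean_dm = c(1.5, 0.5, 0), sd_dm = c(1.2, 1, 0.8),
    mean_abus = c(2, 0.3, -0.2), sd_abus = c(0.9, 1.1, 1),
    rho = c(0.5, 0.2, -0.3)
  ))
  n <- 10000
  cohort <- generate_cohort(cohort_config(n, n, n, seed = 7), model)
  for (cls in c("malignant", "benign", "normal")) {
    sub <- cohort[cohort$truth_class == cls, ]
    row <- model[model$truth_class == cls, ]
    # 4 standard errors on the mean, sd and correlation at n = 10000
    expect_lt(abs(mean(sub$score_dm) - row$mean_dm), 4 * row$sd_dm / sqrt(n))
    expect_lt(abs(mean(sub$score_abus) - row$mean_abus), 4 * row$sd_abus / sqrt(n))
    expect_lt(abs(sd(sub$score_dm) - row$sd_dm), 4 * row$sd_dm / sqrt(2 * n))
    expect_lt(abs(sd(sub$score_abus) - row$sd_abus), 4 * row$sd_abus / sqrt(2 * n))
    expect_lt(abs(cor(sub$score_dm, sub$score_abus) - row$rho),
              4 * (1 - row$rho^2) / sqrt(n))
  }
})

test_that("closed-form mixture AUC behaves as an oracle should", {
  flat <- binormal_model(tibble::tibble(
    truth_class = c("malignant", "benign", "normal"),
    mean_dm = 0, sd_dm = 1, mean_abus = 0, sd_abus = 1, rho = 0
  ))
  expect_equal(analytic_auc(flat, "dm"), 0.5)

  sep <- binormal_model(tibble::tibble(
    truth_class = c("malignant", "benign", "normal"),
    mean_dm = c(2, 0, 0), sd_dm = 1, mean_abus = 0, sd_abus = 1, rho = 0
  ))
  # positive N(2,1) vs negative N(0,1): Phi(2/sqrt(2)), checked by numeric
  # integration of P(X > Y) frozen at 0.9213504
  expect_equal(analytic_auc(sep, "dm", negative_classes = "normal"), 0.9213504,
               tolerance = 1e-7)

  # monotone approach to 1 as the positive mean grows
  aucs <- vapply(c(2, 4, 8, 16), function(mu) {
    m <- sep
    m$mean_dm[m$truth_class == "malignant"] <- mu
    analytic_auc(m, "dm", negative_classes = "normal")
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_lt(1 - aucs[4], 1e-10)

  # mixture weights matter: config-proportional vs equal weights differ
  mix <- binormal_model(tibble::tibble(
    truth_class = c("malignant", "benign", "normal"),
    mean_dm = c(2, 1, 0), sd_dm = 1, mean_abus = 0, sd_abus = 1, rho = 0
  ))
  w_equal <- analytic_auc(mix, "dm")
  w_config <- analytic_auc(mix, "dm", config = cohort_config(42, 114, 274))
  manual <- (114 * pnorm(1 / sqrt(2)) + 274 * pnorm(2 / sqrt(2))) / 388
  expect_equal(w_config, manual, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(w_equal, w_config)))
})

test_that("empirical AUC of generated scores matches the closed form", {
  # randomized model specs under a fixed seed; 3 Monte-Carlo SEs of the
  # binomial-style bound for the Mann-Whitney statistic
  set.seed(31)
  for (k in 1:8) {
    mu <- runif(1, 0.5, 2.5)
    s1 <- runif(1, 0.6, 1.5)
    model <- binormal_model(tibble::tibble(
      truth_class = c("malignant", "benign", "normal"),
      mean_dm = c(mu, 0, 0), sd_dm = c(s1, 1, 1),
      mean_abus = c(mu / 2, 0, 0), sd_abus = 1, rho = runif(1, -0.5, 0.5)
    ))
    n <- 1500
    cohort <- generate_cohort(cohort_config(n, 0, n, seed = 1000 + k), model)
    labels <- binary_labels(cohort)
    truth <- analytic_auc(model, "dm", negative_classes = "normal")
    se <- sqrt(truth * (1 - truth) * (2 * n + 1) / (n * n))  # conservative MW bound
    expect_lt(abs(roc_auc(cohort$score_dm, labels) - truth), 3 * se)
  }
})
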