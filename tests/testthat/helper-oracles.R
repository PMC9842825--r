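# Independent oracles, deliberately naive: these must never share code with
# the implementation paths they check.

# AUC by exhaustive enumeration of (positive, negative) pairs, ties half.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# ROC points by brute-force thresholding at every distinct score value.
brute_roc_points <- function(scores, labels, thresholds) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  data.frame(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thresholds, function(t) mean(neg < t), numeric(1))
  )
}

# small informative cohort with both modality scores and labels
tiny_cohort <- function(n_mal = 20, n_ben = 15, n_norm = 40, seed = 1,
                        model = default_binormal_model()) {
  generate_cohort(cohort_config(n_mal, n_ben, n_norm, seed = seed), model)
}

# binormal scores for one synthetic screening arm (labels 1/0)
binormal_scores <- function(n_pos, n_neg, mu = 1.2, sd_pos = 1) {
  list(
    scores = c(rnorm(n_pos, mu, sd_pos), rnorm(n_neg)),
    labels = rep(c(1L, 0L), c(n_pos, n_neg))
  )
}
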