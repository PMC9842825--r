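# Structural components (placements) of the Mann-Whitney AUC, with midrank
# tie handling: V10_i = fraction of negatives scored below positive i (ties
# half); V01_j = fraction of positives scored above negative j (ties half).
delong_components <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  pos <- labels == 1L
  m <- sum(pos)
  n <- sum(!pos)
  r_all <- rank(scores, ties.method = "average")
  v10 <- (r_all[pos] - rank(scores[pos], ties.method = "average")) / n
  v01 <- 1 - (r_all[!pos] - rank(scores[!pos], ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, n_pos = m, n_neg = n)
}

#' DeLong variance of the empirical AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC estimator from the
#' structural-components decomposition: the sample variances of the
#' positive-case and negative-case placement values, scaled by their
#' respective sample sizes (`S10/n_pos + S01/n_neg`). Ties are handled by
#' midranks.
#'
#' @inheritParams empirical_roc
#' @return The estimated variance of the AUC (>= 0).
#' @export
#' @examples
#' delong_variance(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
delong_variance <- function(scores, labels) {
  comp <- delong_components(scores, labels)
  if (comp$n_pos < 2 || comp$n_neg < 2) {
    abort("DeLong variance requires at least 2 positives and 2 negatives.")
  }
  var(comp$v10) / comp$n_pos + var(comp$v01) / comp$n_neg
}

#' DeLong paired test for two correlated AUCs
#'
#' Compares the AUCs of two continuous scores measured on the same cases
#' (paired design) against the same binary truth. The covariance of the two
#' AUC estimators comes from the paired structural components; the test
#' statistic is `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)` with a
#' two-sided p-value from the standard normal. When the variance of the
#' difference is zero and the AUCs are equal (e.g. the two scores are rank
#' transforms of one another), z is defined as 0 and p as 1.
#'
#' @param scores_a,scores_b Numeric score vectors aligned case-by-case.
#' @param labels Binary truth vector (1 = malignant).
#' @param names Optional length-2 character vector naming the two arms.
#' @return An object of class `delong_result` with elements `auc_a`,
#'   `auc_b`, `var_a`, `var_b`, `cov_ab`, `z`, `p_value`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' set.seed(1)
#' lab <- rep(c(1, 0), c(30, 70))
#' a <- rnorm(100, mean = lab)
#' b <- rnorm(100, mean = 0.8 * lab)
#' delong_test(a, b, lab)
delong_test <- function(scores_a, scores_b, labels, names = c("a", "b")) {
  if (length(scores_a) != length(scores_b)) {
    abort("`scores_a` and `scores_b` must be paired: equal lengths required.")
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  if (ca$n_pos < 2 || ca$n_neg < 2) {
    abort("DeLong test requires at least 2 positives and 2 negatives.")
  }
  var_a <- var(ca$v10) / ca$n_pos + var(ca$v01) / ca$n_neg
  var_b <- var(cb$v10) / cb$n_pos + var(cb$v01) / cb$n_neg
  cov_ab <- stats::cov(ca$v10, cb$v10) / ca$n_pos + stats::cov(ca$v01, cb$v01) / ca$n_neg
  diff <- ca$auc - cb$auc
  var_diff <- max(var_a + var_b - 2 * cov_ab, 0)
  if (var_diff < 1e-16) {
    if (abs(diff) < 1e-12) {
      z <- 0
    } else {
      z <- sign(diff) * Inf
    }
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- 2 * pnorm(-abs(z))
  structure(
    list(
      auc_a = ca$auc, auc_b = cb$auc,
      var_a = var_a, var_b = var_b, cov_ab = cov_ab,
      z = z, p_value = p,
      n_pos = ca$n_pos, n_neg = ca$n_neg,
      names = names
    ),
    class = "delong_result"
  )
}

#' @export
print.delong_result <- function(x, ...) {
  cat("DeLong paired AUC test\n")
  cat(sprintf("  AUC[%s] = %.4f,  AUC[%s] = %.4f  (diff %+.4f)\n",
              x$names[1], x$auc_a, x$names[2], x$auc_b, x$auc_a - x$auc_b))
  cat(sprintf("  z = %.3f, two-sided p = %.4g  (%d pos / %d neg)\n",
              x$z, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}
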