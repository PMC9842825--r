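#' Cohort composition configuration
#'
#' Describes how many cases of each ground-truth class to simulate. The
#' default reproduces the full study cohort composition of 42 malignant,
#' 114 biopsy-proven benign and 274 normal cases (430 in total).
#'
#' @param n_malignant,n_benign,n_normal Non-negative case counts per class.
#' @param seed Integer seed driving all random draws for the cohort.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cohort_config()
#' cohort_config(10, 20, 30, seed = 7)
cohort_config <- function(n_malignant = 42, n_benign = 114, n_normal = 274,
                          seed = 1L) {
  counts <- c(n_malignant = n_malignant, n_benign = n_benign, n_normal = n_normal)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("Class counts must be non-negative integers.")
  }
  if (sum(counts) < 1) {
    abort("At least one case is required: n_malignant + n_benign + n_normal >= 1.")
  }
  structure(
    list(
      n_malignant = as.integer(n_malignant),
      n_benign = as.integer(n_benign),
      n_normal = as.integer(n_normal),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d malignant / %d benign / %d normal (total %d), seed %d\n",
    x$n_malignant, x$n_benign, x$n_normal,
    x$n_malignant + x$n_benign + x$n_normal, x$seed
  ))
  invisible(x)
}

#' Class-conditional binormal score model
#'
#' Specifies, per ground-truth class, the bivariate Gaussian distribution of
#' the two continuous AI suspicion scores (mammography `dm`, automated 3D
#' ultrasound `abus`) and their inter-modality correlation. The binormal
#' family is the standard generative model for ROC analysis and admits a
#' closed-form AUC (see [analytic_auc()]), which the test suite uses as an
#' oracle.
#'
#' @param params A data frame with one row per truth class and columns
#'   `truth_class`, `mean_dm`, `sd_dm`, `mean_abus`, `sd_abus`, `rho`.
#'   All three classes (`malignant`, `benign`, `normal`) must be present,
#'   standard deviations must be strictly positive and `|rho| <= 1`.
#' @return An object of class `binormal_model` (a validated tibble).
#' @seealso [default_binormal_model()] for the calibrated defaults.
#' @export
binormal_model <- function(params) {
  params <- tibble::as_tibble(params)
  needed <- c("truth_class", "mean_dm", "sd_dm", "mean_abus", "sd_abus", "rho")
  missing_cols <- setdiff(needed, names(params))
  if (length(missing_cols) > 0) {
    abort(sprintf("Model is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  params$truth_class <- as.character(params$truth_class)
  missing_classes <- setdiff(truth_levels(), params$truth_class)
  if (length(missing_classes) > 0 || anyDuplicated(params$truth_class) > 0) {
    abort("Model must contain exactly one row per class: malignant, benign, normal.")
  }
  for (cls in params$truth_class) {
    row <- params[params$truth_class == cls, ]
    for (mod in c("dm", "abus")) {
      if (row[[paste0("sd_", mod)]] <= 0) {
        abort(sprintf("Standard deviation must be > 0 for class '%s', modality '%s'.", cls, mod))
      }
    }
    if (abs(row$rho) > 1) {
      abort(sprintf("Correlation must satisfy |rho| <= 1 for class '%s'.", cls))
    }
  }
  params <- params[match(truth_levels(), params$truth_class), needed]
  class(params) <- c("binormal_model", class(params))
  params
}

#' Default calibrated binormal model
#'
#' Class-conditional score distributions calibrated so that, under the
#' default 42/114/274 cohort composition, the closed-form mixture AUCs are
#' approximately 0.832 for the mammography score and 0.841 for the
#' ultrasound score — the single-modality performance regime the package's
#' analyses target. Benign cases sit above normals on both modalities (a
#' biopsied benign lesion typically looks more suspicious than a normal
#' exam), and a moderate within-class correlation of 0.35 leaves the two
#' modalities complementary, so weighted fusion has headroom.
#'
#' @param rho Within-class inter-modality correlation, applied to every
#'   class. Default 0.35.
#' @return A `binormal_model`.
#' @export
#' @examples
#' m <- default_binormal_model()
#' analytic_auc(m, "dm", config = cohort_config())
default_binormal_model <- function(rho = 0.35) {
  binormal_model(tibble::tibble(
    truth_class = c("malignant", "benign", "normal"),
    mean_dm = c(1.49, 0.4, 0), sd_dm = 1,
    mean_abus = c(1.54, 0.4, 0), sd_abus = 1,
    rho = rho
  ))
}

#' Simulate a screening cohort of paired AI scores
#'
#' Draws, for each case, a pair of continuous suspicion scores (one per
#' modality) from the bivariate Gaussian of its truth class. Rows are
#' ordered malignant, benign, normal; case identifiers are zero-padded and
#' unique. The draw is fully determined by `config` (including its seed)
#' and `model`.
#'
#' @param config A [cohort_config()].
#' @param model A [binormal_model()]; defaults to [default_binormal_model()].
#' @return A tibble (`case_id`, `truth_class`, `score_dm`, `score_abus`)
#'   with exactly the requested number of rows per class.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(5, 5, 10, seed = 42))
#' dplyr::count(cohort, truth_class)
generate_cohort <- function(config = cohort_config(),
                            model = default_binormal_model()) {
  stopifnot(inherits(config, "cohort_config"))
  model <- binormal_model(model)
  counts <- c(
    malignant = config$n_malignant,
    benign = config$n_benign,
    normal = config$n_normal
  )
  withr::with_seed(config$seed, {
    per_class <- purrr::map(truth_levels(), function(cls) {
      n <- counts[[cls]]
      row <- model[model$truth_class == cls, ]
      # bivariate normal via the 2x2 Cholesky factor; one stream, class order fixed
      z1 <- rnorm(n)
      z2 <- rnorm(n)
      tibble::tibble(
        truth_class = rep(cls, n),
        score_dm = row$mean_dm + row$sd_dm * z1,
        score_abus = row$mean_abus + row$sd_abus * (row$rho * z1 + sqrt(1 - row$rho^2) * z2)
      )
    })
  })
  out <- dplyr::bind_rows(per_class)
  n_total <- nrow(out)
  out <- dplyr::mutate(
    out,
    case_id = sprintf("case_%0*d", max(4L, nchar(n_total)), dplyr::row_number()),
    truth_class = as_truth(.data$truth_class),
    .before = 1
  )
  out
}

#' Closed-form AUC of a binormal model
#'
#' Exact probability that a score from the positive class exceeds a score
#' from the (possibly mixed) negative class under the Gaussian model:
#' a mixture of normal-CDF terms
#' \eqn{\sum_k w_k \Phi\big((\mu_+ - \mu_k)/\sqrt{\sigma_+^2 + \sigma_k^2}\big)}.
#' Used throughout the tests as the analytic oracle for empirical AUCs.
#'
#' @param model A [binormal_model()].
#' @param modality `"dm"` or `"abus"`.
#' @param positive_class Truth class treated as positive (default
#'   `"malignant"`).
#' @param negative_classes Truth classes pooled as negatives (default
#'   benign + normal).
#' @param neg_weights Optional mixture weights for the negative classes
#'   (normalized internally). If omitted and `config` is given, weights are
#'   proportional to the config's class counts; otherwise equal.
#' @param config Optional [cohort_config()] supplying negative-class counts.
#' @return The AUC as a single probability.
#' @export
#' @examples
#' m <- default_binormal_model()
#' analytic_auc(m, "dm", config = cohort_config())  # ~0.832
analytic_auc <- function(model, modality = c("dm", "abus"),
                         positive_class = "malignant",
                         negative_classes = c("benign", "normal"),
                         neg_weights = NULL, config = NULL) {
  model <- binormal_model(model)
  modality <- match.arg(modality)
  positive_class <- match.arg(positive_class, truth_levels())
  negative_classes <- match.arg(negative_classes, truth_levels(), several.ok = TRUE)
  if (length(negative_classes) == 0) abort("At least one negative class is required.")
  if (positive_class %in% negative_classes) {
    abort("The positive class cannot also be a negative class.")
  }
  if (is.null(neg_weights)) {
    if (!is.null(config)) {
      stopifnot(inherits(config, "cohort_config"))
      neg_weights <- vapply(
        negative_classes,
        function(cls) config[[paste0("n_", cls)]],
        numeric(1)
      )
    } else {
      neg_weights <- rep(1, length(negative_classes))
    }
  }
  if (length(neg_weights) != length(negative_classes) || any(neg_weights < 0) ||
      sum(neg_weights) <= 0) {
    abort("neg_weights must be non-negative, one per negative class, with positive sum.")
  }
  neg_weights <- neg_weights / sum(neg_weights)

  mu_col <- paste0("mean_", modality)
  sd_col <- paste0("sd_", modality)
  pos <- model[model$truth_class == positive_class, ]
  terms <- vapply(seq_along(negative_classes), function(i) {
    neg <- model[model$truth_class == negative_classes[i], ]
    pnorm((pos[[mu_col]] - neg[[mu_col]]) / sqrt(pos[[sd_col]]^2 + neg[[sd_col]]^2))
  }, numeric(1))
  sum(neg_weights * terms)
}
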