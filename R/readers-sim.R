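#' Simulated-reader profile over BI-RADS categories
#'
#' A reader profile gives, for each ground-truth class, a probability
#' distribution over the seven ordinal BI-RADS assessment categories
#' (1 < 2 < 3 < 4a < 4b < 4c < 5). A simulated reader scores each case by
#' drawing from the distribution of the case's class.
#'
#' @param malignant,benign,normal Numeric probability vectors of length 7
#'   (ordered as [birads_levels()]), each non-negative and summing to 1
#'   within 1e-9.
#' @param modality Optional tag ("dm" or "abus") recording which modality
#'   the simulated reader reads; informational only.
#' @return An object of class `reader_profile` (a 3 x 7 probability matrix).
#' @export
reader_profile <- function(malignant, benign, normal, modality = NA_character_) {
  mat <- rbind(malignant = malignant, benign = benign, normal = normal)
  if (ncol(mat) != 7) {
    abort("Each class distribution must have 7 probabilities, one per BI-RADS category.")
  }
  colnames(mat) <- birads_levels()
  for (cls in rownames(mat)) {
    p <- mat[cls, ]
    if (any(p < 0)) abort(sprintf("Negative probability in class '%s'.", cls))
    if (abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("Probabilities for class '%s' sum to %.12f, not 1.", cls, sum(p)))
    }
  }
  structure(mat, modality = modality, class = c("reader_profile", "matrix"))
}

#' @export
print.reader_profile <- function(x, ...) {
  cat(sprintf("<reader_profile>%s\n",
              if (is.na(attr(x, "modality"))) "" else paste0(" modality: ", attr(x, "modality"))))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Build a reader profile from a target operating point
#'
#' Constructs class-conditional BI-RADS distributions whose recall
#' probability at the given threshold equals, exactly, the requested
#' sensitivity (for malignant cases) and one minus the requested
#' specificity (for benign and normal cases). Mass above the threshold
#' escalates with suspicion for malignant cases and decays for
#' non-malignant cases; the shape within each block is a fixed convention,
#' only the block totals are calibrated.
#'
#' @param sensitivity Target recall probability for malignant cases.
#' @param specificity Target non-recall probability for benign/normal cases.
#' @param threshold BI-RADS category at or above which a case is recalled
#'   (default `"3"`).
#' @inheritParams reader_profile
#' @return A `reader_profile`.
#' @export
#' @examples
#' reader_profile_from_operating_point(0.778, 0.454, modality = "dm")
reader_profile_from_operating_point <- function(sensitivity, specificity,
                                                threshold = "3",
                                                modality = NA_character_) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1)
  lev <- birads_levels()
  cut <- match(as.character(as_birads(threshold)), lev)
  above <- seq(cut, length(lev))
  below <- seq_len(cut - 1)
  shape_up <- seq_along(above)          # escalating suspicion
  shape_down <- rev(seq_along(above))   # decaying suspicion
  split_mass <- function(total, idx, shape) {
    p <- numeric(length(lev))
    if (length(idx) > 0 && total > 0) p[idx] <- total * shape / sum(shape)
    p
  }
  mal <- split_mass(sensitivity, above, shape_up) +
    split_mass(1 - sensitivity, below, rev(seq_along(below)))
  neg <- split_mass(1 - specificity, above, shape_down) +
    split_mass(specificity, below, seq_along(below))
  reader_profile(malignant = mal, benign = neg, normal = neg, modality = modality)
}

#' Default four-reader panel
#'
#' Four simulated readers — two reading mammography, two reading automated
#' 3D ultrasound — calibrated to single-reader operating points typical of
#' an enriched dense-breast observer study at recall threshold BI-RADS 3:
#' sensitivities 77.8/79.2/94.2/85.4% against specificities
#' 45.4/57.1/22.1/37.9%. Ultrasound readers trade specificity for
#' sensitivity, as observed in this population.
#'
#' @return Named list of four `reader_profile` objects
#'   (`reader_1` ... `reader_4`).
#' @export
default_reader_profiles <- function() {
  list(
    reader_1 = reader_profile_from_operating_point(0.778, 0.454, modality = "dm"),
    reader_2 = reader_profile_from_operating_point(0.792, 0.571, modality = "dm"),
    reader_3 = reader_profile_from_operating_point(0.942, 0.221, modality = "abus"),
    reader_4 = reader_profile_from_operating_point(0.854, 0.379, modality = "abus")
  )
}

#' Append simulated ordinal reader scores to a cohort
#'
#' Adds one ordered-factor BI-RADS column per profile. Each case's category
#' is drawn independently from the profile's distribution conditional on
#' the case's truth class. Every reader consumes its own RNG sub-stream,
#' keyed by `seed` and the reader's position, so appending an extra reader
#' never perturbs the columns of earlier readers.
#'
#' @param cases A case table with a `truth_class` column.
#' @param profiles Named list of [reader_profile()] objects; names become
#'   column names (unnamed lists get `reader_1`, `reader_2`, ...).
#' @param seed Integer seed for the reader score draws.
#' @return `cases` with one ordinal column appended per profile.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(5, 5, 5, seed = 1))
#' generate_reader_scores(cohort, default_reader_profiles(), seed = 2)
generate_reader_scores <- function(cases, profiles, seed = 1L) {
  if (inherits(profiles, "reader_profile")) profiles <- list(profiles)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- paste0("reader_", seq_along(profiles))
  }
  cls <- as.character(as_truth(cases$truth_class))
  n <- nrow(cases)
  out <- cases
  for (k in seq_along(profiles)) {
    prof <- profiles[[k]]
    if (!inherits(prof, "reader_profile")) prof <- do.call(reader_profile, as.list(prof))
    # sub-stream per reader: independent of how many other readers exist
    col <- withr::with_seed(as.integer(seed) + 7919L * k, {
      drawn <- character(n)
      for (tc in unique(cls)) {
        idx <- which(cls == tc)
        drawn[idx] <- sample(birads_levels(), length(idx), replace = TRUE, prob = prof[tc, ])
      }
      drawn
    })
    out[[names(profiles)[k]]] <- as_birads(col)
  }
  out
}

#' Names of reader columns in a case table
#'
#' @param cases A case table.
#' @return Character vector of columns holding ordinal reader scores
#'   (columns whose name starts with `"reader"`).
#' @export
reader_columns <- function(cases) {
  grep("^reader", names(cases), value = TRUE)
}
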