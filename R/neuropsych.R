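#' The 10-test neuropsychological battery
#'
#' The default battery maps ten standard tests onto six cognitive domains:
#' executive (Trail Making Test Part B), verbal (Boston Naming Test,
#' Controlled Oral Word Association), memory (RAVLT delayed recall and
#' delayed recognition), learning (RAVLT immediate and total learning),
#' psychomotor (TMT Part A), and visuospatial (Complex Figure delayed recall
#' and copy). Both TMT scores carry the `invert` flag: their published norms
#' run opposite to the other tests, so orientation multiplies them by -1 to
#' make negative z mean "more impaired" for every test.
#'
#' @return A `test_battery` data frame with columns `test`, `domain`, `invert`.
#' @export
test_battery <- function() {
  battery <- data.frame(
    test = c("TMT_A", "TMT_B", "BNT", "COWA",
             "RAVLT_Immediate", "RAVLT_Total",
             "RAVLT_Delayed_Recall", "RAVLT_Delayed_Recognition",
             "CFT_Delayed_Recall", "CFT_Copy"),
    domain = c("psychomotor", "executive", "verbal", "verbal",
               "learning", "learning", "memory", "memory",
               "visuospatial", "visuospatial"),
    invert = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  class(battery) <- c("test_battery", "data.frame")
  battery
}

battery_tests <- function(battery) battery$test

check_score_table <- function(table, battery) {
  missing_cols <- setdiff(battery$test, names(table))
  assert_that(length(missing_cols) == 0,
              "schema error: score table lacks test column(s): %s",
              paste(missing_cols, collapse = ", "))
  invisible(TRUE)
}

#' Orient raw test z-scores so negative always means impaired
#'
#' Multiplies the z-scores of tests flagged `invert` in the battery by -1.
#' Applying the operation twice returns the raw table (involution).
#'
#' @param raw_table Data frame with one column per battery test.
#' @param battery A `test_battery`.
#' @return The table with inverted tests sign-flipped and attribute
#'   `oriented` toggled.
#' @export
orient_scores <- function(raw_table, battery = test_battery()) {
  check_score_table(raw_table, battery)
  out <- raw_table
  for (tst in battery$test[battery$invert]) out[[tst]] <- -out[[tst]]
  attr(out, "oriented") <- !isTRUE(attr(raw_table, "oriented"))
  out
}

#' Flag impaired test performance
#'
#' A test is impaired when its oriented z-score lies strictly below the
#' threshold (default -1.645, the normative 5th percentile).
#'
#' @param table Oriented score table.
#' @param battery A `test_battery`.
#' @param threshold Impairment cutoff on the z scale.
#' @return Logical matrix, patients x tests.
#' @export
impairment_flags <- function(table, battery = test_battery(),
                             threshold = -1.645) {
  check_score_table(table, battery)
  z <- as.matrix(table[, battery$test, drop = FALSE])
  assert_that(all(is.finite(z)), "invalid input: z-scores must be finite")
  flags <- z < threshold
  rownames(flags) <- if ("patient_id" %in% names(table)) table$patient_id else NULL
  flags
}

#' Count cognitive domains containing at least one impaired test
#'
#' @param flags Logical patients x tests matrix from [impairment_flags()].
#' @param battery A `test_battery`.
#' @return Integer vector, impaired-domain count per patient (0-6).
#' @export
count_impaired_domains <- function(flags, battery = test_battery()) {
  assert_that(ncol(flags) == nrow(battery),
              "invalid input: flags not aligned to battery")
  domains <- unique(battery$domain)
  hit <- vapply(domains, function(d) {
    cols <- battery$test[battery$domain == d]
    rowSums(flags[, cols, drop = FALSE]) >= 1
  }, logical(nrow(flags)))
  if (nrow(flags) == 1L) hit <- matrix(hit, nrow = 1L)
  as.integer(rowSums(hit))
}

#' Classify patients by breadth of impairment
#'
#' @param domain_count Integer vector of impaired-domain counts.
#' @param min_domains Minimum domain count for the "multi" class.
#' @return Character vector: `"none"`, `"single"`, or `"multi"`.
#' @export
classify_patient <- function(domain_count, min_domains = 2L) {
  assert_that(all(domain_count >= 0 & domain_count <= 6),
              "invalid input: domain counts must lie in [0, 6]")
  ifelse(domain_count == 0, "none",
         ifelse(domain_count >= min_domains, "multi", "single"))
}

#' Average impairment score
#'
#' The arithmetic mean of the oriented z-scores across all battery tests;
#' more negative means more severe overall impairment. Missing scores abort
#' by default; `allow_missing = TRUE` averages the available tests instead.
#'
#' @param table Oriented score table.
#' @param battery A `test_battery`.
#' @param allow_missing Average over available tests when some are NA.
#' @return Numeric vector, one score per patient.
#' @export
average_impairment_score <- function(table, battery = test_battery(),
                                     allow_missing = FALSE) {
  check_score_table(table, battery)
  z <- as.matrix(table[, battery$test, drop = FALSE])
  if (anyNA(z) && !allow_missing) {
    stopf("missing test scores; rerun with allow_missing = TRUE to average over available tests")
  }
  rowMeans(z, na.rm = allow_missing)
}

#' Multi-domain impairment score
#'
#' Counts impaired tests per patient (0-10). `per = "domains"` counts
#' impaired domains instead (0-6).
#'
#' @param flags Logical patients x tests matrix.
#' @param battery A `test_battery` (needed for the domains variant).
#' @param per Count `"tests"` (default) or `"domains"`.
#' @return Integer vector per patient.
#' @export
multi_domain_impairment_score <- function(flags, battery = test_battery(),
                                          per = c("tests", "domains")) {
  per <- match.arg(per)
  if (per == "tests") return(as.integer(rowSums(flags)))
  count_impaired_domains(flags, battery)
}

#' Regress lesion size out of a score
#'
#' Residuals of the OLS fit of `scores` on `volumes`; by construction they
#' have zero mean and zero sample correlation with volume.
#'
#' @param scores Numeric vector.
#' @param volumes Lesion volumes (mm^3), non-constant, same length.
#' @return Numeric residual vector.
#' @export
residualize_on_lesion_size <- function(scores, volumes) {
  assert_that(length(scores) == length(volumes),
              "invalid input: scores and volumes must have equal length")
  assert_that(stats::sd(volumes) > 0,
              "degenerate input: lesion volumes are constant")
  unname(stats::resid(stats::lm(scores ~ volumes)))
}

#' Flag probes above a reference regression band
#'
#' Fits multi-domain impairment score on average impairment score over the
#' reference patients, then flags each probe patient whose multi-domain score
#' exceeds the upper 95% confidence band of the mean prediction at the
#' probe's average score.
#'
#' @param reference Data frame with columns `avg` and `md` (n >= 3).
#' @param probes Data frame with columns `avg` and `md`.
#' @param level Confidence level of the band.
#' @return Data frame: probe `avg`, `md`, fitted value, band `lwr`/`upr`,
#'   logical `higher`.
#' @export
compare_to_reference_regression <- function(reference, probes, level = 0.95) {
  assert_that(all(c("avg", "md") %in% names(reference)) &&
                all(c("avg", "md") %in% names(probes)),
              "invalid input: reference and probes need columns `avg` and `md`")
  assert_that(nrow(reference) >= 3, "invalid input: reference needs n >= 3")
  assert_that(stats::sd(reference$avg) > 0,
              "degenerate input: reference average scores are constant")
  fit <- stats::lm(md ~ avg, data = reference)
  band <- stats::predict(fit, newdata = probes, interval = "confidence",
                         level = level)
  data.frame(avg = probes$avg, md = probes$md,
             fit = band[, "fit"], lwr = band[, "lwr"], upr = band[, "upr"],
             higher = probes$md > band[, "upr"])
}

#' Per-test two-group comparison table
#'
#' Runs one randomized permutation test per battery test between two patient
#' groups and flags significance at the Bonferroni-corrected threshold,
#' reproducing the shape of a standard group-comparison table (group means,
#' SDs, permutation p, corrected significance).
#'
#' @param table Oriented score table with a `group` column.
#' @param battery A `test_battery`.
#' @param groups Length-2 character vector naming the two groups to compare
#'   (first minus second).
#' @param n_perm Permutations per test.
#' @param seed Optional seed; test i uses `seed + i`.
#' @param alpha Family-wise alpha for the Bonferroni correction.
#' @return Data frame, one row per test.
#' @export
group_comparison <- function(table, battery = test_battery(),
                             groups = NULL, n_perm = 1999L, seed = NULL,
                             alpha = 0.05) {
  check_score_table(table, battery)
  assert_that("group" %in% names(table), "invalid input: score table needs a `group` column")
  if (is.null(groups)) groups <- unique(table$group)[1:2]
  assert_that(length(groups) == 2 && all(groups %in% table$group),
              "invalid input: need two groups present in the table")
  thr <- bonferroni_threshold(alpha, nrow(battery))
  rows <- lapply(seq_len(nrow(battery)), function(i) {
    tst <- battery$test[i]
    a <- table[[tst]][table$group == groups[1]]
    b <- table[[tst]][table$group == groups[2]]
    pt <- permutation_group_test(a, b, n_perm = n_perm,
                                 seed = if (is.null(seed)) NULL else seed + i)
    data.frame(test = tst, domain = battery$domain[i],
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               mean_difference = pt$observed_stat,
               p_value = pt$p_value,
               significant = pt$p_value < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "groups") <- groups
  out
}

#' Per-patient impairment profiles
#'
#' Combines impairment flags, impaired-domain counts, classification,
#' average and multi-domain impairment scores, and (when volumes are
#' available) their lesion-size-residualized variants.
#'
#' @param table Oriented score table (needs `patient_id`; uses
#'   `lesion_volume_mm3` when present).
#' @param battery A `test_battery`.
#' @param threshold Impairment cutoff.
#' @param min_domains Minimum impaired-domain count for "multi".
#' @return Data frame, one row per patient.
#' @export
patient_profiles <- function(table, battery = test_battery(),
                             threshold = -1.645, min_domains = 2L) {
  flags <- impairment_flags(table, battery, threshold)
  domain_count <- count_impaired_domains(flags, battery)
  out <- data.frame(
    patient_id = table$patient_id %||% seq_len(nrow(table)),
    group = table$group %||% NA_character_,
    n_impaired_tests = multi_domain_impairment_score(flags, battery),
    n_impaired_domains = domain_count,
    classification = classify_patient(domain_count, min_domains),
    average_impairment = average_impairment_score(table, battery),
    stringsAsFactors = FALSE
  )
  out$multi_domain_impairment <- out$n_impaired_tests
  if ("lesion_volume_mm3" %in% names(table)) {
    out$lesion_volume_mm3 <- table$lesion_volume_mm3
    out$average_impairment_resid <-
      residualize_on_lesion_size(out$average_impairment, out$lesion_volume_mm3)
    out$multi_domain_impairment_resid <-
      residualize_on_lesion_size(out$multi_domain_impairment, out$lesion_volume_mm3)
  }
  out
}
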