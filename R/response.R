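#' Classify per-lesion radiological response
#'
#' Applies per-lesion response thresholds to longitudinal diameter
#' measurements: a lesion *responds* if its longest diameter shrank by at
#' least 30%, *progresses* if it grew by at least 10%, and is *stable* in
#' between (the boundaries belong to the extreme categories, so -30% is a
#' response and +10% a progression). Lesions absent at baseline are
#' classified `new_lesion` and have no defined percent change.
#'
#' @param lesions Data frame with columns `baseline_diameter`,
#'   `followup_diameter` (mm) and `is_new` (logical). A baseline of 0 is
#'   only permitted for new lesions.
#' @param response_threshold,progression_threshold Percent-change cutoffs.
#' @return The input with columns `percent_change` (NA for new lesions) and
#'   `category` (`response`, `stable`, `progression`, `new_lesion`) added.
#' @examples
#' classify_lesions(data.frame(baseline_diameter = 10,
#'                             followup_diameter = 6.9, is_new = FALSE))
#' @export
classify_lesions <- function(lesions, response_threshold = -30,
                             progression_threshold = 10) {
  check_lesions(lesions)
  pc <- 100 * (lesions$followup_diameter - lesions$baseline_diameter) /
    lesions$baseline_diameter
  pc[lesions$is_new] <- NA_real_
  category <- ifelse(lesions$is_new, "new_lesion",
              ifelse(pc <= response_threshold, "response",
              ifelse(pc >= progression_threshold, "progression", "stable")))
  lesions$percent_change <- pc
  lesions$category <- category
  lesions
}

#' Classify a patient's overall response pattern at one assessment
#'
#' Implements the patient-level mixed/homogeneous response call. A patient
#' is *not evaluable* with fewer than two baseline-measurable lesions (a
#' mixed response can only be measured when two or more target lesions can
#' be assessed). Among evaluable patients with at least one responding
#' lesion, the response is *mixed* if any lesion progresses **or** any new
#' lesion appeared (a new lesion makes the response mixed even if all other
#' lesions are responding), and *homogeneous* otherwise. Evaluable patients
#' with no responding lesion are *non-responders*.
#'
#' @param lesions Lesion records for a single patient at a single
#'   assessment (see [classify_lesions()]); a `patient_id` column, if
#'   present, must be constant.
#' @inheritParams classify_lesions
#' @return A one-row data frame: `patient_id`, `category`, `n_lesions`
#'   (measurable lesions), `has_new_lesion`, `n_responding`,
#'   `n_progressing`, `mad_percent_change`.
#' @export
classify_patient <- function(lesions, response_threshold = -30,
                             progression_threshold = 10) {
  if (!is.null(lesions$patient_id) && length(unique(lesions$patient_id)) > 1L)
    stop("records from multiple patients: ",
         paste(unique(lesions$patient_id), collapse = ", "))
  calls <- classify_lesions(lesions, response_threshold, progression_threshold)
  measurable <- !calls$is_new
  n_meas <- sum(measurable)
  has_new <- any(calls$is_new)
  n_resp <- sum(calls$category == "response")
  n_prog <- sum(calls$category == "progression")
  category <- if (n_meas < 2L) "not_evaluable"
    else if (n_resp == 0L) "non_responder"
    else if (n_prog > 0L || has_new) "mixed_response"
    else "homogeneous_response"
  data.frame(
    patient_id = if (is.null(lesions$patient_id)) NA_character_
                 else as.character(lesions$patient_id[1]),
    category = category, n_lesions = n_meas, has_new_lesion = has_new,
    n_responding = n_resp, n_progressing = n_prog,
    mad_percent_change = if (n_meas > 0L)
      median_abs_dev(calls$percent_change[measurable]) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Classify every patient in a lesion table
#'
#' @param lesions Lesion table for many patients (`patient_id` required).
#' @inheritParams classify_lesions
#' @return A data frame with one [classify_patient()] row per patient.
#' @export
classify_cohort <- function(lesions, response_threshold = -30,
                            progression_threshold = 10) {
  stopifnot(!is.null(lesions$patient_id))
  out <- lapply(split(lesions, lesions$patient_id), classify_patient,
                response_threshold = response_threshold,
                progression_threshold = progression_threshold)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-patient MAD of lesion percent change
#'
#' Median absolute deviation (unscaled) of the per-lesion percent diameter
#' changes of one patient. New lesions have no defined percent change and
#' are excluded.
#'
#' @inheritParams classify_patient
#' @return A single number.
#' @export
patient_mad <- function(lesions) {
  calls <- classify_lesions(lesions)
  pc <- calls$percent_change[!calls$is_new]
  if (!length(pc)) stop("no measurable lesions: MAD undefined")
  median_abs_dev(pc)
}

#' RECIST-style sum-of-diameters category
#'
#' The conventional trial-level response call: percent change in the *sum*
#' of baseline-measurable target-lesion diameters. Partial response (PR)
#' at a 30% or greater reduction of the sum; progressive disease (PD) at a
#' 20% or greater increase **or** the appearance of any new lesion; stable
#' disease (SD) otherwise. Contrasting this call with [classify_patient()]
#' shows how per-lesion mixed responses hide inside RECIST PR/SD.
#'
#' @inheritParams classify_patient
#' @return `"PR"`, `"SD"` or `"PD"`.
#' @export
recist_sum_category <- function(lesions) {
  check_lesions(lesions)
  measurable <- !lesions$is_new
  if (!any(measurable)) stop("no baseline-measurable lesions")
  if (any(lesions$is_new)) return("PD")
  change <- 100 * (sum(lesions$followup_diameter[measurable]) -
                   sum(lesions$baseline_diameter[measurable])) /
    sum(lesions$baseline_diameter[measurable])
  if (change <= -30) "PR" else if (change >= 20) "PD" else "SD"
}

#' Summarize response patterns by group and compare groups
#'
#' Tabulates per-group counts of evaluable patients, responders (at least
#' one responding lesion), mixed responses among responders, and new-lesion
#' occurrences; then compares each pair of groups with Fisher's exact test
#' on mixed-vs-homogeneous and new-lesion proportions among responders, and
#' a two-sided Mann-Whitney test on the per-patient MADs.
#'
#' @param assessments Output of [classify_cohort()].
#' @param groups Named character vector or data frame
#'   (`patient_id`, `group`) assigning each patient to a group.
#' @return A list: `summary` (one row per group) and `tests` (a list of
#'   [test_result][fisher_exact_2x2] objects per group pair).
#' @export
cohort_summary <- function(assessments, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$patient_id)
  g <- groups[assessments$patient_id]
  if (anyNA(g)) stop("missing group label for some patients")
  lv <- unique(g)
  if (length(lv) < 2L) stop("need at least two groups")

  per_group <- lapply(lv, function(gr) {
    a <- assessments[g == gr & assessments$category != "not_evaluable", ]
    responders <- a[a$category %in% c("homogeneous_response", "mixed_response"), ]
    data.frame(group = gr, n_evaluable = nrow(a), n_responders = nrow(responders),
               n_mixed = sum(responders$category == "mixed_response"),
               n_new_lesion = sum(responders$has_new_lesion),
               median_mad = stats::median(responders$mad_percent_change),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, per_group)
  empty <- summary$group[summary$n_evaluable == 0L]
  if (length(empty)) {
    warning("excluding group(s) with no evaluable patients: ",
            paste(empty, collapse = ", "))
    summary <- summary[!summary$group %in% empty, ]
  }

  tests <- list()
  grs <- summary$group
  if (length(grs) >= 2L) {
    for (i in seq_len(length(grs) - 1L)) for (j in seq(i + 1L, length(grs))) {
      s1 <- summary[i, ]; s2 <- summary[j, ]
      key <- paste(grs[i], grs[j], sep = "_vs_")
      tests[[paste0(key, "_mixed")]] <- fisher_exact_2x2(
        s1$n_mixed, s1$n_responders - s1$n_mixed,
        s2$n_mixed, s2$n_responders - s2$n_mixed)
      tests[[paste0(key, "_new_lesion")]] <- fisher_exact_2x2(
        s1$n_new_lesion, s1$n_responders - s1$n_new_lesion,
        s2$n_new_lesion, s2$n_responders - s2$n_new_lesion)
      m1 <- assessments$mad_percent_change[
        g == grs[i] & assessments$category != "not_evaluable"]
      m2 <- assessments$mad_percent_change[
        g == grs[j] & assessments$category != "not_evaluable"]
      tests[[paste0(key, "_mad")]] <- mann_whitney_u(m1, m2)
    }
  }
  list(summary = summary, tests = tests)
}

check_lesions <- function(lesions) {
  need <- c("baseline_diameter", "followup_diameter", "is_new")
  if (!all(need %in% names(lesions)))
    stop("lesion table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(lesions$baseline_diameter)) ||
      any(!is.finite(lesions$followup_diameter)))
    stop("diameters must be finite")
  if (any(lesions$followup_diameter < 0) || any(lesions$baseline_diameter < 0))
    stop("diameters must be >= 0")
  if (any(lesions$baseline_diameter == 0 & !lesions$is_new))
    stop("baseline diameter 0 only permitted for new lesions (is_new)")
  if (any(lesions$baseline_diameter > 0 & lesions$is_new))
    stop("new lesions must have baseline diameter 0")
  invisible(lesions)
}
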