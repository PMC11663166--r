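# Anti-amyloid treatment eligibility: appropriate-use criteria published
# after the first anti-Abeta antibody approval, applied per record.

#' Anti-amyloid treatment eligibility criteria
#'
#' The five appropriate-use criteria: (1) clinical diagnosis of AD-type
#' dementia or MCI with no evidence of a non-AD neurologic disorder;
#' (2) MMSE 21-30, or MoCA 17-30 when the MMSE is missing; (3) available
#' MRI; (4) absence of anticoagulant treatment; (5) CSF profile
#' consistent with AD (amyloid-positive Abeta42/Abeta40 ratio).
#'
#' When both MMSE and MoCA are present the MMSE governs by default
#' (`moca_fallback_only = TRUE`); set it to `FALSE` to accept either
#' test in range.  Whether mixed or non-AD etiologies disqualify is
#' controlled through `non_ad_etiologies`, matched against the cohort's
#' free-text `etiology_tag` (records with a missing tag are not
#' excluded on etiology).
#'
#' @param allowed_diagnoses diagnoses passing criterion 1.
#' @param non_ad_etiologies etiology tags that disqualify.
#' @param mmse_range,moca_range inclusive cognitive ranges.
#' @param require_mri,exclude_anticoagulant,require_amyloid_positive
#'   criterion switches, all `TRUE` by default.
#' @param moca_fallback_only if `TRUE`, MoCA is consulted only when the
#'   MMSE is missing.
#' @param cutoffs [assay_cutoffs()] used when amyloid status must be
#'   derived from the ratio.
#' @return Object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(allowed_diagnoses = c("dementia", "MCI"),
                                 non_ad_etiologies = c("FTD", "vascular",
                                                       "alcohol",
                                                       "psychiatric"),
                                 mmse_range = c(21, 30),
                                 moca_range = c(17, 30),
                                 require_mri = TRUE,
                                 exclude_anticoagulant = TRUE,
                                 require_amyloid_positive = TRUE,
                                 moca_fallback_only = TRUE,
                                 cutoffs = assay_cutoffs()) {
  structure(list(allowed_diagnoses = allowed_diagnoses,
                 non_ad_etiologies = non_ad_etiologies,
                 mmse_range = mmse_range, moca_range = moca_range,
                 require_mri = require_mri,
                 exclude_anticoagulant = exclude_anticoagulant,
                 require_amyloid_positive = require_amyloid_positive,
                 moca_fallback_only = moca_fallback_only,
                 cutoffs = cutoffs),
            class = "eligibility_criteria")
}

#' @export
print.eligibility_criteria <- function(x, ...) {
  cat("Anti-amyloid treatment eligibility criteria:\n")
  cat(sprintf("  1. diagnosis in {%s}, etiology not in {%s}\n",
              paste(x$allowed_diagnoses, collapse = ", "),
              paste(x$non_ad_etiologies, collapse = ", ")))
  cat(sprintf("  2. MMSE %d-%d (MoCA %d-%d %s)\n",
              x$mmse_range[1], x$mmse_range[2],
              x$moca_range[1], x$moca_range[2],
              if (x$moca_fallback_only) "when MMSE missing" else "accepted"))
  cat(sprintf("  3. MRI available: %s\n", x$require_mri))
  cat(sprintf("  4. no anticoagulant: %s\n", x$exclude_anticoagulant))
  cat(sprintf("  5. amyloid-positive CSF: %s\n", x$require_amyloid_positive))
  invisible(x)
}

in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]

#' Assess anti-amyloid treatment eligibility per record
#'
#' Applies every enabled criterion; a record is eligible iff all pass.
#' Failures are reported as reasons, never as errors; a missing field
#' required by an enabled criterion yields the reason
#' `"missing:<field>"`.
#'
#' @param cohort cohort data.frame.
#' @param criteria an [eligibility_criteria()] object.
#' @return A data.frame with columns `eligible` (logical) and `reasons`
#'   (semicolon-joined failure reasons, `""` for eligible records),
#'   one row per cohort record.
#' @examples
#' cohort <- data.frame(diagnosis = c("MCI", "SCI"), etiology_tag = NA,
#'                      mmse = c(25, 28), moca = NA,
#'                      mri_available = TRUE, anticoagulant = FALSE,
#'                      amyloid_positive = TRUE)
#' assess_eligibility(cohort, eligibility_criteria())
#' @export
assess_eligibility <- function(cohort, criteria = eligibility_criteria()) {
  n <- nrow(cohort)
  reasons <- vector("list", n)
  add <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  col <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else rep(NA, n)

  dx <- col("diagnosis")
  add(is.na(dx), "missing:diagnosis")
  add(!is.na(dx) & !(dx %in% criteria$allowed_diagnoses), "diagnosis")
  et <- col("etiology_tag")
  add(!is.na(dx) & dx %in% criteria$allowed_diagnoses &
        !is.na(et) & et %in% criteria$non_ad_etiologies, "etiology")

  mmse <- col("mmse"); moca <- col("moca")
  if (criteria$moca_fallback_only) {
    cog_known <- !is.na(mmse) | !is.na(moca)
    cog_pass <- ifelse(!is.na(mmse), in_range(mmse, criteria$mmse_range),
                       in_range(moca, criteria$moca_range))
  } else {
    cog_known <- !is.na(mmse) | !is.na(moca)
    cog_pass <- in_range(mmse, criteria$mmse_range) |
      in_range(moca, criteria$moca_range)
  }
  add(!cog_known, "missing:mmse")
  add(cog_known & !cog_pass, "cognition")

  if (criteria$require_mri) {
    mri <- col("mri_available")
    add(is.na(mri), "missing:mri_available")
    add(!is.na(mri) & !mri, "mri")
  }
  if (criteria$exclude_anticoagulant) {
    ac <- col("anticoagulant")
    add(is.na(ac), "missing:anticoagulant")
    add(!is.na(ac) & ac, "anticoagulant")
  }
  if (criteria$require_amyloid_positive) {
    amy <- col("amyloid_positive")
    if (all(is.na(amy)) && all(c("abeta_ratio", "csf_assay") %in%
                               names(cohort))) {
      amy <- classify_amyloid(cohort$abeta_ratio, cohort$csf_assay,
                              criteria$cutoffs)
    }
    add(is.na(amy), "missing:amyloid_positive")
    add(!is.na(amy) & !amy, "amyloid")
  }

  data.frame(
    eligible = vapply(reasons, function(r) length(r) == 0L, logical(1)),
    reasons = vapply(reasons, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Evaluate a score as a predictor of treatment eligibility
#'
#' Labels every record by [assess_eligibility()] and evaluates the given
#' composite score (or any integer predictor) against those labels via
#' [evaluate_thresholds()], using the analysis subset's own eligible
#' fraction as the prevalence for PPV/NPV.
#'
#' @param cohort cohort data.frame.
#' @param criteria an [eligibility_criteria()].
#' @param score either a `score_spec` (scored on the cohort) or an
#'   integer vector of precomputed scores.
#' @param prevalence optional prevalence override for PPV/NPV.
#' @param conf_level confidence level for the AUC CI.
#' @return A `score_evaluation` (see [evaluate_thresholds()]).
#' @export
eligibility_evaluation <- function(cohort, criteria = eligibility_criteria(),
                                   score = four_item_score_spec(),
                                   prevalence = NULL, conf_level = 0.95) {
  scores <- if (inherits(score, "score_spec"))
    composite_score(cohort, score) else score
  elig <- assess_eligibility(cohort, criteria)$eligible
  if (!any(elig)) stop("no eligible records; evaluation is undefined",
                       call. = FALSE)
  name <- if (inherits(score, "score_spec"))
    paste0(score$name, " vs eligibility") else "eligibility"
  k <- if (inherits(score, "score_spec")) score$max_score else NULL
  evaluate_thresholds(scores, elig, k = k, prevalence = prevalence,
                      conf_level = conf_level, name = name)
}
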