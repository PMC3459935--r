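#' Body mass index
#'
#' @param weight body weight in kg.
#' @param height height in m.
#' @return BMI in kg/m^2.
#' @export
derive_bmi <- function(weight, height) {
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE)) {
    stop("weight and height must be positive")
  }
  weight / height^2
}

#' HOMA insulin-resistance index
#'
#' @param glucose fasting glucose in mM.
#' @param insulin fasting insulin in mU/l.
#' @return HOMA-IR = glucose x insulin / 22.5.
#' @export
derive_homa_ir <- function(glucose, insulin) {
  if (any(glucose < 0, na.rm = TRUE) || any(insulin < 0, na.rm = TRUE)) {
    stop("glucose and insulin must be non-negative")
  }
  glucose * insulin / 22.5
}

#' Metabolic syndrome classification (harmonized definition)
#'
#' Flags subjects meeting at least 3 of the 5 harmonized criteria with
#' Europid waist cutoffs: waist >= 94 cm (men) / >= 80 cm (women);
#' triglycerides >= 1.7 mM; HDL-C < 1.03 mM (men) / < 1.29 mM (women);
#' SBP >= 130 or DBP >= 85 mmHg; fasting glucose >= 5.6 mM. Rows with any
#' missing component return \code{NA}, never a silent \code{FALSE}.
#' Medication-based criteria are not modelled.
#'
#' @param waist waist circumference, cm.
#' @param tg triglycerides, mM.
#' @param hdl HDL-cholesterol, mM.
#' @param sbp,dbp systolic/diastolic blood pressure, mmHg.
#' @param glucose fasting glucose, mM.
#' @param sex \code{"M"} or \code{"F"}.
#' @return logical vector (TRUE = metabolic syndrome), NA where any
#'   component is missing.
#' @export
classify_mets <- function(waist, tg, hdl, sbp, dbp, glucose, sex) {
  stopifnot(all(sex %in% c("M", "F")))
  crit <- cbind(
    waist >= ifelse(sex == "M", 94, 80),
    tg >= 1.7,
    hdl < ifelse(sex == "M", 1.03, 1.29),
    sbp >= 130 | dbp >= 85,
    glucose >= 5.6
  )
  n_met <- rowSums(crit)
  out <- n_met >= 3
  out[rowSums(is.na(crit)) > 0] <- NA
  out
}

#' Weight-change group over the weight-maintenance phase
#'
#' Classifies each subject by how much of the calorie-restriction weight
#' loss was regained (or further lost) by the end of the maintenance phase:
#' \code{regain} if the CID2-to-CID3 gain is at least 50\% of the lost
#' weight, \code{loss} if at least another 50\% was lost, \code{neither}
#' otherwise, and \code{not_applicable} when no weight was lost during the
#' LCD. The 50\% boundaries are inclusive.
#'
#' @param w1,w2,w3 weight (kg) at CID1, CID2, CID3.
#' @return character vector in
#'   \code{{"regain","loss","neither","not_applicable"}}.
#' @export
assign_weight_change_group <- function(w1, w2, w3) {
  lost <- w1 - w2
  out <- rep("neither", length(w1))
  out[(w3 - w2) >= 0.5 * lost] <- "regain"
  out[(w2 - w3) >= 0.5 * lost] <- "loss"
  out[lost <= 0] <- "not_applicable"
  out[is.na(w1) | is.na(w2) | is.na(w3)] <- NA_character_
  out
}

#' Add derived phenotypes to a cohort table
#'
#' Appends BMI, HOMA-IR and the metabolic-syndrome flag per row, plus the
#' per-subject weight-change group (computed from the three visit weights
#' and repeated on every row of the subject).
#'
#' @param cohort a cohort table from [generate_cohort()] (or any table with
#'   the same columns).
#' @return the cohort with columns \code{bmi}, \code{homa_ir}, \code{mets},
#'   \code{weight_change_group} added.
#' @export
derive_phenotypes <- function(cohort) {
  cohort$bmi <- derive_bmi(cohort$weight, cohort$height)
  cohort$homa_ir <- derive_homa_ir(cohort$glucose, cohort$insulin)
  cohort$mets <- classify_mets(cohort$waist, cohort$tg, cohort$hdl,
                               cohort$sbp, cohort$dbp, cohort$glucose,
                               cohort$sex)
  w <- stats::reshape(
    cohort[, c("subject_id", "cid", "weight")],
    idvar = "subject_id", timevar = "cid", direction = "wide")
  grp <- assign_weight_change_group(w$weight.1, w$weight.2, w$weight.3)
  cohort$weight_change_group <- grp[match(cohort$subject_id, w$subject_id)]
  cohort
}
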