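#' Baseline clinical features
#'
#' The pre-treatment features consumed by the EUTOS and ELTS prognostic
#' scores. Any field may be `NA`; score functions report a missing-data
#' result rather than erroring, mirroring cohorts where e.g. spleen size
#' was not recorded for every patient.
#'
#' @param age_years Age in completed years.
#' @param spleen_cm Spleen size below the costal margin (cm).
#' @param basophil_pct Basophils in peripheral blood (%).
#' @param blast_pct Blasts in peripheral blood (%).
#' @param platelet_count Platelet count (10^9/L).
#' @return An object of class `clinical_baseline`.
#' @export
clinical_baseline <- function(age_years = NA, spleen_cm = NA,
                              basophil_pct = NA, blast_pct = NA,
                              platelet_count = NA) {
  num <- function(v) as.numeric(v)
  b <- list(age_years = num(age_years), spleen_cm = num(spleen_cm),
            basophil_pct = num(basophil_pct), blast_pct = num(blast_pct),
            platelet_count = num(platelet_count))
  chk <- function(v, nm, max = Inf) {
    if (!is.na(v) && (v < 0 || v > max)) stop(nm, " out of range: ", v)
  }
  chk(b$age_years, "age_years")
  chk(b$spleen_cm, "spleen_cm")
  chk(b$basophil_pct, "basophil_pct", 100)
  chk(b$blast_pct, "blast_pct", 100)
  if (!is.na(b$platelet_count) && b$platelet_count <= 0) {
    stop("platelet_count must be positive")
  }
  structure(b, class = "clinical_baseline")
}

risk_class <- function(system, score, risk, missing = FALSE) {
  structure(list(system = system, score = score, risk = risk,
                 missing = missing),
            class = "risk_class")
}

#' @export
print.risk_class <- function(x, ...) {
  if (x$missing) {
    cat(sprintf("%s score: missing baseline data\n", x$system))
  } else {
    cat(sprintf("%s score %.4f: %s risk\n", x$system, x$score, x$risk))
  }
  invisible(x)
}

#' EUTOS prognostic score
#'
#' `4 * spleen_cm + 7 * basophil_pct`; a score above 87 is High risk,
#' otherwise Low (EUTOS has no intermediate class).
#'
#' @param baseline A [clinical_baseline()].
#' @return A `risk_class` (`system = "EUTOS"`); `missing = TRUE` when
#'   spleen size or basophil percentage is unavailable.
#' @export
eutos_score <- function(baseline) {
  stopifnot(inherits(baseline, "clinical_baseline"))
  if (is.na(baseline$spleen_cm) || is.na(baseline$basophil_pct)) {
    return(risk_class("EUTOS", NA_real_, NA_character_, missing = TRUE))
  }
  s <- 4 * baseline$spleen_cm + 7 * baseline$basophil_pct
  risk_class("EUTOS", s, if (s > 87) "High" else "Low")
}

#' ELTS prognostic score
#'
#' `0.0025 * (age/10)^3 + 0.0615 * spleen_cm + 0.1052 * blast_pct +
#'  0.4104 * (platelets/1000)^(-0.5)`; High above 2.2185, Low at or
#' below 1.5680, Intermediate otherwise.
#'
#' @param baseline A [clinical_baseline()].
#' @return A `risk_class` (`system = "ELTS"`); `missing = TRUE` when any
#'   of the four inputs is unavailable.
#' @export
elts_score <- function(baseline) {
  stopifnot(inherits(baseline, "clinical_baseline"))
  vals <- c(baseline$age_years, baseline$spleen_cm, baseline$blast_pct,
            baseline$platelet_count)
  if (anyNA(vals)) {
    return(risk_class("ELTS", NA_real_, NA_character_, missing = TRUE))
  }
  s <- 0.0025 * (baseline$age_years / 10)^3 +
    0.0615 * baseline$spleen_cm +
    0.1052 * baseline$blast_pct +
    0.4104 * (baseline$platelet_count / 1000)^(-0.5)
  risk <- if (s > 2.2185) "High" else if (s <= 1.5680) "Low" else "Intermediate"
  risk_class("ELTS", s, risk)
}

#' Milestone molecular-response staging (ELN 2013 reading)
#'
#' Stages a patient's IS value at a landmark month into Optimal /
#' Warning / Failure. At 3 months only the Warning/Optimal boundary
#' (10%) applies; at 6 months Failure above 10%, Warning above 1%; at 12
#' months Failure above 1%, Warning above 0.1%. An IS exactly at a
#' cutoff takes the better stage.
#'
#' @param is_pct IS value (percent).
#' @param month Landmark month: 3, 6 or 12.
#' @return An object of class `eln_stage` with fields `month`, `is_pct`,
#'   `stage`.
#' @export
eln_stage <- function(is_pct, month) {
  stopifnot(is.finite(is_pct), is_pct >= 0)
  if (!month %in% c(3, 6, 12)) {
    stop("milestone staging is defined at months 3, 6 and 12")
  }
  stage <- switch(
    as.character(month),
    "3" = if (is_pct <= 10) "Optimal" else "Warning",
    "6" = if (is_pct > 10) "Failure" else if (is_pct > 1) "Warning"
          else "Optimal",
    "12" = if (is_pct > 1) "Failure" else if (is_pct > 0.1) "Warning"
           else "Optimal"
  )
  structure(list(month = month, is_pct = is_pct, stage = stage),
            class = "eln_stage")
}

#' @export
print.eln_stage <- function(x, ...) {
  cat(sprintf("Month %d, IS %.4g%%: %s\n", x$month, x$is_pct, x$stage))
  invisible(x)
}

#' Map a prognostic class or milestone stage to a response prediction
#'
#' The comparator systems were not designed to predict deep molecular
#' response; to benchmark them against the kinetic classifier, Low risk
#' and Optimal map to a positive (responder) prediction and every other
#' class (Intermediate, High, Warning, Failure) to negative. A
#' missing-data score yields `NA` so the patient can be excluded from
#' comparator metrics.
#'
#' @param x A `risk_class` or `eln_stage`.
#' @return Logical prediction, or `NA` for missing baseline data.
#' @export
score_to_prediction <- function(x) {
  if (inherits(x, "risk_class")) {
    if (isTRUE(x$missing)) return(NA)
    return(x$risk == "Low")
  }
  if (inherits(x, "eln_stage")) return(x$stage == "Optimal")
  stop("score_to_prediction expects a risk_class or eln_stage")
}

#' Benchmark a comparator system against true response labels
#'
#' Computes per-patient predictions from a comparator (EUTOS, ELTS, or
#' milestone staging at a given month) and the resulting confusion
#' matrix, excluding patients with missing baseline data.
#'
#' @param cohort List of [patient_series()] (with `baseline` set for the
#'   score systems).
#' @param system `"EUTOS"`, `"ELTS"`, or `"ELN"`.
#' @param criterion A [response_criterion()] defining the true labels.
#' @param month Landmark month for `system = "ELN"`.
#' @return List: `per_patient` data.frame (`patient_id`, `truth`,
#'   `predicted`), `confusion` over the non-missing patients,
#'   `n_missing`.
#' @export
score_benchmark <- function(cohort, system = c("EUTOS", "ELTS", "ELN"),
                            criterion = response_criterion("MR4.5"),
                            month = 12) {
  system <- match.arg(system)
  truth <- vapply(cohort, label_response, logical(1), criterion = criterion)
  pred <- vapply(cohort, function(p) {
    cls <- switch(
      system,
      EUTOS = eutos_score(if (is.null(p$baseline)) clinical_baseline()
                          else p$baseline),
      ELTS = elts_score(if (is.null(p$baseline)) clinical_baseline()
                        else p$baseline),
      ELN = {
        i <- match(month, p$times)
        if (is.na(i)) stop("patient ", p$patient_id,
                           " has no measurement at month ", month)
        eln_stage(p$is_pct[i], month)
      }
    )
    as.logical(score_to_prediction(cls))
  }, logical(1))
  keep <- !is.na(pred)
  per_patient <- data.frame(
    patient_id = vapply(cohort, `[[`, character(1), "patient_id"),
    truth = truth, predicted = pred
  )
  list(per_patient = per_patient,
       confusion = confusion_metrics(truth[keep], pred[keep]),
       n_missing = sum(!keep))
}
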