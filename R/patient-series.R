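#' A single patient's longitudinal measurement series
#'
#' Holds one patient's WBC counts and IS values on the clinic-visit grid,
#' plus optional baseline clinical features used by the prognostic-score
#' comparators.
#'
#' @param patient_id Character scalar identifier.
#' @param times Numeric vector of measurement times in months, strictly
#'   increasing, non-negative (typically 0, 3, ..., 24).
#' @param wbc Total white blood cell counts (cells/ul), same length as
#'   `times`, all positive.
#' @param is_pct IS values (percent), same length as `times`; each at or
#'   above the detection floor and no larger than `100 * k_is`.
#' @param baseline Optional [clinical_baseline()] record.
#' @param consts Model constants used for validation.
#'
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, times, wbc, is_pct,
                           baseline = NULL,
                           consts = model_constants()) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  times <- as.numeric(times)
  wbc <- as.numeric(wbc)
  is_pct <- as.numeric(is_pct)
  n <- length(times)
  if (length(wbc) != n || length(is_pct) != n) {
    stop("times, wbc and is_pct must have equal length for patient ",
         patient_id)
  }
  if (n > 0) {
    if (any(!is.finite(times)) || any(times < 0)) {
      stop("times must be finite and non-negative for patient ", patient_id)
    }
    if (any(diff(times) <= 0)) {
      stop("times must be strictly increasing for patient ", patient_id)
    }
    if (any(!is.finite(wbc)) || any(wbc <= 0)) {
      stop("all wbc values must be positive for patient ", patient_id)
    }
    bad_low <- is_pct < consts$detection_limit - 1e-12
    bad_high <- is_pct > 100 * consts$k_is + 1e-9
    if (any(!is.finite(is_pct)) || any(bad_low)) {
      stop("IS values must be finite and at or above the detection floor (",
           consts$detection_limit, "%) for patient ", patient_id)
    }
    if (any(bad_high)) {
      stop("IS values cannot exceed ", 100 * consts$k_is,
           "% (k_IS scale maximum) for patient ", patient_id)
    }
  }
  if (!is.null(baseline) && !inherits(baseline, "clinical_baseline")) {
    stop("baseline must be a clinical_baseline or NULL")
  }
  structure(
    list(patient_id = patient_id, times = times, wbc = wbc,
         is_pct = is_pct, baseline = baseline),
    class = "patient_series"
  )
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("Patient %s: %d visits over months [%s, %s]\n",
              x$patient_id, length(x$times),
              format(min(x$times)), format(max(x$times))))
  print(data.frame(time_months = x$times, wbc_per_ul = x$wbc,
                   is_pct = x$is_pct), row.names = FALSE)
  invisible(x)
}

#' Label a patient's response under a molecular-response criterion
#'
#' MR4.0 / MR4.5: the patient is labelled a responder if any IS value at or
#' before `horizon_months` is at or below the criterion threshold; later
#' fluctuation back above the threshold does not revoke the label. CMR: IS
#' must be at or below 0.0032% at both of the criterion's two consecutive
#' late visits (months 21 and 24).
#'
#' @param series A [patient_series()].
#' @param criterion A [response_criterion()].
#' @param horizon_months Time window (months) within which the threshold
#'   must be reached (ignored for CMR, which is anchored to its two fixed
#'   months). Defaults to the last measurement time.
#' @return Logical: did the patient reach the response?
#' @export
label_response <- function(series, criterion = response_criterion("MR4.5"),
                           horizon_months = max(series$times)) {
  stopifnot(inherits(series, "patient_series"),
            inherits(criterion, "response_criterion"))
  if (criterion$name == "CMR") {
    idx <- match(criterion$cmr_months, series$times)
    if (anyNA(idx)) {
      stop("CMR labelling requires measurements at months ",
           paste(criterion$cmr_months, collapse = " and "),
           " for patient ", series$patient_id)
    }
    return(all(series$is_pct[idx] <= criterion$is_threshold))
  }
  keep <- series$times <= horizon_months
  any(series$is_pct[keep] <= criterion$is_threshold)
}

#' Keep only patients with complete measurements on a required grid
#'
#' Mirrors the eligibility rule of the clinical dataset: a patient is
#' retained only if a WBC and an IS value exist at every required time.
#'
#' @param cohort List of [patient_series()].
#' @param required_times Numeric vector of times (months) that must all be
#'   present.
#' @return The eligible subset (a list, possibly empty).
#' @export
filter_eligible <- function(cohort, required_times = seq(0, 24, by = 3)) {
  keep <- vapply(cohort, function(p) {
    all(required_times %in% p$times)
  }, logical(1))
  cohort[keep]
}
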