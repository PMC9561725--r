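#' Three-visit closed-form estimate of leukemic kinetics
#'
#' From exactly three equally spaced visits (t = 0, dt, 2dt) the leukemic
#' compartment's exponential decline is identified in closed form. Each
#' (IS, WBC) pair is inverted to a leukemic count
#' \eqn{\hat y(t)}; then
#' \deqn{\hat y^* = \frac{\hat y(0)\hat y(2\Delta t) - \hat y(\Delta t)^2}
#'       {\hat y(0) - 2\hat y(\Delta t) + \hat y(2\Delta t)}, \qquad
#'       \hat b = \frac{1}{\Delta t}\ln\frac{\hat y(0) - \hat y(\Delta t)}
#'       {\hat y(\Delta t) - \hat y(2\Delta t)}.}
#' These are exact for any noiseless geometric approach to a plateau.
#'
#' Short-circuit: if the patient already satisfies the response criterion
#' within the three visits (any IS at or below the threshold for
#' MR4.0/MR4.5; two consecutive visits at or below 0.0032% for CMR), the
#' patient is a responder by definition and the closed forms are skipped
#' (`early_dmr = TRUE`).
#'
#' Degenerate triples — zero curvature denominator, non-decreasing or
#' non-contracting counts, or a censored IS value that is not early
#' response — yield `valid = FALSE` with a reason code rather than an
#' error; the classifier maps such patients to a non-response prediction.
#'
#' @param series A [patient_series()]; its first three visits are used
#'   and must be spaced `consts$dt` apart.
#' @param c_ratio Shared ABL1 expression ratio (from the training-cohort
#'   fit).
#' @param criterion A [response_criterion()].
#' @param consts [model_constants()].
#' @return An object of class `rapid_estimate`: `y_star_hat` (cells/ul,
#'   negative values floored at 0, raw value kept in `y_star_raw`),
#'   `b_hat` (1/month), `early_dmr`, `valid`, `reason` (NA when valid),
#'   `y_points` (the three inverted counts, NA when skipped).
#' @export
estimate_from_three_points <- function(series, c_ratio,
                                       criterion = response_criterion("MR4.5"),
                                       consts = model_constants()) {
  stopifnot(inherits(series, "patient_series"), c_ratio > 0)
  if (length(series$times) < 3) {
    stop("three-point estimation requires at least 3 visits (patient ",
         series$patient_id, ")")
  }
  t3 <- series$times[1:3]
  if (max(abs(diff(t3) - consts$dt)) > 1e-9) {
    stop("first three visits must be spaced ", consts$dt,
         " months apart (patient ", series$patient_id, ")")
  }
  is3 <- series$is_pct[1:3]
  wbc3 <- series$wbc[1:3]

  early <- if (criterion$name == "CMR") {
    any(is3[1:2] <= criterion$is_threshold &
          is3[2:3] <= criterion$is_threshold)
  } else {
    any(is3 <= criterion$is_threshold)
  }
  out <- function(y_star_raw = NA_real_, b_hat = NA_real_,
                  early_dmr = FALSE, valid = FALSE,
                  reason = NA_character_, y_points = rep(NA_real_, 3)) {
    structure(
      list(y_star_hat = if (is.na(y_star_raw)) NA_real_
                        else max(y_star_raw, 0),
           y_star_raw = y_star_raw, b_hat = b_hat, early_dmr = early_dmr,
           valid = valid, reason = reason, y_points = y_points,
           patient_id = series$patient_id),
      class = "rapid_estimate"
    )
  }
  if (early) return(out(early_dmr = TRUE, valid = TRUE))

  if (any(is3 <= consts$detection_limit)) {
    # censored point without meeting the early rule (CMR only): counts
    # not invertible
    return(out(reason = "censored_point"))
  }
  yy <- is_wbc_to_counts(is3, wbc3, c_ratio, consts)$y
  denom <- yy[1] - 2 * yy[2] + yy[3]
  d01 <- yy[1] - yy[2]
  d12 <- yy[2] - yy[3]
  if (abs(denom) < 1e-12 * max(abs(yy), 1)) {
    return(out(y_points = yy, reason = "zero_denominator"))
  }
  if (d01 <= 0 || d12 <= 0) {
    return(out(y_points = yy, reason = "non_monotone"))
  }
  y_star_raw <- (yy[1] * yy[3] - yy[2]^2) / denom
  b_hat <- log(d01 / d12) / consts$dt
  if (!is.finite(y_star_raw) || !is.finite(b_hat)) {
    return(out(y_points = yy, reason = "non_finite"))
  }
  out(y_star_raw = y_star_raw, b_hat = b_hat, valid = TRUE, y_points = yy)
}

#' @export
print.rapid_estimate <- function(x, ...) {
  if (x$early_dmr) {
    cat(sprintf("Patient %s: early responder within the first three visits\n",
                x$patient_id))
  } else if (!x$valid) {
    cat(sprintf("Patient %s: estimate not computable (%s)\n",
                x$patient_id, x$reason))
  } else {
    cat(sprintf(
      "Patient %s: plateau %.4g cells/ul, reduction rate %.4f /month\n",
      x$patient_id, x$y_star_hat, x$b_hat))
  }
  invisible(x)
}
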