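#' Model constants for CML response kinetics
#'
#' Bundles the fixed quantities used throughout the pipeline: the IS
#' laboratory conversion factor, the IS detection floor, the normal-WBC
#' plateau band enforced during cohort fitting, the constraint penalty
#' weight, and the nominal visit spacing.
#'
#' @param k_is IS conversion factor (dimensionless). The laboratory factor
#'   that maps the raw BCR-ABL1/ABL1 ratio onto the international scale.
#' @param detection_limit Lowest reportable IS value (percent). Measurements
#'   below this are clamped to it.
#' @param x_star_min,x_star_max Bounds (cells/ul) on the normal-WBC plateau,
#'   the normal range for healthy adults.
#' @param penalty_weight Weight of the ramp-function constraint penalty in
#'   the cohort objective.
#' @param dt Nominal spacing between clinic visits (months).
#'
#' @return An object of class `model_constants`.
#' @export
model_constants <- function(k_is = 1.2,
                            detection_limit = 0.0032,
                            x_star_min = 3100,
                            x_star_max = 9800,
                            penalty_weight = 100,
                            dt = 3) {
  stopifnot(
    k_is > 0, detection_limit > 0,
    x_star_min > 0, x_star_max > 0, x_star_min < x_star_max,
    penalty_weight > 0, dt > 0
  )
  structure(
    list(
      k_is = k_is,
      detection_limit = detection_limit,
      x_star_min = x_star_min,
      x_star_max = x_star_max,
      penalty_weight = penalty_weight,
      dt = dt
    ),
    class = "model_constants"
  )
}

#' Molecular response criteria
#'
#' Constructs a response criterion: MR4.0 (IS <= 0.01%), MR4.5
#' (IS <= 0.0032%), or CMR (MR4.5 at two consecutive late visits, by
#' convention months 21 and 24).
#'
#' @param name One of `"MR4.0"`, `"MR4.5"`, `"CMR"`.
#' @return An object of class `response_criterion` with fields `name`,
#'   `is_threshold` (percent) and, for CMR, `cmr_months`.
#' @export
response_criterion <- function(name = c("MR4.5", "MR4.0", "CMR")) {
  name <- match.arg(name)
  thr <- switch(name, "MR4.0" = 0.01, "MR4.5" = 0.0032, "CMR" = 0.0032)
  structure(
    list(
      name = name,
      is_threshold = thr,
      cmr_months = if (name == "CMR") c(21, 24) else NULL
    ),
    class = "response_criterion"
  )
}

#' @export
print.model_constants <- function(x, ...) {
  cat("CML model constants:\n")
  cat(sprintf("  k_IS = %g, detection limit = %g%%\n", x$k_is, x$detection_limit))
  cat(sprintf("  normal-WBC plateau band = [%g, %g] cells/ul\n",
              x$x_star_min, x$x_star_max))
  cat(sprintf("  penalty weight = %g, visit spacing = %g months\n",
              x$penalty_weight, x$dt))
  invisible(x)
}

#' @export
print.response_criterion <- function(x, ...) {
  cat(sprintf("Response criterion %s: IS <= %g%%", x$name, x$is_threshold))
  if (!is.null(x$cmr_months)) {
    cat(sprintf(" at both months %d and %d", x$cmr_months[1], x$cmr_months[2]))
  }
  cat("\n")
  invisible(x)
}
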