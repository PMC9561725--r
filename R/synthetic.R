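#' Configuration for the synthetic cohort generator
#'
#' Describes a two-class cohort: responders (eventual deep molecular
#' response) with fast leukemic decline toward a plateau below the IS
#' detection floor, and non-responders with slow decline toward a
#' detectable residual plateau. Parameter ranges are per class;
#' separability in the (plateau, rate) plane holds by construction when
#' the responder plateau range lies below the non-responder range and
#' the responder rate range above it.
#'
#' @param n_patients Number of patients.
#' @param fraction_dmr Expected responder fraction (class drawn per
#'   patient as the first `round(n * fraction)` patients, so class sizes
#'   are exact, then order shuffled).
#' @param c_true Shared ABL1 expression ratio used by the forward model.
#' @param a_range Normal-WBC recovery rate range (1/month), both classes.
#' @param x_star_range Normal-WBC plateau range (cells/ul).
#' @param x0_range,y0_range Initial count ranges (cells/ul); at diagnosis
#'   the leukemic load dominates (`y0 >> x0`).
#' @param b_range_dmr,b_range_nondmr Leukemic reduction-rate ranges
#'   (1/month) per class.
#' @param y_star_range_dmr,y_star_range_nondmr Leukemic plateau ranges
#'   (cells/ul) per class.
#' @param noise_sigma Standard deviation of the lognormal measurement
#'   noise applied multiplicatively to WBC and to the pre-clamp IS.
#' @param times Measurement grid (months).
#' @param missingness Probability that any single visit is dropped.
#' @param baselines Generate plausible baseline clinical features?
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 32,
                          fraction_dmr = 18 / 32,
                          c_true = 1.5,
                          a_range = c(0.2, 1.0),
                          x_star_range = c(3100, 9800),
                          x0_range = c(1000, 4000),
                          y0_range = c(2e4, 1e5),
                          b_range_dmr = c(0.65, 2.0),
                          b_range_nondmr = c(0.05, 0.28),
                          y_star_range_dmr = c(0.005, 0.06),
                          y_star_range_nondmr = c(1, 80),
                          noise_sigma = 0.1,
                          times = seq(0, 24, by = 3),
                          missingness = 0,
                          baselines = TRUE,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              fraction_dmr = fraction_dmr, c_true = c_true,
              a_range = a_range, x_star_range = x_star_range,
              x0_range = x0_range, y0_range = y0_range,
              b_range_dmr = b_range_dmr, b_range_nondmr = b_range_nondmr,
              y_star_range_dmr = y_star_range_dmr,
              y_star_range_nondmr = y_star_range_nondmr,
              noise_sigma = noise_sigma, times = as.numeric(times),
              missingness = missingness, baselines = isTRUE(baselines),
              seed = as.integer(seed))
  stopifnot(
    cfg$n_patients > 0,
    cfg$fraction_dmr >= 0, cfg$fraction_dmr <= 1,
    cfg$c_true > 0, cfg$noise_sigma >= 0,
    cfg$missingness >= 0, cfg$missingness < 1,
    all(diff(cfg$times) > 0),
    all(unlist(cfg[grep("_range", names(cfg))]) > 0)
  )
  structure(cfg, class = "cohort_config")
}

#' Default cohort configuration mirroring the study conditions
#'
#' 32 patients on a 9-visit grid (months 0 to 24 every 3), an 18:14
#' responder:non-responder split, normal-WBC plateaus spanning the
#' healthy band 3100-9800 cells/ul, diagnosis-like initial loads with
#' the leukemic compartment dominating, and 10% lognormal measurement
#' noise.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_paper_like_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed, ...)
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient kinetics from the class-specific ranges, simulates
#' the exact two-compartment trajectories, forms WBC and IS
#' measurements through the measurement model, applies independent
#' multiplicative lognormal noise to WBC and to the pre-clamp IS, clamps
#' IS at the detection floor, and optionally drops visits at random.
#' Responder-class plateaus are checked against the detectability bound
#' \eqn{y^*_{min}(c, x^*)}: the responder range must lie below it for
#' every admissible `x_star` so the generated responders can actually
#' cross the floor.
#'
#' @param config A [cohort_config()].
#' @param consts [model_constants()].
#' @return List with `cohort` (list of [patient_series()]) and `truth`
#'   (data.frame: `patient_id`, `dmr` (class flag), `a`, `b`, `x_star`,
#'   `y_star`, `x0`, `y0`, plus the shared `c_true`).
#' @examples
#' g <- generate_cohort(cohort_config(n_patients = 4, seed = 1))
#' g$truth
#' g$cohort[[1]]
#' @export
generate_cohort <- function(config = default_paper_like_config(),
                            consts = model_constants()) {
  stopifnot(inherits(config, "cohort_config"))
  y_min_worst <- min_cml_convergence(config$c_true,
                                     min(config$x_star_range), consts)
  if (max(config$y_star_range_dmr) >= y_min_worst) {
    stop("responder y_star range must lie below y_star_min (",
         signif(y_min_worst, 4), " cells/ul at the smallest x_star) so ",
         "responders can cross the detection floor")
  }
  set.seed(config$seed)
  n <- config$n_patients
  n_dmr <- round(n * config$fraction_dmr)
  dmr <- sample(c(rep(TRUE, n_dmr), rep(FALSE, n - n_dmr)))
  runifr <- function(r) stats::runif(1, r[1], r[2])

  cohort <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    b_r <- if (dmr[i]) config$b_range_dmr else config$b_range_nondmr
    ys_r <- if (dmr[i]) config$y_star_range_dmr else config$y_star_range_nondmr
    # responder plateaus drawn log-uniformly: they span decades below
    # the floor-crossing bound
    y_star <- if (dmr[i]) exp(runifr(log(ys_r))) else runifr(ys_r)
    th <- dynamics_params(list(
      a = runifr(config$a_range), b = runifr(b_r),
      x_star = runifr(config$x_star_range), y_star = y_star,
      x0 = runifr(config$x0_range), y0 = runifr(config$y0_range)
    ))
    tr <- simulate_counts(th, config$times)
    wbc_true <- tr$x + tr$y
    is_raw <- tr$y / (config$c_true * tr$x + tr$y) * consts$k_is * 100
    wbc_obs <- wbc_true * exp(stats::rnorm(length(wbc_true), 0,
                                           config$noise_sigma))
    is_obs <- pmin(
      pmax(is_raw * exp(stats::rnorm(length(is_raw), 0,
                                     config$noise_sigma)),
           consts$detection_limit),
      consts$k_is * 100
    )
    keep <- stats::runif(length(config$times)) >= config$missingness
    if (!any(keep)) keep[1] <- TRUE
    baseline <- if (config$baselines) {
      clinical_baseline(
        age_years = round(stats::runif(1, 25, 80)),
        spleen_cm = round(stats::runif(1, 0, 12)),
        basophil_pct = round(stats::runif(1, 0, 12), 1),
        blast_pct = round(stats::runif(1, 0, 5), 1),
        platelet_count = round(stats::runif(1, 150, 900))
      )
    } else NULL
    id <- sprintf("P%02d", i)
    cohort[[i]] <- patient_series(id, config$times[keep], wbc_obs[keep],
                                  is_obs[keep], baseline = baseline,
                                  consts = consts)
    rows[[i]] <- data.frame(patient_id = id, dmr = dmr[i], a = th$a,
                            b = th$b, x_star = th$x_star,
                            y_star = th$y_star, x0 = th$x0, y0 = th$y0,
                            c_true = config$c_true)
  }
  list(cohort = cohort, truth = do.call(rbind, rows))
}
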