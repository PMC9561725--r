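#' Penalized cohort objective
#'
#' Sum over patients and visits of squared natural-log residuals of the
#' modelled IS and WBC against the measurements, plus a ramp-function
#' penalty enforcing the constraints softly:
#' \deqn{\sum_i \sum_t (\ln IS_i(t) - \ln \widehat{IS}_i(t))^2 +
#'       (\ln WBC_i(t) - \ln \widehat{WBC}_i(t))^2 + W \sum_i
#'       [R(x^*_{min} - x^*_i) + R(x^*_i - x^*_{max}) +
#'        R(y^*_{i,min} - y^*_i) + R(-a_i) + R(-b_i)]}
#' with \eqn{R(u) = \max(u, 0)} and weight `W` =
#' `consts$penalty_weight`. The modelled IS carries the detection-limit
#' clamp, so a measurement at the floor contributes zero residual
#' whenever the prediction is also at the floor.
#'
#' @param fit A `cohort_fit`, or any list with a scalar `c` and a named
#'   list `per_patient` of [dynamics_params()] keyed by patient id.
#' @param cohort List of [patient_series()] (each id must appear in
#'   `fit$per_patient`).
#' @param consts [model_constants()].
#' @return Non-negative scalar loss (data term plus penalty).
#' @export
cohort_objective <- function(fit, cohort, consts = model_constants()) {
  stopifnot(fit$c > 0)
  total <- 0
  for (p in cohort) {
    theta <- fit$per_patient[[p$patient_id]]
    if (is.null(theta)) stop("no parameters for patient ", p$patient_id)
    total <- total +
      patient_data_term(unlist(theta[c("a", "b", "x_star", "y_star",
                                       "x0", "y0")]),
                        p, fit$c, consts, hard = TRUE) +
      consts$penalty_weight *
        penalty_terms(unlist(theta[c("a", "b", "x_star", "y_star",
                                     "x0", "y0")]),
                      fit$c, consts)
  }
  total
}

# squared ln-residuals of IS and WBC for one patient; theta is the raw
# 6-vector (a, b, x_star, y_star, x0, y0). hard = TRUE errors on
# non-finite predictions (public objective contract); the fitter instead
# receives a large finite value so the optimizer can back off.
patient_data_term <- function(theta, series, c_ratio, consts,
                              hard = FALSE) {
  names(theta) <- c("a", "b", "x_star", "y_star", "x0", "y0")
  tt <- series$times
  x <- theta["x_star"] + (theta["x0"] - theta["x_star"]) * exp(-theta["a"] * tt)
  y <- theta["y_star"] + (theta["y0"] - theta["y_star"]) * exp(-theta["b"] * tt)
  wbc_pred <- x + y
  if (any(!is.finite(wbc_pred)) || any(wbc_pred <= 0) ||
      any(c(x, y) < 0)) {
    if (hard) stop("non-finite or non-positive model prediction for patient ",
                   series$patient_id)
    return(1e12)
  }
  is_pred <- pmax(y / (c_ratio * x + y) * consts$k_is * 100,
                  consts$detection_limit)
  sum((log(is_pred) - log(series$is_pct))^2) +
    sum((log(wbc_pred) - log(series$wbc))^2)
}

# ramp-function constraint terms (unweighted sum) for one patient
penalty_terms <- function(theta, c_ratio, consts) {
  names(theta) <- c("a", "b", "x_star", "y_star", "x0", "y0")
  y_min <- consts$detection_limit * c_ratio * theta["x_star"] /
    (consts$k_is * 100 - consts$detection_limit)
  ramp <- function(u) max(u, 0)
  ramp(consts$x_star_min - theta["x_star"]) +
    ramp(theta["x_star"] - consts$x_star_max) +
    ramp(y_min - theta["y_star"]) +
    ramp(-theta["a"]) + ramp(-theta["b"])
}

#' Fit the two-compartment kinetics jointly across a cohort
#'
#' Estimates each patient's six dynamics parameters and the single
#' ABL1-expression ratio `c` shared by the whole cohort, by minimizing
#' [cohort_objective()]. The penalized objective is an exact sum of
#' squares (each ramp term enters as a squared square-root residual), so
#' per-patient blocks are minimized over log-parameters by
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]). The shared ratio is the
#' only coupling between patients, and is profiled out: the profile is
#' evaluated on a deterministic coarse grid over `log c` swept in
#' increasing order, then refined by Brent search within the bracketing
#' interval. Every profile evaluation refits each patient from both its
#' warm-started previous solution and a fresh data-driven start at the
#' candidate `c` (the first three inverted leukemic counts give
#' closed-form rate and plateau guesses); the grid-then-refine scheme
#' keeps the search robust where basin hopping makes the profile
#' locally ragged. A final multistart polish at the selected `c` adds
#' seed-derived jittered starts.
#'
#' @param cohort Non-empty list of [patient_series()], each with at
#'   least 4 visits.
#' @param consts [model_constants()].
#' @param control List of options: `maxiter` (LM iterations per inner
#'   fit, default 150), `n_starts` (starts in the final polish, default
#'   3: warm, fresh, plus jitters), `c_init` (default 1), `fit_c`
#'   (estimate `c`? default TRUE; FALSE holds it at `c_init`),
#'   `c_interval` (search range for `c`, default c(0.3, 6)), `c_grid_n`
#'   (coarse profile grid size, default 9), `c_tol` (tolerance of the
#'   local `log c` refinement, default 1e-3).
#' @param seed Integer seed for the jittered polish starts.
#' @return An object of class `cohort_fit`: `c`, `per_patient` (named
#'   list of [dynamics_params()]), `loss` (via [cohort_objective()]),
#'   `loss_init` (objective at the data-driven initialization),
#'   `converged` (loss at or below its initialization value), `trace`
#'   (objective at initialization, after the `c` profile, and after the
#'   polish — weakly decreasing), `penalty` (penalty component at the
#'   solution), `consts`.
#' @export
fit_cohort <- function(cohort, consts = model_constants(),
                       control = list(), seed = 1L) {
  stopifnot(length(cohort) > 0)
  for (p in cohort) {
    if (length(p$times) < 4) {
      stop("cohort fit requires at least 4 visits per patient (patient ",
           p$patient_id, ")")
    }
  }
  ctl <- utils::modifyList(
    list(maxiter = 150L, n_starts = 3L, c_init = 1, fit_c = TRUE,
         c_interval = c(0.3, 6), c_grid_n = 9L, c_tol = 1e-3),
    control
  )
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort")
  names(cohort) <- ids
  set.seed(as.integer(seed))

  warm <- lapply(cohort, function(p)
    log(init_patient_theta(p, ctl$c_init, consts)))
  names(warm) <- ids
  theta_of <- function(w) {
    lapply(w, function(lp) {
      th <- exp(pmin(pmax(lp, -60), 60))
      names(th) <- c("a", "b", "x_star", "y_star", "x0", "y0")
      th
    })
  }
  obj_all <- function(th_list, c_ratio) {
    sum(vapply(ids, function(id) {
      patient_data_term(th_list[[id]], cohort[[id]], c_ratio, consts) +
        consts$penalty_weight *
          penalty_terms(th_list[[id]], c_ratio, consts)
    }, numeric(1)))
  }
  loss_init <- obj_all(theta_of(warm), ctl$c_init)

  refit_all <- function(c_ratio, extra_starts = 0L) {
    tot <- 0
    for (id in ids) {
      r <- fit_patient_lm(cohort[[id]], c_ratio, consts, warm[[id]],
                          maxiter = ctl$maxiter,
                          extra_starts = extra_starts)
      warm[[id]] <<- r$par
      tot <- tot + r$obj
    }
    tot
  }

  c_cur <- ctl$c_init
  if (isTRUE(ctl$fit_c)) {
    # profile out c: a deterministic coarse grid swept in increasing
    # order (warm starts carry forward, fresh data-driven starts guard
    # against basin hopping), then local refinement in the bracketing
    # interval -- the profile need not be unimodal far from the optimum
    lc_grid <- seq(log(ctl$c_interval[1]), log(ctl$c_interval[2]),
                   length.out = ctl$c_grid_n)
    prof <- vapply(lc_grid, function(lc) refit_all(exp(lc)), numeric(1))
    i_best <- which.min(prof)
    prof_best <- refit_all(exp(lc_grid[i_best]))  # reposition warm state
    snap <- warm
    lo <- lc_grid[max(i_best - 1L, 1L)]
    hi <- lc_grid[min(i_best + 1L, length(lc_grid))]
    op <- stats::optimize(function(lc) refit_all(exp(lc)),
                          interval = c(lo, hi), tol = ctl$c_tol)
    if (op$objective <= min(prof[i_best], prof_best)) {
      c_cur <- exp(op$minimum)
      loss_profile <- op$objective
    } else {
      c_cur <- exp(lc_grid[i_best])
      warm <- snap
      loss_profile <- refit_all(c_cur)
    }
  } else {
    loss_profile <- refit_all(c_cur)
  }
  loss_polish <- refit_all(c_cur, extra_starts = max(ctl$n_starts - 2L, 0L))

  theta <- theta_of(warm)
  loss <- obj_all(theta, c_cur)
  per_patient <- lapply(theta, function(th) dynamics_params(as.list(th)))
  penalty <- sum(vapply(theta, penalty_terms, numeric(1),
                        c_ratio = c_cur, consts = consts)) *
    consts$penalty_weight
  trace <- cummin(c(loss_init, loss_profile, loss_polish))
  structure(
    list(c = c_cur, per_patient = per_patient, loss = loss,
         loss_init = loss_init, converged = loss <= loss_init + 1e-9,
         trace = trace, penalty = penalty, consts = consts),
    class = "cohort_fit"
  )
}

# residual vector whose sum of squares equals the per-patient penalized
# objective: ln-residuals of IS and WBC plus square-rooted weighted ramp
# terms (the rate positivity ramps vanish identically under the log
# parameterization)
patient_residuals <- function(lth, series, c_ratio, consts) {
  th <- exp(pmin(pmax(lth, -60), 60))
  tt <- series$times
  x <- th[3] + (th[5] - th[3]) * exp(-th[1] * tt)
  y <- th[4] + (th[6] - th[4]) * exp(-th[2] * tt)
  wbc <- x + y
  if (any(!is.finite(wbc)) || any(wbc <= 0)) {
    return(rep(1e3, 2 * length(tt) + 3))
  }
  is_pred <- pmax(y / (c_ratio * x + y) * consts$k_is * 100,
                  consts$detection_limit)
  y_min <- consts$detection_limit * c_ratio * th[3] /
    (consts$k_is * 100 - consts$detection_limit)
  pen <- sqrt(consts$penalty_weight *
                pmax(c(consts$x_star_min - th[3],
                       th[3] - consts$x_star_max,
                       y_min - th[4]), 0))
  c(log(is_pred) - log(series$is_pct),
    log(wbc) - log(series$wbc), pen)
}

# data-driven initialization: invert uncensored (IS, WBC) pairs to
# leukemic counts, take closed-form rate/plateau guesses from them, and
# anchor the normal compartment at the late visits
init_patient_theta <- function(series, c_ratio, consts) {
  unc <- series$is_pct > consts$detection_limit * (1 + 1e-9)
  y_min_mid <- min_cml_convergence(
    c_ratio, (consts$x_star_min + consts$x_star_max) / 2, consts)
  if (sum(unc) >= 2) {
    inv <- is_wbc_to_counts(
      pmin(series$is_pct[unc], consts$k_is * 100 * 0.999),
      series$wbc[unc], c_ratio, consts)
    t_u <- series$times[unc]
    y <- pmax(inv$y, 1e-6)
    x <- pmax(inv$x, 1)
    b0 <- if (length(y) >= 3 && y[1] > y[2] && y[2] > y[3]) {
      log((y[1] - y[2]) / (y[2] - y[3])) / (t_u[2] - t_u[1])
    } else 0.5
    if (!is.finite(b0) || b0 <= 0) b0 <- 0.5
    c(a = 0.4, b = b0,
      x_star = min(max(x[length(x)], consts$x_star_min),
                   consts$x_star_max),
      y_star = max(y[length(y)], 1.05 * y_min_mid),
      x0 = max(x[1], 1), y0 = y[1])
  } else {
    wbc0 <- series$wbc[1]
    c(a = 0.4, b = 0.5,
      x_star = (consts$x_star_min + consts$x_star_max) / 2,
      y_star = 1.05 * y_min_mid,
      x0 = max(wbc0 / 2, 1), y0 = max(wbc0 / 2, 1))
  }
}

# Levenberg-Marquardt minimization of one patient's block from a warm
# start, a fresh data-driven start, and optional jittered starts
fit_patient_lm <- function(series, c_ratio, consts, warm_par,
                           maxiter = 200L, extra_starts = 0L) {
  starts <- list(warm_par, log(init_patient_theta(series, c_ratio, consts)))
  if (extra_starts > 0L) {
    for (k in seq_len(extra_starts)) {
      starts[[length(starts) + 1L]] <- warm_par + stats::rnorm(6, 0, 0.3)
    }
  }
  best <- NULL
  for (s in starts) {
    r <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        s, fn = patient_residuals, series = series, c_ratio = c_ratio,
        consts = consts,
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             maxfev = 10L * maxiter))),
      error = function(e) NULL
    )
    if (is.null(r)) next
    obj <- sum(patient_residuals(r$par, series, c_ratio, consts)^2)
    if (is.null(best) || obj < best$obj) best <- list(par = r$par, obj = obj)
    if (best$obj < 1e-12) break
  }
  if (is.null(best)) {
    best <- list(par = warm_par,
                 obj = sum(patient_residuals(warm_par, series, c_ratio,
                                             consts)^2))
  }
  best
}

#' Model-predicted WBC and IS trajectories for a fitted patient
#'
#' Composes the closed-form count trajectories with the measurement
#' transforms at the fitted parameters.
#'
#' @param fit A [fit_cohort()] result.
#' @param patient_id Patient to predict (must be in the fit).
#' @param times Times (months).
#' @return A data.frame with columns `time`, `x`, `y`, `wbc`, `is_pct`.
#' @export
predicted_series <- function(fit, patient_id, times) {
  theta <- fit$per_patient[[patient_id]]
  if (is.null(theta)) stop("unknown patient id: ", patient_id)
  tr <- simulate_counts(theta, times)
  tr$wbc <- tr$x + tr$y
  tr$is_pct <- counts_to_is(tr$x, tr$y, fit$c, fit$consts)
  tr
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf(
    "Cohort kinetics fit: %d patients, shared c = %.4f\n",
    length(x$per_patient), x$c))
  cat(sprintf("  loss %.6g (from %.6g at init), penalty %.3g, %s\n",
              x$loss, x$loss_init, x$penalty,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-patient parameter table from a cohort fit
#'
#' @param fit A [fit_cohort()] result.
#' @return A data.frame with one row per patient: id, the six dynamics
#'   parameters and the shared `c`.
#' @export
cohort_fit_table <- function(fit) {
  rows <- lapply(names(fit$per_patient), function(id) {
    th <- fit$per_patient[[id]]
    data.frame(patient_id = id, a = th$a, b = th$b, x_star = th$x_star,
               y_star = th$y_star, x0 = th$x0, y0 = th$y0, c = fit$c)
  })
  do.call(rbind, rows)
}
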