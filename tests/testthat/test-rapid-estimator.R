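consts <- model_constants()
crit45 <- response_criterion("MR4.5")

triple_series <- function(y_points, x = 6000, c_ratio = 1) {
  # build a series whose inversion returns exactly y_points
  isv <- counts_to_is(rep(x, 3), y_points, c_ratio, consts)
  patient_series("t", c(0, 3, 6), rep(x, 3) + y_points, isv)
}

test_that("closed forms recover plateau and rate from model triples", {
  # y(t) = 100 + 9900 exp(-0.5 t)
  th <- list(a = 1, b = 0.5, x_star = 6000, y_star = 100,
             x0 = 6000, y0 = 10000)
  tr <- simulate_counts(th, c(0, 3, 6))
  p <- patient_series("e", c(0, 3, 6), tr$x + tr$y,
                      counts_to_is(tr$x, tr$y, 1.5, consts))
  est <- estimate_from_three_points(p, 1.5, crit45, consts)
  expect_true(est$valid)
  expect_false(est$early_dmr)
  expect_rel_equal(est$y_star_hat, 100, tol = 1e-9)
  expect_rel_equal(est$b_hat, 0.5, tol = 1e-10)

  # geometric decay to zero: numerator cancels exactly
  est2 <- estimate_from_three_points(
    triple_series(c(8000, 4000, 2000)), 1, crit45, consts)
  expect_equal(est2$y_star_hat, 0)
  expect_rel_equal(est2$b_hat, log(2) / 3, tol = 1e-12)
})

test_that("exactness holds across randomized study-condition draws", {
  cfg <- default_paper_like_config()
  set.seed(42)
  n_checked <- 0
  for (k in 1:500) {
    dmr <- k %% 2 == 0
    br <- if (dmr) cfg$b_range_dmr else cfg$b_range_nondmr
    yr <- if (dmr) cfg$y_star_range_dmr else cfg$y_star_range_nondmr
    th <- list(a = runif(1, 0.2, 1), b = runif(1, br[1], br[2]),
               x_star = runif(1, 3100, 9800),
               y_star = exp(runif(1, log(yr[1]), log(yr[2]))),
               x0 = runif(1, 1e3, 4e3), y0 = runif(1, 2e4, 1e5))
    tr <- simulate_counts(th, c(0, 3, 6))
    isv <- counts_to_is(tr$x, tr$y, cfg$c_true, consts)
    if (any(isv <= consts$detection_limit)) next
    p <- patient_series("x", c(0, 3, 6), tr$x + tr$y, isv)
    est <- estimate_from_three_points(p, cfg$c_true, crit45, consts)
    expect_true(est$valid)
    if (est$early_dmr) next
    n_checked <- n_checked + 1
    expect_rel_equal(est$b_hat, th$b, tol = 1e-10)
    # plateau error measured on the data scale: recovering a plateau
    # orders of magnitude below the counts is conditioning-limited
    expect_lt(abs(est$y_star_raw - th$y_star) / th$y0, 1e-10)
  }
  expect_gt(n_checked, 300)
})

test_that("scaling equivariance: counts scale the plateau, not the rate", {
  set.seed(7)
  for (k in 1:20) {
    y3 <- 5e4 * exp(-0.4 * c(0, 3, 6)) + 300
    lam <- runif(1, 0.1, 10)
    e1 <- estimate_from_three_points(triple_series(y3), 1, crit45, consts)
    e2 <- estimate_from_three_points(triple_series(lam * y3), 1, crit45,
                                     consts)
    expect_rel_equal(e2$y_star_hat, lam * e1$y_star_hat, tol = 1e-6)
    expect_rel_equal(e2$b_hat, e1$b_hat, tol = 1e-6)
  }
})

test_that("early responders short-circuit the closed forms", {
  p <- patient_series("e", c(0, 3, 6), rep(6000, 3), c(50, 0.0032, 0.5))
  est <- estimate_from_three_points(p, 1, crit45, consts)
  expect_true(est$early_dmr)
  expect_true(est$valid)
  expect_true(is.na(est$b_hat))
  # MR4.0 triggers at its looser threshold
  p2 <- patient_series("e2", c(0, 3, 6), rep(6000, 3), c(50, 0.01, 0.5))
  expect_true(estimate_from_three_points(
    p2, 1, response_criterion("MR4.0"), consts)$early_dmr)
  expect_false(estimate_from_three_points(
    p2, 1, crit45, consts)$early_dmr)
})

test_that("CMR early rule needs two consecutive floor visits", {
  floorv <- consts$detection_limit
  critc <- response_criterion("CMR")
  p_cons <- patient_series("c1", c(0, 3, 6), rep(6000, 3),
                           c(50, floorv, floorv))
  expect_true(estimate_from_three_points(p_cons, 1, critc, consts)$early_dmr)
  p_single <- patient_series("c2", c(0, 3, 6), rep(6000, 3),
                             c(50, floorv, 0.5))
  est <- estimate_from_three_points(p_single, 1, critc, consts)
  expect_false(est$early_dmr)
  expect_false(est$valid)
  expect_identical(est$reason, "censored_point")
})

test_that("degenerate triples are flagged, not thrown", {
  # constant counts: zero curvature denominator
  e1 <- estimate_from_three_points(triple_series(rep(4000, 3)), 1,
                                   crit45, consts)
  expect_false(e1$valid)
  expect_identical(e1$reason, "zero_denominator")
  # rising counts
  e2 <- estimate_from_three_points(triple_series(c(2000, 4000, 8000)), 1,
                                   crit45, consts)
  expect_false(e2$valid)
  expect_identical(e2$reason, "non_monotone")
  # oscillating
  e3 <- estimate_from_three_points(triple_series(c(4000, 2000, 3000)), 1,
                                   crit45, consts)
  expect_false(e3$valid)
})

test_that("negative raw plateaus are floored at zero", {
  # super-exponential decline: y* estimate goes negative
  e <- estimate_from_three_points(triple_series(c(8000, 2000, 200)), 1,
                                  crit45, consts)
  expect_true(e$valid)
  expect_lt(e$y_star_raw, 0)
  expect_identical(e$y_star_hat, 0)
})

test_that("three-point estimates agree with the full cohort fit when noiseless", {
  d <- make_detectable_cohort(n = 5, seed = 23)
  fit <- fit_cohort(d$cohort, control = list(c_init = d$c, fit_c = FALSE),
                    seed = 2)
  for (i in seq_along(d$cohort)) {
    est <- estimate_from_three_points(d$cohort[[i]], d$c, crit45, consts)
    if (!est$valid || est$early_dmr) next
    th <- fit$per_patient[[d$cohort[[i]]$patient_id]]
    expect_rel_equal(est$b_hat, th$b, tol = 1e-2)
    expect_rel_equal(est$b_hat, d$thetas[[i]]$b, tol = 1e-8)
  }
})
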