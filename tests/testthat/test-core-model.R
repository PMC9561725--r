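consts <- model_constants()

test_that("closed-form trajectories satisfy the kinetics", {
  # fixed point: starting at the plateau stays there
  th <- dynamics_params(list(a = 0.7, b = 0.3, x_star = 6000,
                             y_star = 100, x0 = 6000, y0 = 100))
  tr <- simulate_counts(th, c(0, 1, 5, 24))
  expect_equal(tr$x, rep(6000, 4))
  expect_equal(tr$y, rep(100, 4))

  # frozen closed-form values for an exponential decline
  th2 <- dynamics_params(list(a = 1, b = 0.5, x_star = 5000,
                              y_star = 100, x0 = 5000, y0 = 10000))
  tr2 <- simulate_counts(th2, c(0, 3, 6))
  expect_equal(tr2$y[1], 10000)           # initial condition exact
  expect_rel_equal(tr2$y[2], 100 + 9900 * exp(-1.5), tol = 1e-12)
  expect_rel_equal(tr2$y[3], 100 + 9900 * exp(-3), tol = 1e-12)
  expect_equal(round(tr2$y[2:3], 2), c(2308.99, 592.89))
})

test_that("trajectories agree with a numerical integrator", {
  skip_if_not_installed("deSolve")
  set.seed(4)
  for (k in 1:20) {
    th <- dynamics_params(list(
      a = runif(1, 0.05, 2), b = runif(1, 0.05, 2),
      x_star = runif(1, 3100, 9800), y_star = runif(1, 0, 500),
      x0 = runif(1, 500, 5000), y0 = runif(1, 1e4, 1e5)
    ))
    times <- seq(0, 24, by = 3)
    num <- deSolve::ode(
      y = c(x = th$x0, y = th$y0), times = times,
      func = function(t, s, p) {
        list(c(p$a * (p$x_star - s["x"]), p$b * (p$y_star - s["y"])))
      },
      parms = th, method = "lsoda", rtol = 1e-12, atol = 1e-10
    )
    cf <- simulate_counts(th, times)
    expect_lt(max(abs(cf$x - num[, "x"]) / pmax(num[, "x"], 1)), 1e-8)
    expect_lt(max(abs(cf$y - num[, "y"]) / pmax(num[, "y"], 1)), 1e-8)
  }
})

test_that("counts map to IS per the measurement model", {
  expect_equal(counts_to_is(9000, 1000, 1, consts), 12)
  # no leukemic cells: clamped at the detection floor
  expect_equal(counts_to_is(9000, 0, 1, consts), consts$detection_limit)
  # pure leukemic: IS saturates at the scale maximum
  expect_equal(counts_to_is(0, 5000, 1, consts), 120)
  expect_error(counts_to_is(0, 0, 1, consts), "positive")
})

test_that("IS/WBC inversion is the exact inverse above the floor", {
  inv <- is_wbc_to_counts(12, 10000, 1, consts)
  expect_equal(inv$y, 1000)
  expect_equal(inv$x, 9000)
  # saturated IS means a purely leukemic sample
  inv2 <- is_wbc_to_counts(120 - 1e-9, 8000, 1, consts)
  expect_rel_equal(inv2$y, 8000, tol = 1e-9)
  expect_lt(abs(inv2$x), 1e-3)
  expect_error(is_wbc_to_counts(consts$detection_limit, 8000, 1, consts),
               "detection limit")

  # round-trip property over randomized uncensored inputs
  set.seed(9)
  for (k in 1:200) {
    x <- runif(1, 100, 10000); y <- runif(1, 1, 5e4)
    cc <- runif(1, 0.3, 4)
    isv <- counts_to_is(x, y, cc, consts)
    if (isv <= consts$detection_limit || isv >= 120) next
    back <- is_wbc_to_counts(isv, x + y, cc, consts)
    expect_rel_equal(back$x, x, tol = 1e-9)
    expect_rel_equal(back$y, y, tol = 1e-9)
  }
})

test_that("detectability bound solves its defining equation", {
  expect_rel_equal(min_cml_convergence(1, 9000, consts),
                   0.0032 * 9000 / (120 - 0.0032), tol = 1e-12)
  set.seed(3)
  for (k in 1:50) {
    cc <- runif(1, 0.2, 5); xs <- runif(1, 1000, 12000)
    ym <- min_cml_convergence(cc, xs, consts)
    expect_rel_equal(counts_to_is(xs, ym, cc, consts),
                     consts$detection_limit, tol = 1e-12)
  }
  # vanishing detection limit => vanishing bound (linear in d)
  tiny <- model_constants(detection_limit = 1e-15)
  expect_lt(min_cml_convergence(1, 9000, tiny), 1e-10)
})

test_that("response labels follow the thresholds and stick", {
  mk <- function(isv) patient_series("p", seq(0, 24, by = 3),
                                     rep(6000, 9), isv)
  # dips to the floor at month 12, fluctuates back up: label sticks
  isv <- c(80, 10, 1, 0.1, 0.0032, 0.05, 0.1, 0.2, 0.3)
  expect_true(label_response(mk(isv), response_criterion("MR4.5")))
  # minimum 0.004: below MR4.0 threshold, above MR4.5
  isv2 <- c(80, 10, 1, 0.1, 0.01, 0.004, 0.004, 0.005, 0.006)
  expect_false(label_response(mk(isv2), response_criterion("MR4.5")))
  expect_true(label_response(mk(isv2), response_criterion("MR4.0")))
  # horizon restricts which visits count
  expect_false(label_response(mk(isv), response_criterion("MR4.5"),
                              horizon_months = 9))

  # CMR needs the floor at both late visits
  isv3 <- c(80, 10, 1, 0.1, 0.01, 0.0032, 0.0032, 0.0032, 0.01)
  expect_false(label_response(mk(isv3), response_criterion("CMR")))
  isv4 <- c(80, 10, 1, 0.1, 0.01, 0.0032, 0.0032, 0.0032, 0.0032)
  expect_true(label_response(mk(isv4), response_criterion("CMR")))
  short <- patient_series("q", c(0, 3, 6), rep(6000, 3), c(80, 10, 1))
  expect_error(label_response(short, response_criterion("CMR")), "21")
})

test_that("MR4.5 response implies MR4.0 response (threshold monotonicity)", {
  set.seed(21)
  n_deep <- 0
  for (k in 1:50) {
    isv <- pmax(10^runif(9, -3, 2), 0.0032)
    p <- patient_series("m", seq(0, 24, by = 3), rep(6000, 9), isv)
    mr45 <- label_response(p, response_criterion("MR4.5"))
    mr40 <- label_response(p, response_criterion("MR4.0"))
    expect_true(!mr45 || mr40)
    n_deep <- n_deep + mr45
  }
  expect_gt(n_deep, 5)  # the draw exercises both branches
})

test_that("eligibility filtering requires the complete grid", {
  full <- make_model_patient("full", list(a = .5, b = .5, x_star = 6000,
                                          y_star = 10, x0 = 2000,
                                          y0 = 5e4), 1)
  gappy <- patient_series("gap", c(0, 3, 6, 12, 15, 18, 21, 24),
                          rep(6000, 8), rep(1, 8))
  kept <- filter_eligible(list(full, gappy), seq(0, 24, by = 3))
  expect_length(kept, 1)
  expect_identical(kept[[1]]$patient_id, "full")
  expect_length(filter_eligible(list(), seq(0, 24, by = 3)), 0)
})

test_that("series validation rejects malformed input", {
  expect_error(patient_series("p", c(0, 3, 3), rep(1, 3), rep(1, 3)),
               "increasing")
  expect_error(patient_series("p", c(0, 3), c(1, -1), c(1, 1)),
               "positive")
  expect_error(patient_series("p", c(0, 3), c(1, 1), c(0.001, 1)),
               "floor")
  expect_error(patient_series("p", c(0, 3), c(1, 1), c(150, 1)),
               "maximum")
})
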