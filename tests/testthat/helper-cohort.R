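# shared fixtures built in code: noiseless patients generated straight
# from the forward model, and small class-structured cohorts

make_model_patient <- function(id, theta, c_ratio,
                               times = seq(0, 24, by = 3),
                               consts = model_constants(),
                               baseline = NULL) {
  tr <- simulate_counts(theta, times)
  patient_series(id, times, tr$x + tr$y,
                 counts_to_is(tr$x, tr$y, c_ratio, consts),
                 baseline = baseline, consts = consts)
}

# cohort with every leukemic plateau detectable (no clamped visits), so
# the penalized fit can reach zero data loss and all parameters are
# identifiable
make_detectable_cohort <- function(n = 6, c_ratio = 1.5, seed = 11,
                                   times = seq(0, 24, by = 3)) {
  set.seed(seed)
  thetas <- lapply(seq_len(n), function(i) {
    list(a = runif(1, 0.2, 1), b = runif(1, 0.1, 1.2),
         x_star = runif(1, 3500, 9500),
         y_star = exp(runif(1, log(0.5), log(80))),
         x0 = runif(1, 1000, 4000), y0 = runif(1, 2e4, 1e5))
  })
  cohort <- lapply(seq_len(n), function(i) {
    make_model_patient(sprintf("D%02d", i), thetas[[i]], c_ratio, times)
  })
  list(cohort = cohort, thetas = thetas, c = c_ratio)
}

# rapid-estimate stubs for classifier tests
stub_estimate <- function(y_star, b, early = FALSE, valid = TRUE) {
  list(y_star_hat = y_star, b_hat = b, early_dmr = early, valid = valid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
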