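test_that("region membership is inclusive and short-circuits correctly", {
  thr <- list(Y = 1, B = 0.5)
  expect_true(predict_label(stub_estimate(0, 1), thr))
  # boundary included on both coordinates
  expect_true(predict_label(stub_estimate(1, 0.5), thr))
  expect_false(predict_label(stub_estimate(1.0001, 0.5), thr))
  expect_false(predict_label(stub_estimate(1, 0.4999), thr))
  # early response overrides everything
  expect_true(predict_label(stub_estimate(NA, NA, early = TRUE), thr))
  # invalid estimate is a conservative negative
  expect_false(predict_label(stub_estimate(0, 1, valid = FALSE), thr))
})

test_that("region prediction is monotone in the thresholds", {
  set.seed(19)
  for (k in 1:100) {
    est <- stub_estimate(10^runif(1, -2, 3), runif(1, 0, 2))
    Y <- 10^runif(1, -2, 3); B <- runif(1, 0, 2)
    if (predict_label(est, list(Y = Y, B = B))) {
      expect_true(predict_label(est, list(Y = Y * 2, B = B)))
      expect_true(predict_label(est, list(Y = Y, B = max(B - 0.1, 0))))
    }
  }
})

test_that("confusion metrics match their definitions", {
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  pred <- c(rep(TRUE, 9), FALSE, rep(TRUE, 3), rep(FALSE, 7))
  cm <- confusion_metrics(truth, pred)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(9, 1, 3, 7))
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.7)
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$f1, 18 / 22)
  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$sensitivity,
                 perfect$specificity, perfect$f1), rep(1, 4))
  allpos <- confusion_metrics(truth, rep(TRUE, 20))
  expect_equal(allpos$specificity, 0)
  expect_error(confusion_metrics(logical(0), logical(0)), "non-empty")
})

separable_training <- function() {
  ests <- c(
    lapply(1:6, function(i) stub_estimate(10^runif(1, -2, 0), runif(1, 0.6, 1.5))),
    lapply(1:5, function(i) stub_estimate(10^runif(1, 1, 2.5), runif(1, 0.01, 0.25)))
  )
  list(ests = ests, labels = c(rep(TRUE, 6), rep(FALSE, 5)))
}

test_that("separable training data yield perfect training accuracy", {
  set.seed(20)
  tr <- separable_training()
  for (obj in c("accuracy", "sensitivity", "specificity")) {
    thr <- optimize_thresholds(tr$ests, tr$labels, obj)
    expect_false(thr$degenerate)
    expect_equal(thr$training$accuracy, 1)
    # secondary criterion engages: class-rate objectives still separate
    expect_equal(thr$training$sensitivity, 1)
    expect_equal(thr$training$specificity, 1)
  }
})

test_that("grid search matches an independent exhaustive re-scan", {
  set.seed(22)
  for (k in 1:50) {
    n <- sample(6:14, 1)
    ests <- lapply(seq_len(n), function(i) {
      stub_estimate(10^runif(1, -2, 2.5), runif(1, 0, 1.6),
                    early = runif(1) < 0.1, valid = runif(1) > 0.1)
    })
    labels <- vapply(ests, function(e) {
      isTRUE(e$early_dmr) ||
        (isTRUE(e$valid) && e$y_star_hat < 10 && e$b_hat > 0.4) ||
        runif(1) < 0.15
    }, logical(1))
    if (length(unique(labels)) < 2) next
    obj <- sample(c("accuracy", "sensitivity", "specificity"), 1)
    thr <- optimize_thresholds(ests, labels, obj)

    # oracle: literal re-scan over the same documented grid convention
    fixed_pos <- vapply(ests, function(e) isTRUE(e$early_dmr), logical(1))
    free <- vapply(ests, function(e)
      isTRUE(e$valid) && !isTRUE(e$early_dmr), logical(1))
    ys <- vapply(ests, function(e) e$y_star_hat %||% NA_real_, numeric(1))
    bs <- vapply(ests, function(e) e$b_hat %||% NA_real_, numeric(1))
    pos_y <- ys[free & ys > 0]
    lg <- seq(floor((log10(min(pos_y)) - 0.5) * 10) / 10,
              ceiling((log10(max(pos_y)) + 0.5) * 10) / 10, by = 0.1)
    bg <- seq(0, max(bs[free]) + 0.05, by = 0.05)
    cells <- expand.grid(l = lg, B = bg)
    mets <- t(apply(cells, 1, function(cl) {
      pred <- fixed_pos | (free & ys <= 10^cl[1] & bs >= cl[2])
      c(acc = mean(pred == labels),
        sen = sum(pred & labels) / sum(labels),
        spe = sum(!pred & !labels) / sum(!labels))
    }))
    key <- c(accuracy = "acc", sensitivity = "sen", specificity = "spe")[obj]
    best <- which(mets[, key] >= max(mets[, key]) - 1e-12)
    sel <- if (obj == "accuracy") {
      ctr <- c(mean(cells$l[best]), mean(cells$B[best]))
      d2 <- (cells$l[best] - ctr[1])^2 + (cells$B[best] - ctr[2])^2
      cand <- best[d2 <= min(d2) + 1e-12]
      cand <- cand[cells$l[cand] <= min(cells$l[cand]) + 1e-12]
      cand[which.max(cells$B[cand])]
    } else if (obj == "sensitivity") {
      b2 <- best[mets[best, "spe"] >= max(mets[best, "spe"]) - 1e-12]
      cand <- b2[cells$l[b2] >= max(cells$l[b2]) - 1e-12]
      cand[which.min(cells$B[cand])]
    } else {
      b2 <- best[mets[best, "sen"] >= max(mets[best, "sen"]) - 1e-12]
      cand <- b2[cells$l[b2] <= min(cells$l[b2]) + 1e-12]
      cand[which.max(cells$B[cand])]
    }
    expect_equal(thr$log10_Y, cells$l[sel], tolerance = 1e-9)
    expect_equal(thr$B, cells$B[sel], tolerance = 1e-9)
  }
})

test_that("specificity-optimized thresholds dominate in specificity", {
  set.seed(24)
  for (k in 1:10) {
    # overlapping classes
    n <- 16
    ests <- lapply(seq_len(n), function(i) {
      stub_estimate(10^runif(1, -1, 2), runif(1, 0, 1))
    })
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2) next
    t_acc <- optimize_thresholds(ests, labels, "accuracy")
    t_spe <- optimize_thresholds(ests, labels, "specificity")
    expect_gte(t_spe$training$specificity, t_acc$training$specificity)
  }
})

test_that("single-class training sets return flagged degenerate corners", {
  ests <- list(stub_estimate(1, 0.5))
  thr <- optimize_thresholds(ests, TRUE, "accuracy")
  expect_true(thr$degenerate)
  expect_true(predict_label(stub_estimate(1, 0.5), thr))
})

test_that("LOOCV is exact bookkeeping and order-invariant", {
  g <- generate_cohort(cohort_config(n_patients = 8, noise_sigma = 0,
                                     seed = 2))
  cv <- loocv(g$cohort, seed = 3)
  # zero noise, separable classes: perfect prediction
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$accuracy, mean(cv$per_patient$correct))
  expect_equal(cv$confusion$accuracy, cv$accuracy)

  # permuting the cohort leaves aggregate metrics unchanged
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  cv2 <- loocv(g$cohort[perm], seed = 3)
  expect_equal(cv2$accuracy, cv$accuracy)
  expect_equal(sort(cv2$per_patient$patient_id),
               sort(cv$per_patient$patient_id))
})

test_that("an all-early cohort has perfect sensitivity by the short-circuit", {
  times <- seq(0, 24, by = 3)
  floorv <- model_constants()$detection_limit
  cohort <- lapply(1:4, function(i) {
    patient_series(sprintf("E%d", i), times, rep(6000, 9),
                   c(50, floorv, rep(floorv, 7)))
  })
  cv <- loocv(cohort, seed = 5)
  expect_equal(cv$confusion$sensitivity, 1)
  expect_equal(cv$accuracy, 1)
})
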