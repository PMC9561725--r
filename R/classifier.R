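#' Threshold-region response prediction
#'
#' A patient is predicted to reach deep molecular response when the
#' estimated leukemic kinetics fall in the rectangular region
#' \eqn{\{\hat y^* \le Y \;\mathrm{and}\; \hat b \ge B\}} (both
#' inequalities inclusive). Early responders short-circuit to a positive
#' prediction; estimates that could not be computed map to a negative
#' (non-response) prediction, the clinically conservative call for
#' non-declining counts.
#'
#' @param est A [estimate_from_three_points()] result (or any list with
#'   `y_star_hat`, `b_hat`, `early_dmr`, `valid`).
#' @param thr A `threshold_pair` (or list with `Y` and `B`).
#' @return Logical prediction.
#' @export
predict_label <- function(est, thr) {
  if (isTRUE(est$early_dmr)) return(TRUE)
  if (!isTRUE(est$valid)) return(FALSE)
  (est$y_star_hat <= thr$Y) && (est$b_hat >= thr$B)
}

#' Confusion matrix and derived classification metrics
#'
#' "Positive" means predicted responder (DMR).
#'
#' @param truth,predicted Logical vectors of equal positive length.
#' @return An object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `tn`, `fn` and derived `accuracy`, `sensitivity` (true positive
#'   rate), `specificity` (true negative rate) and `f1`
#'   (`2 tp / (2 tp + fp + fn)`). Rates with an empty denominator are
#'   `NaN`.
#' @export
confusion_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0) stop("confusion_metrics requires non-empty input")
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  tp <- sum(truth & predicted)
  fp <- sum(!truth & predicted)
  tn <- sum(!truth & !predicted)
  fn <- sum(truth & !predicted)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         f1 = 2 * tp / (2 * tp + fp + fn)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "  accuracy %.3f, sensitivity %.3f, specificity %.3f, F1 %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Grid-search optimization of the decision thresholds
#'
#' Exhaustively scans a rectangular grid of candidate thresholds and
#' returns the pair maximizing the requested training objective. The
#' plateau threshold `Y` is scanned on the log10 scale with step 0.1
#' (spanning the positive training estimates plus half a decade each
#' side); the rate threshold `B` on the raw 1/month scale with step 0.05
#' from 0 to just above the largest training rate. Early responders count
#' as fixed positives and non-computable estimates as fixed negatives at
#' every grid cell.
#'
#' Tie-breaking among maximizers follows the objective:
#' \describe{
#'   \item{accuracy}{the pair closest (Euclidean, in the (log10 Y, B)
#'     plane) to the mean of all maximizers; residual ties go to smaller
#'     Y then larger B.}
#'   \item{sensitivity}{restrict to maximal specificity, then take the
#'     largest Y and, among those, the smallest B (the widest region that
#'     still rejects best).}
#'   \item{specificity}{restrict to maximal sensitivity, then the
#'     smallest Y and, among those, the largest B (the tightest region
#'     that still accepts best).}
#' }
#'
#' @param estimates List of [estimate_from_three_points()]-like objects
#'   (training patients).
#' @param labels Logical vector of true response labels, same length.
#' @param objective `"accuracy"`, `"sensitivity"` or `"specificity"`.
#' @return An object of class `threshold_pair`: `Y` (raw cells/ul scale),
#'   `log10_Y`, `B` (1/month), `objective`, `training` (the
#'   [confusion_metrics()] at the chosen pair), and `degenerate` (TRUE
#'   when the training set had a single class or no free estimates, in
#'   which case the returned corner is flagged rather than meaningful).
#' @export
optimize_thresholds <- function(estimates, labels,
                                objective = c("accuracy", "sensitivity",
                                              "specificity")) {
  objective <- match.arg(objective)
  stopifnot(length(estimates) == length(labels), length(labels) > 0)
  labels <- as.logical(labels)

  fixed_pos <- vapply(estimates, function(e) isTRUE(e$early_dmr), logical(1))
  invalid <- vapply(estimates, function(e)
    !isTRUE(e$valid) && !isTRUE(e$early_dmr), logical(1))
  free <- !fixed_pos & !invalid
  ys <- vapply(estimates, function(e)
    if (is.null(e$y_star_hat) || is.na(e$y_star_hat)) NA_real_
    else e$y_star_hat, numeric(1))
  bs <- vapply(estimates, function(e)
    if (is.null(e$b_hat) || is.na(e$b_hat)) NA_real_ else e$b_hat,
    numeric(1))

  pos_y <- ys[free & !is.na(ys) & ys > 0]
  log_y_grid <- if (length(pos_y) > 0) {
    seq(floor((log10(min(pos_y)) - 0.5) * 10) / 10,
        ceiling((log10(max(pos_y)) + 0.5) * 10) / 10, by = 0.1)
  } else {
    seq(-1, 1, by = 0.1)
  }
  b_max <- if (any(free & is.finite(bs))) max(bs[free], na.rm = TRUE) else 1
  b_grid <- seq(0, max(b_max, 0) + 0.05, by = 0.05)

  grid <- expand.grid(log10_Y = log_y_grid, B = b_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  metr <- vapply(seq_len(nrow(grid)), function(k) {
    Y <- 10^grid$log10_Y[k]
    B <- grid$B[k]
    pred <- fixed_pos | (free & !is.na(ys) & !is.na(bs) &
                           ys <= Y & bs >= B)
    tp <- sum(labels & pred); tn <- sum(!labels & !pred)
    c(accuracy = (tp + tn) / length(labels),
      sensitivity = if (n_pos > 0) tp / n_pos else NaN,
      specificity = if (n_neg > 0) tn / n_neg else NaN)
  }, numeric(3))

  degenerate <- n_pos == 0 || n_neg == 0 || !any(free)
  score <- metr[objective, ]
  if (all(is.nan(score))) {
    # single-class training set under a class-rate objective: fall back
    # to the corner accepting everything (no negatives) or nothing
    idx <- if (n_neg == 0) {
      which(grid$log10_Y == max(log_y_grid) & grid$B == 0)
    } else {
      which(grid$log10_Y == min(log_y_grid) & grid$B == max(b_grid))
    }
  } else {
    best <- which(score >= max(score, na.rm = TRUE) - 1e-12)
    idx <- switch(
      objective,
      accuracy = {
        ctr <- c(mean(grid$log10_Y[best]), mean(grid$B[best]))
        d2 <- (grid$log10_Y[best] - ctr[1])^2 + (grid$B[best] - ctr[2])^2
        cand <- best[d2 <= min(d2) + 1e-12]
        cand <- cand[grid$log10_Y[cand] <= min(grid$log10_Y[cand]) + 1e-12]
        cand[which.max(grid$B[cand])]
      },
      sensitivity = {
        sec <- metr["specificity", best]
        if (!all(is.nan(sec))) {
          best <- best[sec >= max(sec, na.rm = TRUE) - 1e-12]
        }
        cand <- best[grid$log10_Y[best] >= max(grid$log10_Y[best]) - 1e-12]
        cand[which.min(grid$B[cand])]
      },
      specificity = {
        sec <- metr["sensitivity", best]
        if (!all(is.nan(sec))) {
          best <- best[sec >= max(sec, na.rm = TRUE) - 1e-12]
        }
        cand <- best[grid$log10_Y[best] <= min(grid$log10_Y[best]) + 1e-12]
        cand[which.max(grid$B[cand])]
      }
    )
  }

  Y <- 10^grid$log10_Y[idx]
  B <- grid$B[idx]
  thr <- structure(list(Y = Y, log10_Y = grid$log10_Y[idx], B = B,
                        objective = objective, degenerate = degenerate),
                   class = "threshold_pair")
  pred <- vapply(estimates, predict_label, logical(1), thr = thr)
  thr$training <- confusion_metrics(labels, pred)
  thr
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(
    "Thresholds (%s-optimized): Y = %.4g cells/ul (log10 %.2f), B = %.2f /month%s\n",
    x$objective, x$Y, x$log10_Y, x$B,
    if (isTRUE(x$degenerate)) " [degenerate training set]" else ""))
  invisible(x)
}

# wrap a cohort fit's per-patient (y*, b) as classifier estimates,
# applying the early-response short-circuit from each patient's first
# three visits
training_estimates <- function(fit, cohort, criterion, consts) {
  lapply(cohort, function(p) {
    is3 <- p$is_pct[1:3]
    early <- if (criterion$name == "CMR") {
      any(is3[1:2] <= criterion$is_threshold &
            is3[2:3] <= criterion$is_threshold)
    } else {
      any(is3 <= criterion$is_threshold)
    }
    th <- fit$per_patient[[p$patient_id]]
    list(patient_id = p$patient_id, y_star_hat = th$y_star, b_hat = th$b,
         early_dmr = early, valid = TRUE)
  })
}

#' Leave-one-out cross-validated response prediction
#'
#' For each patient in turn: the remaining patients form the training
#' set; the cohort kinetics are fitted on it (yielding the shared ratio
#' `c` and each training patient's full-series plateau and reduction
#' rate); the decision thresholds are optimized on those training
#' estimates; and the held-out patient is then predicted from only its
#' first three visits via the closed-form estimator. The aggregate
#' accuracy is the mean of the per-patient correctness scores; pooled
#' sensitivity, specificity and F1 are reported alongside.
#'
#' @param cohort List of [patient_series()] (>= 3 patients, complete
#'   series).
#' @param criterion A [response_criterion()].
#' @param objective Threshold-training objective (see
#'   [optimize_thresholds()]).
#' @param consts [model_constants()].
#' @param control Passed to [fit_cohort()].
#' @param seed Integer; fold f uses seed + f for its fit so the whole
#'   procedure is reproducible.
#' @return An object of class `loocv_result`: `per_patient` data.frame
#'   (`patient_id`, `truth`, `predicted`, `correct`, `c`, `Y`, `B`,
#'   `fit_converged`), `confusion` ([confusion_metrics()] over the pooled
#'   predictions), and `accuracy` (mean correctness, identical to
#'   `confusion$accuracy`).
#' @export
loocv <- function(cohort, criterion = response_criterion("MR4.5"),
                  objective = "accuracy", consts = model_constants(),
                  control = list(), seed = 1L) {
  n <- length(cohort)
  stopifnot(n >= 3)
  truth <- vapply(cohort, label_response, logical(1), criterion = criterion)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- cohort[-i]
    fit <- fit_cohort(train, consts = consts, control = control,
                      seed = as.integer(seed) + i)
    ests <- training_estimates(fit, train, criterion, consts)
    thr <- optimize_thresholds(ests, truth[-i], objective = objective)
    est_i <- estimate_from_three_points(cohort[[i]], fit$c, criterion,
                                        consts)
    pred <- predict_label(est_i, thr)
    rows[[i]] <- data.frame(
      patient_id = cohort[[i]]$patient_id, truth = truth[i],
      predicted = pred, correct = as.integer(pred == truth[i]),
      c = fit$c, Y = thr$Y, B = thr$B, fit_converged = fit$converged
    )
  }
  per_patient <- do.call(rbind, rows)
  confusion <- confusion_metrics(per_patient$truth, per_patient$predicted)
  structure(
    list(per_patient = per_patient, confusion = confusion,
         accuracy = mean(per_patient$correct), criterion = criterion$name,
         objective = objective),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV (%s, %s-optimized thresholds): accuracy %.3f over %d patients\n",
    x$criterion, x$objective, x$accuracy, nrow(x$per_patient)))
  print(x$confusion)
  invisible(x)
}
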