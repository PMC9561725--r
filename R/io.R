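#' Read a cohort from a long-format CSV
#'
#' Expects columns `patient_id`, `time_months`, `wbc_per_ul`, `is_pct`
#' (one row per measurement, header required). Rows are grouped by
#' patient and sorted by time; validation failures name the offending
#' patient and rows. IS values below the detection floor are rejected:
#' censored measurements must be recorded at the floor value itself.
#'
#' @param path CSV file path.
#' @param baseline Optional data.frame of baseline features with columns
#'   `patient_id`, `age_years`, `spleen_cm`, `basophil_pct`, `blast_pct`,
#'   `platelet_count` (e.g. from [read_baseline()]); matched by id.
#' @param consts [model_constants()].
#' @return List of [patient_series()], ordered by first appearance.
#' @export
read_cohort <- function(path, baseline = NULL,
                        consts = model_constants()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "wbc_per_ul", "is_pct")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  }
  for (col in c("time_months", "wbc_per_ul", "is_pct")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0 || anyNA(df[[col]])) {
      stop("non-numeric or missing ", col, " at data row(s) ",
           paste(utils::head(c(bad, which(is.na(df[[col]]))), 5),
                 collapse = ", "))
    }
    df[[col]] <- v
  }
  dup <- duplicated(df[c("patient_id", "time_months")])
  if (any(dup)) {
    k <- which(dup)[1]
    stop("duplicate measurement for patient ", df$patient_id[k],
         " at month ", df$time_months[k])
  }
  low <- df$is_pct < consts$detection_limit - 1e-12
  if (any(low)) {
    k <- which(low)[1]
    stop("IS value ", df$is_pct[k], " for patient ", df$patient_id[k],
         " is below the reporting floor (", consts$detection_limit, "%)")
  }
  ids <- unique(df$patient_id)
  lapply(ids, function(id) {
    sub <- df[df$patient_id == id, ]
    sub <- sub[order(sub$time_months), ]
    bl <- NULL
    if (!is.null(baseline)) {
      row <- baseline[baseline$patient_id == id, ]
      if (nrow(row) == 1) {
        bl <- clinical_baseline(
          age_years = row$age_years, spleen_cm = row$spleen_cm,
          basophil_pct = row$basophil_pct, blast_pct = row$blast_pct,
          platelet_count = row$platelet_count
        )
      }
    }
    patient_series(as.character(id), sub$time_months, sub$wbc_per_ul,
                   sub$is_pct, baseline = bl, consts = consts)
  })
}

#' Write a cohort to the long-format CSV
#'
#' Inverse of [read_cohort()]; the round trip is lossless for times,
#' WBC and IS values.
#'
#' @param cohort List of [patient_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rows <- lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, time_months = p$times,
               wbc_per_ul = p$wbc, is_pct = p$is_pct)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read baseline clinical features from CSV
#'
#' Columns: `patient_id`, `age_years`, `spleen_cm`, `basophil_pct`,
#' `blast_pct`, `platelet_count`. Empty cells become `NA` (missing
#' data, handled downstream by the score calculators).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_baseline <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age_years", "spleen_cm", "basophil_pct",
            "blast_pct", "platelet_count")
  if (!all(need %in% names(df))) {
    stop("baseline CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Baseline features of a generated cohort as a data.frame
#'
#' @param cohort List of [patient_series()] with baselines attached.
#' @return A data.frame in the [read_baseline()] column layout.
#' @export
baseline_table <- function(cohort) {
  rows <- lapply(cohort, function(p) {
    b <- if (is.null(p$baseline)) clinical_baseline() else p$baseline
    data.frame(patient_id = p$patient_id, age_years = b$age_years,
               spleen_cm = b$spleen_cm, basophil_pct = b$basophil_pct,
               blast_pct = b$blast_pct, platelet_count = b$platelet_count)
  })
  do.call(rbind, rows)
}

#' Save a trained prediction model to JSON
#'
#' A self-describing file holding everything needed to predict a new
#' patient: the shared expression ratio, the decision thresholds (with
#' the Y-scale convention recorded), the criterion and objective, the
#' model constants, and provenance (seed). Loading then saving is
#' lossless.
#'
#' @param path Output path.
#' @param c_ratio Shared ABL1 expression ratio.
#' @param thresholds A `threshold_pair`.
#' @param criterion A [response_criterion()].
#' @param consts [model_constants()].
#' @param seed Seed used in training.
#' @return `path`, invisibly.
#' @export
save_model_file <- function(path, c_ratio, thresholds, criterion,
                            consts = model_constants(), seed = NA) {
  obj <- list(
    format = "cmlkinetics-model", version = 1L,
    c = c_ratio,
    thresholds = list(Y = thresholds$Y, log10_Y = thresholds$log10_Y,
                      B = thresholds$B, y_scale = "cells_per_ul",
                      objective = thresholds$objective),
    criterion = criterion$name,
    constants = unclass(consts),
    provenance = list(seed = seed)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a prediction model saved by [save_model_file()]
#'
#' @param path JSON path.
#' @return List with `c`, `thresholds` (class `threshold_pair`),
#'   `criterion` ([response_criterion()]), `consts`
#'   ([model_constants()]), `seed`.
#' @export
read_model_file <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cmlkinetics-model")) {
    stop("not a cmlkinetics model file: ", path)
  }
  thr <- structure(
    list(Y = obj$thresholds$Y, log10_Y = obj$thresholds$log10_Y,
         B = obj$thresholds$B, objective = obj$thresholds$objective,
         degenerate = FALSE),
    class = "threshold_pair"
  )
  list(
    c = obj$c, thresholds = thr,
    criterion = response_criterion(obj$criterion),
    consts = do.call(model_constants,
                     obj$constants[c("k_is", "detection_limit",
                                     "x_star_min", "x_star_max",
                                     "penalty_weight", "dt")]),
    seed = obj$provenance$seed
  )
}
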