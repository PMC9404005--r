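#' External validation of the stage-2 model
#'
#' Predicts log D for held-out compounds with the cascade's stage-2 (ion-pair)
#' model and compares against the best available reference value, with a
#' provable leakage guard: any requested id that sits in the stage-2 training
#' set raises an error.
#'
#' Reference precedence per compound: literature (SFM/SSM-derived) `log_d_ref`
#' first, then the cascade's own stage-1 prediction, then a software-calculated
#' value from `software_reference` if supplied. The signed error is always
#' recomputed as `predicted - reference`. Rows whose absolute relative error
#' exceeds `bound` are flagged `discrepant` rather than dropped.
#'
#' @param cascade A `qsrr_cascade` from [run_cascade()].
#' @param data The compound table the cascade was run on.
#' @param validation_ids Ids of the validation compounds; default
#'   [cascade_ids()]`$validation` (pentachlorophenol W20, benzoic acid W1,
#'   and the disubstituted benzenesulfonic acid S12).
#' @param software_reference Optional tibble (`id`, `logd_calc`) of
#'   software-calculated comparison values, e.g. [calculated_logd_table()];
#'   used as reference only when nothing better exists, and always attached
#'   as the comparison column `logd_calc`.
#' @param bound Relative-error bound used for the discrepancy flag
#'   (default 0.10).
#' @return A tibble of class `prediction_report`: `id`, `name`, `reference`,
#'   `reference_source`, `predicted`, `predicted_source`, `error`,
#'   `rel_error`, `discrepant`, and `logd_calc` when supplied.
#' @examples
#' tbl <- compound_table()
#' cas <- run_cascade(tbl)
#' external_validation(cas, tbl)
#' @export
external_validation <- function(cascade, data,
                                validation_ids = cascade_ids()$validation,
                                software_reference = NULL,
                                bound = 0.10) {
  leaked <- intersect(validation_ids, cascade$stage2$training_ids)
  if (length(leaked) > 0) {
    abort(
      paste0(
        "validation compound(s) present in stage-2 training set: ",
        paste(leaked, collapse = ", ")
      ),
      class = "logdqsrr_leakage_error"
    )
  }
  rows <- select_by_ids(data, validation_ids)
  stage1_labels <- setNames(
    cascade$stage1_predictions$predicted, cascade$stage1_predictions$id
  )
  soft <- if (is.null(software_reference)) {
    setNames(numeric(0), character(0))
  } else {
    setNames(software_reference$logd_calc, software_reference$id)
  }

  reference <- rows$log_d_ref
  reference_source <- ifelse(is.na(reference), NA_character_, "literature (SFM/SSM)")
  use_stage1 <- is.na(reference) & rows$id %in% names(stage1_labels)
  reference[use_stage1] <- stage1_labels[rows$id[use_stage1]]
  reference_source[use_stage1] <- "stage-1 model"
  use_soft <- is.na(reference) & rows$id %in% names(soft)
  reference[use_soft] <- soft[rows$id[use_soft]]
  reference_source[use_soft] <- "software-calculated"
  if (anyNA(reference)) {
    abort(
      paste0(
        "no reference log D available for: ",
        paste(rows$id[is.na(reference)], collapse = ", ")
      ),
      class = "logdqsrr_validation_error"
    )
  }

  predicted <- predict(cascade$stage2, rows)
  error <- predicted - reference
  rel_error <- ifelse(abs(reference) > 0, abs(error) / abs(reference), NA_real_)
  out <- tibble(
    id = rows$id,
    name = rows$name,
    reference = reference,
    reference_source = reference_source,
    predicted = predicted,
    predicted_source = "stage-2 model",
    error = error,
    rel_error = rel_error,
    discrepant = !is.na(rel_error) & rel_error > bound
  )
  if (length(soft) > 0) out$logd_calc <- unname(soft[out$id])
  class(out) <- c("prediction_report", class(out))
  out
}

#' Error summary of a prediction report
#'
#' Maximum and mean absolute signed error, maximum and mean absolute relative
#' error (rows with zero reference are excluded from the relative metrics and
#' counted separately), and the number of rows meeting a configurable
#' relative-error bound.
#'
#' @param report A `prediction_report` (or any tibble with `reference`,
#'   `predicted` columns; `error` is recomputed, never trusted).
#' @param bound Relative-error bound (default 0.10).
#' @return One-row tibble: `n`, `max_abs_error`, `mean_abs_error`,
#'   `mean_signed_error`, `max_rel_error`, `mean_rel_error`, `n_within_bound`,
#'   `n_zero_reference`.
#' @export
relative_error_summary <- function(report, bound = 0.10) {
  if (nrow(report) == 0) {
    abort("empty prediction report", class = "logdqsrr_validation_error")
  }
  error <- report$predicted - report$reference
  nonzero <- abs(report$reference) > 0
  rel <- abs(error[nonzero]) / abs(report$reference[nonzero])
  tibble(
    n = nrow(report),
    max_abs_error = max(abs(error)),
    mean_abs_error = mean(abs(error)),
    mean_signed_error = mean(error),
    max_rel_error = if (any(nonzero)) max(rel) else NA_real_,
    mean_rel_error = if (any(nonzero)) mean(rel) else NA_real_,
    n_within_bound = sum(rel <= bound),
    n_zero_reference = sum(!nonzero)
  )
}
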