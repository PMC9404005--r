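#' Compound id lists of the two-stage study design
#'
#' The fixed training and prediction sets of the IS -> IP cascade on the
#' packaged table:
#' \describe{
#'   \item{stage1_training}{N1-N26 and W1-W20 (46 compounds with reference
#'     log D): training set of the ion-suppression (stage-1) model.}
#'   \item{stage1_prediction}{the 19 ionized compounds retained in
#'     ion-suppression mode but lacking literature log D (W22-W26, W28-W32,
#'     S1, S3-S5, S7-S9, S11, S12), labeled by the stage-1 model.}
#'   \item{stage2_labeled}{the 18 stage-1-labeled compounds entering stage-2
#'     training (all of the above except S12, which is reserved as an
#'     external-validation reference).}
#'   \item{stage2_training}{the 62-compound mixed model group: N1-N26,
#'     W2-W19, and the 18 stage-1-labeled compounds.}
#'   \item{stage2_prediction}{the 8 strongly ionized compounds unretained in
#'     ion-suppression mode (W21, W27, W33, S2, S6, S10, S13, S14), predicted
#'     by the stage-2 ion-pair model.}
#'   \item{validation}{the three external-validation compounds W20, W1, S12,
#'     all held out of stage-2 training.}
#' }
#'
#' @return A named list of character vectors.
#' @export
cascade_ids <- function() {
  stage1_prediction <- c(
    paste0("W", 22:26), paste0("W", 28:32),
    "S1", paste0("S", 3:5), paste0("S", 7:9), "S11", "S12"
  )
  list(
    stage1_training = c(paste0("N", 1:26), paste0("W", 1:20)),
    stage1_prediction = stage1_prediction,
    stage2_labeled = setdiff(stage1_prediction, "S12"),
    stage2_training = c(
      paste0("N", 1:26), paste0("W", 2:19),
      setdiff(stage1_prediction, "S12")
    ),
    stage2_prediction = c(
      "W21", "W27", "W33", "S2", "S6", "S10", "S13", "S14"
    ),
    validation = c("W20", "W1", "S12")
  )
}

#' Run the two-stage IS -> IP QSRR cascade
#'
#' Stage 1 fits the four-descriptor ion-suppression model
#' `log_d_ref ~ log_kw_is + n_e + a + b` on the compounds with reference
#' log D, and labels the ionized compounds that are retained in
#' ion-suppression mode but lack a reference value. Stage 2 fits the ion-pair
#' analogue `~ log_kw_ip + n_e + a + b` on the mixed model group — neutrals
#' and weak acids with reference log D plus the stage-1-labeled compounds —
#' and predicts the strongly ionized compounds that only retain under
#' ion-pair conditions.
#'
#' Training-set assembly fails loudly: every configured training id must be
#' present with complete response and predictors, and the assembled sizes
#' must equal the configured list lengths (46 and 62 for the default design).
#' Prediction lists, by contrast, are filtered to the ids present in `data`,
#' so removing an unknown compound shrinks the prediction table without
#' touching the models.
#'
#' @param data A compound table; default design expects the packaged
#'   [compound_table()].
#' @param ids Id lists as produced by [cascade_ids()]; override to run the
#'   cascade on a different design.
#' @return An object of class `qsrr_cascade`: list with `stage1`, `stage2`
#'   (`qsrr_fit` objects), `stage1_predictions`, `stage2_predictions`
#'   (tibbles: `id`, `name`, `class`, `predicted`, `source`), and `ph`.
#' @examples
#' cas <- run_cascade(compound_table())
#' cas$stage2$n # 62
#' @export
run_cascade <- function(data, ids = cascade_ids()) {
  specs <- qsrr_model_specs()

  stage1 <- fit_qsrr(data,
    response = "log_d_ref", predictors = specs$model5,
    ids = ids$stage1_training, name = "stage 1 (ion suppression)"
  )
  if (stage1$n != length(ids$stage1_training)) {
    abort("stage-1 training set size mismatch", class = "logdqsrr_assembly_error")
  }

  # a compound can only be labeled by stage 1 if it is present AND carries
  # every stage-1 predictor (missing log_kw_is means it never retained in
  # ion-suppression mode)
  pred1_ids <- intersect(ids$stage1_prediction, data$id)
  pred1_rows <- select_by_ids(data, pred1_ids)
  complete1 <- stats::complete.cases(pred1_rows[specs$model5])
  pred1_rows <- pred1_rows[complete1, , drop = FALSE]
  stage1_predictions <- tibble(
    id = pred1_rows$id,
    name = pred1_rows$name,
    class = pred1_rows$class,
    predicted = predict(stage1, pred1_rows),
    source = "stage-1 model"
  )

  # stage-2 response: reference log D where available, else the stage-1 label
  missing_train <- setdiff(ids$stage2_training, data$id)
  if (length(missing_train) > 0) {
    abort(
      paste0(
        "stage-2 training compound(s) absent: ",
        paste(missing_train, collapse = ", ")
      ),
      class = "logdqsrr_assembly_error"
    )
  }
  train2 <- select_by_ids(data, ids$stage2_training)
  labels <- setNames(stage1_predictions$predicted, stage1_predictions$id)
  needs_label <- is.na(train2$log_d_ref)
  unlabeled <- train2$id[needs_label & !(train2$id %in% names(labels))]
  if (length(unlabeled) > 0) {
    abort(
      paste0(
        "stage-2 training compound(s) with neither reference log D nor a ",
        "stage-1 label: ", paste(unlabeled, collapse = ", ")
      ),
      class = "logdqsrr_assembly_error"
    )
  }
  train2$log_d_ref[needs_label] <- labels[train2$id[needs_label]]
  if (nrow(train2) != length(ids$stage2_training)) {
    abort("stage-2 training set size mismatch", class = "logdqsrr_assembly_error")
  }

  stage2 <- fit_qsrr(train2,
    response = "log_d_ref", predictors = specs$model6,
    name = "stage 2 (ion pair, mixed model group)"
  )

  pred2_ids <- intersect(ids$stage2_prediction, data$id)
  pred2_rows <- select_by_ids(data, pred2_ids)
  complete2 <- stats::complete.cases(pred2_rows[specs$model6])
  pred2_rows <- pred2_rows[complete2, , drop = FALSE]
  stage2_predictions <- tibble(
    id = pred2_rows$id,
    name = pred2_rows$name,
    class = pred2_rows$class,
    predicted = predict(stage2, pred2_rows),
    source = "stage-2 model"
  )

  structure(
    list(
      stage1 = stage1,
      stage1_predictions = stage1_predictions,
      stage2 = stage2,
      stage2_predictions = stage2_predictions,
      ph = attr(data, "ph") %||% 7
    ),
    class = "qsrr_cascade"
  )
}

#' @export
print.qsrr_cascade <- function(x, ...) {
  cat("Two-stage QSRR cascade (pH", x$ph, ")\n\n")
  print(x$stage1)
  cat(sprintf(
    "  -> %d compounds labeled by stage 1\n\n", nrow(x$stage1_predictions)
  ))
  print(x$stage2)
  cat(sprintf(
    "  -> %d strongly ionized compounds predicted by stage 2\n",
    nrow(x$stage2_predictions)
  ))
  invisible(x)
}

#' All cascade predictions as one tibble
#'
#' @param x A `qsrr_cascade`.
#' @param ... Unused.
#' @return Tibble of stage-1 and stage-2 predictions: `id`, `name`, `class`,
#'   `predicted`, `source`.
#' @method tidy qsrr_cascade
#' @export
tidy.qsrr_cascade <- function(x, ...) {
  bind_rows(x$stage1_predictions, x$stage2_predictions)
}

#' Two-row model summary of a cascade
#'
#' @param x A `qsrr_cascade`.
#' @param ... Unused.
#' @return Tibble with one row per stage: `stage`, `r.squared`, `sigma`,
#'   `nobs`, `n_predicted`.
#' @method glance qsrr_cascade
#' @export
glance.qsrr_cascade <- function(x, ...) {
  tibble(
    stage = c("stage 1 (IS)", "stage 2 (IP)"),
    r.squared = c(x$stage1$r2, x$stage2$r2),
    sigma = c(x$stage1$sigma, x$stage2$sigma),
    nobs = c(x$stage1$n, x$stage2$n),
    n_predicted = c(nrow(x$stage1_predictions), nrow(x$stage2_predictions))
  )
}
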