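#' Fit a linear QSRR model by ordinary least squares
#'
#' Fits `response ~ predictors` with intercept by OLS on the given compound
#' rows and returns a `qsrr_fit` object carrying the coefficients with
#' classical standard errors, the coefficient of determination, the training
#' size and the training ids. No variable selection, regularization or
#' weighting is applied.
#'
#' @param data A compound table (one row per compound, see
#'   [compound_columns]); any data frame with the named columns works, so
#'   synthetic tables from [simulate_compounds()] fit directly.
#' @param response Name of the response column (default `"log_d_ref"`).
#' @param predictors Character vector of predictor column names, e.g.
#'   `c("log_kw_is", "n_e", "a", "b")`. Must be non-empty and duplicate-free.
#' @param ids Optional character vector of compound ids defining (and
#'   ordering) the training set; rows are selected with [select_by_ids()].
#'   Default: all rows of `data`.
#' @param name Optional model label used in printing.
#' @return An object of class `qsrr_fit` with elements `name`, `response`,
#'   `predictors`, `coefficients` (tibble: term, estimate, std_error,
#'   statistic, p_value), `r2`, `adj_r2`, `sigma`, `n`, `training_ids`,
#'   `fitted`, `residuals`.
#' @seealso [predict.qsrr_fit()], [tidy()], [glance()], [run_cascade()].
#' @examples
#' tbl <- compound_table()
#' m <- fit_qsrr(tbl,
#'   predictors = c("log_kw_is", "n_e", "a", "b"),
#'   ids = cascade_ids()$stage1_training, name = "stage 1"
#' )
#' glance(m)
#' @export
fit_qsrr <- function(data, response = "log_d_ref", predictors,
                     ids = NULL, name = NULL) {
  if (length(predictors) == 0 || anyDuplicated(predictors)) {
    abort("predictors must be non-empty and duplicate-free",
      class = "logdqsrr_spec_error"
    )
  }
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("column(s) not in data: ", paste(missing_cols, collapse = ", ")),
      class = "logdqsrr_schema_error"
    )
  }
  if (!is.null(ids)) data <- select_by_ids(data, ids)
  check_complete(data, c(response, predictors))

  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1) {
    abort(
      sprintf("need n > p + 1 observations (n = %d, p = %d)", n, p),
      class = "logdqsrr_design_error"
    )
  }
  X <- as.matrix(data[predictors])
  if (qr(cbind(1, X))$rank < p + 1) {
    abort("design matrix is rank-deficient", class = "logdqsrr_singular_error")
  }
  df <- data.frame(.y = data[[response]], X)
  fit <- lm(stats::reformulate(predictors, ".y"), data = df)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      # an exactly linear response is legitimate in recovery tests
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  coefficients <- tibble(
    term = c("(Intercept)", predictors),
    estimate = unname(co[, 1]),
    std_error = unname(co[, 2]),
    statistic = unname(co[, 3]),
    p_value = unname(co[, 4])
  )
  structure(
    list(
      name = name %||% paste0("log D ~ ", paste(predictors, collapse = " + ")),
      response = response,
      predictors = predictors,
      coefficients = coefficients,
      r2 = sm$r.squared,
      adj_r2 = sm$adj.r.squared,
      sigma = sm$sigma,
      n = n,
      training_ids = if ("id" %in% names(data)) data$id else NULL,
      fitted = unname(fit$fitted.values),
      residuals = unname(fit$residuals)
    ),
    class = "qsrr_fit"
  )
}

check_complete <- function(data, cols) {
  for (col in cols) {
    bad <- which(!is.finite(data[[col]]))
    if (length(bad) > 0) {
      who <- if ("id" %in% names(data)) data$id[bad[1]] else paste("row", bad[1])
      abort(
        sprintf("missing or non-finite value of '%s' for %s", col, who),
        class = "logdqsrr_validation_error"
      )
    }
  }
  invisible(data)
}

#' Predict log D for new compounds from a fitted QSRR model
#'
#' @param object A `qsrr_fit` from [fit_qsrr()].
#' @param new_data Data frame carrying every predictor column of the model;
#'   rows with a missing predictor raise a validation error naming the
#'   compound and field.
#' @param ... Unused.
#' @return Numeric vector of predicted log D, one value per row of `new_data`.
#' @examples
#' tbl <- compound_table()
#' m <- fit_qsrr(tbl,
#'   predictors = c("log_kw_is", "n_e", "a", "b"),
#'   ids = cascade_ids()$stage1_training
#' )
#' predict(m, select_by_ids(tbl, "S1"))
#' @export
predict.qsrr_fit <- function(object, new_data, ...) {
  missing_cols <- setdiff(object$predictors, names(new_data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("new_data lacks predictor(s): ", paste(missing_cols, collapse = ", ")),
      class = "logdqsrr_schema_error"
    )
  }
  check_complete(new_data, object$predictors)
  X <- as.matrix(new_data[object$predictors])
  beta <- object$coefficients$estimate
  unname(drop(beta[1] + X %*% beta[-1]))
}

#' @export
print.qsrr_fit <- function(x, digits = 3, ...) {
  co <- x$coefficients
  terms <- co$term[-1]
  pieces <- sprintf(
    "%+.*f(±%.*f)·%s", digits, co$estimate[-1], digits, co$std_error[-1], terms
  )
  intercept <- sprintf("%+.*f(±%.*f)", digits, co$estimate[1], digits, co$std_error[1])
  cat("QSRR model: ", x$name, "\n", sep = "")
  cat(
    "  ", x$response, " = ", paste(pieces, collapse = " "), " ", intercept, "\n",
    sep = ""
  )
  cat(sprintf("  N = %d, R² = %.4f, sigma = %.3f\n", x$n, x$r2, x$sigma))
  invisible(x)
}

#' Tidy a QSRR fit into a coefficient tibble
#'
#' @param x A `qsrr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (broom conventions).
#' @method tidy qsrr_fit
#' @export
tidy.qsrr_fit <- function(x, ...) {
  tibble(
    term = x$coefficients$term,
    estimate = x$coefficients$estimate,
    std.error = x$coefficients$std_error,
    statistic = x$coefficients$statistic,
    p.value = x$coefficients$p_value
  )
}

#' One-row model summary of a QSRR fit
#'
#' @param x A `qsrr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `adj.r.squared`, `sigma`, `nobs`,
#'   `df.residual`.
#' @method glance qsrr_fit
#' @export
glance.qsrr_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2,
    adj.r.squared = x$adj_r2,
    sigma = x$sigma,
    nobs = x$n,
    df.residual = x$n - length(x$predictors) - 1
  )
}

#' Canonical single- and multi-descriptor model definitions
#'
#' The descriptor sets of the five ion-suppression-mode models fit on the
#' 46-compound training set (neutrals N1-N26 plus weak acids W1-W20), in
#' increasing order of complexity, and the ion-pair-mode stage-2 model fit on
#' the 62-compound mixed model group:
#' retention alone, retention plus hydrogen-bond acidity, plus basicity,
#' plus net static charge, the full four-descriptor model, and the ion-pair
#' analogue of the full model.
#'
#' @return A named list of character vectors of predictor column names.
#' @export
qsrr_model_specs <- function() {
  list(
    model1 = "log_kw_is",
    model2 = c("log_kw_is", "a"),
    model3 = c("log_kw_is", "b"),
    model4 = c("log_kw_is", "n_e"),
    model5 = c("log_kw_is", "n_e", "a", "b"),
    model6 = c("log_kw_ip", "n_e", "a", "b")
  )
}

#' Fit the five ion-suppression-mode models
#'
#' Fits models 1-5 of [qsrr_model_specs()] on the stage-1 training set (the
#' same 46 compounds for every model) with `log_d_ref` as response.
#'
#' @param data A compound table containing the stage-1 training compounds.
#' @param training_ids Training ids; default [cascade_ids()]`$stage1_training`.
#' @return Named list of `qsrr_fit` objects (`model1` ... `model5`).
#' @examples
#' fits <- fit_is_models(compound_table())
#' purrr::map_dbl(fits, "r2")
#' @export
fit_is_models <- function(data, training_ids = cascade_ids()$stage1_training) {
  specs <- qsrr_model_specs()[paste0("model", 1:5)]
  purrr::imap(
    specs,
    function(predictors, nm) {
      fit_qsrr(data,
        response = "log_d_ref", predictors = predictors,
        ids = training_ids, name = nm
      )
    }
  )
}
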