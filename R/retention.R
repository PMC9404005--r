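#' Retention factor from retention time and dead time
#'
#' Computes the dimensionless retention factor k = (t_R - t_0) / t_0 from a
#' solute's retention time and the column dead time. The alternative
#' denominator `"tR"` computes (t_R - t_0) / t_R instead, for replication of
#' reports that use that variant; the standard chromatographic definition is
#' the default.
#'
#' @param t_r Retention time, minutes. Vectorized.
#' @param t_0 Dead time, minutes; must be positive and `t_r >= t_0`.
#' @param denominator `"t0"` (standard, default) or `"tR"`.
#' @return Numeric vector of retention factors, `>= 0`.
#' @examples
#' retention_factor(5, 1) # 4
#' @export
retention_factor <- function(t_r, t_0, denominator = c("t0", "tR")) {
  denominator <- match.arg(denominator)
  if (any(!is.finite(t_r)) || any(!is.finite(t_0))) {
    abort("t_r and t_0 must be finite", class = "logdqsrr_domain_error")
  }
  if (any(t_0 <= 0)) {
    abort("dead time t_0 must be positive", class = "logdqsrr_domain_error")
  }
  if (any(t_r < t_0)) {
    abort(
      "t_r < t_0: solute elutes before the dead time, retention factor undefined",
      class = "logdqsrr_domain_error"
    )
  }
  (t_r - t_0) / (if (denominator == "t0") t_0 else t_r)
}

#' Double-point retention-time correction (DP-RTC)
#'
#' Recalibrates observed retention times with the affine map fixed by two
#' reference compounds: the map sends each reference's observed time exactly
#' to its nominal time, correcting run-to-run drift in both offset and scale.
#'
#' @param t_obs Observed time(s) to correct, minutes. Vectorized.
#' @param ref_obs Length-2 numeric: observed times of the two references.
#' @param ref_nominal Length-2 numeric: their nominal times, same order.
#' @return Corrected time(s), minutes.
#' @examples
#' dp_rtc_correct(5, ref_obs = c(2, 10), ref_nominal = c(4, 20)) # 10
#' @export
dp_rtc_correct <- function(t_obs, ref_obs, ref_nominal) {
  stopifnot(length(ref_obs) == 2, length(ref_nominal) == 2)
  if (!all(is.finite(c(t_obs, ref_obs, ref_nominal)))) {
    abort("times must be finite", class = "logdqsrr_domain_error")
  }
  if (abs(ref_obs[2] - ref_obs[1]) < .Machine$double.eps * 100) {
    abort(
      "reference observed times coincide; the two-point correction is singular",
      class = "logdqsrr_singular_error"
    )
  }
  slope <- (ref_nominal[2] - ref_nominal[1]) / (ref_obs[2] - ref_obs[1])
  intercept <- ref_nominal[1] - slope * ref_obs[1]
  slope * t_obs + intercept
}

#' Extrapolate log k to 100% aqueous mobile phase (LSS fit)
#'
#' Fits the linear solvent strength (LSS) relation log10 k = log k_w - S * phi
#' per compound and mode by ordinary least squares on the measured retention
#' factors, and reports the extrapolated intercept `log_kw`, the (positive, as
#' written) slope `s`, the coefficient of determination `r2` and the number of
#' distinct mobile-phase compositions used.
#'
#' Replicate injections at the same (compound, mode, phi) are averaged before
#' fitting. If the columns `ref1_obs`, `ref1_nom`, `ref2_obs`, `ref2_nom` are
#' present, each retention time is first recalibrated with [dp_rtc_correct()]
#' (the dead time is assumed to be on the nominal scale already). Fits with
#' fewer than four compositions, or with `r2` below `r2_gate`, are kept but
#' flagged with a warning so borderline solutes can be inspected.
#'
#' @param data Data frame of retention measurements with columns
#'   `compound_id`, `mode` (`"IS"` or `"IP"`), `phi` (organic-modifier volume
#'   fraction in `[0, 1]`), `t_r`, `t_0` (minutes), and optionally the DP-RTC
#'   reference columns above.
#' @param r2_gate Linearity gate; fits with `r2` below it trigger a warning
#'   (not an error). Default 0.99.
#' @param denominator Passed to [retention_factor()].
#' @return A tibble with one row per (compound, mode): `compound_id`, `mode`,
#'   `log_kw`, `s`, `r2`, `n_points`.
#' @examples
#' d <- tibble::tibble(
#'   compound_id = "X", mode = "IS", phi = c(0.1, 0.2, 0.3, 0.4),
#'   t_r = 1 + 10^(2 - 3 * c(0.1, 0.2, 0.3, 0.4)), t_0 = 1
#' )
#' fit_lss(d)
#' @export
fit_lss <- function(data, r2_gate = 0.99, denominator = c("t0", "tR")) {
  denominator <- match.arg(denominator)
  required <- c("compound_id", "mode", "phi", "t_r", "t_0")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "logdqsrr_schema_error"
    )
  }
  if (any(data$phi < 0 | data$phi > 1)) {
    abort("phi must lie in [0, 1] (volume fraction, not percent)",
      class = "logdqsrr_domain_error"
    )
  }
  if (all(c("ref1_obs", "ref1_nom", "ref2_obs", "ref2_nom") %in% names(data))) {
    data$t_r <- purrr::pmap_dbl(
      data[c("t_r", "ref1_obs", "ref1_nom", "ref2_obs", "ref2_nom")],
      function(t_r, ref1_obs, ref1_nom, ref2_obs, ref2_nom) {
        dp_rtc_correct(t_r, c(ref1_obs, ref2_obs), c(ref1_nom, ref2_nom))
      }
    )
  }

  data |>
    group_by(.data$compound_id, .data$mode, .data$phi) |>
    summarise(
      t_r = mean(.data$t_r), t_0 = mean(.data$t_0),
      .groups = "drop"
    ) |>
    group_by(.data$compound_id, .data$mode) |>
    group_modify(function(g, key) {
      fit_lss_one(g, key, r2_gate = r2_gate, denominator = denominator)
    }) |>
    ungroup()
}

fit_lss_one <- function(g, key, r2_gate, denominator) {
  label <- paste0(key$compound_id, " (", key$mode, ")")
  k <- retention_factor(g$t_r, g$t_0, denominator = denominator)
  if (any(k <= 0)) {
    bad <- g$phi[k <= 0][1]
    abort(
      sprintf("retention factor <= 0 for %s at phi = %g; log k undefined", label, bad),
      class = "logdqsrr_domain_error"
    )
  }
  n <- nrow(g)
  if (length(unique(g$phi)) < 2) {
    abort(
      sprintf(
        "%s: fewer than two distinct phi levels after replicate averaging; the LSS design is singular",
        label
      ),
      class = "logdqsrr_singular_error"
    )
  }
  log_k <- log10(k)
  fit <- lm(log_k ~ phi, data = data.frame(phi = g$phi, log_k = log_k))
  sst <- sum((log_k - mean(log_k))^2)
  ssr <- sum(fit$residuals^2)
  r2 <- if (sst < 1e-14) 1 else 1 - ssr / sst
  # a two-point fit interpolates exactly; r2 = 1 by convention
  if (ssr < 1e-14) r2 <- 1
  if (n < 4) {
    warn(
      sprintf("%s: only %d phi levels (>= 4 recommended)", label, n),
      class = "logdqsrr_low_n_warning"
    )
  }
  if (r2 < r2_gate) {
    warn(
      sprintf("%s: r2 = %.4f below the linearity gate %.2f", label, r2, r2_gate),
      class = "logdqsrr_r2_gate_warning"
    )
  }
  tibble(
    log_kw = unname(coef(fit)[1]),
    s = -unname(coef(fit)[2]),
    r2 = r2,
    n_points = n
  )
}
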