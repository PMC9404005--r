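#' Apparent distribution coefficient of a monoprotic acid at a given pH
#'
#' Converts intrinsic lipophilicity (log P, the neutral-form partition
#' coefficient) to the apparent octanol/water distribution coefficient log D
#' at a given mobile-phase pH, assuming only the neutral microspecies
#' partitions:
#'
#' \deqn{\log D = \log P - \log_{10}\bigl(1 + 10^{\,\mathrm{pH} - pK_a}\bigr)}
#'
#' For a neutral compound (missing `pka`) log D equals log P at any pH. Only
#' the monoprotic-acid branch is implemented; requesting `type = "base"`
#' raises a clear not-implemented error rather than returning a silently
#' wrong number.
#'
#' @param log_p Intrinsic log P. Vectorized.
#' @param pka Acid pKa, or `NA` for a neutral compound. Recycled against
#'   `log_p`.
#' @param ph Mobile-phase pH in `[0, 14]`. Default 7.
#' @param type `"acid"` (implemented) or `"base"` (not implemented).
#' @return Numeric vector of log D values; always `<= log_p`, with equality
#'   when ionization is negligible.
#' @examples
#' logd_at_ph(1.87, 4.20, ph = 7) # -0.93 for benzoic acid
#' logd_at_ph(3.30, NA) # neutral: log D = log P
#' @export
logd_at_ph <- function(log_p, pka, ph = 7, type = c("acid", "base")) {
  type <- match.arg(type)
  if (type == "base") {
    abort(
      "only the monoprotic-acid correction is implemented; basic and polyprotic species are out of scope",
      class = "logdqsrr_not_implemented"
    )
  }
  if (length(ph) != 1 || !is.finite(ph) || ph < 0 || ph > 14) {
    abort("ph must be a single value in [0, 14]", class = "logdqsrr_domain_error")
  }
  if (any(!is.finite(log_p))) {
    abort("log_p must be finite", class = "logdqsrr_domain_error")
  }
  if (any(!is.na(pka) & !is.finite(pka))) {
    abort("pka must be finite or NA", class = "logdqsrr_domain_error")
  }
  n <- max(length(log_p), length(pka))
  log_p <- rep_len(log_p, n)
  pka <- rep_len(pka, n)
  correction <- ifelse(is.na(pka), 0, log10(1 + 10^(ph - pka)))
  log_p - correction
}
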