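#' Simulate a compound descriptor table with known log D structure
#'
#' Draws descriptors uniformly from ranges spanning the packaged reference
#' table and builds the response as a known linear function of
#' (log k_w, n_e, a, b) plus Gaussian noise, so every downstream fit can be
#' checked against the generating truth. The same log k_w is used for both
#' modes (the simulator does not model ion-pair retention mechanisms; it
#' targets the pipeline's statistical assumptions only).
#'
#' @param n_compounds Number of compounds (default 50).
#' @param coefficients Named numeric vector of the generating linear model:
#'   `intercept`, `log_kw`, `n_e`, `a`, `b`. Defaults mirror the magnitudes
#'   seen on silica-based C18 retention data (`c(intercept = 0.1,
#'   log_kw = 1.1, n_e = 1.65, a = 0.5, b = -1.25)`).
#' @param descriptor_ranges Named list of `c(min, max)` spans; defaults mirror
#'   the reference table: `log_kw` in `[0.2, 5.7]`, `n_e` in `[-2, 0]`,
#'   `a` in `[0, 1.6]`, `b` in `[0, 1.9]`.
#' @param noise_sd_logd Residual SD on log D (default 0.1 log units).
#' @param sample_from Optional compound table; when given, descriptor rows are
#'   drawn by bootstrap from it (columns `log_kw_is`, `n_e`, `a`, `b`) instead
#'   of uniform sampling, for realism.
#' @param seed Random seed; same seed, same dataset.
#' @return A list of class `synthetic_compounds`: `compounds` (a compound
#'   table with `id`, `name`, `class = NA`, descriptors, and the noisy
#'   `log_d_ref`), and `truth` (the `coefficients` plus the noise-free
#'   `log_d_true` vector).
#' @examples
#' sim <- simulate_compounds(10, noise_sd_logd = 0, seed = 1)
#' sim$truth$coefficients
#' @export
simulate_compounds <- function(n_compounds = 50,
                               coefficients = c(
                                 intercept = 0.1, log_kw = 1.1,
                                 n_e = 1.65, a = 0.5, b = -1.25
                               ),
                               descriptor_ranges = list(
                                 log_kw = c(0.2, 5.7), n_e = c(-2, 0),
                                 a = c(0, 1.6), b = c(0, 1.9)
                               ),
                               noise_sd_logd = 0.1,
                               sample_from = NULL,
                               seed = NULL) {
  stopifnot(n_compounds >= 1, noise_sd_logd >= 0)
  needed <- c("intercept", "log_kw", "n_e", "a", "b")
  if (!all(needed %in% names(coefficients))) {
    abort(
      paste0("coefficients must name: ", paste(needed, collapse = ", ")),
      class = "logdqsrr_spec_error"
    )
  }
  spans <- vapply(descriptor_ranges, function(r) diff(range(r)), numeric(1))
  if (is.null(sample_from) && all(spans == 0)) {
    warn("all descriptor ranges are degenerate; the design is singular",
      class = "logdqsrr_singular_warning"
    )
  }
  draw <- function() {
    if (is.null(sample_from)) {
      tibble(
        log_kw = runif(n_compounds, descriptor_ranges$log_kw[1], descriptor_ranges$log_kw[2]),
        n_e = runif(n_compounds, descriptor_ranges$n_e[1], descriptor_ranges$n_e[2]),
        a = runif(n_compounds, descriptor_ranges$a[1], descriptor_ranges$a[2]),
        b = runif(n_compounds, descriptor_ranges$b[1], descriptor_ranges$b[2])
      )
    } else {
      rows <- sample.int(nrow(sample_from), n_compounds, replace = TRUE)
      tibble(
        log_kw = sample_from$log_kw_is[rows],
        n_e = sample_from$n_e[rows],
        a = sample_from$a[rows],
        b = sample_from$b[rows]
      )
    }
  }
  gen <- function() {
    d <- draw()
    log_d_true <- coefficients[["intercept"]] +
      coefficients[["log_kw"]] * d$log_kw +
      coefficients[["n_e"]] * d$n_e +
      coefficients[["a"]] * d$a +
      coefficients[["b"]] * d$b
    compounds <- tibble(
      id = paste0("SYN", seq_len(n_compounds)),
      name = paste("synthetic compound", seq_len(n_compounds)),
      class = NA_character_,
      log_p = NA_real_,
      pka = NA_real_,
      log_d_ref = log_d_true + rnorm(n_compounds, 0, noise_sd_logd),
      log_kw_is = d$log_kw,
      log_kw_ip = d$log_kw,
      n_e = d$n_e,
      a = d$a,
      b = d$b
    )
    structure(
      list(
        compounds = compounds,
        truth = list(coefficients = coefficients, log_d_true = log_d_true)
      ),
      class = "synthetic_compounds"
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate isocratic retention measurements from LSS truth
#'
#' Generates per-compound retention times over a grid of organic-modifier
#' fractions from the LSS law t_R = t_0 * (1 + 10^(log_kw - s * phi)) with
#' Gaussian instrument noise, floored just above the dead time. Grid points
#' where the noise-free retention factor falls below `k_min` are dropped
#' (emulating solutes eluting at the dead time); compounds with no surviving
#' grid point are excluded entirely and reported with a warning and in the
#' `unretained` attribute.
#'
#' @param truth Data frame with columns `id` (or `compound_id`), `log_kw`,
#'   and `s` (LSS slope, positive).
#' @param mode Measurement mode label (`"IS"` default or `"IP"`).
#' @param phi_grid Organic-modifier volume fractions; default
#'   `seq(0.1, 0.8, by = 0.1)` (at least four levels recommended).
#' @param t_0 Dead time, minutes (default 1).
#' @param noise_sd_tr Retention-time SD, minutes (default 0.01).
#' @param replicates Injections per (compound, phi) (default 1).
#' @param k_min Retention-factor floor below which a grid point is treated as
#'   unretained and dropped (default 1e-3).
#' @param seed Random seed.
#' @return A tibble of measurements (`compound_id`, `mode`, `phi`, `t_r`,
#'   `t_0`) with attribute `unretained` listing excluded compound ids.
#' @examples
#' truth <- tibble::tibble(id = "X", log_kw = 2, s = 3)
#' simulate_retention(truth, noise_sd_tr = 0, phi_grid = c(0.2, 0.4, 0.6, 0.8))
#' @export
simulate_retention <- function(truth, mode = "IS",
                               phi_grid = seq(0.1, 0.8, by = 0.1),
                               t_0 = 1, noise_sd_tr = 0.01,
                               replicates = 1, k_min = 1e-3, seed = NULL) {
  if (!"compound_id" %in% names(truth) && "id" %in% names(truth)) {
    truth <- rename(truth, compound_id = "id")
  }
  stopifnot(
    all(c("compound_id", "log_kw", "s") %in% names(truth)),
    all(is.finite(truth$log_kw)), all(is.finite(truth$s)),
    t_0 > 0, noise_sd_tr >= 0, replicates >= 1
  )
  gen <- function() {
    grid <- tidyr::crossing(
      truth[c("compound_id", "log_kw", "s")],
      phi = phi_grid,
      replicate = seq_len(replicates)
    ) |>
      mutate(k_true = 10^(.data$log_kw - .data$s * .data$phi))
    kept <- filter(grid, .data$k_true >= k_min)
    unretained <- setdiff(truth$compound_id, unique(kept$compound_id))
    if (length(unretained) > 0) {
      warn(
        paste0(
          "unretained compound(s) excluded (no grid point with k >= ",
          format(k_min), "): ", paste(unretained, collapse = ", ")
        ),
        class = "logdqsrr_unretained_warning"
      )
    }
    out <- kept |>
      mutate(
        mode = mode,
        t_r = pmax(
          t_0 * (1 + .data$k_true) + rnorm(dplyr::n(), 0, noise_sd_tr),
          t_0 * (1 + 1e-6)
        ),
        t_0 = t_0
      ) |>
      select("compound_id", "mode", "phi", "t_r", "t_0")
    attr(out, "unretained") <- unretained
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
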