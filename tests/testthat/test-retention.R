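test_that("retention factor follows the standard definition", {
  expect_equal(retention_factor(5, 1), 4)
  expect_equal(retention_factor(2.5, 1.25), 1)
  expect_equal(retention_factor(1, 1), 0)
  # as-printed variant divides by t_R instead
  expect_equal(retention_factor(5, 1, denominator = "tR"), 0.8)
  expect_error(retention_factor(0.5, 1), class = "logdqsrr_domain_error")
  expect_error(retention_factor(5, 0), class = "logdqsrr_domain_error")
})

test_that("two-point correction maps anchors exactly", {
  expect_equal(dp_rtc_correct(5, c(2, 10), c(2, 10)), 5) # identity
  expect_equal(dp_rtc_correct(5, c(2, 10), c(3, 11)), 6) # shift
  expect_equal(dp_rtc_correct(5, c(2, 10), c(4, 20)), 10) # scale
  # both anchors reproduced for an arbitrary affine drift
  obs <- c(2.13, 9.41)
  nom <- c(2.50, 10.10)
  expect_equal(dp_rtc_correct(obs, obs, nom), nom)
  expect_error(dp_rtc_correct(5, c(3, 3), c(2, 10)),
    class = "logdqsrr_singular_error"
  )
})

test_that("correction composed with its inverse is the identity", {
  set.seed(11)
  for (i in 1:20) {
    obs <- sort(runif(2, 1, 10))
    nom <- sort(runif(2, 1, 10))
    t <- runif(5, 0, 20)
    corrected <- dp_rtc_correct(t, obs, nom)
    back <- dp_rtc_correct(corrected, nom, obs)
    expect_equal(back, t, tolerance = 1e-12)
  }
})

test_that("noiseless LSS data is recovered exactly", {
  phi <- c(0.1, 0.2, 0.3, 0.4)
  d <- tibble::tibble(
    compound_id = "X", mode = "IS", phi = phi,
    t_r = 1 + 10^(2 - 3 * phi), t_0 = 1
  )
  fit <- fit_lss(d)
  expect_equal(fit$log_kw, 2, tolerance = 1e-10)
  expect_equal(fit$s, 3, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$n_points, 4L)
})

test_that("noisy LSS recovery stays within 3 standard errors", {
  phi <- seq(0.1, 0.6, by = 0.1)
  true_kw <- 1.5
  true_s <- 2.5
  set.seed(7)
  log_k <- true_kw - true_s * phi + rnorm(6, 0, 0.01)
  d <- tibble::tibble(
    compound_id = "X", mode = "IS", phi = phi,
    t_r = 1 + 10^log_k, t_0 = 1
  )
  fit <- fit_lss(d)
  oracle <- simple_reg_oracle(phi, log_k)
  expect_equal(fit$log_kw, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$s, -oracle$slope, tolerance = 1e-10)
  expect_lt(abs(fit$log_kw - true_kw), 3 * oracle$se_intercept)
  expect_lt(abs(fit$s - true_s), 3 * oracle$se_slope)
})

test_that("LSS equals the closed-form least-squares solution", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    phi <- sort(runif(n, 0.05, 0.9))
    log_k <- runif(1, 0.5, 3) - runif(1, 1, 4) * phi + rnorm(n, 0, 0.05)
    d <- tibble::tibble(
      compound_id = "X", mode = "IP", phi = phi, t_r = 2 * (1 + 10^log_k), t_0 = 2
    )
    fit <- suppressWarnings(fit_lss(d))
    oracle <- simple_reg_oracle(phi, log_k)
    expect_equal(fit$log_kw, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$s, -oracle$slope, tolerance = 1e-10)
  }
})

test_that("a point on the fitted line leaves the fit unchanged", {
  phi <- c(0.1, 0.25, 0.4, 0.55)
  set.seed(5)
  log_k <- 1.8 - 2.2 * phi + rnorm(4, 0, 0.02)
  d <- tibble::tibble(
    compound_id = "X", mode = "IS", phi = phi, t_r = 1 + 10^log_k, t_0 = 1
  )
  fit <- fit_lss(d)
  phi_new <- 0.7
  log_k_new <- fit$log_kw - fit$s * phi_new
  d2 <- dplyr::bind_rows(
    d,
    tibble::tibble(
      compound_id = "X", mode = "IS", phi = phi_new, t_r = 1 + 10^log_k_new, t_0 = 1
    )
  )
  fit2 <- suppressWarnings(fit_lss(d2))
  expect_equal(fit2$log_kw, fit$log_kw, tolerance = 1e-10)
  expect_equal(fit2$s, fit$s, tolerance = 1e-10)
})

test_that("saturated, degenerate and unphysical designs are handled", {
  two <- tibble::tibble(
    compound_id = "X", mode = "IS", phi = c(0.2, 0.5),
    t_r = 1 + 10^(1 - 2 * c(0.2, 0.5)), t_0 = 1
  )
  expect_warning(fit <- fit_lss(two), class = "logdqsrr_low_n_warning")
  expect_equal(fit$r2, 1)
  expect_equal(fit$log_kw, 1, tolerance = 1e-10)

  same_phi <- tibble::tibble(
    compound_id = "X", mode = "IS", phi = 0.3, t_r = c(3, 3.1), t_0 = 1
  )
  expect_error(fit_lss(same_phi), class = "logdqsrr_singular_error")

  dead <- tibble::tibble(
    compound_id = "X", mode = "IS", phi = c(0.1, 0.2, 0.3, 0.4),
    t_r = c(3, 2, 1.5, 1), t_0 = 1
  )
  expect_error(fit_lss(dead), class = "logdqsrr_domain_error")

  noisy <- tibble::tibble(
    compound_id = "X", mode = "IS", phi = c(0.1, 0.3, 0.5, 0.7),
    t_r = c(9, 6, 3.4, 1.4), t_0 = 1
  )
  expect_warning(fit_lss(noisy, r2_gate = 0.999), class = "logdqsrr_r2_gate_warning")
})

test_that("replicates are averaged per (compound, mode, phi) and DP-RTC applied first", {
  phi <- rep(c(0.2, 0.4, 0.6, 0.8), each = 3)
  t_true <- 1 + 10^(1.2 - 1.5 * phi)
  set.seed(3)
  d <- tibble::tibble(
    compound_id = "X", mode = "IS", phi = phi,
    t_r = t_true + rep(c(-0.01, 0, 0.01), times = 4), t_0 = 1
  )
  fit <- fit_lss(d)
  expect_equal(fit$n_points, 4L)
  avg <- d |>
    dplyr::summarise(t_r = mean(t_r), t_0 = 1, .by = c(compound_id, mode, phi))
  expect_equal(fit_lss(avg), fit)

  # the same data recorded on a drifted clock plus its anchors
  drift <- d |>
    dplyr::mutate(
      t_r = 1.1 * t_r + 0.3,
      ref1_obs = 1.1 * 2 + 0.3, ref1_nom = 2,
      ref2_obs = 1.1 * 8 + 0.3, ref2_nom = 8
    )
  expect_equal(fit_lss(drift), fit)
})
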