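# Independent oracles, deliberately coded without lm():
# explicit normal equations for multiple OLS, and the closed-form
# sum-formulas for simple (two-parameter) regression.

ols_oracle <- function(y, X) {
  Xi <- cbind(1, as.matrix(X))
  xtx_inv <- solve(t(Xi) %*% Xi)
  beta <- drop(xtx_inv %*% t(Xi) %*% y)
  resid <- y - drop(Xi %*% beta)
  n <- length(y)
  p <- ncol(Xi)
  sigma2 <- sum(resid^2) / (n - p)
  se <- sqrt(diag(xtx_inv) * sigma2)
  sst <- sum((y - mean(y))^2)
  list(beta = beta, se = se, r2 = 1 - sum(resid^2) / sst)
}

simple_reg_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se_slope <- sqrt((sum(resid^2) / (n - 2)) / sxx)
  se_intercept <- se_slope * sqrt(sum(x^2) / n)
  list(
    intercept = intercept, slope = slope,
    se_intercept = se_intercept, se_slope = se_slope
  )
}

# study table used across tests (with the documented transposition repair)
fixture_table <- function(...) compound_table(...)

write_temp_compounds <- function(lines, ext = "csv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext), .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
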