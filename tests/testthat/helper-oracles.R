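# Independent closed-form oracles used across test files.

# Normal-equation OLS: full coefficient vector.
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Full-design just-identified 2SLS: regressors W = [X s], instruments [X z].
tsls_oracle <- function(y, s, z, X = NULL) {
  W <- cbind(X, s)
  Zm <- cbind(X, z)
  b <- drop(solve(crossprod(Zm, W), crossprod(Zm, y)))
  unname(b[length(b)])
}

# Weighted least squares with an intercept: coefficients (a, b).
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% (w * X), t(X) %*% (w * y)))
}

# Build a minimal analysis_sample from raw pieces (for toy fixtures).
toy_sample <- function(data, G = NULL, earnings = NULL,
                       covariates = character(0)) {
  if (is.null(data$prime_earn)) data$prime_earn <- exp(data$log_prime_earn)
  if (is.null(data$log_prime_earn)) data$log_prime_earn <- log(data$prime_earn)
  if (is.null(data$piv_raw)) data$piv_raw <- data$piv_std
  structure(
    list(label = "toy", data = data, G = G, earnings = earnings,
         covariates = covariates),
    class = "analysis_sample"
  )
}

# Hand-built snp_summary table.
toy_summary <- function(beta_exp, beta_out, se_exp, se_out,
                        snp = paste0("rs", seq_along(beta_exp))) {
  harmonize_summary(data.frame(
    snp = snp, ea = "A", nea = "G", eaf = 0.5,
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    stringsAsFactors = FALSE
  ))
}
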