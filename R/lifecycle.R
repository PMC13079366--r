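#' Age-specific returns to schooling across the life cycle
#'
#' For each requested age, fits the chosen estimator with that age's
#' absolute earnings as the outcome. Individuals with zero earnings at an
#' age (not yet in the labor market) are retained: early ages therefore
#' show the negative returns produced by forgone earnings, and the profile
#' turns positive after the earnings crossover.
#'
#' @param sample an `analysis_sample` carrying the earnings panel (built by
#'   [build_samples()]).
#' @param ages ages to profile; default all ages in the panel.
#' @inheritParams fit_returns
#' @return a `lifecycle_profile` data frame: `age`, `estimator`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `n`.
#' @export
age_specific_returns <- function(sample, method = c("ols", "fe", "mr", "sibmr"),
                                 ages = NULL, covariates = NULL,
                                 cluster = NULL, instrument = "piv_std",
                                 level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "analysis_sample"), !is.null(sample$earnings))
  panel_ages <- as.integer(colnames(sample$earnings))
  if (is.null(ages)) ages <- panel_ages
  outside <- setdiff(ages, panel_ages)
  if (length(outside)) {
    warning("age(s) outside the earnings panel skipped: ",
            paste(outside, collapse = ", "))
    ages <- intersect(ages, panel_ages)
  }
  rows <- lapply(ages, function(a) {
    yv <- sample$earnings[, as.character(a)]
    fit <- fit_returns(sample, outcome = "abs", method = method,
                       covariates = covariates, cluster = cluster,
                       instrument = instrument, level = level,
                       outcome_vector = yv)
    data.frame(age = a, estimator = method, beta = fit$beta, se = fit$se,
               ci_low = fit$ci[1], ci_high = fit$ci[2], n = fit$n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lifecycle_profile", "data.frame")
  out
}

#' Undiscounted lifetime return per year of schooling
#'
#' The unweighted arithmetic mean of the age-specific returns.
#'
#' @param profile a `lifecycle_profile` (or any data frame with `beta`).
#' @return numeric scalar in the profile's outcome units.
#' @export
lifetime_return <- function(profile) {
  stopifnot(nrow(profile) > 0)
  mean(profile$beta)
}

#' Internal rate of return to schooling
#'
#' Solves for the discount rate `r` at which the present value of the
#' age-specific returns is zero:
#' `sum_a beta_a * (1+r)^-(a - a_min) = 0`, discounting to the first
#' profile age. Education is profitable when the IRR exceeds the
#' comparison (real market) rate.
#'
#' @param profile a `lifecycle_profile`; must have negative early and
#'   positive later returns (at least one sign change).
#' @param comparison_rate the market interest rate benchmark, default
#'   0.023 (2.3 percent).
#' @param tol root-finding tolerance, default 1e-6.
#' @return an `irr_result`: `irr`, `bracket`, `comparison_rate`,
#'   `profitable`.
#' @export
internal_rate_of_return <- function(profile, comparison_rate = 0.023,
                                    tol = 1e-6) {
  profile <- profile[order(profile$age), , drop = FALSE]
  beta <- profile$beta
  nz <- beta[beta != 0]
  changes <- sum(diff(sign(nz)) != 0)
  if (changes == 0) {
    stop("profile has no sign change: IRR undefined", call. = FALSE)
  }
  if (changes > 1) {
    warning("multiple sign changes in the profile; ",
            "reporting the root nearest zero")
  }
  periods <- profile$age - min(profile$age)
  npv <- function(r) sum(beta * (1 + r)^(-periods))
  grid <- c(seq(-0.9, 1, by = 0.01), seq(1.1, 10, by = 0.1))
  vals <- vapply(grid, npv, numeric(1))
  flips <- which(diff(sign(vals)) != 0)
  if (!length(flips)) stop("no IRR found in (-0.9, 10)", call. = FALSE)
  roots <- vapply(flips, function(i) {
    stats::uniroot(npv, c(grid[i], grid[i + 1]), tol = tol)$root
  }, numeric(1))
  irr <- roots[which.min(abs(roots))]
  i <- flips[which.min(abs(roots))]
  step <- grid[i + 1] - grid[i]
  bracket <- c(grid[i], grid[i + 1])
  if (irr <= bracket[1]) bracket[1] <- bracket[1] - step
  if (irr >= bracket[2]) bracket[2] <- bracket[2] + step
  structure(
    list(irr = irr, bracket = bracket, comparison_rate = comparison_rate,
         profitable = irr > comparison_rate, n_roots = length(roots)),
    class = "irr_result"
  )
}

#' @export
print.irr_result <- function(x, ...) {
  cat(sprintf("<irr_result> IRR = %.4f (%.2f%%), comparison rate %.2f%%: %s\n",
              x$irr, 100 * x$irr, 100 * x$comparison_rate,
              if (x$profitable) "education pays off" else "not profitable"))
  invisible(x)
}

#' First age at which high-schooling mean earnings overtake low-schooling
#'
#' Splits the sample at the median of schooling and returns the first age
#' at which mean earnings of the high-schooling group exceed those of the
#' low-schooling group (the earnings crossover).
#'
#' @param sample an `analysis_sample` carrying the earnings panel.
#' @return integer age, or `NA` if no crossover occurs in the panel.
#' @export
earnings_crossover_age <- function(sample) {
  stopifnot(!is.null(sample$earnings))
  hi <- sample$data$schooling > stats::median(sample$data$schooling)
  if (!any(hi) || all(hi)) return(NA_integer_)
  mh <- colMeans(sample$earnings[hi, , drop = FALSE])
  ml <- colMeans(sample$earnings[!hi, , drop = FALSE])
  ages <- as.integer(colnames(sample$earnings))
  over <- which(mh > ml)
  if (!length(over)) return(NA_integer_)
  ages[over[1]]
}
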