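# Residualize outcome, schooling and instrument on the covariate design.
residualized_frame <- function(sample, outcome, covariates, instrument) {
  data <- if (inherits(sample, "analysis_sample")) sample$data else sample
  if (is.null(covariates)) {
    covariates <- if (inherits(sample, "analysis_sample")) sample$covariates
    else character(0)
  }
  y <- if (outcome == "log") data$log_prime_earn else data$prime_earn
  z <- if (is.character(instrument)) data[[instrument]] else
    as.numeric(instrument)
  keep <- is.finite(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  z <- z[keep]
  S <- as.numeric(data$schooling)
  X <- cbind(1, covariate_matrix(data, covariates))
  qrX <- qr(X)
  list(data = data, S = S,
       y = qr.resid(qrX, y), s = qr.resid(qrX, S), z = qr.resid(qrX, z))
}

margin_weights_core <- function(S, resid, margins) {
  raw <- vapply(margins, function(m) sum(resid * (S >= m)), numeric(1))
  total <- sum(raw)
  data.frame(margin = margins, raw = raw, weight = raw / total)
}

#' Schooling-margin weights of the OLS and IV estimands
#'
#' The OLS slope and the just-identified IV estimate are weighted averages
#' of increments across schooling margins `1{S >= s}`. The OLS weight on
#' margin s is proportional to `cov(s_res, 1{S >= s})` (Yitzhaki weights,
#' with `s_res` the covariate-residualized schooling) and the IV weight to
#' `cov(z_res, 1{S >= s})`; the unnormalized weights sum to `var(s_res)`
#' and `cov(z_res, S)` respectively.
#'
#' @inheritParams fit_returns
#' @param which `"ols"` or `"iv"` weights.
#' @return a data frame `margin`, `raw`, `weight` (weights sum to 1) with
#'   attribute `total` (the normalizing sum).
#' @export
margin_weights <- function(sample, which = c("ols", "iv"), outcome = "log",
                           covariates = NULL, instrument = "piv_std") {
  which <- match.arg(which)
  fr <- residualized_frame(sample, outcome, covariates, instrument)
  S <- fr$S
  if (length(unique(S)) < 2) {
    stop("degenerate schooling: a single observed value", call. = FALSE)
  }
  margins <- seq(min(S) + 1L, max(S))
  resid <- if (which == "ols") fr$s else fr$z
  out <- margin_weights_core(S, resid, margins)
  attr(out, "total") <- sum(out$raw)
  out
}

#' Covariate-stratum weights of the OLS and IV estimands
#'
#' OLS weights each covariate stratum x proportionally to
#' `P(x) * var(s_res | x)`; IV proportionally to `P(x) * cov(z_res, S | x)`.
#' Under instrument monotonicity all IV stratum weights are nonnegative.
#'
#' @inheritParams margin_weights
#' @param strata a factor/vector defining the strata (default:
#'   sex x parental-earnings quartile).
#' @return data frame `stratum`, `n`, `share`, `w_ols`, `w_iv` (each weight
#'   column sums to 1). Empty strata are dropped.
#' @export
covariate_stratum_weights <- function(sample, strata = NULL, outcome = "log",
                                      covariates = NULL,
                                      instrument = "piv_std") {
  fr <- residualized_frame(sample, outcome, covariates, instrument)
  strata <- default_strata(fr$data, strata)
  levs <- levels(strata)
  n <- length(fr$S)
  rows <- lapply(levs, function(l) {
    idx <- which(strata == l)
    if (!length(idx)) return(NULL)
    sx <- fr$s[idx]; zx <- fr$z[idx]; Sx <- fr$S[idx]
    data.frame(stratum = l, n = length(idx),
               raw_ols = sum((sx - mean(sx))^2) / n,
               raw_iv = sum((zx - mean(zx)) * (Sx - mean(Sx))) / n)
  })
  tab <- do.call(rbind, rows)
  tab$share <- tab$n / n
  tab$w_ols <- tab$raw_ols / sum(tab$raw_ols)
  tab$w_iv <- tab$raw_iv / sum(tab$raw_iv)
  tab[, c("stratum", "n", "share", "w_ols", "w_iv")]
}

default_strata <- function(data, strata) {
  if (is.null(strata)) {
    strata <- interaction(
      ifelse(data$sex == 1, "F", "M"),
      paste0("Q", parent_earn_quartile(data$parent_log_earn)),
      drop = TRUE
    )
  } else if (length(strata) != nrow(data)) {
    stop("strata must have one entry per (included) observation",
         call. = FALSE)
  }
  droplevels(as.factor(strata))
}

# Pool adjacent margins inside a stratum until each pooled group splits the
# stratum with at least min_cell observations on both sides.
pool_margins <- function(S, margins, min_cell) {
  n_ge <- vapply(margins, function(m) sum(S >= m), numeric(1))
  good <- n_ge >= min_cell & (length(S) - n_ge) >= min_cell
  if (!any(good)) return(rep(1L, length(margins)))
  grp <- cumsum(good)
  grp[grp == 0] <- 1L
  grp
}

#' Decompose the gap between the IV (MR) and OLS returns to schooling
#'
#' Splits `theta_iv - theta_ols` into: a covariate component (different
#' weighting of covariate-stratum average effects), a margin component
#' (different weighting of schooling-margin increments within strata), and
#' a residual component attributed to the combination of unobserved
#' confounding in OLS and complier-vs-population averaging, which the
#' decomposition cannot separate. Components sum to the gap exactly by
#' construction.
#'
#' @inheritParams covariate_stratum_weights
#' @param min_cell smallest margin-side cell within a stratum before
#'   adjacent margins are pooled.
#' @param order `"covariate_first"` (default) evaluates the covariate
#'   component at the stratum-level OLS effects and the margin component at
#'   IV stratum weights; `"margin_first"` swaps the sequencing.
#' @return an object of class `mr_ols_decomposition`.
#' @export
decompose_gap <- function(sample, strata = NULL, outcome = "log",
                          covariates = NULL, instrument = "piv_std",
                          min_cell = 30,
                          order = c("covariate_first", "margin_first")) {
  order <- match.arg(order)
  fr <- residualized_frame(sample, outcome, covariates, instrument)
  strata <- default_strata(fr$data, strata)
  theta_ols <- sum(fr$s * fr$y) / sum(fr$s^2)
  theta_iv <- sum(fr$z * fr$y) / sum(fr$z * fr$s)
  gap <- theta_iv - theta_ols
  stab <- covariate_stratum_weights(sample, strata, outcome, covariates,
                                    instrument)
  margin_tabs <- list()
  b_x <- numeric(nrow(stab))
  margin_term <- numeric(nrow(stab))
  for (i in seq_len(nrow(stab))) {
    idx <- which(strata == stab$stratum[i])
    sx <- fr$s[idx]; zx <- fr$z[idx]; yx <- fr$y[idx]; Sx <- fr$S[idx]
    sxc <- sx - mean(sx); zxc <- zx - mean(zx); yxc <- yx - mean(yx)
    b_x[i] <- sum(sxc * yxc) / sum(sxc^2)
    ms <- seq(min(Sx) + 1L, max(Sx))
    if (!length(ms) || length(unique(Sx)) < 2) {
      margin_term[i] <- 0
      next
    }
    grp <- pool_margins(Sx, ms, min_cell)
    groups <- unique(grp)
    lam_ols <- lam_iv <- b_xs <- numeric(length(groups))
    for (g in seq_along(groups)) {
      I <- rowSums(outer(Sx, ms[grp == groups[g]], ">="))
      Ic <- I - mean(I)
      den_ols <- sum(sxc * Ic)
      den_iv_total <- sum(zxc * (Sx - mean(Sx)))
      lam_ols[g] <- den_ols / sum(sxc^2)
      lam_iv[g] <- sum(zxc * Ic) / den_iv_total
      b_xs[g] <- if (abs(den_ols) > 1e-10) sum(yxc * Ic) / den_ols else 0
    }
    margin_tabs[[as.character(stab$stratum[i])]] <-
      data.frame(group = groups, lambda_ols = lam_ols, lambda_iv = lam_iv,
                 increment = b_xs)
    margin_term[i] <- sum((lam_iv - lam_ols) * b_xs)
  }
  w_margin <- switch(order, covariate_first = stab$w_iv,
                     margin_first = stab$w_ols)
  covariate_component <- sum((stab$w_iv - stab$w_ols) * b_x)
  margin_component <- sum(w_margin * margin_term)
  residual_component <- gap - covariate_component - margin_component
  comp <- c(covariate = covariate_component, margin = margin_component,
            residual = residual_component)
  overall_ols <- margin_weights(sample, "ols", outcome, covariates, instrument)
  overall_iv <- margin_weights(sample, "iv", outcome, covariates, instrument)
  structure(
    list(theta_iv = theta_iv, theta_ols = theta_ols, gap = gap,
         components = comp,
         shares = if (abs(gap) > 0) 100 * comp / abs(gap) else comp * NA,
         stratum_weights = stab, stratum_effects = b_x,
         margin_tables = margin_tabs,
         margin_weights_ols = overall_ols, margin_weights_iv = overall_iv,
         order = order),
    class = "mr_ols_decomposition"
  )
}

#' @export
print.mr_ols_decomposition <- function(x, ...) {
  cat("<mr_ols_decomposition>\n")
  cat(sprintf("  theta_IV = %.5f, theta_OLS = %.5f, gap = %.5f\n",
              x$theta_iv, x$theta_ols, x$gap))
  cat(sprintf("  components (%s): covariate %.5f, margin %.5f, residual %.5f\n",
              x$order, x$components["covariate"], x$components["margin"],
              x$components["residual"]))
  if (!anyNA(x$shares)) {
    cat(sprintf("  shares of |gap|: %.1f%% / %.1f%% / %.1f%%\n",
                x$shares["covariate"], x$shares["margin"],
                x$shares["residual"]))
  }
  invisible(x)
}

#' Monotonicity (defier) check from the IV weights
#'
#' Instrument monotonicity implies nonnegative IV weights on every
#' covariate stratum (the testable implication used in practice) and, in
#' expectation, on every schooling margin. The pass criterion uses the
#' stratum weights; margin weights at sparsely populated schooling levels
#' are noise-dominated in finite samples and are reported for inspection
#' (set `include_margins = TRUE` to make them part of the criterion).
#'
#' @param decomposition an `mr_ols_decomposition`.
#' @param tol numerical tolerance, default 1e-8.
#' @param include_margins include the per-margin IV weights in the pass
#'   criterion, default `FALSE`.
#' @return a list with `pass`, `min_margin_weight`, `min_stratum_weight`,
#'   `negative_strata`.
#' @export
monotonicity_check <- function(decomposition, tol = 1e-8,
                               include_margins = FALSE) {
  stopifnot(inherits(decomposition, "mr_ols_decomposition"))
  mw <- min(decomposition$margin_weights_iv$weight)
  sw <- decomposition$stratum_weights
  min_sw <- min(sw$w_iv)
  bad <- sw$stratum[sw$w_iv < -tol]
  list(
    pass = min_sw >= -tol && (!include_margins || mw >= -tol),
    min_margin_weight = mw,
    min_stratum_weight = min_sw,
    negative_strata = as.character(bad)
  )
}
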