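#' Per-SNP exposure and outcome association summary statistics
#'
#' For each SNP in a genotyped sample, runs covariate-adjusted regressions of
#' the exposure (years of schooling) and of the outcome (log prime-age
#' earnings) on the effect-allele count, then harmonizes alleles so every
#' exposure association is nonnegative. Monomorphic SNPs are dropped with a
#' warning.
#'
#' @param sample a genotyped `analysis_sample` (must carry `G`).
#' @param covariates covariate columns to adjust for; default the sample's
#'   covariate set; `character(0)` for crude associations.
#' @return a `snp_summary` data frame with columns `snp`, `ea`, `nea`,
#'   `eaf`, `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @export
per_snp_associations <- function(sample, covariates = NULL) {
  stopifnot(inherits(sample, "analysis_sample"), !is.null(sample$G))
  if (is.null(covariates)) covariates <- sample$covariates
  data <- sample$data
  keep <- is.finite(data$log_prime_earn)
  data <- data[keep, , drop = FALSE]
  G <- sample$G[keep, , drop = FALSE]
  n <- nrow(data)
  X <- cbind(1, covariate_matrix(data, covariates))
  qrX <- qr(X)
  y <- qr.resid(qrX, data$log_prime_earn)
  s <- qr.resid(qrX, as.numeric(data$schooling))
  mono <- apply(G, 2, function(g) length(unique(g)) == 1)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped")
  }
  snp_names <- if (!is.null(colnames(G))) colnames(G) else paste0("rs", seq_len(ncol(G)))
  Gk <- G[, !mono, drop = FALSE]
  eaf <- colMeans(Gk) / 2
  Gt <- qr.resid(qrX, Gk)
  den <- colSums(Gt^2)
  k <- ncol(X) + 1
  slope_se <- function(v) {
    b <- colSums(Gt * v) / den
    rss <- sum(v^2) - b^2 * den
    se <- sqrt(pmax(rss, 0) / (n - k) / den)
    list(b = b, se = se)
  }
  ex <- slope_se(s)
  out <- slope_se(y)
  ss <- data.frame(
    snp = snp_names[!mono], ea = "A", nea = "G", eaf = eaf,
    beta_exp = ex$b, se_exp = ex$se, beta_out = out$b, se_out = out$se,
    stringsAsFactors = FALSE
  )
  harmonize_summary(ss)
}

#' Harmonize a SNP summary table so exposure associations are nonnegative
#'
#' Flips the effect/other allele labels (and the signs of both associations
#' and the allele frequency) for SNPs whose exposure association is
#' negative. Ratio estimates are invariant to this re-coding.
#'
#' @param summary a `snp_summary` data frame.
#' @return the harmonized `snp_summary`.
#' @export
harmonize_summary <- function(summary) {
  flip <- summary$beta_exp < 0
  if (any(flip)) {
    ea <- summary$ea[flip]
    summary$ea[flip] <- summary$nea[flip]
    summary$nea[flip] <- ea
    summary$eaf[flip] <- 1 - summary$eaf[flip]
    summary$beta_exp[flip] <- -summary$beta_exp[flip]
    summary$beta_out[flip] <- -summary$beta_out[flip]
  }
  class(summary) <- c("snp_summary", "data.frame")
  summary
}

check_summary <- function(summary, min_snps = 1, caller = "estimator") {
  stopifnot(is.data.frame(summary))
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(need, names(summary))
  if (length(missing)) stop("summary table lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(summary) < min_snps) {
    stop(caller, " requires at least ", min_snps, " SNPs", call. = FALSE)
  }
  if (any(summary$se_exp <= 0) || any(summary$se_out <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  summary
}

new_mr_result <- function(method, estimate, se, level = 0.95, df = Inf, ...) {
  tq <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df) else
    stats::qnorm(1 - (1 - level) / 2)
  structure(
    c(list(method = method, estimate = estimate, se = se,
           ci = c(estimate - tq * se, estimate + tq * se), level = level),
      list(...)),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: %.5f (se %.5f), %.0f%% CI [%.5f, %.5f], %d SNPs\n",
              x$method, x$estimate, x$se, 100 * x$level, x$ci[1], x$ci[2],
              x$n_snps))
  if (!is.null(x$Q)) {
    cat(sprintf("  Cochran Q = %.2f on %d df (p = %.3g)\n", x$Q, x$Q_df, x$Q_p))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept = %.3g, %.0f%% CI [%.3g, %.3g]\n",
                x$intercept, 100 * x$level, x$intercept_ci[1], x$intercept_ci[2]))
  }
  invisible(x)
}

# IVW weights: instrument strength over outcome noise.
ivw_weights <- function(summary) summary$beta_exp^2 / summary$se_out^2

#' Inverse-variance weighted MR
#'
#' The weighted mean of per-SNP Wald ratios `beta_out/beta_exp` with weights
#' `beta_exp^2/se_out^2` (equivalently, weighted regression of the outcome
#' association on the exposure association through the origin), with
#' Cochran's Q heterogeneity statistic and a multiplicative random-effects
#' standard error (dispersion never shrunk below 1).
#'
#' @param summary a harmonized `snp_summary`.
#' @param level confidence level.
#' @return an `mr_result` with fields `Q`, `Q_df`, `Q_p`.
#' @export
mr_ivw <- function(summary, level = 0.95) {
  summary <- check_summary(summary, 1, "IVW")
  zero <- summary$beta_exp == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with zero exposure association excluded")
    summary <- summary[!zero, , drop = FALSE]
    check_summary(summary, 1, "IVW")
  }
  w <- ivw_weights(summary)
  b <- summary$beta_out / summary$beta_exp
  est <- sum(w * b) / sum(w)
  Q <- sum(w * (b - est)^2)
  df <- nrow(summary) - 1
  disp <- if (df > 0) max(1, Q / df) else 1
  se <- sqrt(disp / sum(w))
  new_mr_result("IVW", est, se, level,
                n_snps = nrow(summary), Q = Q, Q_df = df,
                Q_p = if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE)
                      else NA_real_)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations with an intercept, weights `1/se_out^2`. The slope is the
#' pleiotropy-adjusted causal estimate (valid when instrument strength is
#' independent of direct effects, InSIDE); the intercept estimates the
#' average directional pleiotropic effect and its CI is the Egger intercept
#' test.
#'
#' @inheritParams mr_ivw
#' @return an `mr_result` with `intercept`, `intercept_se`, `intercept_ci`.
#' @export
mr_egger <- function(summary, level = 0.95) {
  summary <- check_summary(summary, 3, "MR-Egger")
  if (stats::sd(summary$beta_exp) < 1e-12) {
    stop("all exposure associations equal: Egger design is collinear",
         call. = FALSE)
  }
  w <- 1 / summary$se_out^2
  fit <- stats::lm(beta_out ~ beta_exp, data = summary, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  df <- nrow(summary) - 2
  # multiplicative random effects: dispersion floor at 1
  infl <- max(1, sm$sigma) / sm$sigma
  slope_se <- co["beta_exp", "Std. Error"] * infl
  int_se <- co["(Intercept)", "Std. Error"] * infl
  tq <- stats::qt(1 - (1 - level) / 2, df)
  res <- new_mr_result("MR-Egger", co["beta_exp", "Estimate"], slope_se, level,
                       df = df, n_snps = nrow(summary),
                       intercept = co["(Intercept)", "Estimate"],
                       intercept_se = int_se)
  res$intercept_ci <- c(res$intercept - tq * int_se, res$intercept + tq * int_se)
  res
}

weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(b)] <= 0.5) return(b[length(b)])
  below <- max(which(cum < 0.5))
  b[below] + (b[below + 1] - b[below]) * (0.5 - cum[below]) /
    (cum[below + 1] - cum[below])
}

#' Weighted-median MR
#'
#' The weighted median of per-SNP Wald ratios under IVW weights: consistent
#' when at least half the weight comes from valid instruments. The standard
#' error is a parametric bootstrap over the summary statistics.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates, default 1000.
#' @param weighted use IVW weights (`TRUE`) or equal weights.
#' @return an `mr_result`.
#' @export
mr_weighted_median <- function(summary, n_boot = 1000, weighted = TRUE,
                               level = 0.95) {
  summary <- check_summary(summary, 3, "weighted median")
  w <- if (weighted) ivw_weights(summary) else rep(1, nrow(summary))
  b <- summary$beta_out / summary$beta_exp
  est <- weighted_median_point(b, w)
  boot <- boot_summary(summary, n_boot, function(s) {
    wb <- if (weighted) ivw_weights(s) else rep(1, nrow(s))
    weighted_median_point(s$beta_out / s$beta_exp, wb)
  })
  new_mr_result(if (weighted) "MR-Median (weighted)" else "MR-Median (simple)",
                est, boot, level, n_snps = nrow(summary))
}

boot_summary <- function(summary, n_boot, statistic) {
  m <- nrow(summary)
  reps <- vapply(seq_len(n_boot), function(i) {
    s <- summary
    s$beta_exp <- stats::rnorm(m, summary$beta_exp, summary$se_exp)
    s$beta_out <- stats::rnorm(m, summary$beta_out, summary$se_out)
    statistic(s)
  }, numeric(1))
  stats::sd(reps)
}

# Modified Silverman bandwidth on the ratio estimates.
mode_bandwidth <- function(b, factor = 1) {
  n <- length(b)
  s <- min(stats::sd(b), stats::mad(b))
  if (s <= 0) s <- stats::sd(b)
  if (s <= 0) s <- 1e-8
  factor * 0.9 * s * n^(-1 / 5)
}

mode_point <- function(b, w, bandwidth_factor) {
  h <- mode_bandwidth(b, bandwidth_factor)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 2048)
  dens <- colSums(w / sum(w) * stats::dnorm(outer(b, grid, "-") / h)) / h
  grid[which.max(dens)]
}

#' Mode-based MR estimator
#'
#' Kernel-smoothed mode of the per-SNP Wald ratios (normal kernel, modified
#' Silverman bandwidth scaled by `bandwidth_factor`), optionally
#' IVW-weighted. Consistent when the largest group of SNPs with the same
#' ratio are valid instruments (ZEMPA). Bootstrap standard error. Ties
#' between density peaks are broken toward the mode carrying more total
#' nearby weight and flagged.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor multiplier on the modified Silverman bandwidth.
#' @return an `mr_result` with a `tie` flag.
#' @export
mr_mode <- function(summary, bandwidth_factor = 1, weighted = FALSE,
                    n_boot = 1000, level = 0.95) {
  summary <- check_summary(summary, 3, "MR-Mode")
  b <- summary$beta_out / summary$beta_exp
  w <- if (weighted) ivw_weights(summary) else rep(1, length(b))
  h <- mode_bandwidth(b, bandwidth_factor)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 2048)
  dens <- colSums(w / sum(w) * stats::dnorm(outer(b, grid, "-") / h)) / h
  peak <- max(dens)
  is_peak <- which(dens >= peak * (1 - 1e-9))
  tie <- FALSE
  est <- grid[which.max(dens)]
  if (length(is_peak) > 1) {
    gaps <- which(diff(is_peak) > 1)
    if (length(gaps)) {
      tie <- TRUE
      cand <- grid[is_peak[c(1, gaps + 1)]]
      near_w <- vapply(cand, function(m) sum(w[abs(b - m) <= h]), numeric(1))
      est <- cand[which.max(near_w)]
    }
  }
  boot <- boot_summary(summary, n_boot, function(s) {
    wb <- if (weighted) ivw_weights(s) else rep(1, nrow(s))
    mode_point(s$beta_out / s$beta_exp, wb, bandwidth_factor)
  })
  new_mr_result(if (weighted) "MR-Mode (weighted)" else "MR-Mode (simple)",
                est, boot, level, n_snps = nrow(summary), tie = tie,
                bandwidth = h)
}

#' Core-gene (ranked-strength) MR
#'
#' Ranks SNPs by instrument strength `beta_exp^2/se_exp^2`, partitions them
#' into `n_groups` ranked groups, and reports the IVW estimate within the
#' core (strongest) group together with the trajectory of cumulative-group
#' IVW estimates. Valid when the strongest instruments are free of
#' pleiotropy.
#'
#' @inheritParams mr_ivw
#' @param n_groups number of ranked groups (>= 2), default 10.
#' @return an `mr_result` whose `trajectory` is a data frame of cumulative
#'   estimates, and `groups` gives each SNP's group.
#' @export
mr_corge <- function(summary, n_groups = 10, level = 0.95) {
  if (n_groups < 2) stop("n_groups must be >= 2", call. = FALSE)
  summary <- check_summary(summary, n_groups, "MR-Corge")
  strength <- summary$beta_exp^2 / summary$se_exp^2
  rk <- rank(-strength, ties.method = "first")
  grp <- ceiling(rk / (nrow(summary) / n_groups))
  grp <- pmin(grp, n_groups)
  traj <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    sub <- summary[grp <= g, , drop = FALSE]
    fit <- mr_ivw(sub, level)
    data.frame(group = g, n_snps = nrow(sub), estimate = fit$estimate,
               se = fit$se, ci_low = fit$ci[1], ci_high = fit$ci[2])
  }))
  core <- mr_ivw(summary[grp == 1, , drop = FALSE], level)
  res <- new_mr_result("MR-Corge (core group)", core$estimate, core$se, level,
                       n_snps = sum(grp == 1))
  res$trajectory <- traj
  res$groups <- grp
  res
}

#' Leave-one-out sensitivity for summary-level MR
#'
#' Recomputes the chosen estimator omitting one SNP at a time and flags
#' SNPs whose omission shifts the estimate by more than `flag_multiple`
#' full-sample standard errors.
#'
#' @inheritParams mr_ivw
#' @param estimator a summary-MR function (e.g. [mr_ivw], [mr_egger]).
#' @param flag_multiple flag threshold in full-sample SEs, default 1.
#' @param ... passed to `estimator`.
#' @return a data frame with one row per omitted SNP (`snp`, `estimate`,
#'   `shift`, `flag`); attribute `full` holds the full-sample result.
#' @export
mr_leave_one_out <- function(summary, estimator = mr_ivw, flag_multiple = 1,
                             ...) {
  summary <- check_summary(summary, 4, "leave-one-out")
  full <- estimator(summary, ...)
  est <- vapply(seq_len(nrow(summary)), function(j) {
    estimator(summary[-j, , drop = FALSE], ...)$estimate
  }, numeric(1))
  out <- data.frame(
    snp = if (!is.null(summary$snp)) summary$snp else seq_len(nrow(summary)),
    estimate = est,
    shift = est - full$estimate,
    flag = abs(est - full$estimate) > flag_multiple * full$se,
    stringsAsFactors = FALSE
  )
  attr(out, "full") <- full
  out
}
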