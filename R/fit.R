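# Within-group demeaning; g is any grouping vector.
demean_within <- function(M, g) {
  grp <- as.integer(factor(g))
  if (is.null(dim(M))) {
    M - (rowsum(M, grp)[, 1] / tabulate(grp))[grp]
  } else {
    means <- rowsum(M, grp) / tabulate(grp)
    M - means[grp, , drop = FALSE]
  }
}

# Residualize columns of M on design X (no-op when X has no columns).
partial_out <- function(M, qr_x) {
  if (is.null(qr_x)) return(M)
  qr.resid(qr_x, M)
}

# Sum over clusters of (sum_i g_i u_i)^2; cl may be a factor of any type.
cluster_meat <- function(score, cl) {
  sums <- rowsum(score, as.integer(factor(cl)))
  sum(sums^2)
}

# Small-sample correction G/(G-1) * (n-1)/(n-k)
cluster_correction <- function(G, n, k) {
  if (G <= 1) return(1)
  G / (G - 1) * (n - 1) / max(n - k, 1)
}

# Cluster-robust variance of a ratio estimator b = sum(g*y)/D with residual u.
# Supports one-way ("cl" vector) and two-way (list of two vectors,
# inclusion-exclusion) clustering.
ratio_se <- function(g_vec, u, D, cl, k) {
  n <- length(u)
  score <- g_vec * u
  if (is.list(cl)) {
    cl12 <- interaction(cl[[1]], cl[[2]], drop = TRUE)
    parts <- list(cl[[1]], cl[[2]], cl12)
    signs <- c(1, 1, -1)
    v <- 0
    for (i in 1:3) {
      G <- length(unique(parts[[i]]))
      v <- v + signs[i] * cluster_correction(G, n, k) *
        cluster_meat(score, parts[[i]])
    }
    G_eff <- min(length(unique(cl[[1]])), length(unique(cl[[2]])))
    list(se = sqrt(max(v, 0)) / abs(D), n_clusters = G_eff)
  } else {
    G <- length(unique(cl))
    v <- cluster_correction(G, n, k) * cluster_meat(score, cl)
    list(se = sqrt(v) / abs(D), n_clusters = G)
  }
}

# Build the covariate design matrix (numeric columns only, as simulated).
covariate_matrix <- function(data, covariates) {
  if (is.null(covariates) || !length(covariates)) {
    return(matrix(numeric(0), nrow(data), 0))
  }
  missing <- setdiff(covariates, names(data))
  if (length(missing)) {
    stop("covariate(s) not in sample: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  X
}

resolve_cluster <- function(data, cluster, method) {
  if (is.null(cluster)) {
    cluster <- if (method %in% c("fe", "sibmr")) {
      c("family_id", "birth_year")
    } else {
      "birth_year"
    }
  }
  if (is.list(cluster)) {
    return(lapply(cluster, function(v) data[[v]]))
  }
  if (length(cluster) == 2) {
    # the paper-style intersection of the two grouping variables
    return(interaction(data[[cluster[1]]], data[[cluster[2]]], drop = TRUE))
  }
  data[[cluster]]
}

prepare_fit <- function(sample, outcome, method, covariates, cluster,
                        instrument, outcome_vector = NULL) {
  data <- if (inherits(sample, "analysis_sample")) sample$data else sample
  if (is.null(covariates)) {
    covariates <- if (inherits(sample, "analysis_sample")) sample$covariates
  }
  y <- if (!is.null(outcome_vector)) {
    outcome_vector
  } else if (outcome == "log") {
    data$log_prime_earn
  } else {
    data$prime_earn
  }
  s <- as.numeric(data$schooling)
  z <- if (method %in% c("mr", "sibmr")) {
    if (is.character(instrument)) data[[instrument]] else as.numeric(instrument)
  }
  keep <- is.finite(y) & is.finite(s)
  if (!is.null(z)) keep <- keep & is.finite(z)
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]; s <- s[keep]
  if (!is.null(z)) z <- z[keep]
  X <- covariate_matrix(data, covariates)
  fe <- method %in% c("fe", "sibmr")
  n_absorbed <- 0L
  dropped_cov <- character(0)
  if (fe) {
    sizes <- table(data$family_id)
    in_fam <- data$family_id %in% as.integer(names(sizes)[sizes >= 2])
    data <- data[in_fam, , drop = FALSE]
    y <- y[in_fam]; s <- s[in_fam]
    if (!is.null(z)) z <- z[in_fam]
    X <- X[in_fam, , drop = FALSE]
    if (!nrow(data)) stop("no families with >= 2 members after filtering",
                          call. = FALSE)
    g <- data$family_id
    y <- demean_within(y, g)
    s <- demean_within(s, g)
    if (!is.null(z)) z <- demean_within(z, g)
    if (ncol(X)) {
      X <- demean_within(X, g)
      wv <- apply(X, 2, function(c) sqrt(mean(c^2)))
      const <- wv < 1e-10
      dropped_cov <- colnames(X)[const]
      X <- X[, !const, drop = FALSE]
      if (ncol(X)) {
        # parental ages etc. become collinear with birth year within family
        qrd <- qr(X)
        if (qrd$rank < ncol(X)) {
          dep <- colnames(X)[qrd$pivot[-seq_len(qrd$rank)]]
          dropped_cov <- c(dropped_cov, dep)
          X <- X[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
        }
      }
    }
    n_absorbed <- length(unique(g))
    if (sqrt(mean(s^2)) < 1e-12) {
      stop("no within-family variation in schooling (degenerate sample)",
           call. = FALSE)
    }
  } else {
    if (ncol(X)) {
      # constants (e.g. birth order in a singleton-family sample) carry no
      # information and are absorbed by the intercept
      const <- apply(X, 2, function(c) stats::sd(c) < 1e-12)
      dropped_cov <- colnames(X)[const]
      X <- X[, !const, drop = FALSE]
    }
    X <- cbind(`(Intercept)` = 1, X)
  }
  qr_x <- if (ncol(X)) qr(X)
  if (!is.null(qr_x) && qr_x$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qr_x$rank)]
    piv <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("rank-deficient covariate design; offending column(s): ",
         paste(piv, collapse = ", "), call. = FALSE)
  }
  list(
    y = partial_out(y, qr_x), s = partial_out(s, qr_x),
    z = if (!is.null(z)) partial_out(z, qr_x),
    cl = resolve_cluster(data, cluster, method),
    n = length(y),
    k = (if (is.null(qr_x)) 0 else ncol(X)) + 1 + n_absorbed,
    data = data, dropped_covariates = dropped_cov,
    n_dropped_rows = n_dropped
  )
}

#' Fit a returns-to-schooling model
#'
#' The central fitting function: regresses (log or absolute) prime-age
#' earnings on years of schooling with covariate adjustment, using one of
#' four identification strategies:
#' \describe{
#'   \item{`"ols"`}{pooled OLS.}
#'   \item{`"fe"`}{family fixed effects (within-family demeaning); used for
#'     the sibling and the DZ/MZ twin models. Covariates constant within
#'     family are dropped.}
#'   \item{`"mr"`}{just-identified two-stage least squares with the
#'     polygenic index as instrument, covariates partialled out of outcome,
#'     exposure and instrument (Frisch-Waugh-Lovell).}
#'   \item{`"sibmr"`}{MR with family fixed effects in the estimation stage
#'     (within-family demeaning of outcome, exposure, instrument and
#'     covariates before 2SLS).}
#' }
#' Inference is cluster-robust with the G/(G-1)(n-1)/(n-k) small-sample
#' correction; confidence intervals are Wald (t, G-1 df) or Anderson-Rubin
#' test inversion for IV models.
#'
#' @param sample an `analysis_sample` from [build_samples()], or a data
#'   frame with columns `schooling`, `prime_earn`/`log_prime_earn`,
#'   `family_id`, `birth_year` and the covariates.
#' @param outcome `"log"` (log prime-age earnings) or `"abs"` (absolute).
#' @param method `"ols"`, `"fe"`, `"mr"` or `"sibmr"`.
#' @param covariates character vector of covariate columns; defaults to the
#'   sample's covariate set. Use `character(0)` for no adjustment.
#' @param cluster cluster variable name, a length-2 character vector for the
#'   intersection of two grouping variables (the default for fixed-effects
#'   models is family x birth cohort, birth cohort otherwise), or a list of
#'   two vectors for two-way clustering by inclusion-exclusion.
#' @param instrument column name (default `"piv_std"`) or numeric vector.
#' @param ci_method `"wald"` or `"ar"` (IV models only).
#' @param level confidence level, default 0.95.
#' @param outcome_vector optional explicit outcome vector overriding
#'   `outcome` (used for age-specific earnings).
#' @return an object of class `returns_fit`.
#' @examples
#' pop <- simulate_population(sim_config(n_families = 2000, n_snps = 30), seed = 2)
#' smp <- build_samples(pop)
#' fit_returns(smp$full, "log", "ols")
#' @export
fit_returns <- function(sample, outcome = c("log", "abs"),
                        method = c("ols", "fe", "mr", "sibmr"),
                        covariates = NULL, cluster = NULL,
                        instrument = "piv_std",
                        ci_method = c("wald", "ar"), level = 0.95,
                        outcome_vector = NULL) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  ci_method <- match.arg(ci_method)
  if (ci_method == "ar" && !method %in% c("mr", "sibmr")) {
    stop("Anderson-Rubin intervals require an IV model", call. = FALSE)
  }
  pf <- prepare_fit(sample, outcome, method, covariates, cluster, instrument,
                    outcome_vector)
  y <- pf$y; s <- pf$s; z <- pf$z
  res <- list(
    method = method, outcome = outcome, level = level, ci_method = ci_method,
    n = pf$n, k = pf$k, dropped_covariates = pf$dropped_covariates,
    label = if (inherits(sample, "analysis_sample")) sample$label else "data",
    call = match.call()
  )
  if (method %in% c("ols", "fe")) {
    D <- sum(s^2)
    if (D < 1e-12) stop("no variation in schooling", call. = FALSE)
    beta <- sum(s * y) / D
    u <- y - beta * s
    sv <- ratio_se(s, u, D, pf$cl, pf$k)
  } else {
    Dz <- sum(z^2)
    Dzs <- sum(z * s)
    if (abs(Dzs) < 1e-10 * sqrt(Dz * sum(s^2)) || Dz < 1e-12) {
      stop("weak or zero first stage: instrument does not move schooling",
           call. = FALSE)
    }
    beta <- sum(z * y) / Dzs
    u <- y - beta * s
    sv <- ratio_se(z, u, Dzs, pf$cl, pf$k)
    fs <- Dzs / Dz
    fs_se <- ratio_se(z, s - fs * z, Dz, pf$cl, pf$k)$se
    rf <- sum(z * y) / Dz
    rf_se <- ratio_se(z, y - rf * z, Dz, pf$cl, pf$k)$se
    res$first_stage_beta <- fs
    res$first_stage_se <- fs_se
    res$reduced_form_beta <- rf
    res$reduced_form_se <- rf_se
    res$F_first_stage <- (fs / fs_se)^2
  }
  res$beta <- beta
  res$se <- sv$se
  res$n_clusters <- sv$n_clusters
  df <- max(sv$n_clusters - 1, 1)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  res$ci <- c(beta - tq * res$se, beta + tq * res$se)
  if (ci_method == "ar") {
    ar <- ar_interval_core(y, s, z, pf$cl, pf$k, level)
    res$ci <- ar$ci
    res$ar_unbounded <- ar$unbounded
  }
  class(res) <- "returns_fit"
  res
}

# Anderson-Rubin machinery on partialled vectors.
ar_stat_core <- function(b, y, s, z, cl, k) {
  r <- y - b * s
  Dz <- sum(z^2)
  cz <- sum(z * r) / Dz
  se <- ratio_se(z, r - cz * z, Dz, cl, k)$se
  (cz / se)^2
}

ar_interval_core <- function(y, s, z, cl, k, level = 0.95) {
  G <- if (is.list(cl)) min(lengths(lapply(cl, unique))) else length(unique(cl))
  df <- max(G - 1, 1)
  crit <- stats::qf(level, 1, df)
  b0 <- sum(z * y) / sum(z * s)
  wald_se <- ratio_se(z, y - b0 * s, sum(z * s), cl, k)$se
  f <- function(b) ar_stat_core(b, y, s, z, cl, k) - crit
  find_side <- function(dir) {
    width <- 10 * wald_se
    for (i in 1:10) {
      b_far <- b0 + dir * width
      if (f(b_far) > 0) {
        return(stats::uniroot(f, sort(c(b0, b_far)), tol = 1e-10)$root)
      }
      width <- width * 2
    }
    dir * Inf
  }
  lo <- find_side(-1)
  hi <- find_side(1)
  list(ci = c(lo, hi), unbounded = !is.finite(lo) || !is.finite(hi))
}

#' Anderson-Rubin p-value function and confidence interval
#'
#' Inverts the weak-instrument-robust Anderson-Rubin test for a
#' just-identified IV model: for candidate coefficient `b`, the statistic is
#' the cluster-robust Wald test that the instrument coefficient is zero in a
#' regression of `y - b*s` on the instrument (covariates partialled out).
#' The confidence set is `{b : p(b) >= 1 - level}` with endpoints located by
#' root bisection from a bracket that is widened until the statistic crosses
#' its critical value; a side that never crosses is reported as unbounded.
#'
#' @inheritParams fit_returns
#' @param grid optional numeric vector of candidate values at which to
#'   return the p-value function.
#' @return a list with `p_value` (a function of b), `ci_low`, `ci_high`,
#'   `unbounded`, and `grid_p` (p-values on `grid` if supplied).
#' @export
ar_confidence_interval <- function(sample, outcome = c("log", "abs"),
                                   method = c("mr", "sibmr"),
                                   covariates = NULL, cluster = NULL,
                                   instrument = "piv_std", level = 0.95,
                                   grid = NULL, outcome_vector = NULL) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  pf <- prepare_fit(sample, outcome, method, covariates, cluster, instrument,
                    outcome_vector)
  cl <- pf$cl
  G <- if (is.list(cl)) min(lengths(lapply(cl, unique))) else length(unique(cl))
  df <- max(G - 1, 1)
  pfun <- function(b) {
    stats::pf(ar_stat_core(b, pf$y, pf$s, pf$z, cl, pf$k), 1, df,
              lower.tail = FALSE)
  }
  ar <- ar_interval_core(pf$y, pf$s, pf$z, cl, pf$k, level)
  list(
    p_value = pfun,
    ci_low = ar$ci[1], ci_high = ar$ci[2], unbounded = ar$unbounded,
    grid_p = if (!is.null(grid)) vapply(grid, pfun, numeric(1))
  )
}

#' @export
print.returns_fit <- function(x, ...) {
  lab <- c(ols = "OLS", fe = "family fixed effects", mr = "MR (2SLS)",
           sibmr = "sibling-MR")[x$method]
  cat(sprintf("<returns_fit> %s, %s earnings, sample '%s'\n", lab, x$outcome,
              x$label))
  cat(sprintf("  beta = %.5f (se %.5f), %s %.0f%% CI [%.5f, %.5f]\n",
              x$beta, x$se, toupper(x$ci_method), 100 * x$level,
              x$ci[1], x$ci[2]))
  cat(sprintf("  n = %d, clusters = %d\n", x$n, x$n_clusters))
  if (!is.null(x$F_first_stage)) {
    cat(sprintf("  first stage = %.4f (F = %.1f), reduced form = %.5f\n",
                x$first_stage_beta, x$F_first_stage, x$reduced_form_beta))
  }
  invisible(x)
}

#' @export
coef.returns_fit <- function(object, ...) c(schooling = object$beta)

#' @export
vcov.returns_fit <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("schooling", "schooling"))
}

#' @export
nobs.returns_fit <- function(object, ...) object$n

#' @export
confint.returns_fit <- function(object, parm, level = NULL, ...) {
  ci <- matrix(object$ci, 1, 2,
               dimnames = list("schooling", c("low", "high")))
  ci
}

#' @export
summary.returns_fit <- function(object, ...) {
  object
}

#' Covariate balance tests for the polygenic instrument
#'
#' Regresses the standardized instrument on each standardized covariate
#' (optionally after within-family demeaning) with cluster-robust inference,
#' plus a joint Wald test of all covariates.
#'
#' @param sample an `analysis_sample` (or data frame with `piv_std`).
#' @param covariates covariates to test; defaults to the sample's set.
#' @param within_family demean instrument and covariates within family
#'   before testing (the genetic-lottery-conditional-on-parents check).
#' @param cluster cluster variable, default `"family_id"`.
#' @return a list with `table` (per-covariate coefficient, se, CI),
#'   `joint_chisq`, `joint_df`, `joint_p`, and `skipped`.
#' @export
balance_test <- function(sample, covariates = NULL, within_family = FALSE,
                         cluster = "family_id", level = 0.95) {
  data <- if (inherits(sample, "analysis_sample")) sample$data else sample
  if (is.null(covariates)) {
    covariates <- if (inherits(sample, "analysis_sample")) sample$covariates
    else setdiff(names(data), c("piv_std", "family_id"))
  }
  z <- as.numeric(scale(data$piv_std))
  X <- covariate_matrix(data, covariates)
  sds <- apply(X, 2, stats::sd)
  skipped <- covariates[!is.finite(sds) | sds == 0]
  if (length(skipped)) {
    warning("skipping constant covariate(s): ", paste(skipped, collapse = ", "))
  }
  X <- scale(X[, is.finite(sds) & sds > 0, drop = FALSE])
  g <- data$family_id
  if (within_family) {
    sizes <- table(g)
    in_fam <- g %in% as.integer(names(sizes)[sizes >= 2])
    if (!any(in_fam)) {
      warning("no multi-member families: all within-family entries skipped")
      return(list(table = NULL, joint_chisq = NA_real_, joint_df = 0L,
                  joint_p = NA_real_, skipped = covariates))
    }
    data <- data[in_fam, , drop = FALSE]
    z <- demean_within(z[in_fam], data$family_id)
    X <- demean_within(X[in_fam, , drop = FALSE], data$family_id)
    wv <- apply(X, 2, function(c) sqrt(mean(c^2)))
    skipped <- c(skipped, colnames(X)[wv < 1e-10])
    X <- X[, wv >= 1e-10, drop = FALSE]
  }
  cl <- data[[cluster]]
  n <- length(z)
  tab <- do.call(rbind, lapply(colnames(X), function(cn) {
    x <- X[, cn]
    D <- sum(x^2)
    b <- sum(x * z) / D
    sv <- ratio_se(x, z - b * x, D, cl, k = 2)
    tq <- stats::qt(1 - (1 - level) / 2, max(sv$n_clusters - 1, 1))
    data.frame(covariate = cn, coef = b, se = sv$se,
               ci_low = b - tq * sv$se, ci_high = b + tq * sv$se)
  }))
  joint <- joint_wald(z, X, cl, intercept = !within_family)
  list(table = tab, joint_chisq = joint$stat, joint_df = joint$df,
       joint_p = joint$p, skipped = unique(skipped))
}

# Multi-regressor cluster-robust Wald test that all slopes are zero.
# Linearly dependent columns (e.g. after within-family demeaning) are pruned.
joint_wald <- function(y, X, cl, intercept = TRUE) {
  if (!ncol(X)) return(list(stat = NA_real_, df = 0L, p = NA_real_))
  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  qr0 <- qr(Xd)
  if (qr0$rank < ncol(Xd)) {
    Xd <- Xd[, qr0$pivot[seq_len(qr0$rank)], drop = FALSE]
  }
  if (!ncol(Xd) || (intercept && ncol(Xd) < 2)) {
    return(list(stat = NA_real_, df = 0L, p = NA_real_))
  }
  qrX <- qr(Xd)
  b <- qr.coef(qrX, y)
  u <- qr.resid(qrX, y)
  XtXi <- solve(crossprod(Xd))
  grp <- as.integer(factor(cl))
  meat <- crossprod(rowsum(Xd * u, grp))
  G <- max(grp)
  V <- cluster_correction(G, length(y), ncol(Xd)) * XtXi %*% meat %*% XtXi
  idx <- if (intercept) -1 else seq_len(ncol(Xd))
  bs <- b[idx]
  Vs <- V[idx, idx, drop = FALSE]
  stat <- drop(t(bs) %*% solve(Vs, bs))
  df <- length(bs)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Subgroup estimates by a stratifying variable
#'
#' Runs [fit_returns()] separately within each stratum. Parental-earnings
#' quartiles are computed on the estimation sample with ties assigned to the
#' lower quartile.
#'
#' @param sample an `analysis_sample`.
#' @param stratifier `"sex"`, `"parent_earn_quartile"`, or any column name.
#' @param min_n strata smaller than this are omitted with a warning.
#' @inheritParams fit_returns
#' @return a list of `returns_fit` objects (one per stratum) with a
#'   `strata` attribute giving stratum sizes.
#' @export
stratified_estimates <- function(sample, stratifier = "sex",
                                 outcome = "log", method = "ols",
                                 covariates = NULL, min_n = 100, ...) {
  data <- sample$data
  strat <- if (stratifier == "parent_earn_quartile") {
    parent_earn_quartile(data$parent_log_earn)
  } else {
    data[[stratifier]]
  }
  if (length(unique(strat)) < 2) {
    stop("stratifier must have at least 2 levels", call. = FALSE)
  }
  if (is.null(covariates)) covariates <- sample$covariates
  covariates <- setdiff(covariates, stratifier)
  out <- list()
  sizes <- integer(0)
  for (lev in sort(unique(strat))) {
    rows <- which(strat == lev)
    if (length(rows) < min_n) {
      warning("stratum ", lev, " below minimum n; omitted")
      next
    }
    sub <- sample
    sub$data <- data[rows, , drop = FALSE]
    if (!is.null(sub$G)) sub$G <- sub$G[rows, , drop = FALSE]
    if (!is.null(sub$earnings)) sub$earnings <- sub$earnings[rows, , drop = FALSE]
    out[[as.character(lev)]] <- fit_returns(sub, outcome = outcome,
                                            method = method,
                                            covariates = covariates, ...)
    sizes[as.character(lev)] <- length(rows)
  }
  attr(out, "strata") <- sizes
  out
}

#' Parental-earnings quartiles with ties to the lower quartile
#' @param x parental (log) earnings.
#' @return integer quartile labels 1-4.
#' @export
parent_earn_quartile <- function(x) {
  br <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  1L + (x > br[1]) + (x > br[2]) + (x > br[3])
}
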