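#' Within-family SNP effects on schooling (family-based GWAS)
#'
#' Estimates each SNP's effect on years of schooling from sibling-demeaned
#' allele counts (family fixed effects), with standard errors clustered by
#' family. SNPs with no within-family genotype variation anywhere are
#' omitted (not zero-filled) with a warning. These weights are free of
#' family-level confounding (dynastic effects, assortative mating,
#' stratification) because within a sibship genotypes differ only through
#' the meiotic lottery.
#'
#' @param sibling_sample a genotyped `analysis_sample` whose families have
#'   >= 2 members (e.g. `genotyped_sibling` from [build_samples()]).
#' @param covariates optional covariates partialled out alongside the family
#'   fixed effects (default none).
#' @return an `fgwas_weights` data frame: `snp`, `beta`, `se`, `n_sibships`;
#'   attribute `discovery_families` records the family ids used.
#' @export
within_family_snp_effects <- function(sibling_sample, covariates = character(0)) {
  stopifnot(inherits(sibling_sample, "analysis_sample"),
            !is.null(sibling_sample$G))
  data <- sibling_sample$data
  G <- sibling_sample$G
  sizes <- table(data$family_id)
  keep <- data$family_id %in% as.integer(names(sizes)[sizes >= 2])
  data <- data[keep, , drop = FALSE]
  G <- G[keep, , drop = FALSE]
  if (!nrow(data)) stop("no sibships of size >= 2", call. = FALSE)
  fam <- data$family_id
  s <- demean_within(as.numeric(data$schooling), fam)
  Gd <- demean_within(G, fam)
  if (length(covariates)) {
    X <- demean_within(covariate_matrix(data, covariates), fam)
    wv <- apply(X, 2, function(c) sqrt(mean(c^2)))
    X <- X[, wv > 1e-10, drop = FALSE]
    if (ncol(X)) {
      qrX <- qr(X)
      s <- qr.resid(qrX, s)
      Gd <- qr.resid(qrX, Gd)
    }
  }
  den <- colSums(Gd^2)
  usable <- den > 1e-10
  if (any(!usable)) {
    warning(sum(!usable), " SNP(s) without within-family variation omitted")
  }
  snp_names <- if (!is.null(colnames(G))) colnames(G) else
    paste0("rs", seq_len(ncol(G)))
  Gd <- Gd[, usable, drop = FALSE]
  den <- den[usable]
  beta <- colSums(Gd * s) / den
  grp <- as.integer(factor(fam))
  # cluster-robust by family, per SNP
  resid_scores <- Gd * s - t(t(Gd^2) * beta)
  meat <- colSums(rowsum(resid_scores, grp)^2)
  Gn <- max(grp)
  n <- nrow(Gd)
  corr <- cluster_correction(Gn, n, 2 + length(unique(fam)))
  se <- sqrt(corr * meat) / den
  out <- data.frame(snp = snp_names[usable], beta = beta, se = se,
                    n_sibships = rep(Gn, sum(usable)),
                    stringsAsFactors = FALSE)
  attr(out, "discovery_families") <- unique(fam)
  class(out) <- c("fgwas_weights", "data.frame")
  out
}

#' Build a polygenic instrument from family-based GWAS weights
#'
#' Applies within-family SNP effect estimates as score weights on an
#' estimation sample whose families are disjoint from the discovery
#' sibships (enforced), standardizing within the estimation sample.
#'
#' @param estimation_sample a genotyped `analysis_sample`.
#' @param fgwas_weights an `fgwas_weights` object (or data frame with
#'   `snp`, `beta`).
#' @param discovery_families family ids of the discovery sample; defaults
#'   to the attribute recorded by [within_family_snp_effects()].
#' @return the estimation sample with a replaced `piv_raw`/`piv_std`
#'   (standardized FGWAS-weighted score) in its data.
#' @export
build_fgwas_piv <- function(estimation_sample, fgwas_weights,
                            discovery_families = attr(fgwas_weights,
                                                      "discovery_families")) {
  stopifnot(inherits(estimation_sample, "analysis_sample"),
            !is.null(estimation_sample$G))
  if (is.null(discovery_families)) {
    stop("discovery family ids are required to verify disjointness",
         call. = FALSE)
  }
  overlap <- intersect(unique(estimation_sample$data$family_id),
                       discovery_families)
  if (length(overlap)) {
    stop("discovery and estimation samples share ", length(overlap),
         " family id(s); they must be disjoint", call. = FALSE)
  }
  G <- estimation_sample$G
  snp_names <- if (!is.null(colnames(G))) colnames(G) else
    paste0("rs", seq_len(ncol(G)))
  idx <- match(fgwas_weights$snp, snp_names)
  if (anyNA(idx)) stop("FGWAS weights reference SNPs absent from the sample",
                       call. = FALSE)
  raw <- compute_piv(G[, idx, drop = FALSE], fgwas_weights$beta)
  estimation_sample$data$piv_raw <- raw
  estimation_sample$data$piv_std <- as.numeric(scale(raw))
  estimation_sample$label <- paste0(estimation_sample$label, "_fgwas")
  estimation_sample
}

#' Norway-only-style MR with a family-based GWAS instrument
#'
#' Two-stage least squares on a disjoint unrelated estimation sample with
#' the FGWAS-weighted polygenic score as instrument. Because the score
#' weights are themselves estimates, the 2SLS standard error conditional on
#' the weights understates the procedure's uncertainty (a generated-
#' regressor problem); the reported standard error therefore adds, in
#' quadrature, the dispersion of the estimate under parametric redraws of
#' the weights from their FGWAS sampling distribution.
#'
#' @param estimation_sample a genotyped `analysis_sample` with family ids
#'   disjoint from the discovery sibships.
#' @param fgwas_weights an `fgwas_weights` object from
#'   [within_family_snp_effects()].
#' @param n_weight_draws weight redraws for the uncertainty propagation,
#'   default 50 (set 0 to skip).
#' @inheritParams fit_returns
#' @return a `returns_fit` with extra fields `se_sampling` (conditional on
#'   weights) and `se_weights` (weight-uncertainty component).
#' @export
fgwas_mr <- function(estimation_sample, fgwas_weights,
                     outcome = c("log", "abs"), covariates = NULL,
                     cluster = NULL, level = 0.95, n_weight_draws = 50) {
  outcome <- match.arg(outcome)
  smp <- build_fgwas_piv(estimation_sample, fgwas_weights)
  fit <- fit_returns(smp, outcome = outcome, method = "mr",
                     covariates = covariates, cluster = cluster,
                     level = level)
  fit$se_sampling <- fit$se
  fit$se_weights <- 0
  if (n_weight_draws > 0) {
    betas <- vapply(seq_len(n_weight_draws), function(b) {
      wb <- fgwas_weights
      wb$beta <- stats::rnorm(nrow(wb), fgwas_weights$beta, fgwas_weights$se)
      sb <- build_fgwas_piv(estimation_sample, wb,
                            attr(fgwas_weights, "discovery_families"))
      fit_returns(sb, outcome = outcome, method = "mr",
                  covariates = covariates, cluster = cluster)$beta
    }, numeric(1))
    fit$se_weights <- stats::sd(betas)
    fit$se <- sqrt(fit$se_sampling^2 + fit$se_weights^2)
    tq <- stats::qt(1 - (1 - level) / 2, max(fit$n_clusters - 1, 1))
    fit$ci <- c(fit$beta - tq * fit$se, fit$beta + tq * fit$se)
    fit$ci_method <- "wald"
  }
  fit$label <- smp$label
  fit
}
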