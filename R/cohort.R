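#' Prime-age earnings: mean of the top earnings years in a window
#'
#' @param earnings_by_age named numeric vector (names are ages) or a matrix
#'   with ages as column names (one row per individual).
#' @param window inclusive age window, default ages 34 to 40.
#' @param k number of top years to average, default 3. If fewer years are
#'   observed in the window, the available years are averaged.
#' @return numeric scalar (or vector for a matrix input).
#' @export
prime_age_earnings <- function(earnings_by_age, window = c(34, 40), k = 3) {
  if (is.matrix(earnings_by_age)) {
    ages <- as.integer(colnames(earnings_by_age))
    keep <- which(ages >= window[1] & ages <= window[2])
    if (!length(keep)) stop("no observed ages in the earnings window", call. = FALSE)
    sub <- earnings_by_age[, keep, drop = FALSE]
    kk <- min(k, ncol(sub))
    return(apply(sub, 1, function(r) mean(sort(r, decreasing = TRUE)[seq_len(kk)])))
  }
  ages <- as.integer(names(earnings_by_age))
  if (is.null(ages) || anyNA(ages)) stop("earnings vector must be named by age",
                                         call. = FALSE)
  vals <- earnings_by_age[ages >= window[1] & ages <= window[2]]
  if (!length(vals)) stop("no observed ages in the earnings window", call. = FALSE)
  mean(sort(vals, decreasing = TRUE)[seq_len(min(k, length(vals)))])
}

#' Potential labor-market experience
#'
#' Years since labor-market entry, with entry at age `schooling + 7`
#' (school entry at 7). Pre-entry ages return 0.
#'
#' @param age age in years.
#' @param schooling_years completed years of schooling.
#' @return nonnegative years of potential experience.
#' @export
potential_experience <- function(age, schooling_years) {
  pmax(age - schooling_years - 7, 0)
}

default_covariates <- c("sex", "birth_year", "birth_order", "n_children",
                        "mother_edu", "father_edu", "parent_log_earn",
                        "mother_age_birth", "father_age_birth")

new_analysis_sample <- function(label, data, G = NULL, earnings = NULL,
                                covariates = default_covariates,
                                standardize_piv = TRUE) {
  if (standardize_piv && nrow(data) > 1 && stats::sd(data$piv_raw) > 0) {
    data$piv_std <- as.numeric(scale(data$piv_raw))
  }
  structure(
    list(label = label, data = data, G = G, earnings = earnings,
         covariates = covariates),
    class = "analysis_sample"
  )
}

#' @export
print.analysis_sample <- function(x, ...) {
  cat(sprintf("<analysis_sample> %s: n = %d, %d families\n", x$label,
              nrow(x$data), length(unique(x$data$family_id))))
  invisible(x)
}

#' Number of individuals in an analysis sample
#' @param object an `analysis_sample`.
#' @param ... unused.
#' @export
nobs.analysis_sample <- function(object, ...) nrow(object$data)

#' Construct the analysis samples from a simulated population
#'
#' Derives prime-age earnings (top-3 mean over ages 34-40) and log earnings,
#' applies the exclusion filters (positive prime-age earnings for the log
#' scale is tracked, parents always recorded in simulation), and builds the
#' sample inventory: full population, sibling, DZ-twin, MZ-twin, genotyped,
#' genotyped-sibling (the within-family GWAS discovery set) and
#' genotyped-unrelated (one offspring per genotyped family, disjoint from
#' the discovery sibships).
#'
#' @param population a `genpop` object.
#' @param covariates covariate column names to carry into every sample.
#' @param window,k prime-age earnings window and top-k, see
#'   [prime_age_earnings()].
#' @return a named list of `analysis_sample` objects with an attribute
#'   `flow_log` counting inclusions/exclusions per sample.
#' @export
build_samples <- function(population, covariates = default_covariates,
                          window = c(34, 40), k = 3) {
  stopifnot(inherits(population, "genpop"))
  off <- population$offspring
  off$prime_earn <- prime_age_earnings(population$earnings, window, k)
  off$log_prime_earn <- ifelse(off$prime_earn > 0, log(off$prime_earn), NA_real_)
  n_zero <- sum(off$prime_earn <= 0)

  flow <- list(total_offspring = nrow(off), zero_prime_earnings = n_zero)

  fam_sizes <- table(off$family_id)
  multi_fams <- as.integer(names(fam_sizes)[fam_sizes >= 2])

  take <- function(rows, label, with_geno = FALSE) {
    d <- off[rows, , drop = FALSE]
    new_analysis_sample(
      label, d,
      G = if (with_geno) population$G[rows, , drop = FALSE],
      earnings = population$earnings[rows, , drop = FALSE],
      covariates = covariates
    )
  }

  samples <- list()
  samples$full <- take(seq_len(nrow(off)), "full")
  sib_rows <- which(off$family_id %in% multi_fams)
  if (!length(sib_rows)) warning("no multi-offspring families: sibling sample is empty")
  samples$sibling <- take(sib_rows, "sibling")

  twin_rows <- function(z) {
    rows <- which(off$zygosity == z)
    fams <- off$family_id[rows]
    complete <- names(table(fams))[table(fams) == 2]
    rows[fams %in% as.integer(complete)]
  }
  samples$twin_dz <- take(twin_rows("DZ"), "twin_dz")
  samples$twin_mz <- take(twin_rows("MZ"), "twin_mz")

  gt_rows <- which(off$genotyped_family)
  samples$genotyped <- take(gt_rows, "genotyped", with_geno = TRUE)

  gt_fams <- unique(off$family_id[gt_rows])
  disc_fams <- intersect(gt_fams, multi_fams)
  gs_rows <- which(off$genotyped_family & off$family_id %in% disc_fams)
  samples$genotyped_sibling <- take(gs_rows, "genotyped_sibling", with_geno = TRUE)

  est_fams <- setdiff(gt_fams, disc_fams)
  cand <- off[off$genotyped_family & off$family_id %in% est_fams, ]
  first <- cand$id[!duplicated(cand$family_id)]
  gu_rows <- which(off$id %in% first)
  samples$genotyped_unrelated <- take(gu_rows, "genotyped_unrelated",
                                      with_geno = TRUE)

  flow$sample_sizes <- vapply(samples, function(s) nrow(s$data), integer(1))
  attr(samples, "flow_log") <- flow
  samples
}

#' Write the sample-construction flow log as JSON
#' @param samples result of [build_samples()].
#' @param path output path.
#' @export
write_flow_log <- function(samples, path) {
  jsonlite::write_json(attr(samples, "flow_log"), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
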