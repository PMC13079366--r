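#' Draw a panel of independent trait-associated SNPs
#'
#' Samples base effect-allele frequencies inside `config$allele_freq_range`,
#' true per-allele schooling effects scaled so that the true polygenic score
#' has SD `pi_first_stage` in schooling units (under Hardy-Weinberg at the
#' base frequencies), GWAS-style score weights (truth plus estimation noise
#' and optional nurture/stratification contamination), per-subpopulation
#' frequency offsets, and direct (pleiotropic) earnings effects for exactly
#' `round(pleio_fraction * n_snps)` SNPs chosen by a seeded shuffle.
#'
#' @param config a [sim_config()] object.
#' @return a `snp_panel` data frame with one row per SNP and columns
#'   `snp`, `effect_allele`, `other_allele`, `freq_1..freq_K`,
#'   `score_weight`, `true_schooling_effect`, `true_direct_effect`,
#'   `nurture_effect`, `strat_dir`.
#' @export
draw_snp_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps
  fr <- config$allele_freq_range
  p <- stats::runif(m, fr[1], fr[2])
  u <- stats::rnorm(m)
  scale_t <- config$pi_first_stage / sqrt(sum(2 * p * (1 - p) * u^2))
  t_eff <- u * scale_t
  sd_t <- stats::sd(t_eff)
  # degenerate cases (one SNP, or a null first stage): keep the weight
  # noise scale sane so the index still has variation
  if (!is.finite(sd_t) || sd_t == 0) sd_t <- max(abs(t_eff[1]), 1 / sqrt(m))
  # Nurture effects and stratification directions are made exactly
  # orthogonal to the true effects within the panel: the independence of the
  # confounding channels from the direct effects is an assumption about the
  # data-generating process, so finite-panel chance alignment (which would
  # confound even an ideal within-family analysis) is removed by design.
  orth <- function(v, basis) {
    if (m >= 3) {
      for (b in basis) {
        nb <- sum(b^2)
        if (nb > 0) v <- v - b * sum(v * b) / nb
      }
    }
    sdv <- stats::sd(v)
    if (is.finite(sdv) && sdv > 0) v / sdv else v
  }
  eta <- orth(stats::rnorm(m), list(t_eff))
  strat_dir <- switch(config$subpop_offset_mode,
    random = orth(stats::rnorm(m), list(t_eff, eta)),
    aligned = ifelse(t_eff >= 0, 1, -1)
  )
  w <- t_eff + sd_t * (config$weight_noise * stats::rnorm(m) +
                       config$weight_dynastic * eta +
                       config$weight_strat * strat_dir)
  n_pleio <- round(config$pleio_fraction * m)
  d_eff <- numeric(m)
  if (n_pleio > 0) {
    idx <- sample.int(m)[seq_len(n_pleio)]
    draw <- config$pleio_mean + stats::rnorm(n_pleio, 0, config$pleio_effect_sd)
    draw[draw == 0] <- config$pleio_effect_sd * 1e-6 + 1e-12
    d_eff[idx] <- sign(t_eff[idx]) * draw
  }
  freqs <- sapply(seq_len(config$n_subpops), function(k) {
    pmin(pmax(p + (k - 1) * config$subpop_freq_offset * strat_dir, 0.01), 0.99)
  })
  freqs <- matrix(freqs, nrow = m)
  colnames(freqs) <- paste0("freq_", seq_len(config$n_subpops))
  panel <- data.frame(
    snp = paste0("rs", seq_len(m)),
    effect_allele = "A",
    other_allele = "G",
    freqs,
    score_weight = w,
    true_schooling_effect = t_eff,
    true_direct_effect = d_eff,
    nurture_effect = eta,
    strat_dir = strat_dir,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

panel_freqs <- function(panel) {
  as.matrix(panel[, grep("^freq_", names(panel)), drop = FALSE])
}

# Binomial genotype draws, one subpopulation frequency vector per column block.
draw_genotypes <- function(n, freq, subpop) {
  m <- length(freq[, 1])
  G <- matrix(0L, n, m)
  for (k in seq_len(ncol(freq))) {
    rows <- which(subpop == k)
    if (!length(rows)) next
    G[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 2L, rep(freq[, k], each = length(rows))),
      nrow = length(rows)
    )
  }
  G
}

#' Simulate genotyped parent pairs
#'
#' Draws maternal and paternal genotypes from subpopulation allele
#' frequencies, induces the target spousal polygenic-score correlation by
#' Gaussian-copula rank matching within subpopulation, and generates the
#' parental phenotypes (education, log earnings, ages at first birth) that
#' seed the dynastic channel and the analysis covariates.
#'
#' @param config a [sim_config()] object.
#' @param panel a `snp_panel` from [draw_snp_panel()].
#' @return a list with elements `pairs` (data frame, one row per family),
#'   `G_mother` and `G_father` (integer genotype matrices).
#' @export
simulate_parent_pairs <- function(config, panel) {
  n <- config$n_families
  freq <- panel_freqs(panel)
  subpop <- sample.int(config$n_subpops, n, replace = TRUE)
  G_m <- draw_genotypes(n, freq, subpop)
  G_f <- draw_genotypes(n, freq, subpop)
  piv_m <- compute_piv(G_m, panel$score_weight)
  piv_f <- compute_piv(G_f, panel$score_weight)
  rho <- config$rho_assortative
  if (rho > 0) {
    perm <- seq_len(n)
    for (k in seq_len(config$n_subpops)) {
      rows <- which(subpop == k)
      nk <- length(rows)
      if (nk < 2) next
      zm <- stats::qnorm(rank(piv_m[rows], ties.method = "random") / (nk + 1))
      target <- rho * zm + sqrt(1 - rho^2) * stats::rnorm(nk)
      f_sorted <- rows[order(piv_f[rows])]
      perm[rows] <- f_sorted[rank(target, ties.method = "random")]
    }
    G_f <- G_f[perm, , drop = FALSE]
    piv_f <- piv_f[perm]
  }
  t_m <- compute_piv(G_m, panel$true_schooling_effect)
  t_f <- compute_piv(G_f, panel$true_schooling_effect)
  t_all_mean <- mean(c(t_m, t_f))
  t_all_sd <- stats::sd(c(t_m, t_f))
  if (!is.finite(t_all_sd) || t_all_sd == 0) t_all_sd <- 1
  tstd_m <- (t_m - t_all_mean) / t_all_sd
  tstd_f <- (t_f - t_all_mean) / t_all_sd
  mid_t_std <- (tstd_m + tstd_f) / 2
  clip_edu <- function(x) pmin(pmax(round(x), 6L), 23L)
  mother_edu <- clip_edu(13 + 1.2 * tstd_m + stats::rnorm(n, 0, config$parent_edu_sd))
  father_edu <- clip_edu(13 + 1.2 * tstd_f + stats::rnorm(n, 0, config$parent_edu_sd))
  parent_log_earn <- 12.8 + 0.3 * mid_t_std + stats::rnorm(n, 0, config$parent_earn_sd)
  ple_std <- as.numeric(scale(parent_log_earn))
  p_gt <- stats::plogis(stats::qlogis(min(max(config$genotyped_prob, 1e-6), 1 - 1e-6)) +
                        config$genotyped_earn_gradient * ple_std)
  genotyped <- stats::rbinom(n, 1L, p_gt) == 1L
  mother_age0 <- pmin(pmax(round(stats::rnorm(n, 27, 4)), 18L), 42L)
  father_age0 <- pmin(pmax(mother_age0 + round(stats::rnorm(n, 2, 3)), 18L), 60L)
  pairs <- data.frame(
    family_id = seq_len(n),
    subpop = subpop,
    piv_mother = piv_m,
    piv_father = piv_f,
    tscore_mother = tstd_m,
    tscore_father = tstd_f,
    gen_ability_mother = stats::rnorm(n),
    gen_ability_father = stats::rnorm(n),
    fam_env = stats::rnorm(n),
    mother_edu = mother_edu,
    father_edu = father_edu,
    parent_log_earn = parent_log_earn,
    mother_age0 = mother_age0,
    father_age0 = father_age0,
    genotyped = genotyped
  )
  list(pairs = pairs, G_mother = G_m, G_father = G_f)
}

#' Mendelian transmission of parental genotypes
#'
#' Each offspring allele is drawn independently and uniformly from the
#' relevant parent's two alleles (a transmitted allele count is Bernoulli
#' with probability g/2 for parental genotype g in 0,1,2). MZ twins receive
#' one draw duplicated; DZ twins and full siblings receive independent draws.
#'
#' @param g_mother,g_father parental genotype vectors (values in 0,1,2).
#' @param n number of offspring to draw.
#' @param zygosity `"none"` (independent draws) or `"mz"` (first draw
#'   duplicated across all offspring).
#' @return an `n` x `length(g_mother)` integer matrix of offspring genotypes.
#' @export
mendelian_transmit <- function(g_mother, g_father, n = 1, zygosity = c("none", "mz")) {
  zygosity <- match.arg(zygosity)
  stopifnot(length(g_mother) == length(g_father),
            all(g_mother %in% 0:2), all(g_father %in% 0:2))
  m <- length(g_mother)
  one <- function() {
    stats::rbinom(m, 1L, g_mother / 2) + stats::rbinom(m, 1L, g_father / 2)
  }
  if (zygosity == "mz") {
    g <- one()
    out <- matrix(g, nrow = n, ncol = m, byrow = TRUE)
  } else {
    out <- t(vapply(seq_len(n), function(i) one(), integer(m)))
  }
  storage.mode(out) <- "integer"
  out
}

# Batch transmission: row i of the output is a child of parental rows i.
transmit_batch <- function(G_m, G_f) {
  n <- nrow(G_m)
  m <- ncol(G_m)
  out <- matrix(stats::rbinom(n * m, 1L, G_m / 2) +
                stats::rbinom(n * m, 1L, G_f / 2), n, m)
  storage.mode(out) <- "integer"
  out
}

#' Polygenic index from genotypes and score weights
#'
#' @param G genotype matrix (individuals x SNPs, effect-allele counts) or a
#'   single genotype vector.
#' @param weights per-SNP score weights.
#' @param standardize if `TRUE`, return the score standardized to mean 0 and
#'   SD 1 within the supplied sample.
#' @return numeric vector of scores.
#' @export
compute_piv <- function(G, weights, standardize = FALSE) {
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  if (ncol(G) != length(weights)) {
    stop("genotype and weight vectors have different lengths", call. = FALSE)
  }
  piv <- as.numeric(G %*% weights)
  if (standardize) {
    s <- stats::sd(piv)
    if (!is.finite(s) || s == 0) stop("cannot standardize a constant score",
                                      call. = FALSE)
    piv <- (piv - mean(piv)) / s
  }
  piv
}

#' Round and clip latent schooling to observed years
#'
#' @param s_star latent continuous schooling.
#' @return integer years of schooling in 6..23.
#' @export
schooling_from_latent <- function(s_star) {
  as.integer(pmin(pmax(round(s_star), 6L), 23L))
}

#' Assign integer years of schooling to a simulated population
#'
#' Latent schooling is 13 plus the first-stage contribution of the
#' standardized true polygenic score (with optional complier-responsiveness
#' heterogeneity), the ability, heritable-ability, family-environment,
#' dynastic and twin-shared channels, and Gaussian noise; observed schooling
#' is the rounded latent value clipped to 6..23.
#'
#' @param population a population under construction (see
#'   [simulate_population()]); used internally but exported for stepwise use.
#' @param config the [sim_config()] in force.
#' @return the population with `offspring$schooling` filled in.
#' @export
generate_schooling <- function(population, config) {
  off <- population$offspring
  s_star <- 13 +
    config$pi_first_stage * (1 + config$hetero_first_stage * off$gain) * off$tscore_std +
    config$ability_on_schooling * off$ability +
    config$gen_ability_on_schooling * off$gen_ability +
    config$fam_env_on_schooling * off$fam_env_i +
    config$dynastic_on_schooling * off$nurture_std +
    off$twin_school +
    stats::rnorm(nrow(off), 0, config$school_noise_sd)
  population$offspring$schooling <- schooling_from_latent(s_star)
  population
}

#' Generate the age-indexed earnings panel
#'
#' Labor-market entry is at age `schooling + 7`; earnings are zero before
#' entry and log-normal afterwards, following a Mincer profile in potential
#' experience `x = age - schooling - 7` with individual return
#' `beta_i = beta_true + hetero_kappa * gain`, plus the configured
#' confounding channels, per-SNP direct effects, a permanent person effect
#' and transitory noise.
#'
#' @inheritParams generate_schooling
#' @return the population with an `earnings` matrix (individuals x ages).
#' @export
generate_earnings_panel <- function(population, config) {
  off <- population$offspring
  if (is.null(off$schooling)) stop("schooling must be generated first", call. = FALSE)
  n <- nrow(off)
  ages <- config$ages
  pleio <- as.numeric(population$G %*% population$panel$true_direct_effect)
  base <- config$mincer_intercept +
    off$beta_i * off$schooling +
    config$ability_on_earnings * off$ability +
    config$gen_ability_on_earnings * off$gen_ability +
    config$fam_env_on_earnings * off$fam_env_i +
    config$dynastic_on_earnings * off$nurture_std +
    pleio +
    config$subpop_earn_offset * (off$subpop - 1) +
    config$sex_earn_effect * (off$sex == 1) +
    stats::rnorm(n, 0, config$earn_person_sd)
  earn <- matrix(0, n, length(ages), dimnames = list(NULL, ages))
  entry <- off$schooling + 7L
  for (j in seq_along(ages)) {
    a <- ages[j]
    x <- a - entry
    active <- x >= 0
    if (!any(active)) next
    lw <- base[active] + config$mincer_slope * x[active] -
      config$mincer_curve * x[active]^2 +
      stats::rnorm(sum(active), 0, config$earn_noise_sd)
    earn[active, j] <- exp(lw)
  }
  population$earnings <- earn
  population
}

#' Simulate a complete pedigree-linked population
#'
#' Runs the full generative chain: SNP panel, parent pairs (with assortative
#' mating and stratification), sibship structure with MZ/DZ twins, Mendelian
#' transmission, polygenic indices, latent confounders, schooling, and the
#' ages-17..62 earnings panel. Identical `config` + `seed` give bit-identical
#' populations.
#'
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed.
#' @return an object of class `genpop`: a list with `config`, `seed`,
#'   `panel`, `parents`, `G_mother`, `G_father`, `offspring`, `G`,
#'   `earnings`, `ages`.
#' @examples
#' pop <- simulate_population(sim_config(n_families = 200, n_snps = 20), seed = 1)
#' pop
#' @export
simulate_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  panel <- draw_snp_panel(config)
  par <- simulate_parent_pairs(config, panel)
  pairs <- par$pairs
  nfam <- nrow(pairs)

  sizes <- sample.int(3L, nfam, replace = TRUE, prob = config$offspring_dist)
  is_twin_fam <- sizes >= 2 & stats::runif(nfam) < config$twin_prob
  is_mz_fam <- is_twin_fam & stats::runif(nfam) < config$mz_share

  fam_of <- rep.int(seq_len(nfam), sizes)
  n_off <- length(fam_of)
  order_in_fam <- sequence(sizes)
  zyg <- rep("none", n_off)
  tw <- is_twin_fam[fam_of] & order_in_fam <= 2
  zyg[tw] <- ifelse(is_mz_fam[fam_of[tw]], "MZ", "DZ")
  # MZ pair: second twin duplicates the first twin's meiosis
  mz_first <- which(zyg == "MZ" & order_in_fam == 1)
  mz_second <- which(zyg == "MZ" & order_in_fam == 2)

  G_m_exp <- par$G_mother[fam_of, , drop = FALSE]
  G_f_exp <- par$G_father[fam_of, , drop = FALSE]
  G <- transmit_batch(G_m_exp, G_f_exp)
  if (length(mz_second)) G[mz_second, ] <- G[mz_first, , drop = FALSE]
  rm(G_m_exp, G_f_exp)

  # heritable latent ability: midparent mean + segregation (shared by MZ)
  seg <- stats::rnorm(n_off, 0, sqrt(0.5))
  if (length(mz_second)) seg[mz_second] <- seg[mz_first]
  gen_ability <- (pairs$gen_ability_mother[fam_of] +
                  pairs$gen_ability_father[fam_of]) / 2 + seg

  sex <- stats::rbinom(n_off, 1L, 0.5)
  if (length(mz_second)) sex[mz_second] <- sex[mz_first]

  yr_range <- range(config$birth_years)
  base_year <- sample(seq(yr_range[1], max(yr_range[1], yr_range[2] - 4)),
                      nfam, replace = TRUE)
  birth_year <- base_year[fam_of] + 2L * (order_in_fam - 1L)
  birth_year[tw & order_in_fam == 2] <- base_year[fam_of[tw & order_in_fam == 2]]
  birth_year <- pmin(birth_year, yr_range[2])

  # family environment with birth-year drift (twins share the drift draw)
  d <- config$fam_env_drift
  fy <- interaction(fam_of, birth_year, drop = TRUE)
  u_fy <- stats::rnorm(nlevels(fy))[as.integer(fy)]
  fam_env_i <- sqrt(max(0, 1 - d^2)) * pairs$fam_env[fam_of] + d * u_fy

  twin_school <- numeric(n_off)
  if (config$twin_school_sd > 0) {
    tw_fams <- which(is_twin_fam)
    draw <- stats::rnorm(nfam, 0, config$twin_school_sd)
    sel <- tw & fam_of %in% tw_fams
    twin_school[sel] <- draw[fam_of[sel]]
  }

  safe_scale <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  piv_raw <- compute_piv(G, panel$score_weight)
  piv_std <- safe_scale(piv_raw)
  t_raw <- compute_piv(G, panel$true_schooling_effect)
  tscore_std <- safe_scale(t_raw)
  nurt_raw <- as.numeric((par$G_mother[fam_of, , drop = FALSE] +
                          par$G_father[fam_of, , drop = FALSE]) %*%
                           panel$nurture_effect)
  sd_n <- stats::sd(nurt_raw)
  nurture_std <- if (is.finite(sd_n) && sd_n > 0) {
    (nurt_raw - mean(nurt_raw)) / sd_n
  } else {
    nurt_raw * 0
  }
  mid_piv <- (pairs$piv_mother[fam_of] + pairs$piv_father[fam_of]) / 2
  mid_piv_std <- safe_scale(mid_piv)

  ability <- stats::rnorm(n_off, 0, config$ability_sd)
  gain <- stats::rnorm(n_off) + config$sex_gain * (sex == 1)

  offspring <- data.frame(
    id = seq_len(n_off),
    family_id = fam_of,
    mother_id = fam_of,
    father_id = fam_of,
    zygosity = zyg,
    sex = sex,
    birth_year = birth_year,
    birth_order = order_in_fam,
    n_children = sizes[fam_of],
    subpop = pairs$subpop[fam_of],
    genotyped_family = pairs$genotyped[fam_of],
    piv_raw = piv_raw,
    piv_std = piv_std,
    tscore_std = tscore_std,
    nurture_std = nurture_std,
    midparent_piv_std = mid_piv_std,
    gen_ability = gen_ability,
    ability = ability,
    gain = gain,
    fam_env_i = fam_env_i,
    twin_school = twin_school,
    beta_i = config$beta_true + config$hetero_kappa * gain,
    mother_edu = pairs$mother_edu[fam_of],
    father_edu = pairs$father_edu[fam_of],
    parent_log_earn = pairs$parent_log_earn[fam_of],
    mother_age_birth = pairs$mother_age0[fam_of] + (birth_year - base_year[fam_of]),
    father_age_birth = pairs$father_age0[fam_of] + (birth_year - base_year[fam_of]),
    stringsAsFactors = FALSE
  )

  population <- list(
    config = config, seed = as.integer(seed), panel = panel,
    parents = pairs, G_mother = par$G_mother, G_father = par$G_father,
    offspring = offspring, G = G, ages = config$ages
  )
  population <- generate_schooling(population, config)
  population <- generate_earnings_panel(population, config)
  class(population) <- "genpop"
  population
}

#' @export
print.genpop <- function(x, ...) {
  cat("<genpop> simulated population (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d families, %d offspring, %d SNPs\n",
              nrow(x$parents), nrow(x$offspring), nrow(x$panel)))
  zyg <- table(x$offspring$zygosity)
  cat("  zygosity:", paste(names(zyg), zyg, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  schooling: mean %.2f y (range %d-%d)\n",
              mean(x$offspring$schooling), min(x$offspring$schooling),
              max(x$offspring$schooling)))
  invisible(x)
}
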