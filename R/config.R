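#' Simulation configuration for a genetically informed schooling cohort
#'
#' Builds the parameter list that drives [simulate_population()]. Defaults
#' describe a *null* cohort: a polygenic index built from 335 independent
#' biallelic SNPs whose one-SD increment shifts schooling by 0.26 years, a
#' true return of 0.08 log points per year of schooling, integer schooling in
#' 6..23, annual earnings over ages 17..62 with a concave experience profile,
#' and every confounding channel switched off. Presets switch on the
#' confounding structures used in the bias-demonstration experiments.
#'
#' @param ... named overrides of individual fields (see Details).
#' @param preset one of `"null"` (all confounding channels off),
#'   `"ability"` (individual-level ability confounding only),
#'   `"family"` (dynastic + assortative mating + population stratification),
#'   `"composite"` (all channels plus heterogeneous complier returns, arranged to
#'   reproduce the qualitative ordering MZ-FE < DZ-FE < sibling-FE < OLS < MR).
#'
#' @details Fields (units in brackets):
#' \describe{
#'   \item{n_families}{number of parent pairs.}
#'   \item{offspring_dist}{probabilities of 1, 2 or 3 offspring per family.}
#'   \item{twin_prob, mz_share}{probability that a multi-offspring family's
#'     first two children are twins, and the MZ share among twin pairs.}
#'   \item{n_snps, allele_freq_range}{SNP panel size and base allele-frequency
#'     support (open interval).}
#'   \item{beta_true}{causal return per year of schooling [log earnings].}
#'   \item{pi_first_stage}{years of schooling per 1 SD of the true polygenic
#'     score.}
#'   \item{weight_noise}{SD of GWAS estimation noise in the score weights,
#'     as a fraction of the SD of the true per-allele effects.}
#'   \item{weight_dynastic, weight_strat}{contamination of the score weights
#'     by per-SNP nurture effects and by the stratification direction, in the
#'     same fractional units (population GWAS weights absorb indirect
#'     effects; a within-family GWAS does not).}
#'   \item{ability_sd, ability_on_schooling, ability_on_earnings}{individual
#'     (non-shared, non-heritable) ability confounder and its loadings.}
#'   \item{gen_ability_on_schooling, gen_ability_on_earnings}{loadings of a
#'     heritable latent ability (MZ correlation 1, DZ/sibling 0.5).}
#'   \item{fam_env_on_schooling, fam_env_on_earnings, fam_env_drift}{shared
#'     family environment loadings; `fam_env_drift` is the share of the family
#'     environment that drifts across birth years (shared by twins, not by
#'     ordinary siblings).}
#'   \item{dynastic_on_schooling, dynastic_on_earnings}{loadings of the
#'     standardized genetic-nurture score (built from parental genotypes with
#'     per-SNP nurture effects independent of the direct effects).}
#'   \item{rho_assortative}{target spousal polygenic-score correlation in
#'     \[0,1), induced by Gaussian-copula rank matching.}
#'   \item{n_subpops, subpop_freq_offset, subpop_offset_mode,
#'     subpop_earn_offset}{population stratification: per-subpopulation
#'     allele-frequency offsets (direction `"random"` or `"aligned"` with the
#'     true effect) and log-earnings intercept shifts.}
#'   \item{pleio_fraction, pleio_effect_sd, pleio_mean}{share of SNPs with a
#'     direct (pleiotropic) earnings effect, its SD, and its mean relative to
#'     the schooling-increasing allele (nonzero mean = directional
#'     pleiotropy).}
#'   \item{hetero_kappa, hetero_first_stage, sex_gain}{loadings of a latent
#'     gain modifier on the individual return and on first-stage
#'     responsiveness (positive values give instrument compliers
#'     above-average returns); `sex_gain` shifts the gain modifier's mean
#'     for women, planting sex-specific returns.}
#'   \item{sex_earn_effect}{log-earnings shift for women relative to men.}
#'   \item{twin_school_sd}{extra schooling environment shared by co-twins.}
#'   \item{mincer_intercept, mincer_slope, mincer_curve}{log-earnings
#'     intercept, experience slope and (positive) experience curvature.}
#'   \item{school_noise_sd, earn_person_sd, earn_noise_sd}{noise SDs for
#'     latent schooling, the permanent person effect and the transitory
#'     age-level earnings shock.}
#'   \item{parent_edu_sd, parent_earn_sd}{noise SDs of the parental
#'     education and log-earnings phenotypes.}
#'   \item{genotyped_prob, genotyped_earn_gradient}{family-level probability
#'     of being in the genotyped subsample and an optional logit gradient in
#'     standardized parental earnings (cohort self-selection).}
#'   \item{birth_years, ages}{offspring birth-year support and the observed
#'     earnings ages.}
#' }
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_population()], [read_sim_config()]
#' @examples
#' cfg <- sim_config(n_families = 500, preset = "ability")
#' cfg$n_snps
#' @export
sim_config <- function(..., preset = c("null", "ability", "family", "composite")) {
  preset <- match.arg(preset)
  cfg <- list(
    n_families = 10000L,
    offspring_dist = c(0.40, 0.45, 0.15),
    twin_prob = 0.02,
    mz_share = 0.5,
    n_snps = 335L,
    allele_freq_range = c(0.05, 0.95),
    beta_true = 0.08,
    pi_first_stage = 0.26,
    weight_noise = 0.2,
    weight_dynastic = 0,
    weight_strat = 0,
    ability_sd = 1,
    ability_on_schooling = 0,
    ability_on_earnings = 0,
    gen_ability_on_schooling = 0,
    gen_ability_on_earnings = 0,
    fam_env_on_schooling = 0,
    fam_env_on_earnings = 0,
    fam_env_drift = 0.5,
    dynastic_on_schooling = 0,
    dynastic_on_earnings = 0,
    rho_assortative = 0,
    n_subpops = 1L,
    subpop_freq_offset = 0,
    subpop_offset_mode = "random",
    subpop_earn_offset = 0,
    pleio_fraction = 0,
    pleio_effect_sd = 0.01,
    pleio_mean = 0,
    hetero_kappa = 0,
    hetero_first_stage = 0,
    sex_gain = 0,
    sex_earn_effect = -0.3,
    twin_school_sd = 0,
    mincer_intercept = 11.2,
    mincer_slope = 0.1292,
    mincer_curve = 0.0038,
    school_noise_sd = 1.5,
    earn_person_sd = 0.3,
    earn_noise_sd = 0.25,
    parent_edu_sd = 2,
    parent_earn_sd = 0.5,
    genotyped_prob = 0.55,
    genotyped_earn_gradient = 0,
    birth_years = 1959:1982,
    ages = 17:62
  )
  presets <- list(
    null = list(),
    ability = list(
      ability_on_schooling = 0.8,
      ability_on_earnings = -0.25
    ),
    family = list(
      dynastic_on_schooling = 0.4,
      dynastic_on_earnings = 0.10,
      weight_dynastic = 0.8,
      rho_assortative = 0.3,
      n_subpops = 2L,
      subpop_freq_offset = 0.03,
      subpop_earn_offset = 0.15,
      weight_strat = 0.5
    ),
    composite = list(
      ability_on_schooling = 0.8,
      ability_on_earnings = -0.25,
      gen_ability_on_schooling = 0.8,
      gen_ability_on_earnings = 0.15,
      fam_env_on_schooling = 0.6,
      fam_env_on_earnings = 0.2,
      fam_env_drift = 0.6,
      twin_school_sd = 0.8,
      dynastic_on_schooling = 0.4,
      dynastic_on_earnings = 0.10,
      weight_dynastic = 0.8,
      rho_assortative = 0.3,
      n_subpops = 2L,
      subpop_freq_offset = 0.03,
      subpop_earn_offset = 0.15,
      weight_strat = 0.5,
      hetero_kappa = 0.02,
      hetero_first_stage = 0.5
    )
  )
  cfg[names(presets[[preset]])] <- presets[[preset]]
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  cfg$preset <- preset
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (!is.numeric(cfg$n_families) || cfg$n_families < 1) {
    stop_cfg("n_families must be a positive integer")
  }
  if (!is.numeric(cfg$n_snps) || cfg$n_snps < 1) {
    stop_cfg("n_snps must be >= 1")
  }
  fr <- cfg$allele_freq_range
  if (length(fr) != 2 || fr[1] <= 0 || fr[2] >= 1 || fr[1] >= fr[2]) {
    stop_cfg("allele_freq_range must be an increasing interval within (0, 1)")
  }
  if (cfg$pleio_fraction < 0 || cfg$pleio_fraction > 1) {
    stop_cfg("pleio_fraction must lie in [0, 1]")
  }
  if (cfg$rho_assortative < 0 || cfg$rho_assortative >= 1) {
    stop_cfg("rho_assortative must lie in [0, 1)")
  }
  if (cfg$mincer_curve < 0) {
    stop_cfg("mincer_curve must be >= 0 (concave experience profile)")
  }
  if (abs(sum(cfg$offspring_dist) - 1) > 1e-8 || any(cfg$offspring_dist < 0)) {
    stop_cfg("offspring_dist must be a probability vector over 1..3 offspring")
  }
  if (!cfg$subpop_offset_mode %in% c("random", "aligned")) {
    stop_cfg("subpop_offset_mode must be 'random' or 'aligned'")
  }
  sds <- c("ability_sd", "school_noise_sd", "earn_person_sd", "earn_noise_sd",
           "parent_edu_sd", "parent_earn_sd", "pleio_effect_sd",
           "weight_noise", "twin_school_sd")
  for (f in sds) {
    if (cfg[[f]] < 0) stop_cfg(paste(f, "must be >= 0"))
  }
  if (cfg$n_subpops < 1) stop_cfg("n_subpops must be >= 1")
  if (cfg$genotyped_prob < 0 || cfg$genotyped_prob > 1) {
    stop_cfg("genotyped_prob must lie in [0, 1]")
  }
  cfg$n_families <- as.integer(cfg$n_families)
  cfg$n_snps <- as.integer(cfg$n_snps)
  cfg$n_subpops <- as.integer(cfg$n_subpops)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> preset:", x$preset, "\n")
  cat(sprintf("  %d families, %d SNPs, beta_true = %.3f, pi = %.3f\n",
              x$n_families, x$n_snps, x$beta_true, x$pi_first_stage))
  on <- c(
    ability = x$ability_on_earnings != 0 || x$ability_on_schooling != 0,
    heritable_ability = x$gen_ability_on_earnings != 0,
    family_env = x$fam_env_on_earnings != 0,
    dynastic = x$dynastic_on_earnings != 0 || x$dynastic_on_schooling != 0,
    assortative = x$rho_assortative > 0,
    stratification = x$n_subpops > 1,
    pleiotropy = x$pleio_fraction > 0,
    heterogeneity = x$hetero_kappa != 0
  )
  cat("  channels on:", if (any(on)) paste(names(on)[on], collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds a mapping whose keys mirror [sim_config()] field names; an
#' optional `preset` key selects the preset the overrides are applied to.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext, call. = FALSE)
  )
  preset <- raw$preset %||% "null"
  raw$preset <- NULL
  do.call(sim_config, c(raw, list(preset = preset)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
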