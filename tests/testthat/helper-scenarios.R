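# Simulated scenarios shared across test files, built once per run.
# Problem sizes follow the experiment designs described in the methods
# vignette; seeds are fixed.

.scenarios <- new.env(parent = emptyenv())

scenario <- function(name) {
  if (!exists(name, envir = .scenarios)) {
    assign(name, .build_scenario(name), envir = .scenarios)
  }
  get(name, envir = .scenarios)
}

.build_scenario <- function(name) {
  build <- function(cfg, seed) {
    pop <- simulate_population(cfg, seed = seed)
    list(pop = pop, samples = suppressWarnings(build_samples(pop)))
  }
  switch(name,
    # ~50,000 offspring, all confounding channels off (flagship null cohort)
    null_big = build(sim_config(n_families = 28500), seed = 1),
    # small null cohort for unit-level checks
    null_small = build(sim_config(n_families = 3000, n_snps = 30,
                                  twin_prob = 0.05), seed = 42),
    # individual-level (ability) confounding only
    ability = build(sim_config(preset = "ability", n_families = 28000,
                               n_snps = 100), seed = 1),
    # dynastic + assortative mating + stratification; sibship-rich cohort
    # sized for a ~20k-sibship within-family GWAS discovery sample
    family = build(sim_config(preset = "family", n_snps = 60,
                              n_families = 30000,
                              offspring_dist = c(0.3, 0.55, 0.15),
                              genotyped_prob = 0.75), seed = 1),
    # 35% of SNPs carry directional direct effects (median robustness)
    pleio_median = build(sim_config(n_families = 30000,
                                    offspring_dist = c(1, 0, 0),
                                    n_snps = 100, genotyped_prob = 1,
                                    twin_prob = 0, pleio_fraction = 0.35,
                                    pleio_mean = 0.025,
                                    pleio_effect_sd = 0.005), seed = 1),
    # directional pleiotropy on every SNP, independent of instrument
    # strength (InSIDE): Egger's design point
    pleio_inside = build(sim_config(n_families = 50000,
                                    offspring_dist = c(1, 0, 0),
                                    n_snps = 35, genotyped_prob = 1,
                                    twin_prob = 0, pleio_fraction = 1,
                                    pleio_mean = 0.015,
                                    pleio_effect_sd = 0.005), seed = 1),
    # clean summary statistics (no pleiotropy), strong per-SNP instruments
    snp_clean = {
      sc <- build(sim_config(n_families = 50000, offspring_dist = c(1, 0, 0),
                             n_snps = 25, genotyped_prob = 1,
                             twin_prob = 0), seed = 3)
      sc$summary <- per_snp_associations(sc$samples$genotyped)
      sc
    },
    stop("unknown scenario: ", name)
  )
}
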