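test_that("SNP panel has the configured size and pleiotropy pattern", {
  set.seed(1)
  p0 <- draw_snp_panel(sim_config(n_snps = 335, pleio_fraction = 0))
  expect_equal(nrow(p0), 335)
  expect_true(all(p0$true_direct_effect == 0))
  fr <- sim_config()$allele_freq_range
  expect_true(all(p0$freq_1 > 0 & p0$freq_1 < 1))
  expect_true(cor(p0$score_weight, p0$true_schooling_effect) > 0.9)

  p1 <- draw_snp_panel(sim_config(n_snps = 10, pleio_fraction = 1))
  expect_equal(sum(p1$true_direct_effect != 0), 10)
  p3 <- draw_snp_panel(sim_config(n_snps = 10, pleio_fraction = 0.3))
  expect_equal(sum(p3$true_direct_effect != 0), 3)
})

test_that("polygenic index is the weighted allele count sum", {
  expect_equal(compute_piv(c(0, 0, 0), c(0.5, -1, 2)), 0)
  # 0*0.1 + 1*(-0.2) + 2*0.05 = -0.1
  expect_equal(compute_piv(c(0, 1, 2), c(0.1, -0.2, 0.05)), -0.1)
  expect_error(compute_piv(c(0, 1), c(0.1, 0.2, 0.3)), "length")
  set.seed(2)
  G <- matrix(rbinom(200 * 12, 2, 0.4), 200, 12)
  z <- compute_piv(G, rnorm(12), standardize = TRUE)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
})

test_that("Mendelian transmission follows the Punnett probabilities", {
  expect_true(all(mendelian_transmit(c(0, 0), c(0, 0), n = 5) == 0))
  expect_true(all(mendelian_transmit(rep(2, 4), rep(0, 4), n = 5) == 1))
  set.seed(3)
  kids <- mendelian_transmit(rep(1, 10000), rep(1, 10000), n = 1)
  # P(0) = P(2) = 1/4, P(1) = 1/2; 3 binomial SEs over 10,000 draws
  p_obs <- tabulate(kids + 1L, 3) / 10000
  expect_lt(abs(p_obs[1] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(p_obs[2] - 0.50), 3 * sqrt(0.50 * 0.50 / 10000))
  expect_lt(abs(p_obs[3] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  mz <- mendelian_transmit(c(1, 1, 2, 0), c(1, 0, 2, 2), n = 3,
                           zygosity = "mz")
  expect_equal(mz[1, ], mz[2, ])
  expect_equal(mz[1, ], mz[3, ])
})

test_that("genetic lottery: offspring expectation is the midparent genotype", {
  set.seed(4)
  gm <- rbinom(8, 2, 0.5)
  gf <- rbinom(8, 2, 0.5)
  kids <- mendelian_transmit(gm, gf, n = 10000)
  mid <- (gm + gf) / 2
  # transmitted-allele variance per parent is g/2*(1-g/2)
  se <- sqrt((gm / 2 * (1 - gm / 2) + gf / 2 * (1 - gf / 2)) / 10000)
  dev <- abs(colMeans(kids) - mid)
  expect_true(all(dev <= pmax(4 * se, 1e-12)))
})

test_that("assortative mating hits the target spousal score correlation", {
  set.seed(5)
  cfg0 <- sim_config(n_families = 10000, n_snps = 40)
  pp0 <- simulate_parent_pairs(cfg0, draw_snp_panel(cfg0))
  expect_lt(abs(cor(pp0$pairs$piv_mother, pp0$pairs$piv_father)), 0.03)
  cfg4 <- sim_config(n_families = 10000, n_snps = 40, rho_assortative = 0.4)
  set.seed(6)
  pp4 <- simulate_parent_pairs(cfg4, draw_snp_panel(cfg4))
  r <- cor(pp4$pairs$piv_mother, pp4$pairs$piv_father)
  expect_gt(r, 0.37)
  expect_lt(r, 0.43)
})

test_that("aligned subpopulation offsets shift the mean polygenic index", {
  set.seed(7)
  cfg <- sim_config(n_families = 4000, n_snps = 50, n_subpops = 2,
                    subpop_freq_offset = 0.1, subpop_offset_mode = "aligned")
  panel <- draw_snp_panel(cfg)
  pp <- simulate_parent_pairs(cfg, panel)
  d <- tapply(pp$pairs$piv_mother, pp$pairs$subpop, mean)
  expect_gt(d["2"] - d["1"], 0)
})

test_that("latent schooling is rounded and clipped to 6..23 years", {
  expect_identical(schooling_from_latent(30), 23L)
  expect_identical(schooling_from_latent(-4), 6L)
  expect_identical(schooling_from_latent(12.6), 13L)
  s <- scenario("null_small")$pop$offspring$schooling
  expect_true(all(s >= 6 & s <= 23))
  expect_true(is.integer(s))
})

test_that("first stage: schooling responds to the index at the configured rate", {
  # null first stage
  set.seed(8)
  cfg0 <- sim_config(n_families = 12000, n_snps = 40, pi_first_stage = 0)
  pop0 <- simulate_population(cfg0, seed = 8)
  b0 <- coef(lm(schooling ~ piv_std, data = pop0$offspring))[2]
  expect_lt(abs(b0), 0.02)
  # configured 0.26 y per SD recovered on the flagship cohort
  off <- scenario("null_big")$pop$offspring
  b <- coef(lm(schooling ~ piv_std, data = off))[2]
  expect_gt(b, 0.24)
  expect_lt(b, 0.28)
})

test_that("earnings are zero before labor-market entry and exactly Mincer after", {
  cfg <- sim_config(n_families = 400, n_snps = 10, school_noise_sd = 0.6,
                    earn_person_sd = 0, earn_noise_sd = 0,
                    sex_earn_effect = 0, twin_prob = 0)
  pop <- simulate_population(cfg, seed = 9)
  off <- pop$offspring
  ages <- as.integer(colnames(pop$earnings))
  entry <- off$schooling + 7L
  pre <- outer(entry, ages, function(e, a) a < e)
  expect_true(all(pop$earnings[pre] == 0))
  expect_true(all(pop$earnings[!pre] > 0))
  # two individuals one schooling year apart, compared at equal experience,
  # differ by exactly beta_true in logs
  i <- which(off$schooling == 13)[1]
  j <- which(off$schooling == 12)[1]
  xi <- 10 # experience years
  yi <- pop$earnings[i, as.character(13 + 7 + xi)]
  yj <- pop$earnings[j, as.character(12 + 7 + xi)]
  expect_equal(unname(log(yi) - log(yj)), cfg$beta_true, tolerance = 1e-10)
})

test_that("within-sibship index differences are a clean lottery", {
  set.seed(10)
  cfg <- sim_config(n_families = 10000, n_snps = 40,
                    offspring_dist = c(0, 1, 0), twin_prob = 0,
                    rho_assortative = 0.4, n_subpops = 2,
                    subpop_freq_offset = 0.05)
  pop <- simulate_population(cfg, seed = 10)
  off <- pop$offspring
  first <- off[off$birth_order == 1, ]
  second <- off[off$birth_order == 2, ]
  d <- first$piv_raw - second$piv_raw
  expect_lt(abs(mean(d) / sd(d)), 0.03)
  expect_lt(abs(cor(d, first$midparent_piv_std)), 0.03)
  expect_lt(abs(cor(d, first$subpop)), 0.03)
  expect_lt(abs(cor(d, first$parent_log_earn)), 0.03)
})

test_that("MZ co-twins share genotypes; DZ co-twins correlate about 0.5", {
  cfg <- sim_config(n_families = 10000, n_snps = 30,
                    offspring_dist = c(0, 1, 0), twin_prob = 1, mz_share = 0.5)
  pop <- simulate_population(cfg, seed = 11)
  off <- pop$offspring
  first <- off[off$birth_order == 1, ]
  second <- off[off$birth_order == 2, ]
  stopifnot(all(first$family_id == second$family_id))
  mz <- first$zygosity == "MZ"
  expect_true(all(pop$G[first$id[mz], ] == pop$G[second$id[mz], ]))
  expect_equal(first$piv_raw[mz], second$piv_raw[mz])
  r_dz <- cor(first$piv_raw[!mz], second$piv_raw[!mz])
  expect_lt(abs(r_dz - 0.5), 0.05)
})

test_that("identical config and seed give bit-identical populations", {
  cfg <- sim_config(n_families = 300, n_snps = 15, preset = "family")
  a <- simulate_population(cfg, seed = 99)
  b <- simulate_population(cfg, seed = 99)
  expect_identical(a$offspring, b$offspring)
  expect_identical(a$G, b$G)
  expect_identical(a$earnings, b$earnings)
  expect_identical(a$panel, b$panel)
})
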