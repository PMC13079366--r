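make_toy <- function(n = 60, seed = 21, families = TRUE) {
  set.seed(seed)
  fam <- if (families) rep(seq_len(n / 2), each = 2) else seq_len(n)
  data.frame(
    id = seq_len(n), family_id = fam,
    birth_year = 1960 + (seq_len(n) %% 8),
    schooling = sample(10:18, n, replace = TRUE),
    piv_std = rnorm(n),
    x1 = rnorm(n), x2 = rnorm(n),
    log_prime_earn = NA_real_, prime_earn = NA_real_
  )
}

test_that("an exact linear outcome is fitted exactly", {
  d <- make_toy()
  d$log_prime_earn <- 2 * d$schooling
  d$prime_earn <- exp(d$log_prime_earn)
  fit <- fit_returns(toy_sample(d), "log", "ols")
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(fit$se, 1e-8)
})

test_that("OLS with covariates matches the normal-equation solution", {
  d <- make_toy()
  set.seed(22)
  d$log_prime_earn <- 0.1 * d$schooling + 0.5 * d$x1 - 0.2 * d$x2 + rnorm(60)
  fit <- fit_returns(toy_sample(d, covariates = c("x1", "x2")), "log", "ols")
  oracle <- ols_oracle(cbind(1, d$x1, d$x2, d$schooling), d$log_prime_earn)
  expect_equal(fit$beta, oracle[4], tolerance = 1e-10)
})

test_that("cluster-robust variance matches the sandwich package", {
  skip_if_not_installed("sandwich")
  d <- make_toy(n = 120)
  set.seed(23)
  d$log_prime_earn <- 0.1 * d$schooling + 0.4 * d$x1 + rnorm(120)
  d$cl <- rep(1:12, each = 10)
  fit <- fit_returns(toy_sample(d, covariates = "x1"), "log", "ols",
                     cluster = "cl")
  lmfit <- lm(log_prime_earn ~ x1 + schooling, data = d)
  V <- sandwich::vcovCL(lmfit, cluster = d$cl, type = "HC1", cadjust = TRUE)
  expect_equal(fit$se, sqrt(V["schooling", "schooling"]), tolerance = 1e-8)
})

test_that("with one observation per cluster the sandwich reduces to HC1", {
  d <- make_toy(n = 50, families = FALSE)
  set.seed(24)
  d$log_prime_earn <- 0.1 * d$schooling + rnorm(50)
  fit_id <- fit_returns(toy_sample(d), "log", "ols", cluster = "id")
  skip_if_not_installed("sandwich")
  lmfit <- lm(log_prime_earn ~ schooling, data = d)
  V <- sandwich::vcovHC(lmfit, type = "HC1")
  expect_equal(fit_id$se, sqrt(V["schooling", "schooling"]), tolerance = 1e-8)
})

test_that("family fixed effects difference out family-level shifts", {
  d <- make_toy()
  set.seed(25)
  d$log_prime_earn <- 0.1 * d$schooling + rnorm(60)
  base <- fit_returns(toy_sample(d), "log", "fe")
  shifted <- d
  shifted$log_prime_earn <- d$log_prime_earn + 5 * d$family_id
  shifted$prime_earn <- exp(shifted$log_prime_earn)
  fit <- fit_returns(toy_sample(shifted), "log", "fe")
  expect_equal(fit$beta, base$beta, tolerance = 1e-10)
})

test_that("two-sibling FE equals the pair-difference slope", {
  d <- make_toy()
  set.seed(26)
  d$log_prime_earn <- 0.1 * d$schooling + rnorm(60)
  fit <- fit_returns(toy_sample(d), "log", "fe")
  odd <- seq(1, 59, 2); even <- seq(2, 60, 2)
  ds <- d$schooling[odd] - d$schooling[even]
  dy <- d$log_prime_earn[odd] - d$log_prime_earn[even]
  expect_equal(fit$beta, sum(ds * dy) / sum(ds^2), tolerance = 1e-10)
})

test_that("concordant-schooling families are a degenerate FE design", {
  d <- make_toy()
  d$schooling <- rep(12L, 60)
  d$log_prime_earn <- rnorm(60)
  expect_error(fit_returns(toy_sample(d), "log", "fe"), "variation")
})

test_that("2SLS equals the Wald ratio without covariates and OLS when Z = S", {
  d <- make_toy(n = 20, families = FALSE, seed = 27)
  set.seed(27)
  d$log_prime_earn <- 0.1 * d$schooling + rnorm(20)
  fit <- fit_returns(toy_sample(d), "log", "mr")
  zc <- d$piv_std - mean(d$piv_std)
  expect_equal(fit$beta,
               sum(zc * d$log_prime_earn) / sum(zc * d$schooling),
               tolerance = 1e-10)
  expect_equal(fit$reduced_form_beta / fit$first_stage_beta, fit$beta,
               tolerance = 1e-10)
  # perfect first stage: 2SLS collapses to OLS
  fit2 <- fit_returns(toy_sample(d), "log", "mr",
                      instrument = as.numeric(d$schooling))
  ols <- fit_returns(toy_sample(d), "log", "ols")
  expect_equal(fit2$beta, ols$beta, tolerance = 1e-10)
})

test_that("partialled 2SLS equals the full-design 2SLS (FWL)", {
  d <- make_toy(n = 80, seed = 28)
  set.seed(28)
  d$log_prime_earn <- 0.1 * d$schooling + 0.3 * d$x1 - 0.1 * d$x2 + rnorm(80)
  fit <- fit_returns(toy_sample(d, covariates = c("x1", "x2")), "log", "mr")
  oracle <- tsls_oracle(d$log_prime_earn, d$schooling, d$piv_std,
                        X = cbind(1, d$x1, d$x2))
  expect_equal(fit$beta, oracle, tolerance = 1e-8)
})

test_that("sibling-MR equals the pair-differenced Wald ratio", {
  d <- make_toy(seed = 29)
  set.seed(29)
  d$piv_std <- rnorm(60)
  d$schooling <- round(12 + 0.8 * d$piv_std + rnorm(60))
  d$log_prime_earn <- 0.1 * d$schooling + rnorm(60)
  fit <- fit_returns(toy_sample(d), "log", "sibmr")
  odd <- seq(1, 59, 2); even <- seq(2, 60, 2)
  dz <- d$piv_std[odd] - d$piv_std[even]
  ds <- d$schooling[odd] - d$schooling[even]
  dy <- d$log_prime_earn[odd] - d$log_prime_earn[even]
  expect_equal(fit$beta, sum(dz * dy) / sum(dz * ds), tolerance = 1e-10)
})

test_that("an MZ-twin-only sample has no within-family instrument variance", {
  cfg <- sim_config(n_families = 150, n_snps = 12,
                    offspring_dist = c(0, 1, 0), twin_prob = 1, mz_share = 1,
                    genotyped_prob = 1)
  pop <- simulate_population(cfg, seed = 31)
  smp <- suppressWarnings(build_samples(pop))
  expect_error(fit_returns(smp$genotyped_sibling, "log", "sibmr"),
               "weak or zero")
})

test_that("absolute-scale estimates are exactly scale equivariant", {
  smp <- scenario("null_small")$samples$genotyped
  fit1 <- fit_returns(smp, "abs", "mr")
  smp2 <- smp
  smp2$data$prime_earn <- smp$data$prime_earn * 3
  fit3 <- fit_returns(smp2, "abs", "mr")
  expect_equal(fit3$beta, 3 * fit1$beta, tolerance = 1e-10)
  expect_equal(fit3$se, 3 * fit1$se, tolerance = 1e-10)
})

test_that("AR inversion: p maximized at the point estimate, CI near Wald when strong", {
  smp <- scenario("null_small")$samples$genotyped
  fit <- fit_returns(smp, "log", "mr")
  expect_gt(fit$F_first_stage, 100)
  ar <- ar_confidence_interval(smp, "log", "mr",
                               grid = fit$beta + seq(-5, 5, by = 0.5) * fit$se)
  p_at_hat <- ar$p_value(fit$beta)
  expect_true(all(ar$grid_p <= p_at_hat + 1e-10))
  expect_false(ar$unbounded)
  w <- fit$ci[2] - fit$ci[1]
  expect_lt(abs(ar$ci_low - fit$ci[1]), 0.1 * w)
  expect_lt(abs(ar$ci_high - fit$ci[2]), 0.1 * w)
})

test_that("AR interval matches the fit_returns ar ci_method", {
  smp <- scenario("null_small")$samples$genotyped
  fit <- fit_returns(smp, "log", "mr", ci_method = "ar")
  ar <- ar_confidence_interval(smp, "log", "mr")
  expect_equal(fit$ci, c(ar$ci_low, ar$ci_high), tolerance = 1e-6)
  expect_error(fit_returns(smp, "log", "ols", ci_method = "ar"), "IV")
})

test_that("balance: lottery-independent covariates show no association", {
  smp <- scenario("null_big")$samples$genotyped
  bal <- balance_test(smp, covariates = c("sex", "birth_year"))
  expect_true(all(abs(bal$table$coef) < 0.03))
})

test_that("balance under family confounding: between-family signal, within-family null", {
  smp <- scenario("family")$samples$genotyped_sibling
  between <- balance_test(smp, covariates = "mother_edu")
  expect_gt(abs(between$table$coef), 0.03)
  within <- balance_test(smp, covariates = "mother_edu", within_family = TRUE)
  expect_true(is.null(within$table) ||
              all(abs(within$table$coef) < 0.03) ||
              "mother_edu" %in% within$skipped)
})

test_that("within-family balance on singleton families skips everything", {
  cfg <- sim_config(n_families = 150, n_snps = 10,
                    offspring_dist = c(1, 0, 0), twin_prob = 0,
                    genotyped_prob = 1)
  pop <- simulate_population(cfg, seed = 32)
  smp <- suppressWarnings(build_samples(pop))
  expect_warning(out <- balance_test(smp$genotyped, within_family = TRUE),
                 "skip|multi")
  expect_true(is.null(out$table) || nrow(out$table) == 0)
})

test_that("constant covariates are skipped with a warning in balance tests", {
  smp <- scenario("null_small")$samples$genotyped
  smp$data$constant_cov <- 1
  expect_warning(out <- balance_test(smp, covariates = c("sex", "constant_cov")),
                 "constant")
  expect_true("constant_cov" %in% out$skipped)
})

test_that("stratified estimates: quartiles partition and homogeneity holds", {
  smp <- scenario("null_small")$samples$full
  q <- parent_earn_quartile(smp$data$parent_log_earn)
  expect_setequal(unique(q), 1:4)
  expect_equal(length(q), nrow(smp$data))
  # ties go to the lower quartile
  x <- c(1, 1, 1, 2, 3, 4, 5, 6)
  expect_equal(parent_earn_quartile(x)[1:3], rep(1L, 3))

  strat <- stratified_estimates(smp, "sex", outcome = "log", method = "ols")
  expect_length(strat, 2)
  b <- vapply(strat, function(f) f$beta, numeric(1))
  s <- vapply(strat, function(f) f$se, numeric(1))
  expect_lt(abs(b[1] - b[2]), 3 * sqrt(sum(s^2)))
})

test_that("planted sex-linked gains order the stratum estimates", {
  cfg <- sim_config(n_families = 6000, n_snps = 20, hetero_kappa = 0.04,
                    sex_gain = 1.5, twin_prob = 0)
  pop <- simulate_population(cfg, seed = 33)
  smp <- suppressWarnings(build_samples(pop))
  strat <- stratified_estimates(smp$full, "sex", outcome = "log",
                                method = "ols")
  # sex = 1 (women) received the positive gain shift (0.04 x 1.5 = 0.06)
  expect_gt(strat[["1"]]$beta - strat[["0"]]$beta,
            3 * sqrt(strat[["1"]]$se^2 + strat[["0"]]$se^2))
})

test_that("small strata are omitted with a warning", {
  smp <- scenario("null_small")$samples$full
  smp$data$rare <- ifelse(seq_len(nrow(smp$data)) <= 10, 3L, 1L)
  expect_warning(out <- stratified_estimates(smp, "rare", min_n = 50),
                 "omitted")
  expect_false("3" %in% names(out))
})
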