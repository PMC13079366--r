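test_that("IVW reproduces the hand-computed worked example", {
  ss <- toy_summary(beta_exp = c(0.1, 0.2, 0.5),
                    beta_out = c(0.01, 0.04, 0.05),
                    se_exp = 0.01, se_out = 0.01)
  fit <- mr_ivw(ss)
  # weights (100, 400, 2500), ratios (0.1, 0.2, 0.1): 340/3000
  expect_equal(fit$estimate, 340 / 3000, tolerance = 1e-10)
  expect_equal(fit$Q,
               100 * (0.1 - 340 / 3000)^2 + 400 * (0.2 - 340 / 3000)^2 +
                 2500 * (0.1 - 340 / 3000)^2,
               tolerance = 1e-10)
  expect_equal(fit$Q_df, 2)
})

test_that("IVW equals weighted through-origin regression; Q = 0 when homogeneous", {
  set.seed(41)
  g <- runif(12, 0.05, 0.3)
  ss <- toy_summary(g, 0.07 * g + rnorm(12, 0, 0.002), 0.01,
                    runif(12, 0.005, 0.02))
  fit <- mr_ivw(ss)
  w <- ss$beta_exp^2 / ss$se_out^2
  origin <- sum((ss$beta_out / ss$beta_exp) * w) / sum(w)
  wls_origin <- sum(ss$beta_out * ss$beta_exp / ss$se_out^2) /
    sum(ss$beta_exp^2 / ss$se_out^2)
  expect_equal(fit$estimate, origin, tolerance = 1e-10)
  expect_equal(fit$estimate, wls_origin, tolerance = 1e-10)

  ss_h <- toy_summary(g, 0.05 * g, 0.01, 0.01)
  fit_h <- mr_ivw(ss_h)
  expect_equal(fit_h$estimate, 0.05, tolerance = 1e-10)
  expect_equal(fit_h$Q, 0, tolerance = 1e-10)
})

test_that("SNPs with a zero exposure association are excluded with a warning", {
  ss <- toy_summary(c(0, 0.2, 0.3), c(0.01, 0.02, 0.03), 0.01, 0.01)
  expect_warning(fit <- mr_ivw(ss), "zero exposure")
  expect_equal(fit$n_snps, 2)
})

test_that("Egger recovers an exact affine relation and the WLS solution", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  ss <- toy_summary(g, 0.005 + 0.06 * g, 0.01, 0.01)
  fit <- mr_egger(ss)
  expect_equal(fit$estimate, 0.06, tolerance = 1e-8)
  expect_equal(fit$intercept, 0.005, tolerance = 1e-8)

  ss3 <- toy_summary(c(0.1, 0.2, 0.3), c(0.02, 0.03, 0.05), 0.01,
                     c(0.01, 0.02, 0.015))
  fit3 <- mr_egger(ss3)
  oracle <- wls_oracle(ss3$beta_exp, ss3$beta_out, 1 / ss3$se_out^2)
  expect_equal(fit3$intercept, oracle[1], tolerance = 1e-10)
  expect_equal(fit3$estimate, oracle[2], tolerance = 1e-10)

  expect_error(mr_egger(toy_summary(rep(0.2, 4), 1:4 / 100, 0.01, 0.01)),
               "collinear")
  expect_error(mr_egger(toy_summary(c(0.1, 0.2), c(0.01, 0.02), 0.01, 0.01)),
               "at least 3")
})

test_that("weighted median interpolates the 50% weight crossing", {
  # equal weights, odd n: the middle order statistic
  ss_odd <- toy_summary(rep(1, 5), c(0.3, 0.1, 0.5, 0.2, 0.4), 0.1, 1)
  fit <- mr_weighted_median(ss_odd, n_boot = 10)
  expect_equal(fit$estimate, 0.3, tolerance = 1e-10)
  # weights (1, 1, 2) on ratios (0.1, 0.2, 0.3):
  # cumulative (0.125, 0.375, 0.75) -> 0.2 + 0.1 * 0.125/0.375
  ss_w <- toy_summary(c(1, 1, sqrt(2)), c(0.1, 0.2, 0.3 * sqrt(2)), 0.1, 1)
  fit_w <- mr_weighted_median(ss_w, n_boot = 10)
  expect_equal(fit_w$estimate, 0.2 + 0.1 * (0.5 - 0.375) / 0.375,
               tolerance = 1e-10)
})

test_that("mode estimator: degenerate and clustered ratio configurations", {
  ss_eq <- toy_summary(rep(0.2, 5), rep(0.2 * 0.07, 5), 0.01, 0.01)
  fit <- mr_mode(ss_eq, n_boot = 10)
  expect_equal(fit$estimate, 0.07, tolerance = 1e-6)

  set.seed(42)
  g <- rep(0.2, 10)
  ratios <- c(rep(0.08, 7) + rnorm(7, 0, 0.003), 0.5, 0.6, 0.7)
  ss_cl <- toy_summary(g, ratios * g, 0.01, 0.01)
  fit_cl <- mr_mode(ss_cl, n_boot = 50)
  expect_lt(abs(fit_cl$estimate - 0.08), fit_cl$bandwidth)
  # doubling the bandwidth moves the estimate less than the bootstrap se
  set.seed(43)
  fit_cl2 <- mr_mode(ss_cl, bandwidth_factor = 2, n_boot = 50)
  expect_lt(abs(fit_cl2$estimate - fit_cl$estimate), fit_cl$se)
})

test_that("core-gene ranking partitions SNPs and tracks IVW when homogeneous", {
  ss <- scenario("snp_clean")$summary
  fit <- mr_corge(ss, n_groups = 5)
  expect_equal(sort(unique(fit$groups)), 1:5)
  expect_equal(length(fit$groups), nrow(ss))
  expect_equal(fit$trajectory$n_snps[5], nrow(ss))
  ivw <- mr_ivw(ss)
  # homogeneous valid SNPs: flat trajectory, core close to full IVW
  expect_lt(abs(fit$estimate - ivw$estimate),
            3 * sqrt(fit$se^2 + ivw$se^2))
  expect_true(all(abs(fit$trajectory$estimate - ivw$estimate) <
                  4 * sqrt(fit$trajectory$se^2 + ivw$se^2)))
  expect_error(mr_corge(ss, n_groups = 1), "n_groups")
})

test_that("core-gene estimate resists pleiotropy planted in weak SNPs", {
  set.seed(44)
  strong <- toy_summary(runif(10, 0.3, 0.5), rep(0, 10), 0.01, 0.01)
  strong$beta_out <- 0.08 * strong$beta_exp
  weak <- toy_summary(runif(10, 0.10, 0.15), rep(0, 10), 0.01, 0.01)
  weak$beta_out <- 0.08 * weak$beta_exp + 0.03  # direct effects
  ss <- rbind(strong, weak)
  class(ss) <- c("snp_summary", "data.frame")
  fit <- mr_corge(ss, n_groups = 4)
  ivw <- mr_ivw(ss)
  # the core (strongest) group contains only valid SNPs
  expect_lt(abs(fit$estimate - 0.08), 0.005)
  expect_gt(ivw$estimate, 0.095)
})

test_that("leave-one-out flags exactly a planted heavy outlier", {
  ss_h <- scenario("snp_clean")$summary
  loo_h <- mr_leave_one_out(ss_h, mr_ivw)
  expect_equal(nrow(loo_h), nrow(ss_h))
  expect_false(any(loo_h$flag))

  g <- c(rep(0.2, 9), 0.4)
  ratios <- c(rep(0.08, 9), 0.5)
  ss_o <- toy_summary(g, ratios * g, 0.01, 0.01)
  loo_o <- mr_leave_one_out(ss_o, mr_ivw)
  expect_identical(which(loo_o$flag), 10L)
  expect_error(mr_leave_one_out(ss_o[1:3, ], mr_ivw), "at least 4")
})

test_that("estimators are invariant to allele re-coding and SNP order", {
  ss <- scenario("snp_clean")$summary
  flipped <- ss
  i <- seq(1, nrow(ss), by = 2)
  flipped$beta_exp[i] <- -flipped$beta_exp[i]
  flipped$beta_out[i] <- -flipped$beta_out[i]
  flipped$eaf[i] <- 1 - flipped$eaf[i]
  ea <- flipped$ea[i]; flipped$ea[i] <- flipped$nea[i]; flipped$nea[i] <- ea
  flipped <- harmonize_summary(flipped)
  expect_equal(mr_ivw(flipped)$estimate, mr_ivw(ss)$estimate,
               tolerance = 1e-10)
  expect_equal(mr_egger(flipped)$estimate, mr_egger(ss)$estimate,
               tolerance = 1e-10)

  perm <- ss[sample(nrow(ss)), ]
  expect_equal(mr_ivw(perm)$estimate, mr_ivw(ss)$estimate, tolerance = 1e-10)
  expect_equal(mr_egger(perm)$estimate, mr_egger(ss)$estimate,
               tolerance = 1e-10)
  set.seed(7); m1 <- mr_weighted_median(ss, n_boot = 10)$estimate
  set.seed(7); m2 <- mr_weighted_median(perm, n_boot = 10)$estimate
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("per-SNP associations recover the panel's true effects", {
  sc <- scenario("snp_clean")
  ss <- sc$summary
  expect_true(all(ss$beta_exp >= 0))
  truth <- sc$pop$panel$true_schooling_effect[match(ss$snp, sc$pop$panel$snp)]
  # harmonization flips the sign of truth along with the coding
  aligned <- abs(truth)
  expect_gt(cor(ss$beta_exp, aligned), 0.9)
  # no-pleiotropy: IVW agrees with individual-level 2SLS within 10%
  tsls <- fit_returns(sc$samples$genotyped, "log", "mr")
  ivw <- mr_ivw(ss)
  expect_lt(abs(ivw$estimate - tsls$beta), 0.1 * abs(tsls$beta) + 2 * ivw$se)
})

test_that("monomorphic SNPs are dropped from the association scan", {
  sc <- scenario("null_small")
  smp <- sc$samples$genotyped
  smp$G[, 3] <- 1L
  expect_warning(ss <- per_snp_associations(smp), "monomorphic")
  expect_equal(nrow(ss), ncol(smp$G) - 1)
})

test_that("summary tables round-trip through the GWAS file format", {
  ss <- scenario("snp_clean")$summary
  f <- tempfile(fileext = ".tsv")
  write_snp_summary(ss, f)
  back <- read_snp_summary(f)
  expect_equal(back$beta_exp, ss$beta_exp, tolerance = 1e-12)
  expect_equal(back$se_out, ss$se_out, tolerance = 1e-12)
  expect_equal(mr_ivw(back)$estimate, mr_ivw(ss)$estimate, tolerance = 1e-10)
})
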