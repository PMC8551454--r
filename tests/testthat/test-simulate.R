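test_that("configuration is validated and structure-inconsistent effects are zeroed", {
  expect_error(sim_config(maf_spectrum = 0.6), "maf_spectrum")
  expect_error(sim_config(maf_spectrum = 0), "maf_spectrum")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(true_model = 3), "true_model")
  c0 <- sim_config(true_model = 0, beta_m_y = -0.7, beta_y_m = -0.7)
  expect_identical(c(c0$beta_m_y, c0$beta_y_m), c(0, 0))
  c1 <- sim_config(true_model = 1, beta_m_y = -0.7, beta_y_m = -0.7)
  expect_identical(c(c1$beta_m_y, c1$beta_y_m), c(-0.7, 0))
  c2 <- sim_config(true_model = 2, beta_m_y = -0.7, beta_y_m = -0.7)
  expect_identical(c(c2$beta_m_y, c2$beta_y_m), c(0, -0.7))
})

test_that("identical config and seed reproduce identical datasets", {
  cfg <- sim_config(n_subjects = 300, n_snps = 20, n_pleiotropic = 3,
                    true_model = 1, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  d3 <- simulate_dataset(sim_config(n_subjects = 300, n_snps = 20,
                                    n_pleiotropic = 3, true_model = 1,
                                    seed = 78))
  expect_false(identical(d1$phenotypes$fa, d3$phenotypes$fa))
})

test_that("empirical MAF stays within exact binomial bounds of the target", {
  n <- 4000
  g <- simulate_genotypes(sim_config(n_subjects = n, n_snps = 40,
                                     maf_spectrum = 0.01, seed = 5))
  counts <- colSums(dplyr::select(g, -IID))
  # each SNP's minor-allele count is Binomial(2n, 0.01): check 99.9% bounds
  lo <- qbinom(5e-4, 2 * n, 0.01)
  hi <- qbinom(1 - 5e-4, 2 * n, 0.01)
  expect_true(all(counts >= lo & counts <= hi))

  g5 <- simulate_genotypes(sim_config(n_subjects = 20000, n_snps = 5,
                                      maf_spectrum = 0.5, seed = 6))
  expect_equal(unname(colMeans(dplyr::select(g5, -IID))), rep(1, 5),
               tolerance = 0.02)
})

test_that("dosages follow Hardy-Weinberg proportions when SNPs are independent", {
  g <- simulate_genotypes(sim_config(n_subjects = 20000, n_snps = 6,
                                     maf_spectrum = c(0.1, 0.2, 0.3, 0.4, 0.45, 0.5),
                                     ld_rho = 0, seed = 8))
  dos <- as.matrix(dplyr::select(g, -IID))
  maf <- c(0.1, 0.2, 0.3, 0.4, 0.45, 0.5)
  for (j in seq_len(6)) {
    obs <- tabulate(dos[, j] + 1, nbins = 3)
    expected <- 20000 * c((1 - maf[j])^2, 2 * maf[j] * (1 - maf[j]), maf[j]^2)
    expect_gt(suppressWarnings(chisq.test(obs, p = expected / 20000)$p.value),
              1e-4)
  }
})

test_that("adjacent-SNP dosage correlation under LD matches a re-simulation oracle", {
  n <- 50000
  rho <- 0.9
  maf <- rep(0.3, 2)
  g <- simulate_genotypes(sim_config(n_subjects = n, n_snps = 2,
                                     maf_spectrum = maf, ld_rho = rho,
                                     seed = 9))
  dos <- as.matrix(dplyr::select(g, -IID))
  r_obs <- cor(dos[, 1], dos[, 2])

  # brute-force oracle: independently re-simulate the same thresholding scheme
  oracle <- withr::with_seed(991, {
    hap <- function() {
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      cbind(z1 > qnorm(1 - 0.3), z2 > qnorm(1 - 0.3)) * 1
    }
    d <- hap() + hap()
    cor(d[, 1], d[, 2])
  })
  expect_lt(abs(r_obs - oracle), 0.02)
  expect_gt(r_obs, 0.5)  # "strong LD" regime really is strong
})

test_that("under the global null, per-SNP association p-values are uniform", {
  d <- simulate_dataset(sim_config(n_subjects = 1000, n_snps = 400,
                                   n_pleiotropic = 0, seed = 10))
  res <- identify_pleiotropic(d$genotypes, d$phenotypes) |>
    suppressMessages()
  frac <- mean(res$p_snp_fa < 0.05)
  # 400 SNPs: binomial(400, 0.05) 3-sigma band
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  ks <- ks.test(res$p_snp_fa, "punif")$p.value
  expect_gt(ks, 0.001)
})

test_that("model 1 with continuous outcome obeys the OLS total-effect identity", {
  cfg <- sim_config(n_subjects = 5000, n_snps = 1, n_pleiotropic = 1,
                    true_model = 1, beta_g_m = 0.3, beta_m_y = 0.5,
                    beta_g_y = 0.1, outcome_type = "continuous", seed = 11)
  d <- simulate_dataset(cfg)
  dat <- one_snp_data(d)
  fit <- fit_snp_regression(dat, "cpd", "snp_1", c("age", "sex"),
                            family = "linear")
  s <- dplyr::filter(tidy(fit), term == "snp_1")
  expect_lt(abs(s$estimate - (0.1 + 0.3 * 0.5)), 3 * s$std.error)
})

test_that("model 0 yields conditional independence; models 1/2 break it", {
  # large-n partial-correlation oracle on the generated data
  pcor_p <- function(d, y_col) {
    rm_ <- resid(lm(reformulate(c("snp_1", "age", "sex"), "fa"), data = d))
    ry <- resid(lm(reformulate(c("snp_1", "age", "sex"), y_col), data = d))
    cor.test(rm_, ry)$p.value
  }
  base <- list(n_subjects = 20000, n_snps = 1, n_pleiotropic = 1,
               outcome_type = "continuous", seed = 12)
  d0 <- simulate_dataset(do.call(sim_config, c(base, true_model = 0)))
  expect_gt(pcor_p(one_snp_data(d0), "cpd"), 0.01)
  d1 <- simulate_dataset(do.call(sim_config, c(base, true_model = 1)))
  expect_lt(pcor_p(one_snp_data(d1), "cpd"), 1e-10)
  d2 <- simulate_dataset(do.call(sim_config, c(base, true_model = 2)))
  expect_lt(pcor_p(one_snp_data(d2), "cpd"), 1e-10)
})

test_that("a degenerate binary outcome triggers a warning", {
  cfg <- sim_config(n_subjects = 50, n_snps = 1, n_pleiotropic = 0,
                    alpha_y = 30, seed = 13)
  expect_warning(simulate_dataset(cfg), "degenerate")
})

test_that("replicate seeds are reproducible and distinct", {
  s1 <- replicate_seeds(42, 10)
  s2 <- replicate_seeds(42, 10)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 10)
})
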