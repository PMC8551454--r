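test_that("all-linear decomposition satisfies total = direct + indirect exactly", {
  d <- simulate_dataset(sim_config(n_subjects = 2000, n_snps = 1,
                                   n_pleiotropic = 1, true_model = 1,
                                   beta_g_m = 0.4, beta_m_y = 0.5,
                                   beta_g_y = 0.1,
                                   outcome_type = "continuous", seed = 51))
  dat <- one_snp_data(d)
  fits <- fit_pathway_models(dat, "snp_1", outcome = "cpd")
  dec <- decompose_effects(fits, "1")
  expect_equal(dec$total, dec$direct + dec$indirect, tolerance = 1e-8)
  expect_equal(dec$indirect, dec$path_a * dec$path_b, tolerance = 1e-12)
  # estimates near the generating values
  expect_lt(abs(dec$path_a - 0.4), 3 * dec$path_a_se)
  expect_lt(abs(dec$path_b - 0.5), 3 * dec$path_b_se)
  expect_lt(abs(dec$direct - 0.1), 3 * dec$direct_se)

  # model 2 mirror: total effect on the mediator decomposes the same way
  d2 <- simulate_dataset(sim_config(n_subjects = 2000, n_snps = 1,
                                    n_pleiotropic = 1, true_model = 2,
                                    beta_g_m = 0.1, beta_g_y = 0.4,
                                    beta_y_m = 0.5,
                                    outcome_type = "continuous", seed = 52))
  fits2 <- fit_pathway_models(one_snp_data(d2), "snp_1", outcome = "cpd")
  dec2 <- decompose_effects(fits2, "2")
  expect_equal(dec2$total, dec2$direct + dec2$indirect, tolerance = 1e-8)
  expect_error(decompose_effects(fits2, "3"), "model_label")
})

test_that("logistic-path decomposition recovers generating log-odds products", {
  d <- simulate_dataset(sim_config(n_subjects = 10000, n_snps = 1,
                                   n_pleiotropic = 1, true_model = 2,
                                   beta_g_y = 0.3, beta_y_m = -0.5,
                                   beta_g_m = 0.1, seed = 53))
  fits <- fit_pathway_models(one_snp_data(d), "snp_1")
  dec <- decompose_effects(fits, "2")
  se_prod <- sqrt(dec$path_a^2 * dec$path_b_se^2 +
                    dec$path_b^2 * dec$path_a_se^2)
  expect_lt(abs(dec$indirect - 0.3 * (-0.5)), 3 * se_prod)
  expect_lt(abs(dec$direct - 0.1), 3 * dec$direct_se)
})

test_that("Sobel z matches the closed-form statistic", {
  d <- simulate_dataset(sim_config(n_subjects = 1500, n_snps = 1,
                                   n_pleiotropic = 1, true_model = 1,
                                   beta_m_y = -0.8, seed = 54))
  dat <- one_snp_data(d)
  res <- test_indirect_effect(dat, "snp_1", model_label = "1",
                              method = "sobel")
  fits <- fit_pathway_models(dat, "snp_1")
  a <- dplyr::filter(tidy(fits$m_on_g), term == "snp_1")
  b <- dplyr::filter(tidy(fits$y_on_gm), term == "fa")
  se <- sqrt(a$estimate^2 * b$std.error^2 + b$estimate^2 * a$std.error^2)
  z <- a$estimate * b$estimate / se
  expect_equal(res$indirect, a$estimate * b$estimate, tolerance = 1e-10)
  expect_equal(res$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
})

test_that("the bootstrap is seed-reproducible and powered for strong effects", {
  d <- simulate_dataset(sim_config(n_subjects = 2000, n_snps = 1,
                                   n_pleiotropic = 1, true_model = 1,
                                   beta_g_m = 0.3, beta_m_y = -0.5, seed = 55))
  dat <- one_snp_data(d)
  r1 <- test_indirect_effect(dat, "snp_1", model_label = "1",
                             n_boot = 300, seed = 9)
  r2 <- test_indirect_effect(dat, "snp_1", model_label = "1",
                             n_boot = 300, seed = 9)
  expect_identical(r1, r2)
  expect_lt(r1$p.value, 0.01)
  expect_true(r1$ci_lower <= r1$indirect & r1$indirect <= r1$ci_upper)
  expect_error(test_indirect_effect(dat, "snp_1", n_boot = 100), "at least 200")
})

test_that("bootstrap intervals cover the true indirect effect at about 95%", {
  a_true <- 0.4; b_true <- 0.5
  seeds <- replicate_seeds(56, 60)
  covered <- vapply(seeds, function(s) {
    d <- simulate_dataset(sim_config(n_subjects = 500, n_snps = 1,
                                     n_pleiotropic = 1, true_model = 1,
                                     beta_g_m = a_true, beta_m_y = b_true,
                                     outcome_type = "continuous", seed = s))
    r <- test_indirect_effect(one_snp_data(d), "snp_1", outcome = "cpd",
                              model_label = "1", n_boot = 200, seed = s)
    r$ci_lower <= a_true * b_true && a_true * b_true <= r$ci_upper
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 3 * sqrt(0.95 * 0.05 / 60))
})

test_that("indirect-effect tests keep their size under the product null", {
  seeds <- replicate_seeds(57, 150)
  rej <- vapply(seeds, function(s) {
    d <- simulate_dataset(sim_config(n_subjects = 400, n_snps = 1,
                                     n_pleiotropic = 0, true_model = 1,
                                     beta_m_y = 0,
                                     outcome_type = "continuous", seed = s))
    test_indirect_effect(one_snp_data(d), "snp_1", outcome = "cpd",
                         model_label = "1", method = "sobel")$p.value < 0.05
  }, logical(1))
  # the double null makes Sobel conservative: at or below nominal size
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 150))
})

test_that("mediation typology covers every sign/significance combination", {
  grid <- expand.grid(ind = c(-1, 1), ind_p = c(0.01, 0.5),
                      dir = c(-1, 1), dir_p = c(0.01, 0.5))
  got <- classify_mediation(grid$ind, grid$ind_p, grid$dir, grid$dir_p)
  expected <- ifelse(grid$ind_p >= 0.05, "none",
               ifelse(grid$dir_p >= 0.05, "indirect_only",
                ifelse(sign(grid$ind) == sign(grid$dir),
                       "complementary", "competitive")))
  expect_identical(got, expected)
  # printed-pattern case: positive significant direct, negative significant
  # indirect is competitive mediation
  expect_identical(classify_mediation(-0.2, 0.001, 0.3, 0.001), "competitive")
  expect_identical(classify_mediation(0.2, 0.001, 0.3, 0.001), "complementary")
  expect_identical(classify_mediation(0.2, 0.001, 0.3, 0.4), "indirect_only")
  expect_identical(classify_mediation(NA, NA_real_, 0.3, 0.4), NA_character_)
})

test_that("run_mediation assembles results for vertical SNPs only", {
  d <- simulate_dataset(sim_config(n_subjects = 2000, n_snps = 10,
                                   n_pleiotropic = 3, true_model = 1,
                                   beta_g_m = -0.5, beta_g_y = 0.3,
                                   beta_m_y = -1.5, seed = 58))
  path <- suppressMessages(discover_pathways(d$genotypes, d$phenotypes))
  med <- run_mediation(d$genotypes, d$phenotypes, path, n_boot = 200, seed = 3)
  expect_equal(nrow(med), sum(path$selected_model %in% c("1", "2")))
  expect_true(all(med$mediation_type %in%
                    c("complementary", "competitive", "indirect_only", "none")))
  empty <- path[0, ]
  expect_message(m0 <- run_mediation(d$genotypes, d$phenotypes, empty),
                 "nothing to mediate")
  expect_equal(nrow(m0), 0)
})
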