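# Monte-Carlo calibration studies for the pipeline's two error-rate
# guarantees and for the consistency of the BIC model selection. These are
# the package's own operating-characteristic checks: each study regenerates
# synthetic cohorts under known truth and scores the procedure against it.

#' Empirical FDR of the step-1 pleiotropy screen
#'
#' Repeatedly simulates cohorts in which a known subset of SNPs carries
#' pleiotropic effects on both traits, runs [identify_pleiotropic()] at the
#' given FDR target, and scores discoveries against the generating truth.
#' The false-discovery proportion of a replicate is the fraction of declared
#' SNPs that are truly null (0 when nothing is declared); the empirical FDR
#' is its mean over replicates.
#'
#' @param n_replicates Number of simulation replicates. Default `200`.
#' @param config A [sim_config()] describing one cohort; its `seed` is
#'   ignored in favour of per-replicate seeds derived from `master_seed`.
#' @param fdr_target Step-1 FDR target. Default `0.15`.
#' @param master_seed Seed for the replicate streams.
#' @return A tibble with one row per replicate (`n_discoveries`, `n_false`,
#'   `fdp`, `power`); summary statistics (`mean_fdr`, `mc_se`, `mean_power`)
#'   are attached as attribute `"summary"`.
#' @export
fdr_calibration_study <- function(n_replicates = 200, config = sim_config(),
                                  fdr_target = 0.15, master_seed = 1L) {
  seeds <- replicate_seeds(master_seed, n_replicates)
  rows <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    d <- simulate_dataset(cfg)
    res <- suppressMessages(
      identify_pleiotropic(d$genotypes, d$phenotypes,
                           outcome = d$truth$outcome_col,
                           fdr_target = fdr_target)
    )
    truth <- d$truth$snps$snp_id[d$truth$snps$pleiotropic]
    disc <- res$snp_id[res$pleiotropic]
    n_false <- sum(!disc %in% truth)
    tibble::tibble(
      replicate = i,
      n_discoveries = length(disc),
      n_false = n_false,
      fdp = if (length(disc) == 0) 0 else n_false / length(disc),
      power = if (length(truth) == 0) NA_real_ else mean(truth %in% disc)
    )
  })
  attr(rows, "summary") <- list(
    mean_fdr = mean(rows$fdp),
    mc_se = stats::sd(rows$fdp) / sqrt(n_replicates),
    mean_power = mean(rows$power)
  )
  rows
}

#' Size of the step-2 conditional-independence test under horizontal pleiotropy
#'
#' Generates replicates under model 0 -- the SNP affects both the mediator
#' and the outcome, which are conditionally independent given genotype and
#' covariates -- and reports how often [test_conditional_independence()]
#' classifies the replicate as vertical. Under the null this misclassification
#' rate should match the nominal level `alpha`.
#'
#' @param n_replicates Number of replicates. Default `2000`.
#' @param n_subjects Cohort size per replicate. Default `2000`.
#' @param beta_g_m,beta_g_y SNP effects on mediator and outcome. Default
#'   `0.3` each.
#' @param outcome_type `"binary"` (default) or `"continuous"`.
#' @param alpha Nominal level of the test. Default `0.05`.
#' @param master_seed Seed for the replicate streams.
#' @return A tibble with one row per replicate (`ci_p`, `classification`);
#'   the vertical fraction and its binomial standard error are attached as
#'   attribute `"summary"`.
#' @export
ci_size_study <- function(n_replicates = 2000, n_subjects = 2000,
                          beta_g_m = 0.3, beta_g_y = 0.3,
                          outcome_type = "binary", alpha = 0.05,
                          master_seed = 1L) {
  seeds <- replicate_seeds(master_seed, n_replicates)
  outcome <- if (outcome_type == "binary") "ss" else "cpd"
  rows <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    d <- simulate_dataset(sim_config(
      n_subjects = n_subjects, n_snps = 1, n_pleiotropic = 1, true_model = 0,
      beta_g_m = beta_g_m, beta_g_y = beta_g_y, outcome_type = outcome_type,
      seed = seeds[i]
    ))
    dat <- dplyr::bind_cols(d$phenotypes, d$genotypes["snp_1"])
    ci <- test_conditional_independence(dat, "snp_1", outcome = outcome,
                                        alpha = alpha)
    tibble::tibble(replicate = i, ci_p = ci$ci_p,
                   classification = ci$classification)
  })
  frac <- mean(rows$classification == "vertical", na.rm = TRUE)
  attr(rows, "summary") <- list(
    vertical_fraction = frac,
    binom_se = sqrt(alpha * (1 - alpha) / n_replicates),
    nominal = alpha
  )
  rows
}

#' Consistency of the BIC mediation-model selection
#'
#' Simulates single-SNP cohorts under each vertical model (binary outcome;
#' the logistic link is what makes the two factorizations distinguishable)
#' across a grid of sample sizes, and reports the fraction of replicates in
#' which [select_mediation_model()] recovers the generating model. Selection
#' accuracy should be monotone non-decreasing in the sample size.
#'
#' @param n_grid Sample sizes. Default `c(500, 2000, 10000)`.
#' @param n_replicates Replicates per (model, n) cell. Default `150`.
#' @param beta_g Per-allele SNP effect on the first trait of the generating
#'   pathway. Default `0.5`.
#' @param beta_cross Mediator-outcome cross effect. Default `-1.5`; cross
#'   effects of this magnitude are needed for the two factorizations to
#'   separate at desk-scale n.
#' @param beta_direct Direct SNP effect on the downstream trait. Default `0.1`.
#' @param master_seed Seed for the replicate streams.
#' @return A tibble with one row per (true_model, n): `accuracy`,
#'   `n_replicates`.
#' @export
selection_consistency_study <- function(n_grid = c(500, 2000, 10000),
                                        n_replicates = 150, beta_g = 0.5,
                                        beta_cross = -1.5, beta_direct = 0.1,
                                        master_seed = 1L) {
  cells <- tidyr::expand_grid(true_model = c(1L, 2L), n = n_grid)
  seeds <- replicate_seeds(master_seed, n_replicates * nrow(cells))
  purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    tm <- cells$true_model[ci]
    n <- cells$n[ci]
    cell_seeds <- seeds[seq_len(n_replicates) + (ci - 1) * n_replicates]
    correct <- vapply(cell_seeds, function(s) {
      cfg <- if (tm == 1) {
        sim_config(n_subjects = n, n_snps = 1, n_pleiotropic = 1,
                   true_model = 1, beta_g_m = beta_g, beta_m_y = beta_cross,
                   beta_g_y = beta_direct, seed = s)
      } else {
        sim_config(n_subjects = n, n_snps = 1, n_pleiotropic = 1,
                   true_model = 2, beta_g_y = beta_g, beta_y_m = beta_cross,
                   beta_g_m = beta_direct, seed = s)
      }
      d <- simulate_dataset(cfg)
      dat <- dplyr::bind_cols(d$phenotypes, d$genotypes["snp_1"])
      sel <- select_mediation_model(dat, "snp_1")
      identical(sel$selected_model, as.character(tm))
    }, logical(1))
    tibble::tibble(true_model = tm, n = n, accuracy = mean(correct),
                   n_replicates = n_replicates)
  })
}
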