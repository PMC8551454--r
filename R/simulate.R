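# Synthetic genotype-covariate-mediator-outcome generator. Datasets are drawn
# under one of three causal structures:
#   model 0 (horizontal pleiotropy): SNP -> FA and SNP -> smoking, FA and
#     smoking conditionally independent given genotype and covariates;
#   model 1 (vertical, imaging mediator): SNP -> FA -> smoking;
#   model 2 (vertical, behavioural mediator): SNP -> smoking -> FA.
# Binary smoking status is generated through a logistic link; cigarettes/day
# as a Gaussian linear model. LD is emulated by a latent Gaussian AR(1) per
# haplotype thresholded at the (1 - MAF) quantile, two haplotypes summed.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort generator.
#' Defaults describe the desk-scale study conditions used throughout the
#' package's calibration simulations: 2,000 subjects, 500 independent SNPs of
#' which 50 carry pleiotropic effects of 0.3 per minor-allele copy on both the
#' FA mediator (in residual-SD units) and the smoking outcome (log-odds), a
#' binary smoking-status outcome, and unit residual standard deviations.
#'
#' Effects inconsistent with the declared causal structure are zeroed:
#' `beta_m_y` and `beta_y_m` under model 0, `beta_y_m` under model 1,
#' `beta_m_y` under model 2. Exactly one structure generates each dataset.
#'
#' @param n_subjects Number of subjects.
#' @param n_snps Number of SNPs.
#' @param maf_spectrum Per-SNP minor-allele frequency, strictly in (0, 0.5].
#'   A scalar is recycled; default an even grid on \[0.05, 0.5\].
#' @param ld_rho Latent adjacent-SNP AR(1) correlation in \[0, 1); 0 (default)
#'   gives independent SNPs in Hardy-Weinberg proportions.
#' @param true_model Generating causal structure: 0, 1 or 2.
#' @param n_pleiotropic Number of non-null SNPs (the first `n_pleiotropic`
#'   columns carry effects); default 50, capped at `n_snps`.
#' @param beta_g_m SNP effect on the mediator (FA units per allele).
#' @param beta_g_y SNP effect on the outcome (log-odds or CPD units per allele).
#' @param beta_m_y Mediator effect on the outcome (model 1 only); negative
#'   by default, reflecting lower white-matter integrity with heavier smoking.
#' @param beta_y_m Outcome effect on the mediator (model 2 only); negative by
#'   default for the same reason.
#' @param sigma_m,sigma_y Residual standard deviations of the mediator and of
#'   a continuous outcome.
#' @param outcome_type `"binary"` (smoking status, logistic link) or
#'   `"continuous"` (cigarettes per day).
#' @param covariate_effects Named numeric vector `c(age = ..., sex = ...)`
#'   applied to centred age (years - 55) and sex, in both trait models.
#' @param alpha_m,alpha_y Intercepts of the mediator and outcome models. The
#'   default outcome intercept -0.85 yields roughly 30% smoking prevalence.
#' @param seed Master seed; all randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 500, n_snps = 20, true_model = 1, seed = 42)
#' str(cfg[c("true_model", "beta_g_m", "beta_m_y")])
#' @export
sim_config <- function(n_subjects = 2000,
                       n_snps = 500,
                       maf_spectrum = NULL,
                       ld_rho = 0,
                       true_model = 0,
                       n_pleiotropic = NULL,
                       beta_g_m = 0.3,
                       beta_g_y = 0.3,
                       beta_m_y = -0.5,
                       beta_y_m = -0.5,
                       sigma_m = 1,
                       sigma_y = 1,
                       outcome_type = c("binary", "continuous"),
                       covariate_effects = c(age = 0.01, sex = -0.1),
                       alpha_m = 0,
                       alpha_y = -0.85,
                       seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_subjects >= 1, n_snps >= 1, sigma_m > 0, sigma_y > 0)
  if (is.null(n_pleiotropic)) n_pleiotropic <- min(50L, n_snps)
  stopifnot(n_pleiotropic >= 0, n_pleiotropic <= n_snps)
  if (!true_model %in% c(0, 1, 2)) {
    stop("`true_model` must be 0, 1 or 2", call. = FALSE)
  }
  if (is.null(maf_spectrum)) {
    maf_spectrum <- seq(0.05, 0.5, length.out = n_snps)
  }
  maf_spectrum <- rep_len(maf_spectrum, n_snps)
  if (any(maf_spectrum <= 0 | maf_spectrum > 0.5)) {
    stop("`maf_spectrum` entries must lie strictly in (0, 0.5]", call. = FALSE)
  }
  if (ld_rho < 0 || ld_rho >= 1) {
    stop("`ld_rho` must lie in [0, 1)", call. = FALSE)
  }
  if (!all(c("age", "sex") %in% names(covariate_effects))) {
    stop("`covariate_effects` must name `age` and `sex`", call. = FALSE)
  }
  # zero effects that the declared causal structure does not contain
  if (true_model == 0) { beta_m_y <- 0; beta_y_m <- 0 }
  if (true_model == 1) beta_y_m <- 0
  if (true_model == 2) beta_m_y <- 0
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
      maf_spectrum = maf_spectrum, ld_rho = ld_rho,
      true_model = as.integer(true_model),
      n_pleiotropic = as.integer(n_pleiotropic),
      beta_g_m = beta_g_m, beta_g_y = beta_g_y,
      beta_m_y = beta_m_y, beta_y_m = beta_y_m,
      sigma_m = sigma_m, sigma_y = sigma_y,
      outcome_type = outcome_type,
      covariate_effects = covariate_effects,
      alpha_m = alpha_m, alpha_y = alpha_y,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# One haplotype matrix: latent AR(1) Gaussians thresholded at the (1 - maf)
# quantile, so each column is Bernoulli(maf) with adjacent-column dependence.
simulate_haplotype <- function(n, maf, ld_rho) {
  m <- length(maf)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (ld_rho > 0 && m > 1) {
    w <- sqrt(1 - ld_rho^2)
    for (j in 2:m) z[, j] <- ld_rho * z[, j - 1] + w * z[, j]
  }
  thr <- stats::qnorm(1 - maf)
  sweep(z, 2, thr, `>`) * 1L
}

#' Simulate additive genotype dosages
#'
#' Draws an `n_subjects` by `n_snps` matrix of minor-allele dosages (0/1/2) by
#' summing two independent haplotypes, each a latent Gaussian AR(1) process
#' thresholded at the MAF-matched quantile. With `ld_rho = 0` the marginal
#' dosage distribution is exactly Hardy-Weinberg: Binomial(2, MAF).
#'
#' @param config A [sim_config()].
#' @return A tibble with subject identifier `IID` and one dosage column per
#'   SNP (`snp_1`, ...). SNP metadata (identifier, chromosome, 1-based
#'   position, target and empirical MAF) is attached as attribute `"snps"`,
#'   retrievable with [snp_info()].
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 100, n_snps = 5, seed = 3))
#' snp_info(g)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_genotypes_impl(config))
}

simulate_genotypes_impl <- function(config) {
  n <- config$n_subjects
  maf <- config$maf_spectrum
  if (config$ld_rho == 0) {
    # independent SNPs: thresholded-normal haplotypes reduce to Bernoulli(maf),
    # so draw Binomial(2, maf) dosages directly
    dos <- vapply(maf, function(f) stats::rbinom(n, 2L, f), integer(n))
  } else {
    dos <- simulate_haplotype(n, maf, config$ld_rho) +
      simulate_haplotype(n, maf, config$ld_rho)
  }
  snp_id <- paste0("snp_", seq_along(maf))
  colnames(dos) <- snp_id
  geno <- tibble::tibble(IID = sprintf("S%05d", seq_len(n)))
  geno <- dplyr::bind_cols(geno, tibble::as_tibble(dos))
  snps <- tibble::tibble(
    snp_id = snp_id,
    chr = 1L,
    bp = 100000L + (seq_along(maf) - 1L) * 50000L,
    counted_allele = "A",
    other_allele = "G",
    maf_target = maf,
    maf = unname(colMeans(dos)) / 2
  )
  attr(geno, "snps") <- snps
  class(geno) <- c("geno_tbl", class(geno))
  geno
}

#' SNP metadata of a genotype table
#'
#' @param geno A genotype tibble produced by [simulate_genotypes()],
#'   [read_genotypes()] or [apply_genotype_qc()].
#' @return A tibble of per-SNP metadata (`snp_id`, `chr`, `bp`, alleles, MAF).
#' @export
snp_info <- function(geno) {
  s <- attr(geno, "snps")
  if (is.null(s)) stop("`geno` carries no SNP metadata", call. = FALSE)
  s
}

dosage_matrix <- function(geno) {
  cols <- setdiff(names(geno), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  m <- as.matrix(geno[cols])
  rownames(m) <- geno$IID
  m
}

#' Simulate a full genotype-phenotype dataset under one causal structure
#'
#' Generates genotypes, covariates (age uniform on 40-70, sex Bernoulli(0.5)),
#' a continuous FA mediator and a smoking outcome under the causal structure
#' declared in the configuration. The first `n_pleiotropic` SNPs enter the
#' trait models additively with the configured per-allele effects; the rest
#' are null. Under model 0 the mediator and outcome are conditionally
#' independent given genotype and covariates; under model 1 the outcome
#' responds to the mediator; under model 2 the mediator responds to the
#' outcome. All generating parameters are returned in a truth record so
#' recovery and error-rate simulations can score results against the truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (tibble, see
#'   [simulate_genotypes()]), `phenotypes` (tibble: `IID`, `age`, `sex`, `fa`,
#'   and `ss` + `smoking_group` for binary outcomes or `cpd` for continuous),
#'   and `truth` (list: the config plus a per-SNP tibble of generating
#'   effects).
#' @examples
#' d <- simulate_dataset(sim_config(n_subjects = 200, n_snps = 10,
#'                                  n_pleiotropic = 2, seed = 9))
#' head(d$phenotypes)
#' dplyr::filter(d$truth$snps, pleiotropic)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  geno <- simulate_genotypes_impl(config)
  n <- config$n_subjects
  G <- dosage_matrix(geno)
  k <- config$n_pleiotropic
  b_m <- c(rep(config$beta_g_m, k), rep(0, config$n_snps - k))
  b_y <- c(rep(config$beta_g_y, k), rep(0, config$n_snps - k))
  g_m <- unname(drop(G %*% b_m))
  g_y <- unname(drop(G %*% b_y))

  age <- stats::runif(n, 40, 70)
  sex <- stats::rbinom(n, 1, 0.5)
  # covariates enter both trait models on the centred-age scale
  zeff <- config$covariate_effects[["age"]] * (age - 55) +
    config$covariate_effects[["sex"]] * sex

  draw_outcome <- function(lp) {
    if (config$outcome_type == "binary") {
      y <- stats::rbinom(n, 1, stats::plogis(lp))
      if (length(unique(y)) < 2) {
        warning("degenerate binary outcome: all subjects have Y = ",
                y[1], call. = FALSE)
      }
      y
    } else {
      lp + stats::rnorm(n, sd = config$sigma_y)
    }
  }

  if (config$true_model == 2) {
    y <- draw_outcome(config$alpha_y + g_y + zeff)
    m <- config$alpha_m + g_m + config$beta_y_m * y + zeff +
      stats::rnorm(n, sd = config$sigma_m)
  } else {
    m <- config$alpha_m + g_m + zeff + stats::rnorm(n, sd = config$sigma_m)
    med <- if (config$true_model == 1) config$beta_m_y * m else 0
    y <- draw_outcome(config$alpha_y + g_y + med + zeff)
  }

  pheno <- tibble::tibble(IID = geno$IID, age = age, sex = sex, fa = m)
  if (config$outcome_type == "binary") {
    pheno$ss <- y
    pheno$smoking_group <- ifelse(y == 1, "current", "never")
  } else {
    pheno$cpd <- y
  }

  truth <- list(
    config = config,
    snps = tibble::tibble(
      snp_id = snp_info(geno)$snp_id,
      pleiotropic = seq_len(config$n_snps) <= k,
      beta_g_m = b_m,
      beta_g_y = b_y
    ),
    outcome_col = if (config$outcome_type == "binary") "ss" else "cpd"
  )
  list(genotypes = geno, phenotypes = pheno, truth = truth)
}

#' Derive independent replicate seeds from a master seed
#'
#' Gives each simulation replicate its own reproducible random stream, so any
#' single replicate of a Monte-Carlo study can be regenerated in isolation.
#'
#' @param master_seed Integer master seed.
#' @param n_replicates Number of replicate seeds to produce.
#' @return An integer vector of length `n_replicates`.
#' @export
replicate_seeds <- function(master_seed, n_replicates) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max, n_replicates))
}
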