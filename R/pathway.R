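# Three-step causal pathway discovery per candidate SNP:
#   step 1 -- composite-null screen for pleiotropy (associated with BOTH the
#             FA mediator and the smoking phenotype) with overall FDR control;
#   step 2 -- conditional-independence test of FA vs smoking given the SNP:
#             independence => horizontal pleiotropy (model 0), otherwise
#             vertical;
#   step 3 -- BIC selection between the two vertical mediation models,
#             model 1 (SNP -> FA -> smoking) vs model 2 (SNP -> smoking -> FA),
#             comparing maximized joint likelihoods (equal parameter counts).

#' Identify potentially pleiotropic variants (step 1)
#'
#' For each SNP, fits the SNP--FA linear model and the SNP--smoking model
#' (logistic for binary status, linear for cigarettes/day), both adjusted for
#' covariates. Pleiotropy is a composite hypothesis -- the variant must be
#' associated with *both* traits -- so the default procedure takes the
#' per-SNP maximum of the two Wald p-values (valid and conservative for the
#' composite null) and applies Benjamini-Hochberg to the max-p list at the
#' overall FDR target (default 0.15). A `"separate"` switch instead runs BH
#' per trait and intersects the two discovery sets.
#'
#' @param geno Genotype tibble (`IID` + dosage columns).
#' @param pheno Phenotype tibble with an `IID` column.
#' @param fa_measure Name of the FA mediator column. Default `"fa"`.
#' @param outcome Name of the smoking column (`"ss"` or `"cpd"`).
#' @param covariates Covariate columns; default `c("age", "sex")`.
#' @param fdr_target Overall false-discovery-rate target in (0, 1).
#'   Default `0.15`.
#' @param method `"maxp"` (default) or `"separate"`.
#' @return A tibble with one row per SNP: component estimates and p-values
#'   (`p_snp_fa`, `p_snp_y`), the composite p-value `p_max`, the BH-adjusted
#'   `q_pleiotropy`, and logical `pleiotropic`.
#' @export
identify_pleiotropic <- function(geno, pheno, fa_measure = "fa", outcome = "ss",
                                 covariates = c("age", "sex"),
                                 fdr_target = 0.15,
                                 method = c("maxp", "separate")) {
  method <- match.arg(method)
  stopifnot(fdr_target > 0, fdr_target < 1)
  snps <- snp_info(geno)
  if (nrow(snps) == 0) {
    message("no candidate SNPs supplied; empty result")
    return(tibble::tibble(snp_id = character(), beta_fa = double(),
                          p_snp_fa = double(), beta_y = double(),
                          p_snp_y = double(), p_max = double(),
                          q_pleiotropy = double(), pleiotropic = logical()))
  }
  covs <- intersect(covariates, names(pheno))
  d <- dplyr::inner_join(pheno[c("IID", fa_measure, outcome, covs)], geno,
                         by = "IID")
  m_all <- d[[fa_measure]]
  y_all <- d[[outcome]]
  y_binary <- is_binary01(y_all)
  Z <- as.matrix(d[covs])
  G <- dosage_matrix(d[c("IID", snps$snp_id)])
  base_ok <- stats::complete.cases(cbind(m_all, y_all, Z))

  # lean per-SNP loop: this is the hot path of replicate-level simulations
  stats_mat <- vapply(seq_len(nrow(snps)), function(j) {
    g <- G[, j]
    ok <- base_ok & !is.na(g)
    X <- cbind(`(Intercept)` = 1, snp = g[ok], Z[ok, , drop = FALSE])
    fa <- tryCatch(wald_snp_linear(X, m_all[ok]), error = function(e) c(NA, NA))
    yy <- tryCatch(
      if (y_binary) wald_snp_logistic(X, y_all[ok]) else wald_snp_linear(X, y_all[ok]),
      error = function(e) c(NA, NA)
    )
    c(fa, yy, sum(ok))
  }, numeric(5))
  out <- dplyr::bind_cols(
    snps["snp_id"],
    tibble::tibble(beta_fa = stats_mat[1, ], p_snp_fa = stats_mat[2, ],
                   beta_y = stats_mat[3, ], p_snp_y = stats_mat[4, ],
                   n = as.integer(stats_mat[5, ]))
  )
  out$p_max <- pmax(out$p_snp_fa, out$p_snp_y)
  if (method == "maxp") {
    out$q_pleiotropy <- stats::p.adjust(out$p_max, method = "BH")
    out$pleiotropic <- !is.na(out$q_pleiotropy) & out$q_pleiotropy <= fdr_target
  } else {
    q_fa <- stats::p.adjust(out$p_snp_fa, method = "BH")
    q_y <- stats::p.adjust(out$p_snp_y, method = "BH")
    out$q_pleiotropy <- pmax(q_fa, q_y)
    out$pleiotropic <- !is.na(q_fa) & !is.na(q_y) &
      q_fa <= fdr_target & q_y <= fdr_target
  }
  if (!any(out$pleiotropic, na.rm = TRUE)) {
    message("no SNP passes the pleiotropy screen at FDR ", fdr_target)
  }
  out
}

#' Conditional-independence test (step 2)
#'
#' Tests whether the FA mediator and the smoking phenotype are conditionally
#' independent given one SNP and the covariates, by a Wald test on the
#' mediator coefficient in the regression of the outcome on (SNP, FA,
#' covariates) -- logistic for binary status, linear for cigarettes/day. A
#' p-value above `alpha` supports horizontal pleiotropy (model 0, the SNP
#' affecting both traits through independent paths); otherwise the
#' relationship is vertical and step 3 chooses between the two mediation
#' directions.
#'
#' @param data Per-subject tibble containing the SNP dosage, the FA measure,
#'   the outcome, and covariates.
#' @param snp Name of the SNP dosage column.
#' @param fa_measure Name of the FA column. Default `"fa"`.
#' @param outcome Name of the smoking column. Default `"ss"`.
#' @param covariates Covariate columns; default `c("age", "sex")`.
#' @param alpha Significance level separating horizontal from vertical.
#'   Default `0.05`.
#' @return A one-row tibble: `snp_id`, `fa_measure`, mediator coefficient
#'   `beta_m`, `ci_p`, and `classification` (`"horizontal"`, `"vertical"`, or
#'   `"indeterminate"` on a failed or separated fit).
#' @export
test_conditional_independence <- function(data, snp, fa_measure = "fa",
                                          outcome = "ss",
                                          covariates = c("age", "sex"),
                                          alpha = 0.05) {
  covs <- intersect(covariates, names(data))
  fit <- tryCatch(
    fit_snp_regression(data, response = outcome, snp = snp,
                       covariates = c(fa_measure, covs)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || fit$separation) {
    note <- if (is.null(fit)) "fit failed" else if (!fit$converged) {
      "logistic fit did not converge"
    } else "numerical separation"
    return(tibble::tibble(snp_id = snp, fa_measure = fa_measure,
                          beta_m = NA_real_, ci_p = NA_real_,
                          classification = "indeterminate", note = note))
  }
  s <- coef_of(fit, fa_measure)
  tibble::tibble(
    snp_id = snp, fa_measure = fa_measure,
    beta_m = s$estimate, ci_p = s$p.value,
    classification = if (s$p.value > alpha) "horizontal" else "vertical",
    note = NA_character_
  )
}

#' Fit the four component regressions of the mediation models
#'
#' On the common complete cases, fits: (1a) FA on SNP + covariates (linear);
#' (1b) outcome on SNP + covariates; (2a) outcome on SNP + FA + covariates;
#' (2b) FA on SNP + outcome + covariates (linear). Outcome models are
#' logistic for a binary outcome, linear otherwise. Model 1's joint
#' likelihood multiplies (1a) and (2a); model 2's multiplies (1b) and (2b).
#'
#' @inheritParams test_conditional_independence
#' @return A named list of class `pathway_fits` with elements `m_on_g`,
#'   `y_on_g`, `y_on_gm`, `m_on_gy` (each a `snp_fit`) and `n`.
#' @export
fit_pathway_models <- function(data, snp, fa_measure = "fa", outcome = "ss",
                               covariates = c("age", "sex")) {
  covs <- intersect(covariates, names(data))
  cols <- c(snp, fa_measure, outcome, covs)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  fits <- list(
    m_on_g = fit_snp_regression(d, fa_measure, snp, covs, family = "linear"),
    y_on_g = fit_snp_regression(d, outcome, snp, covs, family = "auto"),
    y_on_gm = fit_snp_regression(d, outcome, snp, c(fa_measure, covs),
                                 family = "auto"),
    m_on_gy = fit_snp_regression(d, fa_measure, snp, c(outcome, covs),
                                 family = "linear")
  )
  structure(c(fits, list(n = nrow(d), snp = snp, fa_measure = fa_measure,
                         outcome = outcome)),
            class = "pathway_fits")
}

#' Select the best mediation model by BIC (step 3)
#'
#' Compares the two vertical mediation models through their maximized joint
#' likelihoods: model 1 factorizes the joint as P(FA | SNP, Z) x
#' P(outcome | SNP, FA, Z); model 2 as P(outcome | SNP, Z) x
#' P(FA | SNP, outcome, Z). Each joint log-likelihood is the sum of its two
#' component fits' log-likelihoods, and BIC = -2 log L + p log n. The two
#' models have exactly the same parameter count, so the BIC comparison
#' reduces to the likelihood comparison; the model with the smaller BIC is
#' selected, and |BIC difference| below `tie_tol` returns `"indeterminate"`.
#'
#' @inheritParams test_conditional_independence
#' @param tie_tol Absolute BIC-difference tolerance treated as a tie.
#'   Default `1e-6`.
#' @return A one-row tibble: `snp_id`, `fa_measure`, `loglik_m1`, `loglik_m2`,
#'   `bic_m1`, `bic_m2`, `selected_model` (`"1"`, `"2"` or `"indeterminate"`),
#'   `n`.
#' @export
select_mediation_model <- function(data, snp, fa_measure = "fa", outcome = "ss",
                                   covariates = c("age", "sex"),
                                   tie_tol = 1e-6) {
  fits <- tryCatch(
    fit_pathway_models(data, snp, fa_measure, outcome, covariates),
    error = function(e) NULL
  )
  bad <- function(f) is.null(f) || !f$converged || f$separation
  if (is.null(fits) || bad(fits$m_on_g) || bad(fits$y_on_g) ||
      bad(fits$y_on_gm) || bad(fits$m_on_gy)) {
    return(tibble::tibble(snp_id = snp, fa_measure = fa_measure,
                          loglik_m1 = NA_real_, loglik_m2 = NA_real_,
                          bic_m1 = NA_real_, bic_m2 = NA_real_,
                          selected_model = "indeterminate",
                          n = if (is.null(fits)) NA_integer_ else fits$n))
  }
  n <- fits$n
  ll1 <- fits$m_on_g$log_likelihood + fits$y_on_gm$log_likelihood
  ll2 <- fits$y_on_g$log_likelihood + fits$m_on_gy$log_likelihood
  p1 <- fits$m_on_g$n_parameters + fits$y_on_gm$n_parameters
  p2 <- fits$y_on_g$n_parameters + fits$m_on_gy$n_parameters
  stopifnot(p1 == p2)  # structural: models differ only in factorization
  bic1 <- -2 * ll1 + p1 * log(n)
  bic2 <- -2 * ll2 + p2 * log(n)
  sel <- if (abs(bic1 - bic2) < tie_tol) {
    "indeterminate"
  } else if (bic1 < bic2) "1" else "2"
  tibble::tibble(snp_id = snp, fa_measure = fa_measure,
                 loglik_m1 = ll1, loglik_m2 = ll2,
                 bic_m1 = bic1, bic_m2 = bic2,
                 selected_model = sel, n = n)
}

#' Run the full three-step causal pathway discovery
#'
#' Applies step 1 ([identify_pleiotropic()]) over all SNPs, then for each SNP
#' passing the screen runs step 2 ([test_conditional_independence()]) and,
#' when the relationship is vertical, step 3 ([select_mediation_model()]).
#' The final label per (SNP, FA measure) is `"0"` for horizontal pleiotropy,
#' `"1"` or `"2"` for the selected mediation direction, or `"indeterminate"`.
#'
#' @inheritParams identify_pleiotropic
#' @param alpha Step-2 significance level. Default `0.05`.
#' @param tie_tol Step-3 BIC tie tolerance. Default `1e-6`.
#' @return A tibble of class `pathway_result`, one row per candidate SNP,
#'   carrying every step's statistics and `selected_model`.
#' @export
discover_pathways <- function(geno, pheno, fa_measure = "fa", outcome = "ss",
                              covariates = c("age", "sex"), fdr_target = 0.15,
                              alpha = 0.05, tie_tol = 1e-6,
                              method = c("maxp", "separate")) {
  step1 <- identify_pleiotropic(geno, pheno, fa_measure, outcome, covariates,
                                fdr_target, method)
  covs <- intersect(covariates, names(pheno))
  d <- dplyr::inner_join(pheno[c("IID", fa_measure, outcome, covs)], geno,
                         by = "IID")
  hits <- step1$snp_id[step1$pleiotropic %in% TRUE]
  extra <- purrr::map_dfr(step1$snp_id, function(s) {
    if (!s %in% hits) {
      return(tibble::tibble(snp_id = s, ci_p = NA_real_,
                            classification = NA_character_,
                            loglik_m1 = NA_real_, loglik_m2 = NA_real_,
                            bic_m1 = NA_real_, bic_m2 = NA_real_,
                            selected_model = NA_character_))
    }
    ci <- test_conditional_independence(d, s, fa_measure, outcome, covs, alpha)
    if (identical(ci$classification, "vertical")) {
      m <- select_mediation_model(d, s, fa_measure, outcome, covs, tie_tol)
      tibble::tibble(snp_id = s, ci_p = ci$ci_p,
                     classification = ci$classification,
                     loglik_m1 = m$loglik_m1, loglik_m2 = m$loglik_m2,
                     bic_m1 = m$bic_m1, bic_m2 = m$bic_m2,
                     selected_model = m$selected_model)
    } else {
      tibble::tibble(snp_id = s, ci_p = ci$ci_p,
                     classification = ci$classification,
                     loglik_m1 = NA_real_, loglik_m2 = NA_real_,
                     bic_m1 = NA_real_, bic_m2 = NA_real_,
                     selected_model = dplyr::if_else(
                       ci$classification == "horizontal", "0", "indeterminate"))
    }
  })
  out <- dplyr::left_join(step1, extra, by = "snp_id")
  out$fa_measure <- fa_measure
  out <- dplyr::relocate(out, "fa_measure", .after = "snp_id")
  class(out) <- c("pathway_result", class(out))
  out
}
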