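# Effect decomposition and inference for the selected vertical model.
# Model 1 (SNP -> FA -> smoking): direct effect is the SNP coefficient in the
# outcome-given-mediator model, indirect is (SNP->FA) x (FA->outcome), total
# is the SNP coefficient in the marginal outcome model. Model 2 swaps the
# roles of mediator and outcome. With a binary outcome the products live on
# the log-odds scale; total = direct + indirect holds exactly only in the
# all-linear case (logistic non-collapsibility).

#' Decompose total, direct and indirect effects
#'
#' @param fits A [fit_pathway_models()] object.
#' @param model_label `"1"` (FA mediates the SNP effect on smoking) or `"2"`
#'   (smoking mediates the SNP effect on FA).
#' @return A one-row tibble: `model`, `direct`, `direct_se`, `direct_p`,
#'   `indirect` (product of the two path coefficients), `total`, and the path
#'   coefficients `path_a` (SNP to mediator) and `path_b` (mediator to
#'   outcome) with standard errors.
#' @examples
#' d <- simulate_dataset(sim_config(n_subjects = 1000, n_snps = 1,
#'                                  n_pleiotropic = 1, true_model = 1, seed = 4))
#' dat <- dplyr::bind_cols(d$phenotypes, d$genotypes["snp_1"])
#' f <- fit_pathway_models(dat, "snp_1")
#' decompose_effects(f, "1")
#' @export
decompose_effects <- function(fits, model_label) {
  stopifnot(inherits(fits, "pathway_fits"))
  model_label <- as.character(model_label)
  if (!model_label %in% c("1", "2")) {
    stop("`model_label` must be \"1\" or \"2\"", call. = FALSE)
  }
  need <- if (model_label == "1") c("m_on_g", "y_on_gm", "y_on_g") else
    c("y_on_g", "m_on_gy", "m_on_g")
  for (nm in need) {
    if (is.null(fits[[nm]])) {
      stop("missing component fit `", nm, "` for model ", model_label,
           call. = FALSE)
    }
  }
  if (model_label == "1") {
    a <- coef_of(fits$m_on_g, snp_term(fits))
    b <- coef_of(fits$y_on_gm, fits$fa_measure)
    direct <- coef_of(fits$y_on_gm, snp_term(fits))
    total <- coef_of(fits$y_on_g, snp_term(fits))
  } else {
    a <- coef_of(fits$y_on_g, snp_term(fits))
    b <- coef_of(fits$m_on_gy, fits$outcome)
    direct <- coef_of(fits$m_on_gy, snp_term(fits))
    total <- coef_of(fits$m_on_g, snp_term(fits))
  }
  dir_row <- direct
  tot_row <- total
  tibble::tibble(
    model = model_label,
    direct = dir_row$estimate, direct_se = dir_row$std.error,
    direct_p = dir_row$p.value,
    indirect = a$estimate * b$estimate,
    total = tot_row$estimate,
    path_a = a$estimate, path_a_se = a$std.error,
    path_b = b$estimate, path_b_se = b$std.error
  )
}

snp_term <- function(fits) fits$snp

#' Test the indirect (mediation) effect
#'
#' Inference on the product-of-coefficients indirect effect, either by the
#' Sobel normal approximation `z = a b / sqrt(a^2 se_b^2 + b^2 se_a^2)` or by
#' a nonparametric subject-level bootstrap with a percentile interval
#' (default: 1,000 resamples, avoiding the Sobel normality assumption, which
#' is poor for products near the null). Bootstrap resamples with a degenerate
#' binary variable are redrawn and counted.
#'
#' @param data Per-subject tibble with the SNP, FA, outcome and covariates.
#' @param snp,fa_measure,outcome,covariates As in [fit_pathway_models()].
#' @param model_label `"1"` or `"2"`.
#' @param method `"bootstrap"` (default) or `"sobel"`.
#' @param n_boot Bootstrap resamples (at least 200). Default `1000`.
#' @param level Interval coverage. Default `0.95`.
#' @param seed Optional seed making the bootstrap reproducible.
#' @return A one-row tibble: `indirect`, `ci_lower`, `ci_upper`, `p.value`,
#'   `method`, `n_boot`, `n_redrawn`.
#' @export
test_indirect_effect <- function(data, snp, fa_measure = "fa", outcome = "ss",
                                 covariates = c("age", "sex"),
                                 model_label = "1",
                                 method = c("bootstrap", "sobel"),
                                 n_boot = 1000, level = 0.95, seed = NULL) {
  method <- match.arg(method)
  model_label <- as.character(model_label)
  covs <- intersect(covariates, names(data))
  cols <- c(snp, fa_measure, outcome, covs)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  y_binary <- is_binary01(d[[outcome]])

  paths <- function(dd) {
    Z <- as.matrix(dd[covs])
    g <- dd[[snp]]
    if (model_label == "1") {
      fa_fit <- fit_linear_mle(cbind(`(Intercept)` = 1, snp = g, Z), dd[[fa_measure]])
      Xb <- cbind(`(Intercept)` = 1, snp = g, med = dd[[fa_measure]], Z)
      b_fit <- if (y_binary) fit_logistic_mle(Xb, dd[[outcome]]) else
        fit_linear_mle(Xb, dd[[outcome]])
      a <- coef_of(fa_fit, "snp"); b <- coef_of(b_fit, "med")
    } else {
      Xa <- cbind(`(Intercept)` = 1, snp = g, Z)
      a_fit <- if (y_binary) fit_logistic_mle(Xa, dd[[outcome]]) else
        fit_linear_mle(Xa, dd[[outcome]])
      Xb <- cbind(`(Intercept)` = 1, snp = g, med = dd[[outcome]], Z)
      b_fit <- fit_linear_mle(Xb, dd[[fa_measure]])
      a <- coef_of(a_fit, "snp"); b <- coef_of(b_fit, "med")
    }
    list(a = a, b = b)
  }

  pp <- paths(d)
  est <- pp$a$estimate * pp$b$estimate

  if (method == "sobel") {
    se <- sqrt(pp$a$estimate^2 * pp$b$std.error^2 +
                 pp$b$estimate^2 * pp$a$std.error^2)
    z <- est / se
    zq <- stats::qnorm(1 - (1 - level) / 2)
    return(tibble::tibble(indirect = est, ci_lower = est - zq * se,
                          ci_upper = est + zq * se,
                          p.value = 2 * stats::pnorm(-abs(z)),
                          method = "sobel", n_boot = NA_integer_,
                          n_redrawn = 0L))
  }

  if (n_boot < 200) stop("`n_boot` must be at least 200", call. = FALSE)
  boot_once <- function() {
    repeat {
      idx <- sample.int(nrow(d), replace = TRUE)
      dd <- d[idx, , drop = FALSE]
      degenerate <- (y_binary && length(unique(dd[[outcome]])) < 2) ||
        stats::sd(dd[[snp]]) == 0
      if (!degenerate) return(list(dd = dd, redrawn = FALSE))
      redraws <<- redraws + 1L
    }
  }
  run <- function() {
    redraws <<- 0L
    vals <- vapply(seq_len(n_boot), function(i) {
      dd <- boot_once()$dd
      p <- tryCatch(paths(dd), error = function(e) NULL)
      if (is.null(p)) NA_real_ else p$a$estimate * p$b$estimate
    }, numeric(1))
    vals[!is.na(vals)]
  }
  redraws <- 0L
  vals <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  alpha2 <- (1 - level) / 2
  ci <- stats::quantile(vals, c(alpha2, 1 - alpha2), names = FALSE, type = 7)
  # two-sided percentile p: twice the smaller tail proportion beyond zero
  p_lo <- mean(vals <= 0)
  p_hi <- mean(vals >= 0)
  pv <- min(1, 2 * min(p_lo, p_hi))
  tibble::tibble(indirect = est, ci_lower = ci[1], ci_upper = ci[2],
                 p.value = pv, method = "bootstrap",
                 n_boot = length(vals), n_redrawn = redraws)
}

#' Classify the mediation type
#'
#' Standard typology by significance and sign: a significant indirect effect
#' with a significant direct effect of the same sign is *complementary*
#' mediation; with a significant direct effect of the opposite sign,
#' *competitive*; with a non-significant direct effect, *indirect-only*. A
#' non-significant indirect effect gives `"none"`.
#'
#' @param indirect,direct Effect estimates (vectorized).
#' @param indirect_p,direct_p Their two-sided p-values.
#' @param alpha Significance level. Default `0.05`.
#' @return Character vector: `"complementary"`, `"competitive"`,
#'   `"indirect_only"` or `"none"`.
#' @examples
#' classify_mediation(indirect = -0.1, indirect_p = 0.01,
#'                    direct = 0.3, direct_p = 0.002)  # competitive
#' @export
classify_mediation <- function(indirect, indirect_p, direct, direct_p,
                               alpha = 0.05) {
  dplyr::case_when(
    is.na(indirect_p) ~ NA_character_,
    indirect_p >= alpha ~ "none",
    direct_p >= alpha | is.na(direct_p) ~ "indirect_only",
    sign(indirect) == sign(direct) ~ "complementary",
    .default = "competitive"
  )
}

#' Mediation analysis for the vertically classified SNPs
#'
#' For each row of a [discover_pathways()] result with `selected_model` `"1"`
#' or `"2"`, decomposes the effects, tests the indirect effect, and assigns
#' the mediation type.
#'
#' @param geno Genotype tibble.
#' @param pheno Phenotype tibble.
#' @param pathway_tbl A [discover_pathways()] result.
#' @param covariates Covariate columns; default `c("age", "sex")`.
#' @param outcome Name of the smoking column. Default `"ss"`.
#' @param method,n_boot,level Passed to [test_indirect_effect()].
#' @param alpha Classification significance level. Default `0.05`.
#' @param seed Master seed; each SNP's bootstrap gets its own derived stream.
#' @return A tibble of class `mediation_result`, one row per mediated
#'   (SNP, FA measure) pair: effects, interval, p-values, `mediation_type`.
#' @export
run_mediation <- function(geno, pheno, pathway_tbl, outcome = "ss",
                          covariates = c("age", "sex"),
                          method = c("bootstrap", "sobel"), n_boot = 1000,
                          level = 0.95, alpha = 0.05, seed = 1L) {
  method <- match.arg(method)
  rows <- pathway_tbl[pathway_tbl$selected_model %in% c("1", "2"), , drop = FALSE]
  empty <- tibble::tibble(
    snp_id = character(), fa_measure = character(), model = character(),
    direct = double(), direct_p = double(), indirect = double(),
    ci_lower = double(), ci_upper = double(), indirect_p = double(),
    total = double(), mediation_type = character()
  )
  if (nrow(rows) == 0) {
    message("no SNP classified as vertical; nothing to mediate")
    return(structure(empty, class = c("mediation_result", class(empty))))
  }
  covs <- intersect(covariates, names(pheno))
  seeds <- replicate_seeds(seed, nrow(rows))
  out <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    s <- rows$snp_id[i]
    fa <- rows$fa_measure[i]
    d <- dplyr::inner_join(pheno[c("IID", fa, outcome, covs)],
                           geno[c("IID", s)], by = "IID")
    fits <- fit_pathway_models(d, s, fa, outcome, covs)
    dec <- decompose_effects(fits, rows$selected_model[i])
    ind <- test_indirect_effect(d, s, fa, outcome, covs,
                                model_label = rows$selected_model[i],
                                method = method, n_boot = n_boot,
                                level = level, seed = seeds[i])
    tibble::tibble(
      snp_id = s, fa_measure = fa, model = dec$model,
      direct = dec$direct, direct_p = dec$direct_p,
      indirect = dec$indirect, ci_lower = ind$ci_lower,
      ci_upper = ind$ci_upper, indirect_p = ind$p.value,
      total = dec$total,
      mediation_type = classify_mediation(dec$indirect, ind$p.value,
                                          dec$direct, dec$direct_p, alpha)
    )
  })
  structure(out, class = c("mediation_result", class(out)))
}
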