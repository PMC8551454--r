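# Genotype quality control and smoking / white-matter phenotype derivation.
# Filter order is part of the contract: SNP-level filters (MAF, HWE,
# missingness) first, then the subject-level missingness filter on the
# retained SNPs. Per-SNP statistics are computed on observed (non-missing)
# genotypes.

#' Genotype quality-control thresholds
#'
#' Defaults reproduce the standard biobank GWAS filter set: minor-allele
#' frequency below 0.01 removed, Hardy-Weinberg equilibrium p-value below
#' 0.001 removed, SNPs with more than 5% missing genotypes removed, then
#' subjects with more than 2% missing genotypes removed.
#'
#' @param maf_min Minimum minor-allele frequency retained.
#' @param hwe_p_min Minimum HWE test p-value retained.
#' @param snp_missing_max Maximum per-SNP missing-genotype proportion.
#' @param subject_missing_max Maximum per-subject missing-genotype proportion.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, hwe_p_min = 0.001,
                          snp_missing_max = 0.05, subject_missing_max = 0.02) {
  vals <- c(maf_min, hwe_p_min, snp_missing_max, subject_missing_max)
  if (any(vals < 0 | vals > 1)) {
    stop("all QC thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 snp_missing_max = snp_missing_max,
                 subject_missing_max = subject_missing_max),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' Hardy-Weinberg expectations at the sample allele frequency (default), or an
#' exact mid-p test that enumerates the conditional distribution of the
#' heterozygote count given the minor-allele count.
#'
#' @param n0,n1,n2 Vectors of genotype counts: major homozygote, heterozygote,
#'   minor homozygote.
#' @param method `"chisq"` (default, deterministic and fast) or `"exact"`
#'   (mid-p).
#' @return A numeric vector of p-values.
#' @examples
#' hwe_test(25, 50, 25)        # exact HWE proportions: p = 1
#' hwe_test(30, 0, 30)         # total disequilibrium: p ~ 0
#' @export
hwe_test <- function(n0, n1, n2, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (method == "chisq") {
    n <- n0 + n1 + n2
    p <- (n1 + 2 * n2) / (2 * n)
    e0 <- n * (1 - p)^2
    e1 <- n * 2 * p * (1 - p)
    e2 <- n * p^2
    # monomorphic SNPs: expected counts at the boundary, no disequilibrium
    mono <- p == 0 | p == 1
    chi2 <- rep(0, length(n))
    ok <- !mono
    chi2[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
      (n1[ok] - e1[ok])^2 / e1[ok] +
      (n2[ok] - e2[ok])^2 / e2[ok]
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    mapply(hwe_exact_midp, n0, n1, n2)
  }
}

# Exact HWE: conditional on n subjects and n_minor minor alleles, the
# heterozygote count has the classic hypergeometric-type pmf; mid-p sums
# probabilities below the observed one plus half the ties.
hwe_exact_midp <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  n_minor <- n1 + 2 * n2
  if (n_minor == 0 || n_minor == 2 * n) return(1)
  het <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # pmf of the heterozygote count given the minor-allele count:
  # proportional to n! 2^het / (n_AA! n_Aa! n_aa!)
  logp <- lfactorial(n) + het * log(2) -
    lfactorial((n_minor - het) / 2) - lfactorial(het) -
    lfactorial(n - (n_minor + het) / 2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[het == n1]
  sum(pr[pr < obs - 1e-12]) + 0.5 * sum(pr[abs(pr - obs) <= 1e-12])
}

#' Apply genotype quality control
#'
#' Removes SNPs failing the MAF, HWE or per-SNP missingness thresholds (all
#' SNP-level statistics computed on observed genotypes), then removes
#' subjects exceeding the per-subject missingness threshold on the retained
#' SNPs. Minor alleles are re-identified from the sample: when the counted
#' allele's frequency exceeds 0.5, MAF is taken as one minus it.
#'
#' @param geno Genotype tibble (`IID` + dosage columns, values 0/1/2/NA).
#' @param thresholds A [qc_thresholds()].
#' @param hwe_method Passed to [hwe_test()].
#' @return The filtered genotype tibble, with updated `"snps"` metadata and a
#'   `"qc_report"` attribute (retrievable with [qc_report()]) counting
#'   removals per criterion.
#' @export
apply_genotype_qc <- function(geno, thresholds = qc_thresholds(),
                              hwe_method = c("chisq", "exact")) {
  hwe_method <- match.arg(hwe_method)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  G <- dosage_matrix(geno)
  bad_vals <- G[!is.na(G) & !(G %in% c(0, 1, 2))]
  if (length(bad_vals) > 0) {
    stop("dosages must be 0, 1, 2 or missing; found ", bad_vals[1],
         call. = FALSE)
  }
  n_obs <- colSums(!is.na(G))
  snp_miss <- 1 - n_obs / nrow(G)
  n0 <- colSums(G == 0, na.rm = TRUE)
  n1 <- colSums(G == 1, na.rm = TRUE)
  n2 <- colSums(G == 2, na.rm = TRUE)
  freq <- (n1 + 2 * n2) / (2 * pmax(n_obs, 1))
  maf <- pmin(freq, 1 - freq)
  hwe_p <- hwe_test(n0, n1, n2, method = hwe_method)

  fail_maf <- maf < thresholds$maf_min
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  fail_miss <- snp_miss > thresholds$snp_missing_max
  keep_snp <- !(fail_maf | fail_hwe | fail_miss)
  if (!any(keep_snp)) stop("no SNPs remain after QC", call. = FALSE)

  G2 <- G[, keep_snp, drop = FALSE]
  subj_miss <- rowMeans(is.na(G2))
  keep_subj <- subj_miss <= thresholds$subject_missing_max
  if (!any(keep_subj)) stop("no subjects remain after QC", call. = FALSE)

  out <- geno[keep_subj, c("IID", colnames(G2)), drop = FALSE]
  snps <- snp_info(geno)
  snps <- snps[match(colnames(G2), snps$snp_id), , drop = FALSE]
  G3 <- G2[keep_subj, , drop = FALSE]
  f3 <- colMeans(G3, na.rm = TRUE) / 2
  snps$maf <- pmin(f3, 1 - f3)
  snps$counted_allele_is_minor <- f3 <= 0.5
  attr(out, "snps") <- snps
  attr(out, "qc_report") <- tibble::tibble(
    criterion = c("maf", "hwe", "snp_missingness", "subject_missingness"),
    threshold = c(thresholds$maf_min, thresholds$hwe_p_min,
                  thresholds$snp_missing_max, thresholds$subject_missing_max),
    n_removed = c(sum(fail_maf), sum(fail_hwe), sum(fail_miss),
                  sum(!keep_subj)),
    n_tested = c(rep(ncol(G), 3), nrow(G))
  )
  class(out) <- c("geno_tbl", setdiff(class(out), "geno_tbl"))
  out
}

#' Quality-control report of a filtered genotype table
#'
#' @param geno Output of [apply_genotype_qc()].
#' @return A tibble with one row per QC criterion: threshold, number removed,
#'   number tested.
#' @export
qc_report <- function(geno) {
  r <- attr(geno, "qc_report")
  if (is.null(r)) stop("`geno` carries no QC report", call. = FALSE)
  r
}

#' Derive binary smoking status
#'
#' Maps the raw smoking category (current / never / past, possibly missing)
#' to the binary smoking-status phenotype: current smokers coded 1, never
#' smokers 0, past smokers and missing values set to missing so the same
#' table can serve analyses that exclude different groups.
#'
#' @param pheno Phenotype tibble.
#' @param smoking_col Name of the raw category column. Default `"smoking_group"`.
#' @return `pheno` with an added (or replaced) numeric `ss` column.
#' @examples
#' p <- tibble::tibble(smoking_group = c("current", "never", "past", NA))
#' derive_smoking_status(p)$ss
#' @export
derive_smoking_status <- function(pheno, smoking_col = "smoking_group") {
  if (!smoking_col %in% names(pheno)) {
    stop("column `", smoking_col, "` not found", call. = FALSE)
  }
  raw <- as.character(pheno[[smoking_col]])
  known <- c("current", "never", "past")
  bad <- setdiff(unique(raw[!is.na(raw)]), known)
  if (length(bad) > 0) {
    stop("unrecognized smoking category level(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ss <- dplyr::case_match(raw, "current" ~ 1, "never" ~ 0,
                          "past" ~ NA_real_, NA ~ NA_real_)
  if (all(is.na(ss))) {
    warning("all smoking-status values are missing after derivation",
            call. = FALSE)
  }
  pheno$ss <- ss
  pheno
}

#' Recode cigarettes-per-day to the analysis scale
#'
#' Values below one cigarette per day are recoded to 0 and values above 60 are
#' capped at 60; values in between are unchanged and missing values propagate.
#' The mapping is monotone non-decreasing into \[0, 60\].
#'
#' @param x Nonnegative numeric vector of raw cigarettes-per-day values.
#' @return The recoded numeric vector.
#' @examples
#' recode_cpd(c(0.5, 30, 75, NA))
#' @export
recode_cpd <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("cigarettes-per-day values must be nonnegative", call. = FALSE)
  }
  dplyr::case_when(is.na(x) ~ NA_real_, x < 1 ~ 0, x > 60 ~ 60,
                   .default = as.numeric(x))
}

#' Screen FA measures for association with smoking
#'
#' Regresses each fractional-anisotropy measure on the smoking phenotype
#' (optionally adjusting for covariates; adjusted is the default) and flags
#' the measures showing lower white-matter integrity with smoking: negative
#' smoking coefficient with p < `alpha`. Only flagged measures proceed to the
#' causal pathway analysis.
#'
#' @param pheno Phenotype tibble.
#' @param outcome Name of the smoking column (`"ss"` or `"cpd"`).
#' @param fa_cols Character vector of FA column names; default every column
#'   starting with `"fa"`.
#' @param covariates Covariates to adjust for; default `c("age", "sex")`.
#' @param adjusted Adjust for covariates (default) or run the unadjusted
#'   univariate screen.
#' @param alpha Significance level of the screen. Default 0.05.
#' @return A tibble with one row per FA measure in input order: `fa_measure`,
#'   smoking `estimate`, `p.value`, `n`, and logical `keep`. Constant FA
#'   columns are skipped with a warning (`keep = NA`).
#' @export
screen_fa_measures <- function(pheno, outcome = "ss", fa_cols = NULL,
                               covariates = c("age", "sex"),
                               adjusted = TRUE, alpha = 0.05) {
  if (is.null(fa_cols)) {
    fa_cols <- grep("^fa", names(pheno), value = TRUE)
  }
  if (length(fa_cols) == 0) stop("no FA columns to screen", call. = FALSE)
  covs <- if (adjusted) intersect(covariates, names(pheno)) else character()
  purrr::map_dfr(fa_cols, function(fc) {
    cols <- c(fc, outcome, covs)
    d <- pheno[stats::complete.cases(pheno[cols]), cols, drop = FALSE]
    if (nrow(d) == 0 || stats::sd(d[[fc]]) == 0) {
      warning("FA measure `", fc, "` is constant; skipped", call. = FALSE)
      return(tibble::tibble(fa_measure = fc, estimate = NA_real_,
                            p.value = NA_real_, n = nrow(d), keep = NA))
    }
    X <- cbind(`(Intercept)` = 1, as.matrix(d[c(outcome, covs)]))
    fit <- fit_linear_mle(X, d[[fc]])
    sm <- fit$coefficients[fit$coefficients$term == outcome, ]
    tibble::tibble(fa_measure = fc, estimate = sm$estimate,
                   p.value = sm$p.value, n = nrow(d),
                   keep = sm$estimate < 0 & sm$p.value < alpha)
  })
}
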