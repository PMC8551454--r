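---
title: "Causal pathway discovery for pleiotropic variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal pathway discovery for pleiotropic variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pleiopath)
library(dplyr)
```

## The problem

A genetic variant associated with two traits — here a white-matter
fractional-anisotropy (FA) measure and a smoking phenotype — may act through
qualitatively different causal structures:

* **model 0 (horizontal pleiotropy)** — the SNP affects both traits through
  independent paths, and the traits are conditionally independent given
  genotype and covariates;
* **model 1 (vertical, imaging mediator)** — SNP → FA → smoking;
* **model 2 (vertical, behavioural mediator)** — SNP → smoking → FA.

`pleiopath` implements a hybrid constraint/score causal-discovery procedure
that assigns each candidate SNP to one of these structures and, for the
vertical cases, quantifies the mediation. The smoking phenotype is either
binary smoking status (SS: current = 1 vs never = 0, past smokers set to
missing) or continuous cigarettes per day (CPD, recoded so values below one
are 0 and values above 60 are capped at 60).

## The model and the three steps

Write $G_{ij} \in \{0,1,2\}$ for the minor-allele dosage of subject $i$ at
SNP $j$, $M_{il}$ for the $l$-th FA measure, $Y_i$ for the smoking phenotype
and $Z_i$ for covariates (age and sex at the pathway stage). Four component
regressions are used throughout:

* (1a) $M = \alpha_1 + \beta_{1j} G_j + \gamma_1 Z + \varepsilon_1$,
  $\varepsilon_1 \sim N(0, \sigma_1^2)$;
* (1b) $\operatorname{logit} P(Y = 1) = \alpha_2 + \beta_{2j} G_j + \gamma_2 Z$
  for SS, or the analogous linear model for CPD;
* (2a) $Y$ on $(G_j, M, Z)$ — logistic for SS, linear for CPD, with mediator
  coefficient $\beta_{32}$;
* (2b) $M = \alpha_4 + \beta_{41j} G_j + \beta_{42} Y + \gamma_4 Z +
  \varepsilon_4$.

**Step 1 — pleiotropy screen with overall FDR control.** A pleiotropic
variant must be associated with *both* traits, a composite hypothesis whose
null includes "associated with at most one". Per SNP we take
$p_{\max} = \max(p_{\text{SNP--FA}}, p_{\text{SNP--smoking}})$, a valid
(conservative) composite-null p-value, and apply Benjamini–Hochberg to the
$p_{\max}$ list at the overall target FDR 0.15. A switch
(`method = "separate"`) instead runs BH per trait at the target and
intersects the discovery sets. The max-p construction is a documented,
standard choice for this composite null; it is deliberately pluggable
because reasonable alternatives exist.

**Step 2 — horizontal vs vertical.** Horizontal pleiotropy is characterized
by conditional independence of the two traits given the SNP. We test the
mediator coefficient $\beta_{32}$ in model (2a) by a Wald test, conditioning
on one SNP at a time; $p > 0.05$ supports horizontal pleiotropy (model 0),
otherwise the variant is classified vertical. A non-converged or separated
logistic fit yields `"indeterminate"` with a diagnostic, never a silent
classification.

**Step 3 — BIC selection between the mediation directions.** The two
vertical models factorize the joint distribution of $(M, Y)$ given $(G, Z)$:

$$\hat L(M1) = L_{1a} \cdot L_{2a}, \qquad \hat L(M2) = L_{1b} \cdot L_{2b},$$

each evaluated at the MLE, and $\mathrm{BIC} = -2\log\hat L + p\log n$. The
two factorizations have exactly the same parameter count, so the BIC
comparison reduces to comparing maximized likelihoods; the model with the
smaller BIC (larger likelihood) is selected. So that the joint likelihoods
are genuine maximized likelihoods, linear components report the Gaussian
*profile* log-likelihood with the residual variance maximized using divisor
$n$ (the same convention as `stats::logLik.lm`), and the variance counts as
a parameter in `n_parameters` identically on both sides.

### Likelihood equivalence in the all-linear case

When the outcome is continuous, both factorizations span the *same*
unrestricted bivariate-Gaussian family, so their maximized joint likelihoods
coincide exactly and no data can separate them. This is the classic Markov
equivalence of the two DAGs under linear-Gaussian parameterization:

```{r}
d <- simulate_dataset(sim_config(n_subjects = 800, n_snps = 1,
                                 n_pleiotropic = 1, true_model = 1,
                                 beta_m_y = -0.5,
                                 outcome_type = "continuous", seed = 47))
dat <- bind_cols(d$phenotypes, d$genotypes["snp_1"])
select_mediation_model(dat, "snp_1", outcome = "cpd")[, c("loglik_m1", "loglik_m2", "selected_model")]
```

This is why the selection carries a tie rule: $|\Delta \mathrm{BIC}| <
10^{-6}$ (pure numerical noise) returns `"indeterminate"` rather than a
coin-flip. With a *binary* outcome the logistic link breaks the equivalence
— the marginal of a logistic model integrated over a Gaussian mediator is
not exactly logistic, and the reverse conditional is not exactly Gaussian —
so selection is consistent, but the Kullback–Leibler separation is small
unless the mediator–outcome effect is substantial. The package's
consistency study (`selection_consistency_study()`) therefore uses a binary
outcome with cross-effect 1.5 in absolute value; at weaker cross-effects
(say 0.5 log-odds per mediator SD) the two models are practically
indistinguishable even at $n = 10{,}000$, which is a genuine limitation of
likelihood-based direction selection, not of the implementation.

## Mediation decomposition and typology

For model 1 the direct effect is $\beta_{31j}$ (SNP coefficient in 2a), the
indirect effect is the product $\beta_{1j}\beta_{32}$, and the total effect
is $\beta_{2j}$ from the marginal fit (1b); model 2 swaps the roles
($\beta_{41j}$, $\beta_{2j}\beta_{42}$, $\beta_{1j}$). When all components
are linear and share the covariate set and sample, total = direct + indirect
is an exact OLS identity (asserted to $10^{-8}$ in the tests). With a binary
outcome the products live on the log-odds scale and the identity holds only
approximately (logistic non-collapsibility); the package documents rather
than hides this.

Indirect-effect inference defaults to a nonparametric subject-level
bootstrap (1,000 resamples, percentile interval), which avoids the Sobel
normality assumption — poor for products near the null; the Sobel test
$z = \hat a\hat b / \sqrt{\hat a^2 se_b^2 + \hat b^2 se_a^2}$ is available
as a fast alternative. Bootstrap resamples in which the binary outcome or
the SNP becomes constant are redrawn and counted. Under the double null the
product test is conservative — its size stays below the nominal level —
which the test suite checks by simulation.

A significant indirect effect is classified by the sign and significance of
the direct effect: same sign → *complementary* mediation; opposite sign →
*competitive*; non-significant direct → *indirect-only*; a non-significant
indirect effect gives *none*. The classification level is 0.05 two-sided,
configurable.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable against
known truth without any restricted data access. Its defaults are the
reference study conditions used by the calibration studies: 2,000 subjects,
500 SNPs of which the first 50 carry effects of 0.3 per minor-allele copy on
both traits (mediator effects in residual-SD units, binary-outcome effects
in log-odds), unit residual standard deviations, binary outcome.

Other fixed choices, with reasons:

* **Genotypes.** Additive dosages are two summed haplotypes; each haplotype
  is a latent Gaussian AR(1) (correlation `ld_rho`) thresholded at the
  $(1-\mathrm{MAF})$ quantile, a tractable scheme whose adjacent-SNP dosage
  correlation we verify against a brute-force re-simulation oracle. With
  `ld_rho = 0` this reduces exactly to Binomial(2, MAF) — Hardy–Weinberg
  proportions — and is drawn directly.
* **Covariates.** Age uniform on 40–70 years (a typical biobank imaging
  window), sex Bernoulli(0.5). Effects enter on the centred-age scale
  (years − 55) with defaults 0.01 per year and −0.1 for sex, small relative
  to the genetic effects under study.
* **Outcome intercept.** −0.85 on the log-odds scale, giving ≈30% smoking
  prevalence, in the range of current-vs-never cohorts.
* **Mediator–outcome signs.** Default cross-effects are negative (−0.5):
  lower white-matter integrity accompanies heavier smoking, which is also
  the sign convention the FA screen (`screen_fa_measures()`) selects for.
* **Reproducibility.** Each replicate of a Monte-Carlo study receives its
  own seed derived from a master seed (`replicate_seeds()`), so any single
  replicate can be regenerated in isolation; identical configuration and
  seed reproduce byte-identical datasets and result bundles (the run
  manifest deliberately contains no timestamps).

What the generator does *not* emulate: recombination maps and realistic LD
block structure, population stratification, imputation dosage uncertainty,
site/batch effects, and the measurement pipeline behind real FA values.
Passing calibration tests therefore demonstrates the procedure's operating
characteristics under clean additive-logistic data, not robustness to those
real-data complications.

## Preprocessing conventions

Genotype QC applies the standard biobank filter set with SNP-level filters
first (MAF < 0.01, Hardy–Weinberg equilibrium p < 0.001 by a one-degree
chi-square test on observed genotype counts, per-SNP missingness > 5%), then
removes subjects with > 2% missing genotypes on the retained SNPs. The
chi-square test is the default for determinism and speed; an exact mid-p
variant (`hwe_method = "exact"`) is available. Per-SNP statistics use
observed genotypes, and the minor allele is re-identified from the sample
when the counted allele's frequency exceeds one half. QC is idempotent, and
the SNP-before-subject filter order is part of the contract (filter-order
invariance is *not* claimed).

The FA screen regresses each FA measure on the smoking phenotype and keeps
measures with a negative smoking coefficient and p < 0.05. Whether the
original univariate screen adjusted for covariates is ambiguous, so both
modes exist; the adjusted mode (age and sex) is the default, since the
downstream models adjust for the same covariates.

At the association-scan stage the requested covariate set defaults to age,
sex, BMI, genotyping chip and ten principal components, degrading with a
logged notice to whichever columns the phenotype table actually has — the
synthetic cohorts carry only age and sex. Genome-wide significant SNPs
(p < 5 × 10⁻⁸) seed locus windows extended by ±250 kb to absorb LD
neighbours; overlapping padded windows are merged (via
`GenomicRanges::reduce`) so no SNP is double-counted. All internal
coordinates are 1-based inclusive; BED export converts to 0-based half-open.

## Numerical choices and degenerate inputs

* Linear fits solve by QR; rank deficiency is an error naming the collinear
  columns, never a silent drop. Wald p-values use the $t$ reference with the
  unbiased variance for linear fits and the normal reference for logistic.
* Logistic fits flag non-convergence and numerical separation (fitted
  probabilities within $10^{-8}$ of 0/1); flagged fits are excluded from
  GWAS ranking and propagate `"indeterminate"` through steps 2–3.
* Degenerate simulated binary outcomes (all 0 or all 1) warn at generation.
* Constant FA columns are skipped by the screen with a warning.
* Empty selections anywhere in the pipeline produce empty, well-typed
  tables plus an explicit notice — never an error.

## Calibration studies and problem sizes

Three study functions regenerate the package's operating characteristics:

* `fdr_calibration_study()` — 200 replicates at the reference conditions;
  empirical FDR of step 1 must sit at or below 0.15 (plus two Monte-Carlo
  standard errors). The max-p construction makes it conservative in
  practice.
* `ci_size_study()` — 2,000 model-0 replicates ($n = 2{,}000$, effects 0.3
  on both traits); the fraction misclassified as vertical should match the
  nominal 0.05 within binomial error.
* `selection_consistency_study()` — 150 replicates per cell over
  $n \in \{500, 2{,}000, 10{,}000\}$ under each vertical model (binary
  outcome, SNP effect 0.5, cross-effect −1.5); accuracy must be monotone
  non-decreasing in $n$ and at least 95% at $n = 10{,}000$.

These sizes were chosen to give stable Monte-Carlo estimates (binomial
standard errors of roughly 0.005–0.03) while each study completes in a few
minutes on a single CPU; the test suite runs them at exactly these sizes.

## Known limitations

* Step 2 conditions on one SNP at a time, not on the joint SNP set or a
  polygenic term; SNPs in strong LD with a causal variant are not
  distinguished from the causal variant itself.
* Direction selection between the two vertical models is only informative
  when the link functions differ (binary outcome) or cross-effects are
  strong; the all-linear case is fundamentally non-identifiable.
* Binary-outcome mediation effects are log-odds-scale coefficient products;
  no rare-outcome approximation or counterfactual-scale estimand is
  attempted, and exposure–mediator interactions are not modelled.
* No sensitivity analysis for unmeasured mediator–outcome confounding is
  provided beyond the residual diagnostics implicit in the component fits.
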