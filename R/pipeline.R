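# End-to-end orchestration: simulate (or load) -> genotype QC -> phenotype
# derivation -> FA screen -> per-SNP association scan with locus windows ->
# three-step pathway discovery -> mediation analysis. Every stage's output is
# a tibble; the bundle carries a machine-readable manifest (config echo,
# seeds, per-stage sample sizes, thresholds) and contains no timestamps, so
# identical configuration and seed reproduce identical bundles byte for byte.

#' Pipeline run configuration
#'
#' Defaults reproduce the study's analysis constants: QC thresholds
#' (MAF 0.01, HWE p 0.001, SNP missingness 5%, subject missingness 2%),
#' genome-wide threshold 5e-8 with 250 kb locus padding, overall FDR target
#' 0.15 for the pleiotropy screen, significance level 0.05 for the
#' conditional-independence test, FA screen and mediation classification, and
#' cigarettes-per-day recoding caps of 0 and 60.
#'
#' @param simulation A [sim_config()] to generate the cohort, or `NULL` when
#'   reading from files.
#' @param genotype_path,phenotype_path Input files (used when `simulation` is
#'   `NULL`).
#' @param genotype_dialect `"raw"` or `"vcf"`.
#' @param outcome `"ss"` (binary smoking status) or `"cpd"`.
#' @param qc A [qc_thresholds()].
#' @param gwas_threshold Genome-wide significance threshold. Default `5e-8`.
#' @param window_pad Locus padding in base pairs. Default `250000`.
#' @param fdr_target Step-1 overall FDR target. Default `0.15`.
#' @param alpha Significance level for step 2, the FA screen and mediation
#'   classification. Default `0.05`.
#' @param covariates Covariates for the pathway and mediation stages.
#'   Default `c("age", "sex")`.
#' @param gwas_covariates Covariates requested at the association-scan stage
#'   (drops gracefully to available columns).
#' @param inference `"bootstrap"` or `"sobel"`. Default `"bootstrap"`.
#' @param n_boot Bootstrap resamples. Default `1000`.
#' @param seed Master seed for simulation and bootstrap streams.
#' @param output_dir Directory for per-stage TSVs and the JSON manifest, or
#'   `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, genotype_path = NULL,
                       phenotype_path = NULL, genotype_dialect = "raw",
                       outcome = c("ss", "cpd"), qc = qc_thresholds(),
                       gwas_threshold = 5e-8, window_pad = 250000,
                       fdr_target = 0.15, alpha = 0.05,
                       covariates = c("age", "sex"),
                       gwas_covariates = c("age", "sex", "bmi", "chip",
                                           paste0("pc", 1:10)),
                       inference = c("bootstrap", "sobel"), n_boot = 1000,
                       seed = 1L, output_dir = NULL) {
  outcome <- match.arg(outcome)
  inference <- match.arg(inference)
  if (is.null(simulation) && (is.null(genotype_path) || is.null(phenotype_path))) {
    stop("provide either a `simulation` config or both data paths", call. = FALSE)
  }
  if (inherits(qc, "list") && !inherits(qc, "qc_thresholds")) {
    qc <- do.call(qc_thresholds, qc)
  }
  structure(
    list(simulation = simulation, genotype_path = genotype_path,
         phenotype_path = phenotype_path, genotype_dialect = genotype_dialect,
         outcome = outcome, qc = qc, gwas_threshold = gwas_threshold,
         window_pad = window_pad, fdr_target = fdr_target, alpha = alpha,
         covariates = covariates, gwas_covariates = gwas_covariates,
         inference = inference, n_boot = n_boot, seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Run the full causal-pathway pipeline
#'
#' Executes simulate/load, QC, phenotype derivation, FA screening, the
#' association scan with locus-window selection, three-step pathway
#' discovery, and mediation analysis, logging subjects and SNPs in and out of
#' each stage. Stages downstream of an empty selection complete with empty
#' tables and an explicit notice rather than failing.
#'
#' @param config A [run_config()].
#' @return A list of class `pleio_run`: `qc_report`, `fa_screen`, `gwas`,
#'   `loci`, `windows`, `pathway`, `mediation`, `manifest`. When
#'   `config$output_dir` is set, each table is also written as TSV plus a
#'   JSON `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(...) message("[pleiopath] ", ...)

  if (!is.null(config$simulation)) {
    sim <- simulate_dataset(config$simulation)
    geno_raw <- sim$genotypes
    pheno <- sim$phenotypes
  } else {
    geno_raw <- read_genotypes(config$genotype_path,
                               dialect = config$genotype_dialect)
    pheno <- read_phenotypes(config$phenotype_path)
  }
  log_stage("input: ", nrow(geno_raw), " subjects, ",
            nrow(snp_info(geno_raw)), " SNPs")

  geno <- apply_genotype_qc(geno_raw, config$qc)
  qcr <- qc_report(geno)
  log_stage("QC: ", nrow(geno), " subjects, ", nrow(snp_info(geno)),
            " SNPs retained")

  if (config$outcome == "ss" && !"ss" %in% names(pheno) &&
      "smoking_group" %in% names(pheno)) {
    pheno <- derive_smoking_status(pheno)
  }
  if (config$outcome == "cpd" && "cpd" %in% names(pheno)) {
    pheno$cpd <- recode_cpd(pheno$cpd)
  }
  if (!config$outcome %in% names(pheno)) {
    stop("phenotype table lacks the `", config$outcome, "` column", call. = FALSE)
  }

  fa_screen <- screen_fa_measures(pheno, outcome = config$outcome,
                                  covariates = config$covariates,
                                  alpha = config$alpha)
  fa_keep <- fa_screen$fa_measure[fa_screen$keep %in% TRUE]
  log_stage("FA screen: ", length(fa_keep), " of ", nrow(fa_screen),
            " measures retained")

  scan <- snp_scan(geno, pheno, response = config$outcome,
                   covariates = config$gwas_covariates)
  loci <- select_gwas_loci(scan, config$gwas_threshold)
  windows <- locus_windows(loci, config$window_pad)
  cand <- snps_in_windows(snp_info(geno), windows)
  log_stage("GWAS: ", nrow(loci), " genome-wide significant SNPs, ",
            nrow(windows), " windows, ", nrow(cand), " candidate SNPs")

  empty_pathway <- tibble::tibble(
    snp_id = character(), fa_measure = character(), pleiotropic = logical(),
    selected_model = character()
  )
  if (nrow(cand) == 0 || length(fa_keep) == 0) {
    log_stage("no candidate SNPs or FA measures; downstream tables empty")
    pathway <- empty_pathway
    mediation <- run_mediation(geno, pheno, empty_pathway,
                               outcome = config$outcome, seed = config$seed)
  } else {
    geno_cand <- geno[c("IID", cand$snp_id)]
    attr(geno_cand, "snps") <- cand
    class(geno_cand) <- c("geno_tbl", class(geno_cand))
    pathway <- purrr::map_dfr(fa_keep, function(fa) {
      discover_pathways(geno_cand, pheno, fa_measure = fa,
                        outcome = config$outcome,
                        covariates = config$covariates,
                        fdr_target = config$fdr_target, alpha = config$alpha)
    })
    log_stage("pathway: ", sum(pathway$pleiotropic %in% TRUE),
              " pleiotropic (SNP, FA) pairs")
    mediation <- run_mediation(geno, pheno, pathway, outcome = config$outcome,
                               covariates = config$covariates,
                               method = config$inference,
                               n_boot = config$n_boot, alpha = config$alpha,
                               seed = config$seed)
    log_stage("mediation: ", nrow(mediation), " mediated pairs")
  }

  manifest <- list(
    package = "pleiopath",
    version = as.character(utils::packageVersion("pleiopath")),
    seed = config$seed,
    outcome = config$outcome,
    thresholds = list(
      qc = unclass(config$qc), gwas_threshold = config$gwas_threshold,
      window_pad = config$window_pad, fdr_target = config$fdr_target,
      alpha = config$alpha, n_boot = config$n_boot,
      inference = config$inference
    ),
    simulation = if (!is.null(config$simulation)) {
      unclass(config$simulation)
    },
    stage_sizes = list(
      subjects_in = nrow(geno_raw), snps_in = nrow(snp_info(geno_raw)),
      subjects_qc = nrow(geno), snps_qc = nrow(snp_info(geno)),
      fa_retained = length(fa_keep), gwas_hits = nrow(loci),
      candidate_snps = nrow(cand),
      pleiotropic = sum(pathway$pleiotropic %in% TRUE),
      mediated = nrow(mediation)
    )
  )

  out <- structure(
    list(qc_report = qcr, fa_screen = fa_screen, gwas = scan, loci = loci,
         windows = windows, pathway = pathway, mediation = mediation,
         manifest = manifest),
    class = "pleio_run"
  )
  if (!is.null(config$output_dir)) write_run_bundle(out, config$output_dir)
  out
}

write_run_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("qc_report", "fa_screen", "gwas", "loci", "windows", "pathway",
              "mediation")
  for (t in tables) {
    readr::write_tsv(tibble::as_tibble(run[[t]]),
                     file.path(dir, paste0(t, ".tsv")), progress = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pleio_run <- function(x, ...) {
  s <- x$manifest$stage_sizes
  cat("<pleio_run>\n")
  cat("  subjects: ", s$subjects_in, " -> ", s$subjects_qc, " after QC\n", sep = "")
  cat("  SNPs: ", s$snps_in, " -> ", s$snps_qc, " after QC; ",
      s$gwas_hits, " genome-wide significant; ", s$candidate_snps,
      " in extended windows\n", sep = "")
  cat("  FA measures retained: ", s$fa_retained, "\n", sep = "")
  cat("  pleiotropic pairs: ", s$pleiotropic, "; mediated: ", s$mediated,
      "\n", sep = "")
  invisible(x)
}
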