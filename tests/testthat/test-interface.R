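test_that("genotype dosage tables round-trip through the raw dialect", {
  d <- simulate_dataset(sim_config(n_subjects = 50, n_snps = 6,
                                   n_pleiotropic = 1, seed = 61))
  path <- withr::local_tempfile(fileext = ".raw")
  write_genotypes(d$genotypes, path)
  back <- read_genotypes(path)
  expect_equal(dplyr::as_tibble(back)[names(d$genotypes)],
               dplyr::as_tibble(d$genotypes))
  expect_equal(snp_info(back)$snp_id, snp_info(d$genotypes)$snp_id)
  expect_equal(snp_info(back)$bp, snp_info(d$genotypes)$bp)
})

test_that("phenotype tables round-trip", {
  d <- simulate_dataset(sim_config(n_subjects = 30, n_snps = 2, seed = 62))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(d$phenotypes, path)
  expect_equal(read_phenotypes(path), d$phenotypes)
})

test_that("VCF genotypes convert to minor-allele dosage with REF-minor flagging", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("P", 1:6)), collapse = "\t"),
    # ALT is minor (freq 3/12): dosage counts ALT
    paste(c("1", "1000", "rs1", "A", "G", ".", ".", ".", "GT",
            "0/0", "0/1", "0/0", "0/1", "0/0", "0/1"), collapse = "\t"),
    # REF is minor (ALT freq 9/12): dosage counts REF, flagged
    paste(c("1", "2000", "rs2", "T", "C", ".", ".", ".", "GT",
            "1/1", "1/1", "1/1", "0/1", "0/1", "0/1"), collapse = "\t"),
    # missing genotype propagates
    paste(c("1", "3000", "rs3", "T", "C", ".", ".", ".", "GT",
            "./.", "0/1", "0/0", "0/0", "0/0", "0/0"), collapse = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes(path, dialect = "vcf")
  s <- snp_info(g)
  # rs1: P2 is 0/1 counting ALT; rs2: P2 is 1/1, i.e. zero copies of the
  # minor REF allele; P4 is 0/1 -> one REF copy; rs3: P2 is 0/1
  expect_equal(unname(unlist(g[g$IID == "P2", c("rs1", "rs2", "rs3")])),
               c(1, 0, 1))
  expect_equal(g$rs2[g$IID == "P4"], 1)
  expect_false(s$ref_is_minor[s$snp_id == "rs1"])
  expect_true(s$ref_is_minor[s$snp_id == "rs2"])
  expect_identical(s$counted_allele[s$snp_id == "rs2"], "T")
  # heterozygote dosage is 1 under either counting; homozygous-common is 0
  expect_equal(unname(unlist(g[g$IID == "P1", c("rs1", "rs2")])), c(0, 0))
  expect_true(is.na(g$rs3[g$IID == "P1"]))
  expect_equal(s$maf, c(0.25, 0.25, 0.1), tolerance = 1e-12)
})

test_that("BED export converts 1-based inclusive to 0-based half-open", {
  w <- tibble::tibble(chr = c(1, 2), start_bp = c(1, 250000),
                      end_bp = c(1000, 850000))
  path <- withr::local_tempfile(fileext = ".bed")
  write_windows_bed(w, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, c(0, 249999))
  expect_equal(bed$V3, c(1000, 850000))
})

test_that("YAML configuration mirrors run_config fields and rejects unknowns", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "outcome: ss", "fdr_target: 0.15", "gwas_threshold: 5.0e-8",
    "seed: 7",
    "simulation:", "  n_subjects: 100", "  n_snps: 5", "  seed: 7"
  ), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$fdr_target, 0.15)
  expect_equal(cfg$simulation$n_subjects, 100L)

  writeLines(c("outcome: ss", "bogus_key: 1"), path)
  expect_error(read_run_config(path), "bogus_key")
})

test_that("defaults encode every analysis constant", {
  cfg <- run_config(simulation = sim_config())
  expect_equal(cfg$qc$maf_min, 0.01)
  expect_equal(cfg$qc$hwe_p_min, 0.001)
  expect_equal(cfg$qc$snp_missing_max, 0.05)
  expect_equal(cfg$qc$subject_missing_max, 0.02)
  expect_equal(cfg$gwas_threshold, 5e-8)
  expect_equal(cfg$window_pad, 250000)
  expect_equal(cfg$fdr_target, 0.15)
  expect_equal(cfg$alpha, 0.05)
  expect_error(run_config(), "simulation")
})

test_that("the pipeline completes with empty downstream tables when nothing passes", {
  cfg <- run_config(
    simulation = sim_config(n_subjects = 400, n_snps = 10, n_pleiotropic = 0,
                            seed = 63),
    seed = 63
  )
  msgs <- capture.output(r <- run_pipeline(cfg), type = "message")
  expect_true(any(grepl("downstream tables empty|0 genome-wide", msgs)))
  expect_equal(nrow(r$loci), 0)
  expect_equal(nrow(r$mediation), 0)
  expect_s3_class(r$qc_report, "tbl_df")
})

test_that("identical config and seed give byte-identical result bundles", {
  make_cfg <- function(dir) run_config(
    simulation = sim_config(n_subjects = 1200, n_snps = 25, n_pleiotropic = 3,
                            true_model = 1, beta_g_m = -0.5, beta_g_y = 0.4,
                            beta_m_y = -1.5, seed = 64),
    n_boot = 200, seed = 64, output_dir = dir
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(run_pipeline(make_cfg(d1)))
  suppressMessages(run_pipeline(make_cfg(d2)))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # manifest records every decision-relevant threshold
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$thresholds$fdr_target, 0.15)
  expect_equal(man$thresholds$gwas_threshold, 5e-8)
  expect_equal(man$thresholds$window_pad, 250000)
  expect_equal(man$thresholds$qc$maf_min, 0.01)
})

test_that("a simulation-backed run recovers the generating vertical model", {
  cfg <- run_config(
    simulation = sim_config(n_subjects = 2000, n_snps = 60, n_pleiotropic = 6,
                            true_model = 1, beta_g_m = -0.5, beta_g_y = 0.3,
                            beta_m_y = -1.5, seed = 65),
    n_boot = 200, seed = 65
  )
  r <- suppressMessages(run_pipeline(cfg))
  hits <- r$pathway[r$pathway$pleiotropic %in% TRUE, ]
  expect_gt(nrow(hits), 0)
  expect_gt(mean(hits$selected_model == "1"), 0.5)
  expect_gt(nrow(r$mediation), 0)
})

test_that("plot builders return ggplot objects", {
  d <- simulate_dataset(sim_config(n_subjects = 300, n_snps = 10,
                                   n_pleiotropic = 2, beta_g_y = 0.8,
                                   seed = 66))
  scan <- suppressMessages(snp_scan(d$genotypes, d$phenotypes, "ss"))
  expect_s3_class(plot_gwas(scan), "ggplot")
  expect_s3_class(autoplot(scan), "ggplot")
  med <- tibble::tibble(
    snp_id = "snp_1", fa_measure = "fa", model = "1", direct = 0.1,
    direct_p = 0.2, indirect = -0.3, ci_lower = -0.5, ci_upper = -0.1,
    indirect_p = 0.01, total = -0.2, mediation_type = "indirect_only"
  )
  class(med) <- c("mediation_result", class(med))
  expect_s3_class(plot_mediation(med), "ggplot")
  expect_error(plot_mediation(med[0, ]), "empty")
})
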