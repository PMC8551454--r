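# Readers and writers for dosage tables (PLINK .raw-style TSV, VCF),
# phenotype tables and run configuration files. All writers are plain-text
# and deterministic so result bundles are byte-reproducible.

#' Write a genotype dosage table
#'
#' PLINK `.raw`-style TSV: `FID`, `IID`, then one minor-allele dosage column
#' per SNP. SNP metadata is written alongside as `<path>.snps.tsv`.
#'
#' @param geno Genotype tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  out <- dplyr::bind_cols(tibble::tibble(FID = geno$IID), geno)
  readr::write_tsv(out, path, progress = FALSE)
  s <- attr(geno, "snps")
  if (!is.null(s)) readr::write_tsv(s, paste0(path, ".snps.tsv"), progress = FALSE)
  invisible(path)
}

#' Read a genotype dosage table
#'
#' Two dialects: `"raw"` reads a PLINK `.raw`-style TSV (pedigree columns
#' `FID`/`PAT`/`MAT`/`SEX`/`PHENOTYPE` are recognized and dropped; a
#' `<path>.snps.tsv` sidecar is picked up automatically when present);
#' `"vcf"` reads a VCF and converts diploid genotypes to *minor*-allele
#' dosages -- the counted allele is whichever of REF/ALT is rarer in the
#' file, and the choice is recorded per SNP in the metadata
#' (`counted_allele`, `ref_is_minor`).
#'
#' @param path Input file.
#' @param dialect `"raw"` (default) or `"vcf"`.
#' @param snp_info Optional SNP metadata tibble overriding the sidecar.
#' @return A genotype tibble (`IID` + dosage columns) with `"snps"` metadata.
#' @export
read_genotypes <- function(path, dialect = c("raw", "vcf"), snp_info = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") return(read_genotypes_vcf(path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  drop <- intersect(c("FID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(d))
  d <- d[setdiff(names(d), drop)]
  if (!"IID" %in% names(d)) stop("dosage table lacks an IID column", call. = FALSE)
  d$IID <- as.character(d$IID)
  snp_cols <- setdiff(names(d), "IID")
  bad <- !vapply(d[snp_cols], is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric dosage column(s): ", paste(snp_cols[bad], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(snp_info)) {
    sidecar <- paste0(path, ".snps.tsv")
    if (file.exists(sidecar)) {
      snp_info <- readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE)
    } else {
      snp_info <- tibble::tibble(
        snp_id = snp_cols, chr = NA_integer_, bp = NA_integer_,
        maf = vapply(d[snp_cols], function(x) {
          f <- mean(x, na.rm = TRUE) / 2
          min(f, 1 - f)
        }, numeric(1))
      )
    }
  }
  attr(d, "snps") <- snp_info
  class(d) <- c("geno_tbl", class(d))
  d
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  # ALT-allele count per genotype; "." missing
  alt_count <- function(x) {
    vapply(x, function(xi) {
      if (is.na(xi) || xi %in% c(".", "./.", ".|.")) return(NA_integer_)
      a <- strsplit(gsub("\\|", "/", xi), "/", fixed = TRUE)[[1]]
      if (any(a == ".")) return(NA_integer_)
      if (length(a) != 2) stop("mixed ploidy is unsupported", call. = FALSE)
      sum(a != "0")
    }, integer(1), USE.NAMES = FALSE)
  }
  dos <- apply(gt, 2, alt_count)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt),
                                       dimnames = dimnames(gt))
  alt_freq <- rowMeans(dos, na.rm = TRUE) / 2
  ref_is_minor <- alt_freq > 0.5
  dos[ref_is_minor, ] <- 2L - dos[ref_is_minor, , drop = FALSE]
  snp_id <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                   paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"])
  geno <- tibble::tibble(IID = colnames(gt))
  dosm <- t(dos)
  colnames(dosm) <- snp_id
  geno <- dplyr::bind_cols(geno, tibble::as_tibble(dosm))
  f <- unname(colMeans(dosm, na.rm = TRUE)) / 2
  attr(geno, "snps") <- tibble::tibble(
    snp_id = snp_id,
    chr = utils::type.convert(fix[, "CHROM"], as.is = TRUE),
    bp = as.integer(fix[, "POS"]),
    counted_allele = ifelse(ref_is_minor, fix[, "REF"], fix[, "ALT"]),
    other_allele = ifelse(ref_is_minor, fix[, "ALT"], fix[, "REF"]),
    ref_is_minor = ref_is_minor,
    maf = pmin(f, 1 - f)
  )
  class(geno) <- c("geno_tbl", class(geno))
  geno
}

#' Read / write a phenotype table
#'
#' Plain TSV with a header; `IID` is coerced to character.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"IID" %in% names(d)) stop("phenotype table lacks an IID column", call. = FALSE)
  d$IID <- as.character(d$IID)
  d
}

#' @rdname read_phenotypes
#' @param pheno Phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}

#' Export locus windows as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the exported start is `start_bp - 1` and the end is `end_bp`.
#'
#' @param windows Window tibble (`chr`, `start_bp`, `end_bp`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- tibble::tibble(chrom = windows$chr,
                        chromStart = windows$start_bp - 1L,
                        chromEnd = windows$end_bp)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [run_config()] arguments; unknown keys raise an error.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), c(known, "simulation"))
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sim <- vals$simulation
  vals$simulation <- NULL
  if (!is.null(sim)) vals$simulation <- do.call(sim_config, sim)
  do.call(run_config, vals)
}
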