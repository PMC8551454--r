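# Per-SNP association scan and locus-window selection: the screening stage
# that nominates candidate loci for the causal pathway analysis. Coordinates
# are 1-based inclusive throughout; BED export converts to 0-based half-open.

#' Per-SNP association scan
#'
#' Fits one regression per SNP (response on dosage plus covariates; logistic
#' for a binary response, linear otherwise) and collects the Wald statistics
#' into a single tidy table. Logistic fits showing numerical separation or
#' non-convergence are flagged; [select_gwas_loci()] excludes them from
#' ranking. Covariates absent from `pheno` are dropped with a message, so the
#' same call works on synthetic data carrying only age and sex and on richer
#' tables with BMI, chip and principal components.
#'
#' @param geno Genotype tibble (`IID` + dosage columns).
#' @param pheno Phenotype tibble with an `IID` column.
#' @param response Name of the response column in `pheno`.
#' @param covariates Covariate columns requested; default
#'   `c("age", "sex", "bmi", "chip", paste0("pc", 1:10))`, degrading to the
#'   columns that exist.
#' @param family `"auto"` (default), `"linear"` or `"logistic"`.
#' @return A tibble of class `snp_scan` with one row per SNP: `snp_id`, `chr`,
#'   `bp`, `estimate`, `std.error`, `statistic`, `p.value`, `n`, `flagged`.
#' @export
snp_scan <- function(geno, pheno, response,
                     covariates = c("age", "sex", "bmi", "chip", paste0("pc", 1:10)),
                     family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  covs <- intersect(covariates, names(pheno))
  dropped <- setdiff(covariates, covs)
  if (length(dropped) > 0) {
    message("covariate(s) not present, dropped: ", paste(dropped, collapse = ", "))
  }
  snps <- snp_info(geno)
  d <- dplyr::inner_join(pheno[c("IID", response, covs)], geno, by = "IID")
  y_all <- d[[response]]
  if (family == "auto") {
    family <- if (is_binary01(y_all)) "logistic" else "linear"
  }
  Z <- as.matrix(d[covs])
  G <- dosage_matrix(d[c("IID", snps$snp_id)])
  base_ok <- stats::complete.cases(cbind(y_all, Z))

  rows <- purrr::map(seq_len(nrow(snps)), function(j) {
    g <- G[, j]
    ok <- base_ok & !is.na(g)
    X <- cbind(`(Intercept)` = 1, snp = g[ok], Z[ok, , drop = FALSE])
    fit <- tryCatch(
      switch(family,
        linear = fit_linear_mle(X, y_all[ok]),
        logistic = fit_logistic_mle(X, y_all[ok])
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(estimate = NA_real_, std.error = NA_real_,
                            statistic = NA_real_, p.value = NA_real_,
                            n = sum(ok), flagged = TRUE))
    }
    s <- coef_of(fit, "snp")
    tibble::tibble(estimate = s$estimate, std.error = s$std.error,
                   statistic = s$statistic, p.value = s$p.value,
                   n = fit$n, flagged = !fit$converged || fit$separation)
  })
  out <- dplyr::bind_cols(snps[c("snp_id", "chr", "bp")], dplyr::bind_rows(rows))
  class(out) <- c("snp_scan", class(out))
  out
}

#' Select genome-wide significant SNPs
#'
#' Keeps SNPs whose Wald p-value falls below the genome-wide threshold
#' (default 5e-8), excluding flagged fits, sorted by genomic position. The
#' selection is monotone in the threshold: a larger threshold always contains
#' a smaller threshold's selection.
#'
#' @param scan A [snp_scan()] table.
#' @param threshold Significance threshold in (0, 1\]. Default `5e-8`.
#' @return The selected rows of `scan`, sorted by chromosome and position.
#' @export
select_gwas_loci <- function(scan, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold <= 1)
  scan |>
    dplyr::filter(!.data$flagged, !is.na(.data$p.value),
                  .data$p.value < threshold) |>
    dplyr::arrange(.data$chr, .data$bp)
}

#' Extend locus windows and merge overlaps
#'
#' Pads each peak window by a fixed distance on both sides (default 250 kb,
#' the conventional allowance for linkage disequilibrium with the lead
#' signal), clips at position 1, and merges overlapping or bookended windows
#' on the same chromosome so no SNP is counted twice.
#'
#' @param windows Tibble with columns `chr`, `start_bp`, `end_bp` (1-based
#'   inclusive).
#' @param pad Padding in base pairs on each side. Default `250000`.
#' @return A tibble of pairwise-disjoint windows covering every padded input.
#' @examples
#' peaks <- tibble::tibble(chr = 1, start_bp = 500000, end_bp = 600000)
#' extend_regions(peaks)
#' @export
extend_regions <- function(windows, pad = 250000) {
  stopifnot(pad >= 0)
  if (nrow(windows) == 0) {
    return(tibble::tibble(chr = integer(), start_bp = integer(),
                          end_bp = integer()))
  }
  if (any(windows$start_bp < 1 | windows$start_bp > windows$end_bp)) {
    stop("windows must satisfy 1 <= start_bp <= end_bp", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(windows$chr),
    ranges = IRanges::IRanges(start = pmax(1, windows$start_bp - pad),
                              end = windows$end_bp + pad)
  )
  red <- GenomicRanges::reduce(gr)
  tibble::tibble(
    chr = as.vector(GenomicRanges::seqnames(red)),
    start_bp = GenomicRanges::start(red),
    end_bp = GenomicRanges::end(red)
  ) |>
    dplyr::mutate(chr = utils::type.convert(.data$chr, as.is = TRUE)) |>
    dplyr::arrange(.data$chr, .data$start_bp)
}

#' Windows around significant SNPs
#'
#' Convenience wrapper: turns each selected SNP into a degenerate peak at its
#' position and applies [extend_regions()].
#'
#' @param selected Output of [select_gwas_loci()].
#' @param pad Padding in base pairs. Default `250000`.
#' @return Merged locus windows (see [extend_regions()]).
#' @export
locus_windows <- function(selected, pad = 250000) {
  extend_regions(
    tibble::tibble(chr = selected$chr, start_bp = selected$bp,
                   end_bp = selected$bp),
    pad = pad
  )
}

#' SNPs falling inside locus windows
#'
#' @param snps SNP metadata tibble (`snp_id`, `chr`, `bp`).
#' @param windows Window tibble from [extend_regions()] / [locus_windows()].
#' @return The rows of `snps` lying in any window, in position order.
#' @export
snps_in_windows <- function(snps, windows) {
  if (nrow(windows) == 0) return(snps[0, , drop = FALSE])
  hits <- purrr::map_lgl(seq_len(nrow(snps)), function(i) {
    any(windows$chr == snps$chr[i] &
          windows$start_bp <= snps$bp[i] &
          windows$end_bp >= snps$bp[i])
  })
  dplyr::arrange(snps[hits, , drop = FALSE], .data$chr, .data$bp)
}
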