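# Shared fixture builders. Everything is generated in code at test time.

# Genotype tibble from an explicit dosage matrix, with minimal SNP metadata.
make_geno <- function(dos, bp = NULL, chr = 1L) {
  n <- nrow(dos)
  m <- ncol(dos)
  ids <- colnames(dos)
  if (is.null(ids)) ids <- paste0("snp_", seq_len(m))
  if (m > 0) colnames(dos) <- ids
  g <- tibble::tibble(IID = sprintf("S%05d", seq_len(n)))
  g <- dplyr::bind_cols(g, tibble::as_tibble(dos))
  attr(g, "snps") <- tibble::tibble(
    snp_id = ids, chr = chr,
    bp = if (is.null(bp)) 1000L * seq_len(m) else as.integer(bp),
    maf = pmin(colMeans(dos, na.rm = TRUE) / 2,
               1 - colMeans(dos, na.rm = TRUE) / 2)
  )
  class(g) <- c("geno_tbl", class(g))
  g
}

# Dosage vector with exact genotype counts (n0 major hom, n1 het, n2 minor hom).
dosage_counts <- function(n0, n1, n2) rep(c(0, 1, 2), c(n0, n1, n2))

# One-SNP analysis table: phenotypes joined with the dosage column.
one_snp_data <- function(sim) {
  dplyr::bind_cols(sim$phenotypes, sim$genotypes["snp_1"])
}

# Reference interval-union oracle used against extend_regions().
union_windows_oracle <- function(windows, pad) {
  out <- list()
  for (ch in unique(windows$chr)) {
    w <- windows[windows$chr == ch, , drop = FALSE]
    s <- pmax(1, w$start_bp - pad)
    e <- w$end_bp + pad
    o <- order(s)
    s <- s[o]; e <- e[o]
    cs <- s[1]; ce <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] <= ce + 1) ce <- max(ce, e[i]) else {
        out[[length(out) + 1]] <- c(ch, cs, ce)
        cs <- s[i]; ce <- e[i]
      }
    }
    out[[length(out) + 1]] <- c(ch, cs, ce)
  }
  m <- do.call(rbind, out)
  tibble::tibble(chr = m[, 1], start_bp = m[, 2], end_bp = m[, 3]) |>
    dplyr::arrange(chr, start_bp)
}
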