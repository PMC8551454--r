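# Diagnostic figures: a Manhattan-style view of the association scan and a
# forest-style view of the mediation decomposition.

#' Manhattan-style plot of an association scan
#'
#' @param scan A [snp_scan()] table.
#' @param threshold Significance line. Default `5e-8`.
#' @return A ggplot object.
#' @export
plot_gwas <- function(scan, threshold = 5e-8) {
  d <- dplyr::filter(scan, !is.na(.data$p.value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bp / 1e6, y = -log10(.data$p.value))) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$chr)),
                        show.legend = length(unique(d$chr)) > 1, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  colour = "chr") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.snp_scan <- function(object, ...) plot_gwas(object, ...)

#' Forest-style plot of mediation effects
#'
#' Direct and indirect effects per SNP, indirect effects with their bootstrap
#' (or Sobel) intervals, coloured by mediation type.
#'
#' @param mediation A [run_mediation()] table.
#' @return A ggplot object.
#' @export
plot_mediation <- function(mediation) {
  if (nrow(mediation) == 0) {
    stop("empty mediation table: nothing to plot", call. = FALSE)
  }
  d <- tidyr::pivot_longer(
    mediation, c("direct", "indirect"),
    names_to = "effect", values_to = "estimate"
  ) |>
    dplyr::mutate(
      lo = dplyr::if_else(.data$effect == "indirect", .data$ci_lower, NA_real_),
      hi = dplyr::if_else(.data$effect == "indirect", .data$ci_upper, NA_real_)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$snp_id,
                                  colour = .data$mediation_type,
                                  shape = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      height = 0.2, na.rm = TRUE,
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~fa_measure) +
    ggplot2::labs(x = "effect estimate", y = NULL,
                  colour = "mediation type", shape = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mediation_result <- function(object, ...) plot_mediation(object, ...)
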