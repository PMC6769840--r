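# ggplot2 figures for call sets and summaries.

cnv_fill_scale <- function() {
  ggplot2::scale_fill_manual(
    values = c(gain = "#2c7fb8", loss = "#d7301f"),
    name = "CNV type",
    labels = c(gain = "duplication", loss = "deletion"))
}

#' Size distribution of CNV calls
#'
#' Histogram of call lengths (kbp) stacked by type, the conventional cohort
#' size-distribution figure.
#'
#' @param calls CNV call tibble (needs `length_kbp` or `start_bp`/`end_bp`).
#' @param binwidth_kbp Histogram bin width in kbp.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(calls, binwidth_kbp = 100) {
  stopifnot_cols(calls, c("chrom", "type"), "calls")
  if (!"length_kbp" %in% names(calls))
    calls <- mutate(calls, length_kbp = (.data$end_bp - .data$start_bp) / 1000)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$length_kbp,
                                      fill = .data$type)) +
    ggplot2::geom_histogram(binwidth = binwidth_kbp, boundary = 0,
                            colour = "grey20", linewidth = 0.2) +
    cnv_fill_scale() +
    ggplot2::labs(x = "CNV size (kbp)", y = "CNV count") +
    ggplot2::theme_minimal()
}

#' Per-chromosome distribution of CNV calls
#'
#' @param calls CNV call tibble.
#' @return A ggplot object (grouped bars per chromosome by type).
#' @export
plot_chromosome_distribution <- function(calls) {
  stopifnot_cols(calls, c("chrom", "type"), "calls")
  calls <- mutate(calls, chrom = factor(.data$chrom,
                                        levels = chrom_order(.data$chrom)))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$chrom, fill = .data$type)) +
    ggplot2::geom_bar(position = ggplot2::position_dodge2(preserve =
                                                            "single")) +
    cnv_fill_scale() +
    ggplot2::labs(x = "chromosome", y = "CNV count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Normalized profile with segment overlay
#'
#' Per-bin diploid ratios along the genome with optional segment means and
#' calling thresholds; the standard per-sample inspection figure.
#'
#' @param profile Normalized-profile tibble.
#' @param segments Optional [cbs_segment()] output for the same sample.
#' @param thresholds Ratio thresholds to draw as reference lines.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, segments = NULL,
                         thresholds = c(0.7, 1.3)) {
  stopifnot_cols(profile, c("chrom", "start", "ratio"), "profile")
  profile <- mutate(profile,
                    chrom = factor(.data$chrom,
                                   levels = chrom_order(.data$chrom)))
  p <- ggplot2::ggplot(filter(profile, is.finite(.data$ratio)),
                       ggplot2::aes(x = .data$start / 1e6,
                                    y = .data$ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey30") +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "#d7301f") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "diploid ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    segments <- mutate(segments,
                       chrom = factor(.data$chrom,
                                      levels = levels(profile$chrom)))
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                   y = .data$mean_ratio, yend = .data$mean_ratio),
      colour = "#2c7fb8", linewidth = 1)
  }
  p
}

#' Plot a cohort summary
#'
#' @param object A `cohort_summary`.
#' @param type `"sizes"` (size histogram) or `"chromosomes"` (per-chromosome
#'   bars).
#' @param ... Passed to the underlying `plot_*` function.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object,
                                    type = c("sizes", "chromosomes"), ...) {
  type <- match.arg(type)
  switch(type,
         sizes = plot_size_distribution(object$calls, ...),
         chromosomes = plot_chromosome_distribution(object$calls))
}
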