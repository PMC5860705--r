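#' Bar chart of call-set type composition
#'
#' @param callset population SV tibble.
#' @return a ggplot object.
#' @export
plot_type_composition <- function(callset) {
  type_composition(callset) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$sv_type, y = .data$n,
                                 fill = .data$sv_type)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "SVs") +
    ggplot2::theme_minimal()
}

#' Per-chromosome SV counts and densities
#'
#' @param callset population SV tibble.
#' @param chrom_lengths chromosome lengths (named vector or tibble).
#' @return a ggplot object.
#' @export
plot_chromosome_distribution <- function(callset, chrom_lengths) {
  df <- chromosome_distribution(callset, chrom_lengths)
  df$chrom <- factor(df$chrom, levels = df$chrom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "chromosome", y = "SVs") +
    ggplot2::theme_minimal()
}

#' Window counts and hotspot calls along the genome
#'
#' Plots the sliding-window SV counts produced by [hotspot_scan()] with
#' merged hotspot intervals shaded.
#'
#' @param hotspots result of [hotspot_scan()] (its `"windows"`
#'   attribute supplies the per-window scan).
#' @return a ggplot object.
#' @export
plot_hotspots <- function(hotspots) {
  win <- attr(hotspots, "windows")
  if (is.null(win)) abort("no window scan attached; pass hotspot_scan() output")
  p <- ggplot2::ggplot(win, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                         y = .data$sv_count)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "SVs per window") +
    ggplot2::theme_minimal()
  if (nrow(hotspots) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(hotspots),
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.2)
  }
  p
}

#' SV count versus transcript count per gene
#'
#' Bubble view of the gene-level table behind the SV–transcript
#' correlation.
#'
#' @param gene_table tibble from [gene_sv_table()].
#' @return a ggplot object.
#' @export
plot_gene_sv_transcripts <- function(gene_table) {
  gene_table %>%
    count(.data$n_transcripts, .data$sv_count, name = "genes") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$n_transcripts, y = .data$sv_count,
                                 size = .data$genes)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = "transcripts per gene", y = "SVs per gene",
                  size = "genes") +
    ggplot2::theme_minimal()
}
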