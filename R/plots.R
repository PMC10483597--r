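# ggplot2 views of the main result types.

#' Plot a log2ratio track
#'
#' Per-target log2ratios in panel order with the deletion and duplication
#' thresholds; points beyond a threshold are highlighted.
#'
#' @param track A `log2ratio_track`.
#' @param genes Optional gene subset.
#' @param params A [caller_params()] supplying the threshold lines.
#' @return A ggplot.
#' @export
plot_log2ratio <- function(track, genes = NULL, params = caller_params()) {
  dat <- as_tibble(track)
  if (!is.null(genes)) dat <- filter(dat, .data$gene %in% genes)
  dat$index <- seq_len(nrow(dat))
  dat$state <- dplyr::case_when(
    dat$l <= params$del_het ~ "deletion",
    dat$l >= params$dup ~ "duplication",
    TRUE ~ "neutral"
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$index, .data$l, colour = .data$state)) +
    ggplot2::geom_hline(yintercept = c(params$del_het, params$dup),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(
      deletion = "#C0392B", duplication = "#2471A3", neutral = "grey40"
    )) +
    ggplot2::facet_grid(~gene, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "target (panel order)", y = "log2 ratio",
                  title = unique(dat$sample_id)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' @export
autoplot.log2ratio_track <- function(object, ...) plot_log2ratio(object, ...)

#' Plot per-gene carrier rate comparison
#'
#' Dumbbell-style view of the per-gene carrier proportions in the two
#' groups, ordered by Fisher P value; significant genes are marked.
#'
#' @param rates Output of [rate_comparison()].
#' @param labels Names for the two groups.
#' @return A ggplot.
#' @export
plot_gene_rates <- function(rates, labels = c("LGR", "SNV/InDel")) {
  long <- rates %>%
    mutate(gene = factor(.data$gene, levels = rev(.data$gene))) %>%
    tidyr::pivot_longer(c("prop_a", "prop_b"), names_to = "side",
                        values_to = "prop") %>%
    mutate(side = ifelse(.data$side == "prop_a", labels[1], labels[2]))
  ggplot2::ggplot(long, ggplot2::aes(100 * .data$prop, .data$gene,
                                     colour = .data$side)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene), colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(
      data = filter(rates, .data$significant) %>%
        mutate(gene = factor(.data$gene, levels = levels(long$gene))),
      ggplot2::aes(x = 100 * pmax(.data$prop_a, .data$prop_b), y = .data$gene),
      label = "*", colour = "black", nudge_x = 0.3, size = 5
    ) +
    ggplot2::labs(x = "carrier proportion (%)", y = NULL, colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot the germline-by-somatic co-occurrence matrix
#'
#' Tile heatmap of log2 odds ratios with significance asterisks.
#'
#' @param co Output of [cooccurrence_matrix()].
#' @return A ggplot.
#' @export
plot_cooccurrence <- function(co) {
  co$log2_or <- log2(co$odds_ratio)
  ggplot2::ggplot(co, ggplot2::aes(.data$somatic_gene, .data$germline_gene,
                                   fill = .data$log2_or)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = filter(co, .data$significant), label = "*") +
    ggplot2::scale_fill_gradient2(low = "#2471A3", mid = "white",
                                  high = "#C0392B", midpoint = 0) +
    ggplot2::labs(x = "somatic gene", y = "germline gene",
                  fill = "log2 OR") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Boxplot of a per-sample metric by germline mutation group
#'
#' @param patients Grouped patients joined with their metrics.
#' @param metric Column to plot (tidy-eval).
#' @return A ggplot.
#' @export
plot_metric_by_group <- function(patients, metric) {
  dat <- filter(patients, !.data$excluded)
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, {{ metric }},
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::theme_bw()
}
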