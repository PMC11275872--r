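# Standard figures for the network analyses, each backed by a CSV of its
# plotted values so every visual can be recomputed.

save_fig <- function(plot, path, width = 7, height = 6) {
  ggplot2::ggsave(path, plot = plot, width = width, height = height, dpi = 150)
  path
}

#' Export correlation-network figures with backing CSVs
#'
#' Writes, for whichever inputs are supplied: per-group correlation heatmaps
#' masked at the significance threshold, network diagrams (edge width
#' proportional to |r|, negative edges dashed), a volcano plot of permuted
#' correlation differences with the |diff| and alpha quadrants delimited, a
#' parallel-coordinate plot of significantly changed pairs, and descending
#' degree and betweenness bar charts. Every figure `<name>.png` is
#' accompanied by `<name>.csv` holding exactly the plotted values. Empty
#' inputs are skipped with a message.
#'
#' @param out_dir output directory (created if needed).
#' @param correlations named list of [correlation_matrix()]s (names used in
#'   file names), or NULL.
#' @param networks named list of [build_network()] results, or NULL.
#' @param permutation tibble from [permute_correlation_differences()], or
#'   NULL.
#' @param alpha significance threshold drawn on heatmaps and the volcano.
#' @param min_abs_diff difference threshold drawn on the volcano and used to
#'   select parallel-coordinate pairs.
#' @return character vector of files written (invisibly).
#' @export
export_figures <- function(out_dir, correlations = NULL, networks = NULL,
                           permutation = NULL, alpha = 0.01,
                           min_abs_diff = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, plot, name, ...) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, csv)
    png <- save_fig(plot, file.path(out_dir, paste0(name, ".png")), ...)
    written <<- c(written, csv, png)
  }

  for (nm in names(correlations)) {
    corr <- correlations[[nm]]
    long <- correlation_long(corr)
    long$r_masked <- ifelse(!is.na(long$p) & long$p < alpha, long$r, NA_real_)
    if (nrow(long) == 0) { message("no correlations for ", nm); next }
    pl <- ggplot2::ggplot(long, ggplot2::aes(.data$region_a, .data$region_b,
                                             fill = .data$r_masked)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                    high = "#B2182B", limits = c(-1, 1),
                                    na.value = "grey92",
                                    name = sprintf("r (p < %g)", alpha)) +
      ggplot2::labs(title = sprintf("%s %s regional correlations",
                                    corr$group, corr$channel),
                    x = NULL, y = NULL) +
      ggplot2::theme_minimal(base_size = 8) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5))
    emit(long, pl, paste0("heatmap_", nm))
  }

  for (nm in names(networks)) {
    net <- networks[[nm]]
    edges <- network_edges(net)
    if (nrow(edges) == 0) { message("network ", nm, " has no edges"); next }
    lay <- igraph::layout_with_fr(net$graph)
    nodes <- tibble::tibble(region = igraph::V(net$graph)$name,
                            x = lay[, 1], y = lay[, 2])
    seg <- dplyr::left_join(edges, nodes, by = c("from" = "region"))
    seg <- dplyr::left_join(seg, nodes, by = c("to" = "region"),
                            suffix = c("", "_to"))
    pl <- ggplot2::ggplot() +
      ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                     yend = .data$y_to, linewidth = abs(.data$r),
                     linetype = factor(.data$sign, c(1, -1),
                                       c("positive", "negative"))),
        color = "grey40") +
      ggplot2::geom_point(data = nodes,
                          ggplot2::aes(.data$x, .data$y), size = 2) +
      ggplot2::geom_text(data = nodes,
                         ggplot2::aes(.data$x, .data$y, label = .data$region),
                         vjust = -0.8, size = 2.5) +
      ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
      ggplot2::labs(title = sprintf("%s %s co-activation network (|r| > %g, p < %g)",
                                    net$group, net$channel, net$r_min,
                                    net$alpha),
                    linetype = NULL) +
      ggplot2::theme_void()
    emit(seg, pl, paste0("network_", nm))

    met <- node_metrics(net)$nodes
    for (metric in c("degree", "betweenness")) {
      top <- dplyr::arrange(met, dplyr::desc(.data[[metric]]))
      top <- utils::head(top[top[[metric]] > 0, ], 20)
      if (nrow(top) == 0) next
      pb <- ggplot2::ggplot(top,
                            ggplot2::aes(stats::reorder(.data$region,
                                                        .data[[metric]]),
                                         .data[[metric]])) +
        ggplot2::geom_col(fill = "grey30") +
        ggplot2::coord_flip() +
        ggplot2::labs(x = NULL, y = metric,
                      title = sprintf("%s %s: top %s", net$group, net$channel,
                                      metric)) +
        ggplot2::theme_minimal(base_size = 9)
      emit(top, pb, paste0(metric, "_", nm), width = 5, height = 5)
    }
  }

  if (!is.null(permutation)) {
    if (nrow(permutation) == 0) {
      message("permutation results empty; volcano skipped")
    } else {
      volc <- permutation
      volc$neg_log10_p <- -log10(volc$p_value)
      volc$highlight <- abs(volc$diff) >= min_abs_diff &
        volc$p_value < alpha
      pv <- ggplot2::ggplot(volc, ggplot2::aes(.data$diff,
                                               .data$neg_log10_p,
                                               color = .data$highlight)) +
        ggplot2::geom_point(alpha = 0.6, size = 1) +
        ggplot2::geom_vline(xintercept = c(-min_abs_diff, min_abs_diff),
                            linetype = "dashed") +
        ggplot2::geom_hline(yintercept = -log10(alpha),
                            linetype = "dashed") +
        ggplot2::scale_color_manual(values = c("FALSE" = "grey60",
                                               "TRUE" = "#B2182B"),
                                    guide = "none") +
        ggplot2::labs(x = "correlation difference (group B - group A)",
                      y = expression(-log[10] ~ p)) +
        ggplot2::theme_minimal()
      emit(volc, pv, "volcano")

      sig <- volc[volc$highlight, , drop = FALSE]
      if (nrow(sig) > 0) {
        par <- tidyr::pivot_longer(
          sig[, c("region_a", "region_b", "r_a", "r_b")],
          cols = c("r_a", "r_b"), names_to = "side", values_to = "r")
        par$pair <- paste(par$region_a, par$region_b, sep = "-")
        pp <- ggplot2::ggplot(par, ggplot2::aes(.data$side, .data$r,
                                                group = .data$pair,
                                                color = .data$pair)) +
          ggplot2::geom_line() + ggplot2::geom_point() +
          ggplot2::labs(x = NULL, y = "Pearson r", color = "pair") +
          ggplot2::theme_minimal()
        emit(par, pp, "parallel_coordinates")
      } else {
        message("no significant pairs; parallel-coordinate plot skipped")
      }
    }
  }
  invisible(written)
}
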