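#' Plot the mapping outputs
#'
#' Writes two PNG figures: the per-chromosome homozygosity scores of both
#' pools (mutant in red, sibling in blue), and the candidate chromosome's
#' windowed homozygosity/heterozygosity ratio with the smoothed fit overlaid,
#' the critical region shaded and a dashed vertical line at the peak.
#'
#' @param scores output of [chromosome_homozygosity_scores()].
#' @param windows window table with a `fitted` column (as produced by
#'   [run_pipeline()]).
#' @param region a `critical_region` or `NULL`.
#' @param out_dir output directory.
#' @return named list of written file paths (`fig_scores`, `fig_ratio`).
#' @export
make_figures <- function(scores, windows, region, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fig_scores <- file.path(out_dir, "fig_homozygosity_scores.png")
  fig_ratio <- file.path(out_dir, "fig_ratio_fit.png")

  sc <- scores[!is.na(scores$score), , drop = FALSE]
  sc$chrom <- factor(sc$chrom, levels = unique(scores$chrom))
  p1 <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$chrom, y = .data$score,
                                         fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(mutant = "#c0392b", sibling = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "homozygosity score",
                  title = "Per-chromosome homozygosity score") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  ggplot2::ggsave(fig_scores, p1, width = 8, height = 3.5, dpi = 120)

  if (is.null(windows) || nrow(windows) == 0) {
    p2 <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no data") +
      ggplot2::theme_void()
  } else {
    w <- windows
    w$mb <- w$center / 1e6
    p2 <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mb))
    if (!is.null(region))
      p2 <- p2 + ggplot2::annotate("rect", xmin = region$start / 1e6,
                                   xmax = region$end / 1e6, ymin = -Inf, ymax = Inf,
                                   alpha = 0.15, fill = "#27ae60")
    p2 <- p2 +
      ggplot2::geom_point(ggplot2::aes(y = .data$ratio), colour = "grey40", size = 0.8) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2980b9", linewidth = 0.9)
    if (!is.null(region))
      p2 <- p2 + ggplot2::geom_vline(xintercept = region$peak_pos / 1e6,
                                     colour = "#c0392b", linetype = "dashed")
    p2 <- p2 +
      ggplot2::labs(x = sprintf("%s position (Mb)", w$chrom[1]),
                    y = "hom/het ratio",
                    title = "Windowed homozygosity/heterozygosity ratio") +
      ggplot2::theme_minimal(base_size = 10)
  }
  ggplot2::ggsave(fig_ratio, p2, width = 8, height = 3.5, dpi = 120)
  list(fig_scores = fig_scores, fig_ratio = fig_ratio)
}
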