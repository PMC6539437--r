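#' Genome-scan plot: SNP-index of each pool and the delta track
#'
#' Three stacked panels per chromosome — Pool A (wild-type bulk) window
#' mean SNP-index, Pool B (mutant bulk) window mean SNP-index, and the
#' window mean delta(SNP-index) with the simulated null band as a grey
#' ribbon. Candidate regions are shaded in the delta panel.
#'
#' @param object A [mutmap_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mutmap_scan
#' @export
autoplot.mutmap_scan <- function(object, ...) {
  w <- object$windows %>% filter(.data$n_snps > 0)
  mid <- (w$start + w$end) / 2
  long <- dplyr::bind_rows(
    tibble(chrom = w$chrom, pos = mid, value = w$mean_index_a,
           lo = NA_real_, hi = NA_real_, panel = "SNP-index (Pool A)"),
    tibble(chrom = w$chrom, pos = mid, value = w$mean_index_b,
           lo = NA_real_, hi = NA_real_, panel = "SNP-index (Pool B)"),
    tibble(chrom = w$chrom, pos = mid, value = w$mean_delta,
           lo = w$ci_lower, hi = w$ci_upper, panel = "delta(SNP-index)")
  ) %>%
    mutate(panel = factor(.data$panel, levels = c(
      "SNP-index (Pool A)", "SNP-index (Pool B)", "delta(SNP-index)"
    )))
  band <- long %>% filter(!is.na(.data$lo))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos / 1e6,
                                          y = .data$value)) +
    ggplot2::geom_ribbon(
      data = band, ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "grey80", na.rm = TRUE
    ) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::facet_grid(panel ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_bw()
  if (nrow(object$regions) > 0) {
    shade <- object$regions %>%
      mutate(panel = factor("delta(SNP-index)", levels = levels(long$panel)))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p
}

#' Fine-mapping diagram: recombinant counts along the chromosome
#'
#' Markers on their physical positions with the recombinant-chromosome
#' count labelled; the delimited interval is shaded.
#'
#' @param object A [finemap()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot finemap_result
#' @export
autoplot.finemap_result <- function(object, ...) {
  m <- object$markers
  iv <- object$interval
  ggplot2::ggplot(m, ggplot2::aes(x = .data$pos / 1e6, y = 0)) +
    ggplot2::annotate("rect", xmin = iv$left_pos / 1e6,
                      xmax = iv$right_pos / 1e6, ymin = -0.5, ymax = 0.5,
                      fill = "firebrick", alpha = 0.15) +
    ggplot2::geom_point(shape = 3, size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$marker), angle = 90,
                       hjust = 0, nudge_y = 0.08, size = 2.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$recombinants),
                       nudge_y = -0.15, size = 3) +
    ggplot2::scale_y_continuous(limits = c(-0.6, 1), breaks = NULL) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = sprintf("interval %s - %s (%.2f kb)",
                                  iv$left_marker, iv$right_marker,
                                  iv$span_kb)) +
    ggplot2::theme_minimal()
}
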