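# ggplot2 visualisations for the main result types.

#' Dot plot of synteny blocks
#'
#' Anchors are drawn in gene-rank space, faceted by chromosome pair and
#' coloured by block orientation.
#'
#' @param object A `synteny_blocks` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synteny_blocks
#' @export
autoplot.synteny_blocks <- function(object, ...) {
  anchors <- object |>
    select("block_id", "orientation", "anchors") |>
    tidyr::unnest("anchors")
  ggplot2::ggplot(anchors,
                  ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                               colour = .data$orientation)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom_b),
                        cols = ggplot2::vars(.data$chrom_a),
                        scales = "free") +
    ggplot2::labs(x = "gene rank (reference)", y = "gene rank (target)",
                  colour = "orientation") +
    ggplot2::theme_minimal()
}

#' Karyotype painting plot
#'
#' Each chromosome is drawn as a bar of gene-rank segments coloured by
#' assigned proto-chromosome; unpainted runs are grey.
#'
#' @param object A `painting` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot painting
#' @export
autoplot.painting <- function(object, ...) {
  seg <- painting_segments(object)
  ggplot2::ggplot(seg,
                  ggplot2::aes(xmin = .data$start_rank,
                               xmax = .data$end_rank + 1,
                               ymin = 0, ymax = 1, fill = .data$proto)) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chromosome),
                        switch = "y") +
    ggplot2::scale_fill_hue(na.value = "grey85") +
    ggplot2::labs(x = "gene rank", fill = "proto-chromosome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
}

#' Observed versus expected block counts per ancestral arm
#'
#' @param object An `arm_randomization` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot arm_randomization
#' @export
autoplot.arm_randomization <- function(object, ...) {
  d <- object$table |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "kind", values_to = "blocks")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$blocks,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "ancestral chromosome arm", y = "synteny blocks",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
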