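# ggplot2 views of the result types: sequence logos, domain architectures,
# and intron conservation maps.

#' Plot a sequence logo
#'
#' Stacked letter heights per column; the height of a stack equals the
#' column's information content in bits.
#'
#' @param logo A `coro_logo` tibble from [sequence_logo()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_logo <- function(logo, ...) {
  dat <- logo |> filter(!is.na(.data$height)) |> group_by(.data$column) |>
    arrange(.data$height, .by_group = TRUE) |>
    mutate(ymax = cumsum(.data$height), ymin = .data$ymax - .data$height) |>
    ungroup()
  ggplot2::ggplot(dat) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$column - 0.45,
                                    xmax = .data$column + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$residue),
                       colour = "grey30", linewidth = 0.1, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(x = .data$column,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$residue), size = 2) +
    ggplot2::labs(x = "alignment column", y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_logo
#' @param object A `coro_logo`.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.coro_logo <- function(object, ...) plot_logo(object, ...)

#' Plot domain architectures
#'
#' Draws each sequence as a line with its resolved domain hits as boxes, in
#' the style of family-overview domain cartoons.
#'
#' @param architectures Output of [assemble_architecture()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_architecture <- function(architectures, ...) {
  hits <- architectures |> select("seq_id", "hits") |> tidyr::unnest("hits",
    names_sep = "_")
  hits$seq_id <- factor(hits$seq_id, levels = rev(architectures$seq_id))
  ggplot2::ggplot(hits) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = max(.data$hits_end),
                                       y = .data$seq_id, yend = .data$seq_id),
                          colour = "grey70") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$hits_start, xmax = .data$hits_end,
                                    ymin = as.numeric(.data$seq_id) - 0.35,
                                    ymax = as.numeric(.data$seq_id) + 0.35,
                                    fill = .data$hits_domain_name)) +
    ggplot2::labs(x = "residue", y = NULL, fill = "domain") +
    ggplot2::theme_minimal()
}

#' Plot projected intron positions across homologs
#'
#' Marks each gene's introns at their alignment columns, coloured by phase;
#' conserved exon borders line up vertically, and border-flag verdicts (if
#' provided) are drawn as point shapes.
#'
#' @param marks Projected intron marks (with `column`).
#' @param flags Optional output of [flag_borders()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_intron_map <- function(marks, flags = NULL, ...) {
  dat <- marks
  if (!is.null(flags)) {
    dat <- left_join(dat, flags[c("gene_id", "intron_index", "verdict")],
                     by = c("gene_id", "intron_index"))
  } else {
    dat$verdict <- "supported"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$column, y = .data$gene_id,
                                    colour = factor(.data$phase),
                                    shape = .data$verdict)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(supported = 16, suspicious = 4)) +
    ggplot2::labs(x = "alignment column", y = NULL, colour = "phase") +
    ggplot2::theme_minimal()
}
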