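# ggplot2 views of the main result types.

#' Plot a linear genome map of ORFs and hr loci
#'
#' Forward-strand ORFs are drawn above the axis, reverse-strand below,
#' hr loci as a middle track — the familiar circular-genome figure
#' unrolled.
#'
#' @param orfs ORF tibble (`start`, `span`, `strand`, optionally `name`).
#' @param hrs Optional hr tibble (`start`, `span`, `label`).
#' @param genome_length Genome length in bp (x-axis limit).
#' @return A ggplot object.
#' @export
plot_genome_map <- function(orfs, hrs = NULL, genome_length = NULL) {
  orfs <- dplyr::mutate(orfs,
    y = ifelse(.data$strand == "+", 1, -1),
    xmin = .data$start, xmax = .data$start + .data$span)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = orfs,
      ggplot2::aes(xmin = .data$xmin / 1e3, xmax = .data$xmax / 1e3,
                   ymin = .data$y * 0.2, ymax = .data$y * 0.9,
                   fill = .data$strand),
      colour = "grey20", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c("+" = "#4477AA", "-" = "#EE6677")) +
    ggplot2::labs(x = "position (kb)", y = NULL, fill = "strand") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(hrs) && nrow(hrs) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = hrs,
      ggplot2::aes(xmin = .data$start / 1e3,
                   xmax = (.data$start + .data$span) / 1e3,
                   ymin = -0.12, ymax = 0.12),
      fill = "black")
  }
  if (!is.null(genome_length)) {
    p <- p + ggplot2::xlim(0, genome_length / 1e3)
  }
  p
}

#' Plot synteny blocks as an index cross-map
#'
#' Each shared ortholog is a point (focal rank vs subject rank); block
#' membership is shown by colour and inverted blocks descend.
#'
#' @param blocks Tibble from [synteny_map()].
#' @return A ggplot object.
#' @export
plot_synteny <- function(blocks) {
  pts <- tidyr::unnest(
    blocks[, c("block", "orientation", "query_index", "subject_index")],
    cols = c("query_index", "subject_index"))
  ggplot2::ggplot(pts,
    ggplot2::aes(x = .data$query_index, y = .data$subject_index,
                 colour = .data$orientation,
                 group = .data$block)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_colour_manual(values = c(collinear = "#228833",
                                            inverted = "#AA3377")) +
    ggplot2::labs(x = "focal gene rank", y = "subject gene rank",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a restriction digest as a gel-like lane diagram
#'
#' @param digest Tibble from [digest_genome()].
#' @return A ggplot object (log-scaled fragment sizes per enzyme lane).
#' @export
plot_digest <- function(digest) {
  lanes <- tidyr::unnest(digest[, c("enzyme", "fragments")],
                         cols = "fragments")
  ggplot2::ggplot(lanes,
    ggplot2::aes(x = .data$enzyme, y = .data$fragments)) +
    ggplot2::geom_point(shape = 95, size = 10) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "fragment size (bp)") +
    ggplot2::theme_minimal()
}
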