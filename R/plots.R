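#' Synteny dot plot of anchor chains
#'
#' Each chain block is drawn as a segment in reference coordinates
#' (x axis) against scaffold coordinates (y axis), faceted by chromosome
#' and colored by scaffold.
#'
#' @param object A `scaf_chains` tibble from [chain_blocks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaf_chains <- function(object, ...) {
  if (nrow(object) == 0L) abort("no chains to plot")
  segs <- bind_rows(lapply(seq_len(nrow(object)), function(i) {
    r <- object[i, ]
    bc <- chain_block_coords(r)
    q0 <- if (r$qStrand == "+") bc$qb else r$qSize - bc$qe
    q1 <- if (r$qStrand == "+") bc$qe else r$qSize - bc$qb
    tibble(chrom = r$tName, scaffold = r$qName,
           t0 = bc$tb, t1 = bc$te, q0 = q0, q1 = q1)
  }))
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$t0, xend = .data$t1, y = .data$q0, yend = .data$q1,
      color = .data$scaffold)) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "reference position (bp)",
                  y = "scaffold position (bp)",
                  title = "anchor chains") +
    ggplot2::theme_minimal()
}

#' Distribution of per-scaffold intersecting fractions
#'
#' @param object A `scaf_fresult` from [intersecting_fraction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaf_fresult <- function(object, ...) {
  d <- object$per_scaffold[object$per_scaffold$Z > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$aggregate_F, linetype = 2) +
    ggplot2::labs(x = "per-scaffold C/Z", y = "scaffolds",
                  title = sprintf("intersecting fraction (aggregate F = %.3f)",
                                  object$aggregate_F)) +
    ggplot2::theme_minimal()
}

#' Map of anchored scaffolds along reference chromosomes
#'
#' Draws each report row as a horizontal span on its chromosome, colored
#' by orientation.
#'
#' @param report A [scaffold_report()] table.
#' @return A ggplot object.
#' @export
plot_scaffold_map <- function(report) {
  if (nrow(report) == 0L) abort("empty report")
  ggplot2::ggplot(report) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$ref_start, xend = .data$ref_end,
      y = .data$chromosome, yend = .data$chromosome,
      color = .data$strand), linewidth = 4, alpha = 0.7) +
    ggplot2::labs(x = "reference position (bp)", y = NULL,
                  color = "orientation",
                  title = "scaffolds anchored on reference chromosomes") +
    ggplot2::theme_minimal()
}
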