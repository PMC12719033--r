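#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
print.fs_efficiency <- function(x, ...) {
  cat(sprintf("+1 frameshift efficiency: %.2f%%\n", x$percent))
  cat(sprintf("  ORF1: %.4g reads over %d codons (%.4g reads/codon)\n",
              x$orf1_reads, x$orf1_codons, x$orf1_density))
  cat(sprintf("  ORF2: %.4g reads over %d codons (%.4g reads/codon)\n",
              x$orf2_reads, x$orf2_codons, x$orf2_density))
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% bootstrap CI [%.2f, %.2f] (B = %d, seed = %d)\n",
                100 * x$ci$conf, x$ci$lo, x$ci$hi, x$ci$B, x$ci$seed))
  }
  invisible(x)
}

#' Tidy a frameshift-efficiency estimate
#'
#' @param x an `fs_efficiency` object from [estimate_efficiency()].
#' @param ... unused.
#' @return a one-row tibble with the estimate, densities, codon counts,
#'   read totals and (when present) the bootstrap interval.
#' @export
tidy.fs_efficiency <- function(x, ...) {
  tibble(
    percent = x$percent,
    orf1_density = x$orf1_density, orf2_density = x$orf2_density,
    orf1_codons = x$orf1_codons, orf2_codons = x$orf2_codons,
    orf1_reads = x$orf1_reads, orf2_reads = x$orf2_reads,
    ci_lo = if (is.null(x$ci)) NA_real_ else x$ci$lo,
    ci_hi = if (is.null(x$ci)) NA_real_ else x$ci$hi
  )
}

#' Glance at a frameshift-efficiency estimate
#'
#' @param x an `fs_efficiency` object.
#' @param ... unused.
#' @return a one-row tibble: `percent`, `ci_lo`, `ci_hi`, `n_reads`.
#' @exportS3Method generics::glance
glance.fs_efficiency <- function(x, ...) {
  tibble(
    percent = x$percent,
    ci_lo = if (is.null(x$ci)) NA_real_ else x$ci$lo,
    ci_hi = if (is.null(x$ci)) NA_real_ else x$ci$hi,
    n_reads = x$orf1_reads + x$orf2_reads
  )
}

#' Plot sub-codon phase fractions by region
#'
#' Bar panel per region, in the style of frame-phasing figures: one bar
#' per sub-codon phase (displayed as frames 1-3), height = fraction of
#' region reads.
#'
#' @param object a `fs_phasing` tibble from [frame_phasing()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fs_phasing <- function(object, ...) {
  df <- mutate(object, frame = factor(.data$phase + 1L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$fraction,
                                   fill = .data$frame)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_fill_manual(values = c("#2166ac", "#e08214", "#878787")) +
    ggplot2::labs(x = "sub-codon frame", y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' Plot an A-site count track colored by sub-codon phase
#'
#' Coverage bars colored by phase relative to an anchor, the direct
#' visualization of a reading-frame change along a transcript.
#'
#' @param track A-site count track tibble.
#' @param anchor 0-based position defining phase 0 (e.g. the ORF1 start).
#' @param regions optional region tibble drawn as background strips.
#' @return a ggplot object.
#' @export
plot_frame_track <- function(track, anchor = 0L, regions = NULL) {
  df <- mutate(track, frame = factor(((.data$pos - anchor) %% 3L) + 1L))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$count,
                                        color = .data$frame))
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.08
    )
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::scale_color_manual(values = c("#2166ac", "#e08214", "#878787"),
                                name = "frame") +
    ggplot2::labs(x = "transcript position (nt)", y = "A-site reads") +
    ggplot2::theme_minimal()
}
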