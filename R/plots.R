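#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline geom_step
#'   geom_segment geom_hline geom_point labs facet_wrap theme_minimal
NULL

#' Plot an insert-size model over its observed lengths
#'
#' Histogram of insert lengths with the `LC`/`UC` cut-offs marked.
#'
#' @param object An `insert_model`.
#' @param lengths Numeric vector of observed insert lengths to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.insert_model <- function(object, lengths, ...) {
  df <- tibble(l = lengths)
  ggplot(df, aes(x = .data$l)) +
    geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = c(object$lc[1], object$uc[1]),
               linetype = "dashed", colour = "firebrick") +
    labs(x = "insert length (bp)", y = "pairs",
         title = sprintf("Insert-size model: LC = %.0f, UC = %.0f (alpha = %g)",
                         object$lc[1], object$uc[1], object$alpha[1])) +
    theme_minimal()
}

#' Plot the transformed depth signal with its segmentation
#'
#' @param windows Transformed window tibble (column `y`).
#' @param segments Segment tibble from [segment_depth()].
#' @param chrom Optional single chromosome to display.
#' @return A ggplot object.
#' @export
plot_depth_segments <- function(windows, segments, chrom = NULL) {
  if (!is.null(chrom)) {
    windows <- windows[windows$chrom == chrom, ]
    segments <- segments[segments$chrom == chrom, ]
  }
  w <- windows[!windows$masked, ]
  ggplot() +
    geom_point(data = w, aes(x = .data$start, y = .data$y),
               size = 0.3, alpha = 0.4, colour = "grey50") +
    geom_segment(data = segments,
                 aes(x = .data$start, xend = .data$end,
                     y = .data$mean_y, yend = .data$mean_y,
                     colour = .data$state), linewidth = 1.1) +
    geom_hline(yintercept = c(-0.4, 0.4), linetype = "dotted") +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (bp)", y = "sqrt-scaled depth (y)", colour = "state") +
    theme_minimal()
}

#' Plot SV calls along the genome
#'
#' One horizontal bar per call over its source region, coloured by reported
#' type; insertion points are marked where present.
#'
#' @param calls SV-call tibble from [define_svs()].
#' @return A ggplot object.
#' @export
plot_sv_calls <- function(calls) {
  calls <- calls %>% mutate(yy = row_number())
  ins <- calls[!is.na(calls$insert_chrom), ]
  p <- ggplot(calls) +
    geom_segment(aes(x = .data$source_lo, xend = .data$source_hi,
                     y = .data$yy, yend = .data$yy,
                     colour = .data$reported_type), linewidth = 2) +
    facet_wrap(~source_chrom, scales = "free_x") +
    labs(x = "position (bp)", y = NULL, colour = "type") +
    theme_minimal()
  if (nrow(ins)) {
    p <- p + geom_point(data = ins,
                        aes(x = .data$insert_lo, y = .data$yy), shape = 25)
  }
  p
}
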