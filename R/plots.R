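#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contact matrix
#'
#' Heat map of log10(1 + counts) over genomic bins; the Ori domain
#' appears as a high-contact block, Ter as a low-contact one.
#'
#' @param object A [contact_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_matrix <- function(object, ...) {
  bin <- attr(object, "bin")
  df <- tidyr::expand_grid(i = seq_len(nrow(object)),
                           j = seq_len(ncol(object)))
  df$value <- object[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$i - 0.5) * bin / 1e6,
    y = (.data$j - 0.5) * bin / 1e6,
    fill = log10(1 + .data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(1+n)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "position (Mb)", y = "position (Mb)",
      title = sprintf("Contact matrix (%s, %d-kb bins)",
                      attr(object, "condition"), bin %/% 1000))
}

#' Plot a clustering test
#'
#' Null histograms per method and statistic with the observed value as
#' a vertical line.
#'
#' @param object A `clustering_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clustering_result <- function(object, ...) {
  nulls <- tidyr::pivot_longer(object$nulls, c(total, clustering),
                               names_to = "statistic")
  obs <- tidyr::pivot_longer(object$observed, c(total, clustering),
                             names_to = "statistic")
  ggplot2::ggplot(nulls, ggplot2::aes(x = value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = value), colour = "red") +
    ggplot2::facet_grid(method ~ statistic, scales = "free") +
    ggplot2::labs(x = "statistic under the null", y = "draws")
}

#' Plot binned expression against its shuffle envelope
#'
#' @param object A [binned_expression_null()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binned_expression <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = (start + end) / 2e3)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = null_lo, ymax = null_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = observed), colour = "steelblue") +
    ggplot2::labs(x = "position (kb)", y = "mean log2 ratio per bin")
}

#' Plot a corrected interaction profile with peaks
#'
#' @param profile A tibble from [correct_binned_interactions()].
#' @param peaks Optional result of [find_peaks()] on the same profile.
#' @return A ggplot.
#' @export
plot_corrected_profile <- function(profile, peaks = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = (start + end) / 2e3, y = corrected)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (kb)",
                  y = "interactions per fragment / copy number")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = peaks, inherit.aes = FALSE, alpha = 0.2, fill = "red",
      ggplot2::aes(xmin = start / 1e3, xmax = end / 1e3,
                   ymin = -Inf, ymax = Inf))
  }
  p
}
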