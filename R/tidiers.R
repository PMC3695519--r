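#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an interaction network
#'
#' @param x A `gcc_network`.
#' @param ... Unused.
#' @return The pair tibble (`frag_a`, `frag_b`, `count`).
#' @export
tidy.gcc_network <- function(x, ...) x$pairs

#' One-row network summary
#'
#' @param x A `gcc_network`.
#' @param ... Unused.
#' @return A tibble with condition, interaction and read-pair totals,
#'   cutoff state and the input/dropped/control tallies.
#' @export
glance.gcc_network <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    n_interactions = nrow(x$pairs),
    n_read_pairs = sum(x$pairs$count),
    cutoff = x$cutoff,
    cutoff_applied = x$cutoff_applied,
    n_input = x$tally$n_input,
    n_dropped = x$tally$n_dropped,
    n_control = x$tally$n_control)
}

#' Tidy a clustering test
#'
#' @param x A `clustering_result`.
#' @param ... Unused.
#' @return The p-value table: one row per method x statistic with
#'   observed value, null mean/sd and both tail p-values.
#' @export
tidy.clustering_result <- function(x, ...) x$p

#' One-row clustering-test summary
#'
#' @param x A `clustering_result`.
#' @param ... Unused.
#' @return A wide tibble with the observed statistics and the
#'   upper-tail p-values per method.
#' @export
glance.clustering_result <- function(x, ...) {
  wide <- x$p |>
    dplyr::transmute(name = paste0("p_high_", statistic, "_", method),
                     value = p_high) |>
    tidyr::pivot_wider()
  dplyr::bind_cols(
    tibble::tibble(total = x$observed$total,
                   clustering = x$observed$clustering,
                   n_random = x$n_random,
                   estimator = x$estimator, mode = x$mode),
    wide)
}

#' Weighted summary of a loop-length distribution
#'
#' @param x A `loop_lengths` tibble.
#' @param ... Unused.
#' @return Count-weighted mean, median and quartiles of the circular
#'   midpoint distances.
#' @export
glance.loop_lengths <- function(x, ...) {
  q <- weighted_quantile(x$distance, x$count, c(0.25, 0.5, 0.75))
  tibble::tibble(
    n_interactions = nrow(x),
    n_read_pairs = sum(x$count),
    mean = sum(x$distance * x$count) / sum(x$count),
    q25 = q[1], median = q[2], q75 = q[3])
}
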