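new_gcc_network <- function(pairs, condition, map, cutoff = NA_real_,
                            cutoff_applied = FALSE, tally = NULL) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("frag_a", "frag_b", "count") %in% names(pairs)))
  abort_if(any(pairs$frag_a > pairs$frag_b),
           "pair keys must be canonical (frag_a <= frag_b)")
  abort_if(any(pairs$count < 1), "pair counts must be >= 1")
  structure(
    list(pairs = pairs, condition = condition,
         genome_length = map$length, n_fragments = nrow(map$fragments),
         cutoff = cutoff, cutoff_applied = cutoff_applied,
         tally = tally %||% list(n_input = sum(pairs$count),
                                 n_dropped = 0L, n_control = 0L),
         control = NULL),
    class = "gcc_network"
  )
}

#' @export
print.gcc_network <- function(x, ...) {
  cat(sprintf(
    "<gcc_network> condition '%s': %d interactions, %d read pairs%s\n",
    x$condition, nrow(x$pairs), sum(x$pairs$count),
    if (x$cutoff_applied) sprintf(" (cutoff %g applied)", x$cutoff) else ""))
  if (!is.null(x$control)) {
    cat(sprintf("  + ligation-control network: %d interactions, %d read pairs\n",
                nrow(x$control$pairs), sum(x$control$pairs$count)))
  }
  invisible(x)
}

#' Assemble a fragment-pair interaction network from mapped read pairs
#'
#' Read pairs with both ends uniquely mapped are assigned to restriction
#' fragments; each retained pair increments the count of its unordered
#' fragment pair (canonical key `frag_a <= frag_b`; both ends in one
#' fragment give a self-interaction). Pairs flagged as ligation controls
#' are routed to a separate control network (available as `$control`),
#' from which the significance cutoff is later derived. Pairs with any
#' non-uniquely mapped end are discarded, so that
#' `sum(counts) + n_dropped + n_control == n_input` (the tally is kept on
#' the returned object).
#'
#' @param pairs A data frame of mapped read pairs with columns `pos1`,
#'   `pos2` (0-based bp), logical `unique1`, `unique2`, and optionally
#'   `is_control` (logical), `condition`, `sample`, `strand1`, `strand2`.
#' @param map A [genome_map].
#' @param condition Condition label for the network (e.g. `"EXP"`,
#'   `"SHX"`). If the input has a `condition` column, only matching rows
#'   are used; an absent label is an error.
#' @return A `gcc_network`; duplicate read pairs are counted, not
#'   deduplicated.
#' @export
assemble_network <- function(pairs, map, condition = NULL) {
  stopifnot(inherits(map, "genome_map"))
  pairs <- tibble::as_tibble(pairs)
  abort_if(!all(c("pos1", "pos2", "unique1", "unique2") %in% names(pairs)),
           "pairs must have columns pos1, pos2, unique1, unique2")
  if (!is.null(condition) && "condition" %in% names(pairs)) {
    sub <- pairs[pairs$condition == condition, , drop = FALSE]
    abort_if(nrow(sub) == 0 && nrow(pairs) > 0,
             sprintf("unknown condition label '%s'", condition))
    pairs <- sub
  }
  condition <- condition %||% "all"
  L <- map$length
  abort_if(any(pairs$pos1 < 0 | pairs$pos1 >= L |
                 pairs$pos2 < 0 | pairs$pos2 >= L),
           "read position outside genome")
  if (!"is_control" %in% names(pairs)) pairs$is_control <- FALSE
  n_input <- nrow(pairs)
  ok <- pairs$unique1 & pairs$unique2
  n_dropped <- sum(!ok)
  kept <- pairs[ok, , drop = FALSE]

  tally_pairs <- function(df) {
    if (nrow(df) == 0) {
      return(tibble::tibble(frag_a = integer(), frag_b = integer(),
                            count = integer()))
    }
    fa <- locate_position(df$pos1, map)
    fb <- locate_position(df$pos2, map)
    dplyr::count(
      tibble::tibble(frag_a = pmin(fa, fb), frag_b = pmax(fa, fb)),
      frag_a, frag_b, name = "count") |>
      dplyr::arrange(frag_a, frag_b)
  }

  genomic <- tally_pairs(kept[!kept$is_control, , drop = FALSE])
  control <- tally_pairs(kept[kept$is_control, , drop = FALSE])
  n_control <- sum(control$count)

  net <- new_gcc_network(
    genomic, condition, map,
    tally = list(n_input = n_input, n_dropped = n_dropped,
                 n_control = n_control))
  net$control <- new_gcc_network(
    control, paste0(condition, "_control"), map,
    tally = list(n_input = n_control, n_dropped = 0L, n_control = 0L))
  net
}

#' Significance cutoff from the ligation-control network
#'
#' Exogenous DNA spiked before ligation measures the background rate of
#' random inter-molecular ligation; genomic interactions are deemed
#' significant only when their read count exceeds what the controls
#' reach. The default rule is the maximum count observed among control
#' interactions (conservative: controls empirically bound the random
#' background); a quantile of the control counts is available as an
#' alternative.
#'
#' @param control_network A `gcc_network` built from control-flagged
#'   pairs (e.g. `net$control`).
#' @param method `"max"` (default) or `"quantile"`.
#' @param q Quantile used when `method = "quantile"`.
#' @param per_million Express the cutoff per million read pairs of the
#'   control library instead of as a raw count; pass the genomic
#'   library size to [apply_cutoff()] to use it (default: raw counts,
#'   the global rule).
#' @return The cutoff; interactions are retained when
#'   `count > cutoff` (after any per-million scaling). An empty control
#'   network yields 0 with a warning.
#' @export
derive_cutoff <- function(control_network, method = c("max", "quantile"),
                          q = 0.95, per_million = FALSE) {
  method <- match.arg(method)
  counts <- control_network$pairs$count
  if (length(counts) == 0) {
    rlang::warn("no ligation-control interactions: cutoff set to 0")
    return(0)
  }
  co <- switch(method,
               max = max(counts),
               quantile = unname(stats::quantile(counts, q, type = 1)))
  if (per_million) co * 1e6 / sum(counts) else co
}

#' Apply a significance cutoff to a network
#'
#' Retains interactions with `count > cutoff` (strictly greater). An
#' all-filtered network is returned empty, not an error.
#'
#' @param net A `gcc_network`.
#' @param cutoff Count threshold, typically from [derive_cutoff()].
#' @param library_size When the cutoff is on the per-million scale, the
#'   genomic library size it should be rescaled by (defaults to the
#'   network's own read-pair total).
#' @param per_million Interpret `cutoff` as per million read pairs.
#' @return The filtered network with `cutoff_applied = TRUE`.
#' @export
apply_cutoff <- function(net, cutoff, per_million = FALSE,
                         library_size = NULL) {
  stopifnot(inherits(net, "gcc_network"))
  if (per_million) {
    library_size <- library_size %||% sum(net$pairs$count)
    cutoff <- cutoff * library_size / 1e6
  }
  net$pairs <- dplyr::filter(net$pairs, count > cutoff)
  net$cutoff <- cutoff
  net$cutoff_applied <- TRUE
  net
}

#' Classify interactions by genomic separation
#'
#' Interactions are `self` (both ends in one fragment), `adjacent`
#' (circularly consecutive fragments), `short` (midpoint separation below
#' the threshold) or `long` (at or above it, up to half the genome). The
#' 800-bp default separates ligation neighbours from genuine long-range
#' contacts.
#'
#' @param net A cutoff-applied `gcc_network`.
#' @param map The [genome_map] the network was built on.
#' @param threshold Short/long boundary in bp (default 800).
#' @return The network's pair tibble with `distance` (circular midpoint
#'   distance in bp) and `class` columns.
#' @export
classify_interactions <- function(net, map, threshold = 800) {
  stopifnot(inherits(net, "gcc_network"), inherits(map, "genome_map"))
  abort_if(threshold >= map$length / 2,
           "threshold must be below half the genome length")
  p <- net$pairs
  n <- nrow(map$fragments)
  abort_if(nrow(p) > 0 && max(p$frag_b) > n, "unknown fragment id")
  mids <- map$fragments$midpoint
  d <- circular_distance(mids[p$frag_a], mids[p$frag_b], map$length)
  cls <- dplyr::case_when(
    p$frag_a == p$frag_b ~ "self",
    frag_adjacent(p$frag_a, p$frag_b, n) ~ "adjacent",
    d < threshold ~ "short",
    TRUE ~ "long"
  )
  dplyr::mutate(p, distance = d,
                class = factor(cls, levels = c("self", "adjacent",
                                               "short", "long")))
}

#' Compare two condition networks
#'
#' Set algebra on the interaction keys of two cutoff-applied networks
#' from the same genome: interactions specific to either condition and
#' shared interactions with both counts.
#'
#' @param net_a,net_b Cutoff-applied `gcc_network`s.
#' @return A tibble (`frag_a`, `frag_b`, `count_a`, `count_b`, `status`)
#'   with `status` in `specific_a` / `specific_b` / `shared`; the three
#'   key sets are disjoint and their union is the union of the two
#'   networks' keys. Condition labels are kept as attributes.
#' @export
compare_conditions <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "gcc_network"), inherits(net_b, "gcc_network"))
  abort_if(net_a$genome_length != net_b$genome_length ||
             net_a$n_fragments != net_b$n_fragments,
           "networks were built on different genomes")
  abort_if(!net_a$cutoff_applied || !net_b$cutoff_applied,
           "apply the significance cutoff to both networks first")
  out <- dplyr::full_join(
    dplyr::rename(net_a$pairs, count_a = count),
    dplyr::rename(net_b$pairs, count_b = count),
    by = c("frag_a", "frag_b")) |>
    dplyr::mutate(status = dplyr::case_when(
      is.na(count_b) ~ "specific_a",
      is.na(count_a) ~ "specific_b",
      TRUE ~ "shared")) |>
    dplyr::arrange(frag_a, frag_b)
  attr(out, "condition_a") <- net_a$condition
  attr(out, "condition_b") <- net_b$condition
  class(out) <- c("gcc_comparison", class(out))
  out
}

#' Cohen's kappa for replicate concordance
#'
#' Chance-corrected agreement between two binary detection vectors
#' (interaction present/absent) over a stated universe of fragment
#' pairs: `kappa = (p_o - p_e) / (1 - p_e)`, the standard two-rater
#' binary form. The universe matters — including all possible pairs
#' inflates agreement through absent–absent cells — so callers state it
#' explicitly (see [network_presence()], which uses the union of detected
#' pairs by default).
#'
#' @param presence_a,presence_b Equal-length logical (or 0/1) vectors.
#' @return Kappa in `[-1, 1]`; `NA` with a warning when both raters are
#'   constant and identical (expected agreement 1, kappa undefined).
#' @examples
#' replicate_kappa(rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 5, 10, 15)),
#'                 rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 10, 15)))
#' @export
replicate_kappa <- function(presence_a, presence_b) {
  a <- as.logical(presence_a)
  b <- as.logical(presence_b)
  abort_if(length(a) != length(b) || length(a) == 0,
           "presence vectors must be non-empty and of equal length")
  po <- mean(a == b)
  pa <- mean(a)
  pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe == 1) {
    rlang::warn("expected agreement is 1 (both raters constant): kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Presence vectors for two networks over a pair universe
#'
#' @param net_a,net_b `gcc_network`s on the same genome.
#' @param universe `"union"` (all pairs detected in either network, the
#'   recommended kappa universe) or `"all"` (every possible unordered
#'   fragment pair, including self pairs).
#' @return A list with logical vectors `a` and `b` and the `pairs`
#'   tibble of the universe.
#' @export
network_presence <- function(net_a, net_b, universe = c("union", "all")) {
  universe <- match.arg(universe)
  key <- function(p) paste(p$frag_a, p$frag_b)
  if (universe == "union") {
    u <- dplyr::distinct(
      dplyr::bind_rows(net_a$pairs[c("frag_a", "frag_b")],
                       net_b$pairs[c("frag_a", "frag_b")])) |>
      dplyr::arrange(frag_a, frag_b)
  } else {
    n <- net_a$n_fragments
    u <- tibble::tibble(
      frag_a = rep.int(seq_len(n), n - seq_len(n) + 1L),
      frag_b = sequence(n - seq_len(n) + 1L, from = seq_len(n)))
  }
  list(a = key(u) %in% key(net_a$pairs),
       b = key(u) %in% key(net_b$pairs),
       pairs = u)
}
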