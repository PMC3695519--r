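#' Genome-wide contact matrix
#'
#' Accumulates interaction counts into an `n x n` symmetric matrix of
#' genomic bins (fragments assigned by midpoint); the diagonal holds
#' intra-bin interactions, including fragment self-interactions. The sum
#' of the upper triangle plus the diagonal equals the network's total
#' count.
#'
#' @param net A cutoff-applied `gcc_network`.
#' @param map The [genome_map].
#' @param bin Bin size in bp (50-kb bins show the Ori and Ter domains;
#'   20-kb bins resolve candidate domain boundaries).
#' @param cn Optional copy-number profile (from
#'   [copy_number_profile()]); when given, entry `(i, j)` is divided by
#'   `cn_i * cn_j`, the product-form pairwise dosage correction.
#' @return A symmetric matrix of class `contact_matrix` with attributes
#'   `bin`, `genome_length` and `condition`.
#' @export
contact_matrix <- function(net, map, bin = 50000, cn = NULL) {
  stopifnot(inherits(net, "gcc_network"), inherits(map, "genome_map"))
  abort_if(bin > map$length, "bin larger than the genome")
  n_bins <- ceiling(map$length / bin)
  frag_bin <- floor(map$fragments$midpoint / bin) + 1L
  M <- matrix(0, n_bins, n_bins)
  p <- net$pairs
  if (nrow(p) > 0) {
    ba <- frag_bin[p$frag_a]
    bb <- frag_bin[p$frag_b]
    lin <- c((bb - 1) * n_bins + ba,
             ((ba - 1) * n_bins + bb)[ba != bb])
    s <- rowsum(c(p$count, p$count[ba != bb]), lin)
    M[as.integer(rownames(s))] <- s[, 1]
  }
  if (!is.null(cn)) {
    cnb <- cn_per_bin(cn, bin, map$length)
    M <- M / outer(cnb, cnb)
  }
  structure(M, bin = bin, genome_length = map$length,
            condition = net$condition, class = c("contact_matrix", "matrix"))
}

# add w to acc over index ranges [lo, hi] (lo > hi means empty)
range_accumulate <- function(lo, hi, w, n) {
  ok <- lo <= hi
  acc <- numeric(n + 1)
  if (any(ok)) {
    s <- rowsum(w[ok], lo[ok])
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
    e <- rowsum(w[ok], hi[ok] + 1L)
    acc[as.integer(rownames(e))] <- acc[as.integer(rownames(e))] - e[, 1]
  }
  cumsum(acc)[seq_len(n)]
}

#' Crossing-fragment profile
#'
#' For every interaction, the fragments whose midpoints lie strictly
#' inside the shorter arc between the two endpoint midpoints are
#' "crossed" by it; each fragment's crossing value is the count-weighted
#' (or, with `weighted = FALSE`, per-interaction) sum of interactions
#' crossing it. A sharp macrodomain boundary would appear as a dip in
#' this profile. The shorter arc is the maximum-likelihood loop path on
#' a circle; when the two arcs are exactly equal (antipodal endpoints)
#' both arcs are counted at half weight.
#'
#' @param net A cutoff-applied `gcc_network`.
#' @param map The [genome_map].
#' @param ori Origin position in bp, used to order the output.
#' @param weighted Weight by read count (default) or count each
#'   interaction once.
#' @return A tibble (`id`, `midpoint`, `dist_ori`, `crossing`) ordered
#'   by circular distance from the origin.
#' @export
crossing_profile <- function(net, map, ori = 0, weighted = TRUE) {
  stopifnot(inherits(net, "gcc_network"), inherits(map, "genome_map"))
  fr <- map$fragments
  L <- map$length
  n <- nrow(fr)
  ord <- order(fr$midpoint)
  mids <- fr$midpoint[ord]          # sorted midpoints
  pos_of <- integer(n)              # fragment id -> rank in sorted order
  pos_of[fr$id[ord]] <- seq_len(n)

  p <- net$pairs[net$pairs$frag_a != net$pairs$frag_b, , drop = FALSE]
  cross_sorted <- numeric(n)
  if (nrow(p) > 0) {
    w <- if (weighted) p$count else rep(1, nrow(p))
    ma <- pmin(fr$midpoint[p$frag_a], fr$midpoint[p$frag_b])
    mb <- pmax(fr$midpoint[p$frag_a], fr$midpoint[p$frag_b])
    d_in <- mb - ma                  # inner (non-wrapping) arc length
    d_out <- L - d_in
    # strict interior of the inner arc in sorted-midpoint rank space
    lo_in <- findInterval(ma, mids) + 1L
    hi_in <- findInterval(mb - 1, mids)
    # strict interior of the outer (wrapping) arc: two linear pieces
    lo_out <- findInterval(mb, mids) + 1L
    hi_out <- findInterval(ma - 1, mids)

    tie <- d_in == d_out
    wt <- ifelse(tie, w / 2, w)       # antipodal ties: both arcs, half weight
    use_in <- d_in < d_out | tie
    use_out <- d_out < d_in | tie
    cross_sorted <-
      range_accumulate(lo_in[use_in], hi_in[use_in], wt[use_in], n) +
      range_accumulate(lo_out[use_out], rep.int(n, sum(use_out)),
                       wt[use_out], n) +
      range_accumulate(rep.int(1L, sum(use_out)), hi_out[use_out],
                       wt[use_out], n)
  }
  crossing <- numeric(n)
  crossing[fr$id[ord]] <- cross_sorted
  tibble::tibble(id = fr$id, midpoint = fr$midpoint,
                 dist_ori = circular_distance(fr$midpoint, mod_pos(ori, L), L),
                 crossing = crossing) |>
    dplyr::arrange(dist_ori)
}

#' Loop-length distribution
#'
#' Circular midpoint distances of all interactions, carrying their read
#' counts as weights. Self-interactions contribute distance 0.
#'
#' @param net A cutoff-applied `gcc_network`.
#' @param map The [genome_map].
#' @return A tibble of class `loop_lengths` (`frag_a`, `frag_b`,
#'   `count`, `distance`); summarize with [generics::glance()]
#'   (count-weighted mean, median and quartiles).
#' @export
loop_lengths <- function(net, map) {
  stopifnot(inherits(net, "gcc_network"), inherits(map, "genome_map"))
  abort_if(nrow(net$pairs) == 0, "empty network")
  mids <- map$fragments$midpoint
  out <- dplyr::mutate(
    net$pairs,
    distance = circular_distance(mids[frag_a], mids[frag_b], map$length))
  class(out) <- c("loop_lengths", class(out))
  out
}

#' Distinct partners per fragment
#'
#' Number of distinct fragments each fragment interacts with; a fragment
#' self-interaction makes the fragment its own (single) partner, and
#' read counts do not matter. Fragments without interactions report 0.
#'
#' @param net A `gcc_network`.
#' @return A tibble (`fragment`, `partners`) over all fragments.
#' @export
partner_counts <- function(net) {
  stopifnot(inherits(net, "gcc_network"))
  p <- net$pairs
  edges <- dplyr::bind_rows(
    tibble::tibble(fragment = p$frag_a, partner = p$frag_b),
    tibble::tibble(fragment = p$frag_b, partner = p$frag_a)[
      p$frag_a != p$frag_b, ])
  counts <- edges |>
    dplyr::distinct() |>
    dplyr::count(fragment, name = "partners")
  tibble::tibble(fragment = seq_len(net$n_fragments)) |>
    dplyr::left_join(counts, by = "fragment") |>
    dplyr::mutate(partners = dplyr::coalesce(partners, 0L))
}

#' Peak calling on a binned profile
#'
#' Flags bins exceeding `median + 3 * MAD` of the covered bins as peaks
#' and merges adjacent peak bins (including across the circular wrap)
#' into intervals. A robust threshold is used because the corrected
#' profiles are heavy-tailed near the origin.
#'
#' @param profile A tibble with `start`, `end` and a value column, e.g.
#'   from [correct_binned_interactions()].
#' @param value_col Name of the value column (default `"corrected"`).
#' @return A tibble (`peak`, `start`, `end`, `n_bins`, `max_value`); for
#'   an interval wrapping the origin of coordinates `start > end`.
#' @export
find_peaks <- function(profile, value_col = "corrected") {
  v <- profile[[value_col]]
  covered <- !is.na(v) & is.finite(v)
  abort_if(sum(covered) < 10, "fewer than 10 covered bins: refusing to call peaks")
  thr <- stats::median(v[covered]) + 3 * stats::mad(v[covered])
  is_peak <- covered & v > thr
  if (!any(is_peak)) {
    return(tibble::tibble(peak = integer(), start = numeric(),
                          end = numeric(), n_bins = integer(),
                          max_value = numeric()))
  }
  r <- rle(is_peak)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- tibble::tibble(from = run_start[r$values], to = run_end[r$values])
  wrap <- nrow(runs) > 1 && is_peak[1] && is_peak[length(is_peak)]
  if (wrap) {
    # join the last run onto the first across the origin
    runs$from[1] <- runs$from[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  out <- purrr::pmap_dfr(runs, function(from, to) {
    idx <- if (from <= to) from:to else c(from:nrow(profile), 1:to)
    tibble::tibble(start = profile$start[from], end = profile$end[to],
                   n_bins = length(idx), max_value = max(v[idx]))
  })
  dplyr::mutate(out, peak = dplyr::row_number(), .before = 1)
}
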