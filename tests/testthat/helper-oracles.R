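# Independent brute-force oracles used to validate the vectorized
# implementations on tiny problems. These deliberately share no code
# with the package internals.

# is circular position pos inside the half-open circular interval
# [s, s + len) on a circle of length L?
in_circ_interval <- function(pos, s, len, L) {
  ((pos - s) %% L) < len
}

# region indices whose interval overlaps fragment fid of `map`
oracle_regions_of_fragment <- function(fid, map, regions) {
  fr <- map$fragments[map$fragments$id == fid, ]
  L <- map$length
  frag_pos <- (fr$start + seq_len(fr$length) - 1) %% L
  which(vapply(seq_len(nrow(regions)), function(j) {
    any(in_circ_interval(frag_pos, regions$start[j] %% L,
                         regions$length[j], L))
  }, logical(1)))
}

# exhaustive total / clustering tally over a network's pairs
oracle_region_stats <- function(pairs, map, regions) {
  total <- 0
  clustering <- 0
  for (k in seq_len(nrow(pairs))) {
    ra <- oracle_regions_of_fragment(pairs$frag_a[k], map, regions)
    rb <- oracle_regions_of_fragment(pairs$frag_b[k], map, regions)
    if (length(ra) + length(rb) > 0) total <- total + pairs$count[k]
    hit <- FALSE
    for (i in ra) for (j in rb) if (i != j) hit <- TRUE
    if (hit) clustering <- clustering + pairs$count[k]
  }
  c(total = total, clustering = clustering)
}

# fragments whose midpoints lie strictly inside the shorter arc between
# two midpoints (half weight to both arcs on an exact tie)
oracle_crossing <- function(net, map) {
  fr <- map$fragments
  L <- map$length
  out <- stats::setNames(numeric(nrow(fr)), fr$id)
  p <- net$pairs[net$pairs$frag_a != net$pairs$frag_b, , drop = FALSE]
  for (k in seq_len(nrow(p))) {
    ma <- fr$midpoint[fr$id == p$frag_a[k]]
    mb <- fr$midpoint[fr$id == p$frag_b[k]]
    fwd <- (mb - ma) %% L
    inside_fwd <- ((fr$midpoint - ma) %% L) > 0 &
      ((fr$midpoint - ma) %% L) < fwd
    inside_bwd <- ((fr$midpoint - mb) %% L) > 0 &
      ((fr$midpoint - mb) %% L) < (L - fwd)
    w <- p$count[k]
    if (fwd < L - fwd) {
      out[inside_fwd] <- out[inside_fwd] + w
    } else if (fwd > L - fwd) {
      out[inside_bwd] <- out[inside_bwd] + w
    } else {
      out[inside_fwd] <- out[inside_fwd] + w / 2
      out[inside_bwd] <- out[inside_bwd] + w / 2
    }
  }
  out
}

# build a gcc_network directly from a pair tibble for unit tests
make_test_network <- function(pairs, map, condition = "EXP",
                              cutoff_applied = TRUE) {
  pairs <- tibble::tibble(frag_a = pmin(pairs$frag_a, pairs$frag_b),
                          frag_b = pmax(pairs$frag_a, pairs$frag_b),
                          count = pairs$count)
  net <- assemble_network(
    tibble::tibble(pos1 = 0, pos2 = 0, unique1 = TRUE, unique2 = TRUE),
    map)
  net$pairs <- dplyr::arrange(pairs, frag_a, frag_b)
  net$condition <- condition
  net$cutoff <- 0
  net$cutoff_applied <- cutoff_applied
  net$tally <- list(n_input = sum(pairs$count), n_dropped = 0L,
                    n_control = 0L)
  net
}

# regular map: n fragments of equal width on a circle
regular_map <- function(n, width = 100) {
  genome_map(n * width, seq(0, (n - 1) * width, by = width))
}

# random genome string for digestion properties
random_genome <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
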