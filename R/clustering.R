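#' Build a region set
#'
#' Regions are half-open circular intervals `[start, end)` with
#' `end = start + length` (possibly exceeding the genome length for a
#' wrapping interval). Binding-site region sets are typically built from
#' peak positions with [regions_from_points()].
#'
#' @param start Start coordinates in bp, `[0, L)`.
#' @param length Interval lengths in bp (`>= 1`, `< L`).
#' @param L Genome length.
#' @param label Optional set label (e.g. `"matS"`, `"SeqA"`).
#' @return A tibble (`region`, `start`, `end`, `length`) with attributes
#'   `genome_length` and `label`.
#' @export
region_set <- function(start, length, L, label = NULL) {
  start <- mod_pos(as.numeric(start), L)
  length <- as.numeric(length)
  if (base::length(length) == 1) length <- rep(length, base::length(start))
  abort_if(any(length < 1) || any(length >= L),
           "region lengths must be in [1, L)")
  out <- tibble::tibble(region = seq_along(start), start = start,
                        end = start + length, length = length)
  attr(out, "genome_length") <- L
  attr(out, "label") <- label
  out
}

#' Region set from point positions
#'
#' Expands peak binding positions by a flank on either side, the way
#' site lists (matS, SeqA, SlmA, NAP peaks) are turned into analysis
#' regions: each point becomes `[p - flank, p + flank]` inclusive, i.e.
#' a `2 * flank + 1` bp interval.
#'
#' @param points Peak positions in bp.
#' @param flank Bases either side of the point (typically 50, 100, 250
#'   or 500).
#' @param L Genome length.
#' @param label Optional set label.
#' @return A [region_set()] tibble.
#' @export
regions_from_points <- function(points, flank, L, label = NULL) {
  region_set(points - flank, 2 * flank + 1, L, label = label)
}

# per-fragment region overlap summary: how many regions each fragment
# overlaps, and the min/max region index among them
region_fragment_index <- function(map, regions) {
  n <- nrow(map$fragments)
  L <- map$length
  nreg <- integer(n)
  minreg <- rep.int(NA_integer_, n)
  maxreg <- rep.int(NA_integer_, n)
  for (j in seq_len(nrow(regions))) {
    s <- mod_pos(regions$start[j], L)
    last <- mod_pos(regions$end[j] - 1, L)
    a <- locate_position(s, map)
    b <- locate_position(last, map)
    ids <- if (regions$length[j] >= L) seq_len(n)
           else if (a <= b) a:b else c(a:n, 1:b)
    # a sub-fragment region can wrap onto the same fragment: a > b with
    # identical id handled by the c() above producing duplicates
    ids <- unique(ids)
    nreg[ids] <- nreg[ids] + 1L
    minreg[ids] <- pmin(minreg[ids], j, na.rm = TRUE)
    maxreg[ids] <- pmax(maxreg[ids], j, na.rm = TRUE)
  }
  list(n = nreg, min = minreg, max = maxreg)
}

# vectorized core shared by region_stats and the permutation loop
region_stats_core <- function(fa, fb, w, idx) {
  na_ <- idx$n[fa]
  nb_ <- idx$n[fb]
  touch <- na_ > 0L | nb_ > 0L
  both <- na_ > 0L & nb_ > 0L
  # clustering requires two DIFFERENT regions among the endpoint overlaps
  same_single <- both & idx$min[fa] == idx$max[fa] &
    idx$min[fb] == idx$max[fb] & idx$min[fa] == idx$min[fb]
  clust <- both & !same_single
  c(total = sum(w[touch]), clustering = sum(w[clust]))
}

# drop excluded interaction classes and return bare vectors
filter_network_classes <- function(net, map, exclude, threshold) {
  p <- classify_interactions(net, map, threshold = threshold)
  if (base::length(exclude) > 0) {
    p <- p[!(as.character(p$class) %in% exclude), , drop = FALSE]
  }
  list(fa = p$frag_a, fb = p$frag_b, count = p$count)
}

#' Interaction and clustering frequencies of a region set
#'
#' The total interaction frequency is the summed read count of network
#' interactions touching at least one region (an interaction touches a
#' region when an endpoint fragment overlaps the region interval under
#' circular arithmetic; each interaction is counted once however many
#' regions it touches). The clustering frequency is the summed count of
#' interactions whose two endpoints overlap two *different* regions of
#' the set — the quantity that asks whether the regions colocalize.
#' Self- and short-distance interactions are excluded by default, since
#' they are trivially enriched around any region.
#'
#' @param net A cutoff-applied `gcc_network`.
#' @param regions A [region_set()] tibble (`n >= 1`; clustering needs
#'   `n >= 2` to be informative).
#' @param map The [genome_map].
#' @param exclude Interaction classes removed before tallying (default
#'   `c("self", "short")`).
#' @param threshold Short/long boundary in bp.
#' @param mode `"counts"` (summed read counts, default) or `"binary"`
#'   (distinct interactions).
#' @return A one-row tibble (`total`, `clustering`);
#'   `clustering <= total` always.
#' @export
region_stats <- function(net, regions, map, exclude = c("self", "short"),
                         threshold = 800, mode = c("counts", "binary")) {
  mode <- match.arg(mode)
  abort_if(nrow(regions) == 0, "empty region set")
  e <- filter_network_classes(net, map, exclude, threshold)
  w <- if (mode == "counts") e$count else rep(1L, base::length(e$count))
  idx <- region_fragment_index(map, regions)
  s <- region_stats_core(e$fa, e$fb, w, idx)
  tibble::tibble(total = s[["total"]], clustering = s[["clustering"]])
}

#' Random-spacing (RS) randomization of a region set
#'
#' Every region receives an independent uniform start position and keeps
#' its length; randomized regions may not overlap one another (binding
#' sites are disjoint in the real sets), enforced by whole-set rejection
#' resampling. Set `allow_overlap = TRUE` to lift the constraint.
#'
#' @param regions A [region_set()] tibble.
#' @param L Genome length.
#' @param allow_overlap Permit overlapping placements (default FALSE).
#' @param max_attempts Rejection-sampling budget (default 10000).
#' @return A randomized region set (same lengths, same count).
#' @export
randomize_rs <- function(regions, L, allow_overlap = FALSE,
                         max_attempts = 10000) {
  lens <- regions$length
  abort_if(sum(lens) >= L, "regions do not fit on the genome")
  m <- base::length(lens)
  for (attempt in seq_len(max_attempts)) {
    starts <- sample.int(L, m, replace = TRUE) - 1
    if (allow_overlap || m == 1 || !circular_overlaps(starts, lens, L)) {
      return(region_set(starts, lens, L, label = attr(regions, "label")))
    }
  }
  rlang::abort("could not place regions without overlap")
}

# TRUE if any two circular intervals (starts, lens) overlap
circular_overlaps <- function(starts, lens, L) {
  ord <- order(starts)
  s <- starts[ord]
  l <- lens[ord]
  gap <- mod_pos(c(s[-1], s[1]) - s, L)
  any(gap < l) || anyDuplicated(s) > 0
}

#' Conserved-linear-spacing (CLS) randomization of a region set
#'
#' Rotates the whole region configuration by one uniform offset: every
#' pairwise circular gap between regions is preserved exactly, so the
#' null keeps the linear arrangement of the set and randomizes only its
#' placement on the circle.
#'
#' @param regions A [region_set()] tibble.
#' @param L Genome length.
#' @param offset Optional fixed rotation in bp (drawn uniformly from
#'   `[0, L)` when `NULL`).
#' @return The rotated region set.
#' @export
randomize_cls <- function(regions, L, offset = NULL) {
  u <- offset %||% (sample.int(L, 1) - 1)
  region_set(mod_pos(regions$start + u, L), regions$length, L,
             label = attr(regions, "label"))
}

#' Empirical permutation p-value
#'
#' Plain frequency convention: `p_high = #(null >= observed) / N` and
#' `p_low = #(null <= observed) / N`. The `"add_one"` estimator
#' `(r + 1) / (N + 1)` counts the observed value as one of the
#' permutations and never returns 0; it is the right choice for
#' calibration studies.
#'
#' @param observed Observed statistic.
#' @param null Vector of null statistics (non-empty).
#' @param tail `"high"` or `"low"`.
#' @param estimator `"plain"` (default) or `"add_one"`.
#' @return The p-value in `[0, 1]`.
#' @export
empirical_p <- function(observed, null, tail = c("high", "low"),
                        estimator = c("plain", "add_one")) {
  tail <- match.arg(tail)
  estimator <- match.arg(estimator)
  abort_if(base::length(null) == 0, "empty null distribution")
  r <- if (tail == "high") sum(null >= observed) else sum(null <= observed)
  n <- base::length(null)
  if (estimator == "plain") r / n else (r + 1) / (n + 1)
}

#' Circular permutation test for spatial clustering of a region set
#'
#' The central statistic of the analysis: are a set of genomic regions
#' (binding sites, regulated genes) in a different interaction
#' environment — and in particular, do they interact with *each other* —
#' more or less than expected from their number, lengths and (for CLS)
#' linear arrangement? Observed total-interaction and clustering
#' frequencies are compared with `n_random` randomized region sets under
#' the RS (independent uniform placement) and CLS (whole-set rotation)
#' nulls, giving empirical upper- and lower-tail p-values for each
#' statistic and method.
#'
#' Under a fixed `seed` the draws are reproducible: one RNG stream
#' seeded once, all draws for the first method taken first, then all
#' draws for the second.
#'
#' @param net A cutoff-applied `gcc_network`.
#' @param regions A [region_set()] tibble with `n >= 2` regions.
#' @param map The [genome_map].
#' @param n_random Number of randomized sets per method (default 1000).
#' @param methods Any of `"RS"`, `"CLS"`.
#' @param exclude,threshold,mode Passed to [region_stats()].
#' @param estimator Passed to [empirical_p()].
#' @param seed Optional integer seed.
#' @param allow_overlap Passed to [randomize_rs()].
#' @return An object of class `clustering_result`: observed stats, the
#'   full null distributions (`$nulls`), and a p-value table (`$p`).
#'   Use [generics::tidy()] for the p-value table and
#'   [generics::glance()] for a one-row summary.
#' @export
clustering_test <- function(net, regions, map, n_random = 1000,
                            methods = c("RS", "CLS"),
                            exclude = c("self", "short"), threshold = 800,
                            mode = c("counts", "binary"),
                            estimator = c("plain", "add_one"),
                            seed = NULL, allow_overlap = FALSE) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  methods <- match.arg(methods, several.ok = TRUE)
  abort_if(nrow(regions) < 2, "clustering needs at least 2 regions")
  L <- map$length
  e <- filter_network_classes(net, map, exclude, threshold)
  w <- if (mode == "counts") e$count else rep(1L, base::length(e$count))
  stat_of <- function(rg) {
    region_stats_core(e$fa, e$fb, w, region_fragment_index(map, rg))
  }
  obs <- stat_of(regions)

  run <- function() {
    purrr::map_dfr(methods, function(meth) {
      draws <- matrix(0, n_random, 2,
                      dimnames = list(NULL, c("total", "clustering")))
      for (k in seq_len(n_random)) {
        rg <- if (meth == "RS") {
          randomize_rs(regions, L, allow_overlap = allow_overlap)
        } else {
          randomize_cls(regions, L)
        }
        draws[k, ] <- stat_of(rg)
      }
      tibble::tibble(method = meth, draw = seq_len(n_random),
                     total = draws[, 1], clustering = draws[, 2])
    })
  }
  nulls <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  p <- tidyr::expand_grid(method = methods,
                          statistic = c("total", "clustering")) |>
    purrr::pmap_dfr(function(method, statistic) {
      nv <- nulls[[statistic]][nulls$method == method]
      tibble::tibble(
        method = method, statistic = statistic,
        observed = obs[[statistic]],
        null_mean = mean(nv), null_sd = stats::sd(nv),
        p_high = empirical_p(obs[[statistic]], nv, "high", estimator),
        p_low = empirical_p(obs[[statistic]], nv, "low", estimator))
    })

  structure(
    list(observed = tibble::tibble(total = obs[["total"]],
                                   clustering = obs[["clustering"]]),
         nulls = nulls, p = p, n_random = n_random, methods = methods,
         mode = mode, estimator = estimator, seed = seed,
         label = attr(regions, "label")),
    class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else sprintf(" for '%s'", x$label)
  cat(sprintf("<clustering_result>%s: %d randomizations per method (%s)\n",
              lab, x$n_random, paste(x$methods, collapse = ", ")))
  print(x$p)
  invisible(x)
}
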