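#' Windowed read depth with GC content
#'
#' Counts read starts per tiling window of the circular genome (the last
#' window may be short) and records each window's GC fraction from the
#' sequence. In fast-growing bacteria with overlapping replication rounds
#' the depth profile carries the Ori-to-Ter copy-number gradient that
#' this module estimates.
#'
#' @param starts Read-start positions in bp (0-based).
#' @param seq Genome sequence (character / `DNAString`); `NULL` leaves GC
#'   as `NA` and disables GC normalization downstream.
#' @param window Window size in bp (default 1000).
#' @param L Genome length; required when `seq` is `NULL`.
#' @return A tibble (`window`, `start`, `end`, `width`, `count`, `gc`,
#'   `covered`) with attributes `genome_length` and `window`.
#' @export
depth_windows <- function(starts, seq = NULL, window = 1000, L = NULL) {
  if (!is.null(seq)) {
    seq <- as_genome_string(seq)
    L <- nchar(seq)
  }
  abort_if(is.null(L), "supply `seq` or `L`")
  abort_if(window > L, "window larger than the genome")
  abort_if(length(starts) > 0 && (min(starts) < 0 || max(starts) >= L),
           "read start outside genome")
  n_win <- ceiling(L / window)
  ws <- (seq_len(n_win) - 1) * window
  we <- pmin(ws + window, L)
  counts <- tabulate(floor(starts / window) + 1L, nbins = n_win)
  gc <- rep(NA_real_, n_win)
  if (!is.null(seq)) {
    dna <- Biostrings::DNAString(seq)
    v <- Biostrings::Views(dna, start = ws + 1, end = we)
    gc <- as.numeric(
      Biostrings::letterFrequency(v, "GC", as.prob = TRUE))
  }
  out <- tibble::tibble(window = seq_len(n_win), start = ws, end = we,
                        width = we - ws, count = counts, gc = gc,
                        covered = counts > 0)
  attr(out, "genome_length") <- L
  attr(out, "window") <- window
  out
}

# merge ordered GC bins forward until each group has >= min_windows members
merge_gc_bins <- function(bin_idx, covered, min_windows) {
  bins <- sort(unique(bin_idx[covered]))
  sizes <- vapply(bins, function(b) sum(bin_idx == b & covered), integer(1))
  grp <- integer(length(bins))
  g <- 1L
  acc <- 0L
  for (i in seq_along(bins)) {
    grp[i] <- g
    acc <- acc + sizes[i]
    if (acc >= min_windows && i < length(bins)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  # a trailing undersized group joins its predecessor
  if (acc < min_windows && g > 1) grp[grp == g] <- g - 1L
  stats::setNames(grp, bins)
}

#' GC-normalized relative copy number
#'
#' Divides each window's read count by the median count of windows with
#' similar GC (bins of `gc_bin_width` over the observed GC range; bins
#' with fewer than `min_windows` covered windows are merged with their
#' neighbours), then rescales so the genome-wide median over covered
#' windows is 1. This removes smooth GC-dependent coverage bias while
#' preserving the relative Ori:Ter dosage profile; no segmentation is
#' attempted because only the relative per-window values enter the
#' downstream corrections.
#'
#' @param depth A tibble from [depth_windows()].
#' @param gc_bin_width GC bin width (default 0.05).
#' @param min_windows Minimum covered windows per GC bin (default 10).
#' @return The depth tibble with a `cn` column (NA for uncovered
#'   windows); `median(cn[covered]) == 1`.
#' @export
copy_number_profile <- function(depth, gc_bin_width = 0.05,
                                min_windows = 10) {
  abort_if(all(depth$count == 0), "all-zero depth profile")
  covered <- depth$covered
  cn <- rep(NA_real_, nrow(depth))
  if (all(is.na(depth$gc))) {
    cn[covered] <- depth$count[covered]
  } else {
    brks <- seq(min(depth$gc[covered]) - 1e-9,
                max(depth$gc[covered]) + gc_bin_width, by = gc_bin_width)
    idx <- findInterval(depth$gc, brks)
    grp_map <- merge_gc_bins(idx, covered, min_windows)
    grp <- grp_map[as.character(idx)]
    med <- tapply(depth$count[covered], grp[covered], stats::median)
    cn[covered] <- depth$count[covered] / med[as.character(grp[covered])]
  }
  cn <- cn / stats::median(cn[covered])
  out <- dplyr::mutate(depth, cn = cn)
  attr(out, "genome_length") <- attr(depth, "genome_length")
  attr(out, "window") <- attr(depth, "window")
  out
}

#' Ori:Ter copy-number ratio
#'
#' Mean relative copy number within `flank` bp of the replication origin
#' divided by the same around the terminus. Rapidly growing cells with
#' overlapping replication rounds show ratios near 3:1. The flank should
#' stay small relative to the genome so the means sample the gradient's
#' endpoints (about 2% of the genome length, i.e. 100 kb on the 4.64-Mb
#' chromosome, the default).
#'
#' @param cn A tibble from [copy_number_profile()].
#' @param ori,ter Origin / terminus positions in bp.
#' @param flank Averaging half-width in bp (default 1e5).
#' @param L Genome length; defaults to the tibble's attribute.
#' @return The ratio (a single number).
#' @export
ori_ter_ratio <- function(cn, ori, ter, flank = 1e5, L = NULL) {
  L <- L %||% attr(cn, "genome_length")
  abort_if(is.null(L), "genome length not available")
  mid <- (cn$start + cn$end) / 2
  ok <- !is.na(cn$cn)
  near_ori <- ok & circular_distance(mid, ori, L) <= flank
  near_ter <- ok & circular_distance(mid, ter, L) <= flank
  abort_if(!any(near_ori) || !any(near_ter),
           "no covered windows within the flank of ori or ter")
  mean(cn$cn[near_ori]) / mean(cn$cn[near_ter])
}

# mean copy number per analysis bin from a window-level profile
cn_per_bin <- function(cn, bin, L) {
  mid <- (cn$start + cn$end) / 2
  b <- floor(mid / bin) + 1L
  n_bins <- ceiling(L / bin)
  out <- rep(NA_real_, n_bins)
  m <- tapply(cn$cn, b, mean, na.rm = TRUE)
  out[as.integer(names(m))] <- as.numeric(m)
  out
}

#' Copy-number-corrected binned interaction frequencies
#'
#' Tallies (by default long-distance) interaction counts into genomic
#' bins — an interaction with endpoints in two different bins contributes
#' its count to both — and divides each bin's tally by the number of
#' fragment midpoints it contains times its mean relative copy number.
#' This is the per-bin (1-D) correction used to ask whether interaction
#' frequency merely tracks DNA dosage.
#'
#' @param net A cutoff-applied `gcc_network`.
#' @param cn A profile from [copy_number_profile()] covering the genome.
#' @param map The [genome_map].
#' @param bin Bin size in bp (default 10000).
#' @param classes Interaction classes to tally (default `"long"`; use
#'   `"all"` for everything).
#' @param threshold Short/long boundary passed to
#'   [classify_interactions()].
#' @return A tibble (`bin`, `start`, `end`, `n_fragments`, `cn`, `raw`,
#'   `corrected`, `flagged`); bins with no fragments (or no copy-number
#'   estimate) have `corrected = NA` and `flagged = TRUE`.
#' @export
correct_binned_interactions <- function(net, cn, map, bin = 10000,
                                        classes = "long", threshold = 800) {
  stopifnot(inherits(net, "gcc_network"), inherits(map, "genome_map"))
  abort_if(!net$cutoff_applied, "apply the significance cutoff first")
  L <- map$length
  n_bins <- ceiling(L / bin)
  frag_bin <- floor(map$fragments$midpoint / bin) + 1L
  n_frag <- tabulate(frag_bin, nbins = n_bins)

  p <- classify_interactions(net, map, threshold = threshold)
  if (!identical(classes, "all")) p <- p[p$class %in% classes, , drop = FALSE]
  raw <- numeric(n_bins)
  if (nrow(p) > 0) {
    ba <- frag_bin[p$frag_a]
    bb <- frag_bin[p$frag_b]
    s1 <- rowsum(p$count, ba)
    raw[as.integer(rownames(s1))] <- raw[as.integer(rownames(s1))] + s1[, 1]
    other <- bb != ba
    if (any(other)) {
      s2 <- rowsum(p$count[other], bb[other])
      raw[as.integer(rownames(s2))] <- raw[as.integer(rownames(s2))] + s2[, 1]
    }
  }
  cnb <- cn_per_bin(cn, bin, L)
  flagged <- n_frag == 0 | is.na(cnb)
  corrected <- ifelse(flagged, NA_real_, raw / (n_frag * cnb))
  tibble::tibble(
    bin = seq_len(n_bins),
    start = (seq_len(n_bins) - 1) * bin,
    end = pmin(seq_len(n_bins) * bin, L),
    n_fragments = n_frag, cn = cnb, raw = raw,
    corrected = corrected, flagged = flagged)
}
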