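#' Circular-genome restriction map
#'
#' A `genome_map` is the coordinate backbone of all analyses: a circular
#' genome of length `L` partitioned into restriction fragments by a set of
#' cut positions. Coordinates are 0-based, half-open and circular; fragment
#' ids are consecutive in coordinate order starting at the first cut.
#'
#' @param length Genome length in bp (circular).
#' @param cut_positions Integer vector of cut coordinates in `[0, L)`.
#'   With `k >= 1` cuts there are exactly `k` fragments; with 0 cuts a
#'   single fragment spans the whole circle.
#' @param motif,cut_offset Optional provenance of the cuts (recognition
#'   word and cut offset within it).
#'
#' @return An object of class `genome_map` with elements `length`, `motif`,
#'   `cut_offset`, `cut_positions` and `fragments`, a tibble with columns
#'   `id`, `start`, `end`, `length`, `midpoint`. `end = start + length` and
#'   may exceed the genome length for the fragment wrapping the coordinate
#'   origin; all positions are interpreted modulo the genome length.
#' @export
genome_map <- function(length, cut_positions = integer(),
                       motif = NA_character_, cut_offset = NA_integer_) {
  L <- as.numeric(length)
  abort_if(!is.finite(L) || L < 1, "genome length must be a positive number")
  cuts <- sort(unique(as.numeric(cut_positions)))
  abort_if(base::length(cuts) > 0 && (min(cuts) < 0 || max(cuts) >= L),
           "cut positions must lie in [0, L)")
  if (base::length(cuts) == 0) {
    frags <- tibble::tibble(
      id = 1L, start = 0, end = L, length = L,
      midpoint = floor(L / 2)
    )
  } else {
    k <- base::length(cuts)
    starts <- cuts
    lens <- if (k == 1) L else c(diff(cuts), L - cuts[k] + cuts[1])
    frags <- tibble::tibble(
      id = seq_len(k),
      start = starts,
      end = starts + lens,
      length = lens,
      midpoint = mod_pos(starts + floor(lens / 2), L)
    )
  }
  structure(
    list(length = L, motif = motif, cut_offset = cut_offset,
         cut_positions = cuts, fragments = frags),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> circular genome of %s bp, %d fragment(s)\n",
              format(x$length, big.mark = ","), nrow(x$fragments)))
  if (!is.na(x$motif)) {
    cat(sprintf("  digested at '%s' (cut offset %d)\n", x$motif, x$cut_offset))
  }
  print(x$fragments, n = 5)
  invisible(x)
}

#' Fragments of a genome map
#'
#' @param map A [genome_map].
#' @return The fragment tibble (`id`, `start`, `end`, `length`, `midpoint`).
#' @export
fragments <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  map$fragments
}

validate_dna <- function(seq) {
  bad <- regexpr("[^ACGT]", seq)[1]
  abort_if(bad > 0, sprintf(
    "sequence contains a non-ACGT character ('%s') at position %d",
    substr(seq, bad, bad), bad))
  invisible(seq)
}

as_genome_string <- function(seq) {
  if (inherits(seq, "DNAStringSet")) {
    abort_if(base::length(seq) != 1,
             "expected a single circular replicon, got multiple records")
    seq <- seq[[1]]
  }
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  seq <- toupper(as.character(seq))
  abort_if(base::length(seq) != 1 || nchar(seq) == 0, "empty sequence")
  validate_dna(seq)
  seq
}

#' In-silico digestion of a circular genome
#'
#' Scans a circular DNA sequence for every occurrence of a restriction
#' motif (occurrences wrapping the coordinate origin included, and
#' overlapping occurrences both cut) and places one cut per occurrence at
#' `(site_start + cut_offset) mod L`. The default is HhaI (GCG^C): a
#' 4-base cutter recognizing GCGC and cleaving after the third base. The
#' 2-nt overhang is ignored; a single blunt cut coordinate defines
#' fragment boundaries, since fragment identity rather than end chemistry
#' matters downstream.
#'
#' @param seq Character scalar, `DNAString` or single-record
#'   `DNAStringSet`; A/C/G/T only.
#' @param motif Recognition word (non-degenerate), default `"GCGC"`.
#' @param cut_offset Cut position within the motif, `0..nchar(motif)`.
#' @return A [genome_map].
#' @examples
#' digest_genome("AAAAGCGCAAAAGCGCAAAA")
#' @export
digest_genome <- function(seq, motif = "GCGC", cut_offset = 3) {
  seq <- as_genome_string(seq)
  motif <- toupper(motif)
  abort_if(grepl("[^ACGT]", motif), "motif must be non-degenerate (ACGT only)")
  abort_if(cut_offset < 0 || cut_offset > nchar(motif),
           "cut_offset must lie within the motif")
  L <- nchar(seq)
  # double the sequence by motif length - 1 so wrap-spanning sites are seen
  extended <- paste0(seq, substr(seq, 1, nchar(motif) - 1))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(extended))
  starts0 <- Biostrings::start(hits) - 1  # 0-based site starts
  starts0 <- starts0[starts0 < L]
  cuts <- sort(unique(mod_pos(starts0 + cut_offset, L)))
  genome_map(L, cuts, motif = motif, cut_offset = cut_offset)
}

#' Circular distance between genome coordinates
#'
#' Shorter-arc distance on a circle of length `L`; always in `[0, L/2]`.
#'
#' @param a,b Coordinates in `[0, L)` (vectorized).
#' @param L Genome length.
#' @return Numeric vector of distances.
#' @export
circular_distance <- function(a, b, L) {
  abort_if(any(a < 0 | a >= L | b < 0 | b >= L, na.rm = TRUE),
           "coordinates must lie in [0, L)")
  d <- abs(a - b)
  pmin(d, L - d)
}

#' Locate a position on a genome map
#'
#' @param pos Coordinates in `[0, L)` (vectorized).
#' @param map A [genome_map].
#' @return Integer fragment id(s) whose half-open circular interval
#'   contains each position.
#' @export
locate_position <- function(pos, map) {
  stopifnot(inherits(map, "genome_map"))
  L <- map$length
  abort_if(any(pos < 0 | pos >= L, na.rm = TRUE),
           "position out of range [0, L)")
  cuts <- map$cut_positions
  if (base::length(cuts) == 0) return(rep(1L, base::length(pos)))
  idx <- findInterval(pos, cuts)
  idx[idx == 0L] <- base::length(cuts)  # before first cut: wrapping fragment
  as.integer(idx)
}

# circularly adjacent fragment ids (|i - j| == 1 mod n)
frag_adjacent <- function(a, b, n) {
  d <- abs(a - b)
  n > 1 & (d == 1 | d == n - 1)
}
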