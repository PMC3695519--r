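#' Read a circular genome from FASTA
#'
#' Reads a single-record FASTA file; multi-record input is rejected
#' (one circular replicon only).
#'
#' @param path FASTA file path.
#' @return The genome sequence as an upper-case character scalar.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  abort_if(length(set) != 1,
           sprintf("expected a single circular replicon, got %d records",
                   length(set)))
  as_genome_string(set)
}

#' Write / read a genome map as BED-like TSV
#'
#' Columns `id`, `start`, `end` (0-based half-open; `end` exceeds the
#' genome length for the fragment wrapping the coordinate origin) plus a
#' header comment carrying the genome length.
#'
#' @param map A [genome_map].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(map, path) {
  readr::write_tsv(map$fragments[c("id", "start", "end")], path)
  invisible(path)
}

pair_cols <- readr::cols(
  pos1 = readr::col_double(), strand1 = readr::col_character(),
  unique1 = readr::col_logical(), pos2 = readr::col_double(),
  strand2 = readr::col_character(), unique2 = readr::col_logical(),
  sample = readr::col_character(), condition = readr::col_character(),
  is_control = readr::col_logical())

#' Read mapped read pairs from the TSV dialect
#'
#' Columns: `pos1`, `strand1`, `unique1`, `pos2`, `strand2`, `unique2`,
#' `sample`, `condition`, `is_control`. Positions are 0-based bp.
#'
#' @param path TSV file.
#' @return A mapped-pair tibble for [assemble_network()].
#' @export
read_pairs_tsv <- function(path) {
  readr::read_tsv(path, col_types = pair_cols)
}

#' Read mapped read pairs from SAM
#'
#' Converts the SAM to BAM (Rsamtools) and pairs records by query name.
#' An end is uniquely mapped when it is mapped with mapping quality at
#' least `mapq_min`. Pairs with an end on a contig named in
#' `control_ref` are flagged as ligation controls (spiked control DNA is
#' mapped to its own reference).
#'
#' @param path SAM (or BAM) file.
#' @param mapq_min Minimum mapping quality for uniqueness (default 30).
#' @param control_ref Character vector of control contig names.
#' @param sample,condition Labels attached to all pairs.
#' @return A mapped-pair tibble for [assemble_network()].
#' @export
read_pairs_sam <- function(path, mapq_min = 30, control_ref = character(),
                           sample = "sample1", condition = "EXP") {
  bam <- if (grepl("\\.bam$", path)) path else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "mapq")))[[1]]
  first <- bitwAnd(b$flag, 64L) > 0L
  df <- tibble::tibble(
    qname = b$qname, first = first, rname = as.character(b$rname),
    strand = as.character(b$strand), pos = b$pos, mapq = b$mapq)
  ends <- split(df, df$first)
  e1 <- ends[["TRUE"]]
  e2 <- ends[["FALSE"]]
  m <- match(e1$qname, e2$qname)
  ok <- !is.na(m)
  e1 <- e1[ok, ]
  e2 <- e2[m[ok], ]
  uniq <- function(e) !is.na(e$pos) & !is.na(e$mapq) & e$mapq >= mapq_min
  tibble::tibble(
    pos1 = e1$pos - 1, strand1 = e1$strand, unique1 = uniq(e1),
    pos2 = e2$pos - 1, strand2 = e2$strand, unique2 = uniq(e2),
    sample = sample, condition = condition,
    is_control = e1$rname %in% control_ref | e2$rname %in% control_ref)
}

#' Write / read an interaction network as TSV
#'
#' Triplet format `frag_a`, `frag_b`, `count` with the condition,
#' genome size and cutoff state in commented header lines.
#'
#' @param net A `gcc_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  hdr <- sprintf("# condition=%s genome_length=%s n_fragments=%d cutoff=%s applied=%s",
                 net$condition, format(net$genome_length, scientific = FALSE),
                 net$n_fragments, net$cutoff, net$cutoff_applied)
  writeLines(hdr, path)
  readr::write_tsv(net$pairs, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  meta <- stats::setNames(
    sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  pairs <- readr::read_tsv(path, comment = "#", col_types = "iii")
  map <- genome_map(as.numeric(meta[["genome_length"]]),
                    integer())  # shape-only map for validation
  net <- new_gcc_network(pairs, meta[["condition"]], map,
                         cutoff = suppressWarnings(as.numeric(meta[["cutoff"]])),
                         cutoff_applied = meta[["applied"]] == "TRUE")
  net$n_fragments <- as.integer(meta[["n_fragments"]])
  net
}

#' Read a region set from BED
#'
#' Reads BED intervals (0-based half-open, as native BED). With
#' `flank > 0` each record is treated as a point site (its start
#' position, the convention for peak calls stored as 1-bp features) and
#' expanded to `point +/- flank`.
#'
#' @param path BED file.
#' @param L Genome length.
#' @param flank Bases either side of the point (0 keeps intervals as
#'   given; typical site analyses use 50, 100, 250 or 500).
#' @param label Optional set label (defaults to the file name).
#' @return A [region_set()] tibble.
#' @export
read_regions_bed <- function(path, L, flank = 0,
                             label = sub("\\.bed$", "", basename(path))) {
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- BiocGenerics::start(gr) - 1
  end <- BiocGenerics::end(gr)
  if (flank > 0) {
    regions_from_points(start0, flank, L, label = label)
  } else {
    region_set(start0, end - start0, L, label = label)
  }
}

#' Read a gene annotation + expression TSV
#'
#' Long format: `gene_id`, `start`, `end`, `strand`, `condition`,
#' `replicate`, `level` (one row per gene x condition x replicate).
#'
#' @param path TSV file.
#' @return A tibble for [log2_ratios()].
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), strand = readr::col_character(),
    condition = readr::col_character(), replicate = readr::col_integer(),
    level = readr::col_double()))
}
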