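#' Per-gene log2 condition ratios
#'
#' Combines replicate expression levels by geometric mean (ratios are
#' multiplicative), floors levels at a small positive constant, and
#' computes `log2(numerator / denominator)` per gene. Per-replicate
#' ratios (replicates matched by index across conditions) are kept to
#' support a sign-consistency rule when calling regulated genes.
#'
#' @param tbl Long-format expression tibble with columns `gene_id`,
#'   `start`, `end`, `strand`, `condition`, `replicate`, `level`.
#' @param numerator,denominator Condition labels (default `"SHX"` over
#'   `"EXP"`: stringent response versus exponential growth).
#' @param floor Level floor applied before ratios (default 1, one unit
#'   of the expression scale).
#' @return A per-gene tibble (`gene_id`, `start`, `end`, `strand`,
#'   `level_num`, `level_den`, `log2_ratio`, `consistent`) where
#'   `consistent` records whether all matched replicate ratios agree in
#'   sign with the combined ratio.
#' @export
log2_ratios <- function(tbl, numerator = "SHX", denominator = "EXP",
                        floor = 1) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("gene_id", "start", "condition", "replicate", "level")
  abort_if(!all(need %in% names(tbl)),
           "expression table must have gene_id, start, condition, replicate, level")
  abort_if(!all(c(numerator, denominator) %in% tbl$condition),
           "missing condition in expression table")
  if (!"end" %in% names(tbl)) tbl$end <- tbl$start
  if (!"strand" %in% names(tbl)) tbl$strand <- "+"
  tbl <- dplyr::mutate(tbl, level = pmax(level, floor))
  gm <- function(x) exp(mean(log(x)))

  per_gene <- tbl |>
    dplyr::filter(condition %in% c(numerator, denominator)) |>
    dplyr::group_by(gene_id, start, end, strand, condition) |>
    dplyr::arrange(replicate, .by_group = TRUE) |>
    dplyr::summarise(gmean = gm(level), levels = list(level),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition,
                       values_from = c(gmean, levels))
  num_g <- per_gene[[paste0("gmean_", numerator)]]
  den_g <- per_gene[[paste0("gmean_", denominator)]]
  lnum <- per_gene[[paste0("levels_", numerator)]]
  lden <- per_gene[[paste0("levels_", denominator)]]
  ratio <- log2(num_g / den_g)
  consistent <- purrr::pmap_lgl(
    list(lnum, lden, ratio), function(a, b, r) {
      k <- min(length(a), length(b))
      reps <- log2(a[seq_len(k)] / b[seq_len(k)])
      all(sign(reps[reps != 0]) == sign(r)) || r == 0
    })
  tibble::tibble(
    gene_id = per_gene$gene_id, start = per_gene$start,
    end = per_gene$end, strand = per_gene$strand,
    level_num = num_g, level_den = den_g,
    log2_ratio = ratio, consistent = consistent) |>
    dplyr::arrange(start)
}

#' Call up-, down- and unchanged genes
#'
#' A gene is `up` when its combined log2 ratio is at or above the
#' threshold with replicate ratios consistently of the same sign, `down`
#' symmetrically, and `unchanged` otherwise. The |log2| >= 1 default is
#' a conventional two-fold rule; the threshold is a tunable.
#'
#' @param ratios A tibble from [log2_ratios()].
#' @param threshold Absolute log2-ratio threshold (default 1).
#' @return The input with a `call` factor column
#'   (`up`/`down`/`unchanged`); the three calls partition the genes.
#' @export
call_regulated <- function(ratios, threshold = 1) {
  dplyr::mutate(ratios, call = factor(dplyr::case_when(
    log2_ratio >= threshold & consistent ~ "up",
    log2_ratio <= -threshold & consistent ~ "down",
    TRUE ~ "unchanged"), levels = c("up", "down", "unchanged")))
}

#' Binned expression with a positional shuffle null
#'
#' Bins genes by start coordinate, averages a per-gene value (log2
#' ratio by default) per bin, and compares with the same averages after
#' shuffling the values over the fixed gene positions `n_shuffles`
#' times ("randomized genomes"). Bins whose observed mean falls outside
#' the per-bin 2.5–97.5% envelope indicate linear clustering of
#' expression changes.
#'
#' @param ratios A per-gene tibble (e.g. from [log2_ratios()]).
#' @param L Genome length.
#' @param bin Bin size in bp (default 50000).
#' @param n_shuffles Number of value shuffles (default 1000).
#' @param value_col Column to average (default `"log2_ratio"`).
#' @param probs Envelope probabilities (default `c(0.025, 0.975)`).
#' @return A tibble (`bin`, `start`, `end`, `n_genes`, `observed`,
#'   `null_mean`, `null_lo`, `null_hi`) of class `binned_expression`;
#'   bins with no genes have `NA` observed values.
#' @export
binned_expression_null <- function(ratios, L, bin = 50000,
                                   n_shuffles = 1000,
                                   value_col = "log2_ratio",
                                   probs = c(0.025, 0.975)) {
  v <- ratios[[value_col]]
  abort_if(is.null(v), sprintf("no column '%s'", value_col))
  n_bins <- ceiling(L / bin)
  b <- floor(ratios$start / bin) + 1L
  n_g <- tabulate(b, nbins = n_bins)
  sum_obs <- rep(NA_real_, n_bins)
  s <- rowsum(v, b)
  sum_obs[as.integer(rownames(s))] <- s[, 1]
  observed <- sum_obs / ifelse(n_g == 0, NA, n_g)

  null_mat <- matrix(NA_real_, n_shuffles, n_bins)
  for (k in seq_len(n_shuffles)) {
    sk <- rowsum(sample(v), b)
    null_mat[k, as.integer(rownames(sk))] <- sk[, 1]
  }
  null_mat <- sweep(null_mat, 2, ifelse(n_g == 0, NA, n_g), "/")
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    start = (seq_len(n_bins) - 1) * bin,
    end = pmin(seq_len(n_bins) * bin, L),
    n_genes = n_g,
    observed = observed,
    null_mean = colMeans(null_mat),
    null_lo = apply(null_mat, 2, stats::quantile, probs[1], na.rm = FALSE),
    null_hi = apply(null_mat, 2, stats::quantile, probs[2], na.rm = FALSE))
  class(out) <- c("binned_expression", class(out))
  out
}

#' Autocorrelation of expression along gene order
#'
#' Orders genes by start coordinate and computes the standard sample
#' autocorrelation of their log2 ratios at lags `0..max_lag`. High
#' values far beyond lag 1 mean that a gene's regulation predicts its
#' linear neighbours' — clustering of regulation along the chromosome.
#' The ordering is treated as linear (circular wrap ignored): for lags
#' much smaller than the gene count the wrap contribution is
#' negligible.
#'
#' @param ratios A per-gene tibble with `start` and a value column.
#' @param max_lag Maximum lag in genes (default 32).
#' @param value_col Column to autocorrelate (default `"log2_ratio"`).
#' @return A tibble (`lag`, `acf`); `acf[lag == 0] == 1`.
#' @export
expression_acf <- function(ratios, max_lag = 32,
                           value_col = "log2_ratio") {
  v <- ratios[[value_col]][order(ratios$start)]
  abort_if(base::length(v) < max_lag + 2,
           "need at least max_lag + 2 genes")
  abort_if(stats::sd(v) == 0, "zero-variance expression series")
  a <- stats::acf(v, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = 0:max_lag, acf = as.numeric(a$acf))
}

#' Correlation of expression change with GC content
#'
#' Pearson correlation between per-gene GC fraction (computed from the
#' genome sequence over each gene body, circular wrap allowed) and the
#' log2 expression ratio — a check that expression clustering is not a
#' base-composition artifact.
#'
#' @param ratios A per-gene tibble with `start`, `end`, `log2_ratio`.
#' @param seq Genome sequence.
#' @return A one-row tibble (`r`, `p_value`, `n`).
#' @export
gc_expression_correlation <- function(ratios, seq) {
  seq <- as_genome_string(seq)
  L <- nchar(seq)
  abort_if(nrow(ratios) < 3, "need at least 3 genes for a correlation")
  dna <- Biostrings::DNAString(seq)
  gc_of <- function(s, e) {
    s <- mod_pos(s, L)
    e2 <- mod_pos(e - 1, L) + 1
    if (e2 > s) {
      v <- Biostrings::subseq(dna, s + 1, e2)
    } else {  # wrapping gene body
      v <- Biostrings::xscat(Biostrings::subseq(dna, s + 1, L),
                             Biostrings::subseq(dna, 1, e2))
    }
    sum(Biostrings::letterFrequency(v, c("G", "C"))) / length(v)
  }
  gc <- purrr::map2_dbl(ratios$start, ratios$end, gc_of)
  abort_if(stats::sd(gc) == 0 || stats::sd(ratios$log2_ratio) == 0,
           "degenerate variance")
  ct <- stats::cor.test(gc, ratios$log2_ratio, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(ratios))
}
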