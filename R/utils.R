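# positive modulus for bp coordinates
mod_pos <- function(x, L) ((x %% L) + L) %% L

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
  invisible(NULL)
}

# weighted quantile, type-1 (inverse empirical CDF)
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

utils::globalVariables(c(
  ".", "frag_a", "frag_b", "count", "count_a", "count_b", "status",
  "id", "start", "end", "length", "midpoint", "distance", "class",
  "window", "gc", "cn", "covered", "bin", "corrected", "raw",
  "n_fragments", "flagged", "gene_id", "condition", "replicate",
  "level", "log2_ratio", "call", "observed", "null_lo", "null_hi",
  "null_mean", "n_genes", "lag", "acf", "method", "statistic",
  "p_high", "p_low", "null_sd", "value", "partners", "fragment",
  "dist_ori", "crossing", "pos1", "pos2", "unique1", "unique2",
  "is_control", "strand", "draw", "total", "clustering", "region",
  "peak", "n_bins", "max_value", "consistent", "width", "label"
))
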