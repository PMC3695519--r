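#' Synthetic-data configuration
#'
#' Ground-truth parameters for the generators that emulate the
#' statistical structure of a GCC experiment on a circular bacterial
#' chromosome: a 4-cutter digest (mean inter-site spacing 256 bp, the
#' GCGC expectation), an Ori-to-Ter copy-number gradient
#' `cn(x) = R^(1 - d_ori(x) / (L/2))` from overlapping replication
#' rounds, distance-decaying contact intensities with an Ori-domain
#' enrichment, a planted clustered region set, spiked ligation-control
#' pairs, windowed read depth, and gene-order-autocorrelated expression
#' log ratios with planted regulated blocks.
#'
#' Default sizes are desk-scale (500-kb genome) with all rate-, ratio-
#' and spacing-like parameters at chromosome-realistic values; see the
#' methods vignette for the reasoning behind each default.
#'
#' @param L Genome length in bp.
#' @param mean_spacing Mean restriction-site spacing in bp.
#' @param ori,ter Origin / terminus positions (antipodal by default).
#' @param R Ori:Ter copy-number gradient ratio (`>= 1`).
#' @param gamma Contact-decay exponent (`>= 0`).
#' @param lambda0 Base contact intensity.
#' @param alpha Ori-domain contact enrichment (`>= 1`).
#' @param ori_radius Ori-domain radius in bp.
#' @param m_regions,region_length,region_min_gap Planted region set:
#'   count, length (bp) and minimum pairwise midpoint separation (bp).
#' @param beta Pairwise contact enrichment between distinct planted
#'   regions (`>= 1`; 1 means no planted signal).
#' @param control_pairs,control_rate Ligation-control spike: number of
#'   candidate fragment pairs and Poisson mean count per pair.
#' @param depth_mean Mean read-start count per copy-number window.
#' @param cn_window Copy-number window size in bp.
#' @param gc_bias Exponent of the multiplicative GC coverage bias
#'   (`(gc / mean gc)^gc_bias`; 0 disables it).
#' @param n_genes Gene count (default 0.9 genes/kb, enterobacterial
#'   density).
#' @param ar_rho,ar_sd AR(1) parameter and stationary sd of the
#'   background expression log2-ratio series along gene order.
#' @param block_genes,block_log2 Planted regulated blocks: one up- and
#'   one down-block of `block_genes` contiguous genes at
#'   `+/- block_log2`; 0 genes disables them.
#' @param rep_sd Per-replicate log2 noise sd.
#' @param n_replicates Replicates per condition.
#' @param overdispersion Contact-count overdispersion: 0 (default) gives
#'   Poisson counts; `d > 0` gives negative binomial with
#'   `var = mu + d * mu^2`. The pipeline's statistics are count sums and
#'   ranks, so they are insensitive to mild overdispersion.
#' @param seed Master seed; each generator draws from a stream derived
#'   from it (fixed documented offsets), so every generator is
#'   individually reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(L = 500000, mean_spacing = 256,
                         ori = 0, ter = NULL,
                         R = 3, gamma = 1, lambda0 = 1000,
                         alpha = 4, ori_radius = 0.1 * L,
                         m_regions = 10, region_length = 1000,
                         region_min_gap = 10000, beta = 10,
                         control_pairs = 200, control_rate = 1,
                         depth_mean = 50, cn_window = 1000, gc_bias = 0,
                         n_genes = round(0.9e-3 * L),
                         ar_rho = 0.85, ar_sd = 0.5,
                         block_genes = 20, block_log2 = 3,
                         rep_sd = 0.05, n_replicates = 2,
                         overdispersion = 0, seed = NULL) {
  abort_if(R < 1, "R must be >= 1")
  abort_if(gamma < 0, "gamma must be >= 0")
  abort_if(alpha < 1 || beta < 1, "alpha and beta must be >= 1")
  cfg <- list(L = L, mean_spacing = mean_spacing, ori = mod_pos(ori, L),
              ter = mod_pos(ter %||% (ori + L / 2), L),
              R = R, gamma = gamma, lambda0 = lambda0, alpha = alpha,
              ori_radius = ori_radius, m_regions = m_regions,
              region_length = region_length,
              region_min_gap = region_min_gap, beta = beta,
              control_pairs = control_pairs, control_rate = control_rate,
              depth_mean = depth_mean, cn_window = cn_window,
              gc_bias = gc_bias, n_genes = n_genes,
              ar_rho = ar_rho, ar_sd = ar_sd,
              block_genes = block_genes, block_log2 = block_log2,
              rep_sd = rep_sd, n_replicates = n_replicates,
              overdispersion = overdispersion, seed = seed)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_config> L = %s bp, spacing %g bp, R = %g, gamma = %g,\n",
    "  lambda0 = %g, alpha = %g, beta = %g (%d planted regions), seed = %s\n"),
    format(x$L, big.mark = ","), x$mean_spacing, x$R, x$gamma,
    x$lambda0, x$alpha, x$beta, x$m_regions,
    if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# seed offsets per generator, documented in the vignette
with_cfg_seed <- function(cfg, offset, code) {
  if (is.null(cfg$seed)) code else withr::with_seed(cfg$seed + offset, code)
}

# the Ori->Ter dosage gradient: cn(x) = R^(1 - d_ori(x)/(L/2))
cn_gradient <- function(x, cfg) {
  d <- circular_distance(mod_pos(x, cfg$L), cfg$ori, cfg$L)
  cfg$R^(1 - d / (cfg$L / 2))
}

#' Simulate a circular genome with restriction sites
#'
#' Plants GCGC motifs at geometric spacing (mean `mean_spacing`) in a
#' G-free background drawn from A/C/T with a smoothly varying C
#' fraction, so the only motif occurrences are the planted ones and the
#' GC content varies along the genome (exercising GC normalization).
#'
#' @param cfg A [synth_config()].
#' @return A list with `seq` (character), `map` (the [genome_map] from
#'   digesting `seq`) and `config`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_cfg_seed(cfg, 1L, {
    L <- cfg$L
    motif_len <- 4L
    x <- seq_len(L) - 1
    # local (25-kb period) GC heterogeneity; keeping GC variation
    # short-scale avoids confounding GC with chromosome position
    p_c <- 0.3 + 0.2 * sin(2 * pi * x / 25000)
    is_c <- stats::runif(L) < p_c
    chars <- ifelse(is_c, "C", sample(c("A", "T"), L, replace = TRUE))
    if (cfg$mean_spacing < L) {
      gap_mean <- max(cfg$mean_spacing - motif_len, 1)
      n_est <- ceiling(1.5 * L / cfg$mean_spacing) + 20
      gaps <- stats::rgeom(n_est, 1 / (gap_mean + 1))
      starts <- cumsum(gaps + motif_len) - motif_len
      starts <- starts[starts + motif_len <= L]
      for (s in starts) {
        chars[(s + 1):(s + motif_len)] <- c("G", "C", "G", "C")
      }
    }
    seq <- paste(chars, collapse = "")
    list(seq = seq, map = digest_genome(seq), config = cfg)
  })
}

# plant m regions with pairwise midpoint separation >= region_min_gap
plant_regions <- function(cfg) {
  if (cfg$m_regions == 0) return(region_set(numeric(), 1, cfg$L)[0, ])
  for (attempt in 1:10000) {
    starts <- sample.int(cfg$L, cfg$m_regions, replace = TRUE) - 1
    mids <- mod_pos(starts + cfg$region_length / 2, cfg$L)
    d <- outer(mids, mids, function(a, b) circular_distance(a, b, cfg$L))
    if (all(d[upper.tri(d)] >= cfg$region_min_gap)) {
      return(region_set(starts, cfg$region_length, cfg$L,
                        label = "planted"))
    }
  }
  rlang::abort("could not plant regions with the requested separation")
}

#' Simulate a GCC interaction network with known ground truth
#'
#' For every unordered fragment pair the contact intensity is
#' `lambda0 * cn_i * cn_j * (d_ij + 1)^(-gamma)` times `alpha` when both
#' midpoints fall in the Ori domain and `beta` when the endpoints lie in
#' two distinct planted regions; counts are Poisson. The truth record
#' stores every per-fragment factor and the planted region set.
#'
#' @param cfg A [synth_config()].
#' @param map The [genome_map] (from [simulate_genome()]).
#' @param condition Condition label (default `"EXP"`).
#' @return A `gcc_network` with a `$truth` list (`fragments` tibble with
#'   per-fragment cn / Ori-domain / region membership, `regions`,
#'   `config`).
#' @export
simulate_network <- function(cfg, map, condition = "EXP") {
  stopifnot(inherits(cfg, "synth_config"), inherits(map, "genome_map"))
  with_cfg_seed(cfg, 2L, {
    n <- nrow(map$fragments)
    mids <- map$fragments$midpoint
    L <- map$length
    cn <- cn_gradient(mids, cfg)
    in_ori <- circular_distance(mids, cfg$ori, L) <= cfg$ori_radius
    regions <- plant_regions(cfg)
    ridx <- integer(n)
    if (nrow(regions) > 0) {
      ix <- region_fragment_index(map, regions)
      ridx <- ifelse(ix$n > 0, ix$min, 0L)
    }
    fa <- rep.int(seq_len(n), rev(seq_len(n)))
    fb <- sequence(rev(seq_len(n)), from = seq_len(n))
    d <- circular_distance(mids[fa], mids[fb], L)
    lam <- cfg$lambda0 * cn[fa] * cn[fb] * (d + 1)^(-cfg$gamma)
    both_ori <- in_ori[fa] & in_ori[fb]
    lam[both_ori] <- lam[both_ori] * cfg$alpha
    planted <- ridx[fa] > 0L & ridx[fb] > 0L & ridx[fa] != ridx[fb]
    lam[planted] <- lam[planted] * cfg$beta
    lam <- pmin(lam, 1e6)  # overflow guard
    counts <- if ((cfg$overdispersion %||% 0) > 0) {
      stats::rnbinom(length(lam), size = 1 / cfg$overdispersion, mu = lam)
    } else {
      stats::rpois(length(lam), lam)
    }
    keep <- counts > 0L
    net <- new_gcc_network(
      tibble::tibble(frag_a = fa[keep], frag_b = fb[keep],
                     count = counts[keep]),
      condition, map)
    net$cutoff <- 0
    net$cutoff_applied <- TRUE  # generated above background by construction
    net$truth <- list(
      fragments = tibble::tibble(id = seq_len(n), cn = cn,
                                 ori_domain = in_ori, region = ridx),
      regions = regions, config = cfg)
    net
  })
}

#' Simulate ligation-control read pairs
#'
#' Uniformly random fragment pairs at low Poisson counts, flagged as
#' controls: the background of random inter-molecular ligation that the
#' significance cutoff is derived from.
#'
#' @param cfg A [synth_config()].
#' @param map The [genome_map].
#' @param condition Condition label carried on the pairs.
#' @return A mapped-pair tibble (`pos1`, `strand1`, `unique1`, `pos2`,
#'   `strand2`, `unique2`, `sample`, `condition`, `is_control`) suitable
#'   for [assemble_network()].
#' @export
simulate_controls <- function(cfg, map, condition = "EXP") {
  stopifnot(inherits(cfg, "synth_config"), inherits(map, "genome_map"))
  with_cfg_seed(cfg, 3L, {
    n <- nrow(map$fragments)
    fr <- map$fragments
    fa <- sample.int(n, cfg$control_pairs, replace = TRUE)
    fb <- sample.int(n, cfg$control_pairs, replace = TRUE)
    counts <- stats::rpois(cfg$control_pairs, cfg$control_rate)
    rand_pos <- function(f) {
      mod_pos(fr$start[f] + floor(stats::runif(length(f)) * fr$length[f]),
              map$length)
    }
    # one ligation junction per pair slot; its reads share the positions
    slot <- tibble::tibble(
      pos1 = rand_pos(fa),
      strand1 = sample(c("+", "-"), length(fa), replace = TRUE),
      unique1 = TRUE,
      pos2 = rand_pos(fb),
      strand2 = sample(c("+", "-"), length(fb), replace = TRUE),
      unique2 = TRUE,
      sample = "control_spike", condition = condition, is_control = TRUE)
    slot[rep(seq_len(nrow(slot)), counts), ]
  })
}

#' Simulate windowed read depth under the copy-number gradient
#'
#' Per-window counts are Poisson with mean
#' `depth_mean * cn(window) * (gc / mean gc)^gc_bias`, and read starts
#' are uniform within their window.
#'
#' @param cfg A [synth_config()].
#' @param map The [genome_map].
#' @param seq Genome sequence; required when `gc_bias != 0`.
#' @return A list with `starts` (read-start positions) and `truth` (a
#'   per-window tibble with the generating `cn`).
#' @export
simulate_depth <- function(cfg, map, seq = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_cfg_seed(cfg, 4L, {
    L <- cfg$L
    w <- cfg$cn_window
    n_win <- ceiling(L / w)
    ws <- (seq_len(n_win) - 1) * w
    we <- pmin(ws + w, L)
    cn_w <- cn_gradient((ws + we) / 2, cfg)
    bias <- rep(1, n_win)
    if (cfg$gc_bias != 0) {
      abort_if(is.null(seq), "gc_bias != 0 requires the genome sequence")
      gc <- depth_windows(integer(), seq = seq, window = w)$gc
      bias <- (gc / mean(gc))^cfg$gc_bias
    }
    counts <- stats::rpois(n_win, cfg$depth_mean * cn_w * bias)
    starts <- rep(ws, counts) +
      floor(stats::runif(sum(counts)) * rep(we - ws, counts))
    list(starts = starts,
         truth = tibble::tibble(window = seq_len(n_win), start = ws,
                                end = we, cn = cn_w, bias = bias))
  })
}

#' Simulate an expression table with genome-order structure
#'
#' Genes at uniform positions carry log2 SHX/EXP ratios from a
#' stationary AR(1) process along gene order (parameter `ar_rho`,
#' stationary sd `ar_sd`) plus planted contiguous up- and down-regulated
#' blocks; per-replicate levels add lognormal noise around a gene base
#' level.
#'
#' @param cfg A [synth_config()].
#' @return A list with `expression` (long tibble: `gene_id`, `start`,
#'   `end`, `strand`, `condition`, `replicate`, `level`) and `truth`
#'   (per-gene tibble with the generating `true_log2` and block
#'   membership).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_cfg_seed(cfg, 5L, {
    n <- cfg$n_genes
    L <- cfg$L
    starts <- sort(sample.int(L, n)) - 1
    len <- 800
    rho <- cfg$ar_rho
    eps <- stats::rnorm(n) * sqrt(1 - rho^2)
    x <- if (rho == 0) eps else {
      as.numeric(stats::filter(eps, rho, method = "recursive",
                               init = stats::rnorm(1)))
    }
    x <- x * cfg$ar_sd
    block <- rep("none", n)
    if (cfg$block_genes > 0 && n >= 2 * cfg$block_genes) {
      repeat {
        up0 <- sample.int(n - cfg$block_genes + 1, 1)
        dn0 <- sample.int(n - cfg$block_genes + 1, 1)
        if (abs(up0 - dn0) >= cfg$block_genes) break
      }
      up_idx <- up0:(up0 + cfg$block_genes - 1)
      dn_idx <- dn0:(dn0 + cfg$block_genes - 1)
      x[up_idx] <- x[up_idx] + cfg$block_log2
      x[dn_idx] <- x[dn_idx] - cfg$block_log2
      block[up_idx] <- "up"
      block[dn_idx] <- "down"
    }
    gene_id <- sprintf("g%04d", seq_len(n))
    base <- exp(stats::rnorm(n, log(100), 1))
    reps <- seq_len(cfg$n_replicates)
    expr <- tidyr::expand_grid(gene = seq_len(n), condition = c("EXP", "SHX"),
                               replicate = reps) |>
      dplyr::mutate(
        gene_id = gene_id[gene],
        start = starts[gene], end = starts[gene] + len,
        strand = rep(sample(c("+", "-"), n, replace = TRUE),
                     each = 2 * length(reps)),
        level = base[gene] *
          2^(ifelse(condition == "SHX", x[gene], 0) +
               stats::rnorm(dplyr::n(), 0, cfg$rep_sd))) |>
      dplyr::select(gene_id, start, end, strand, condition, replicate, level)
    list(expression = expr,
         truth = tibble::tibble(gene_id = gene_id, start = starts,
                                true_log2 = x, block = block))
  })
}
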