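test_that("simulated genomes carry the requested restriction-site density", {
  cfg <- synth_config(L = 100000, seed = 71)
  g <- simulate_genome(cfg)
  n <- nrow(fragments(g$map))
  expected <- cfg$L / cfg$mean_spacing
  expect_lt(abs(n - expected), 3 * sqrt(expected))  # renewal-count 3 sigma
  # determinism under the master seed
  g2 <- simulate_genome(cfg)
  expect_equal(g$seq, g2$seq)
  # no restriction sites: a single fragment
  g3 <- simulate_genome(synth_config(L = 5000, mean_spacing = 1e9,
                                     seed = 71, m_regions = 0))
  expect_equal(nrow(fragments(g3$map)), 1)
})

test_that("simulated networks satisfy network invariants and the decay law", {
  cfg <- synth_config(L = 60000, seed = 72, m_regions = 0, lambda0 = 500)
  g <- simulate_genome(cfg)
  net <- simulate_network(cfg, g$map)
  expect_true(all(net$pairs$frag_a <= net$pairs$frag_b))
  expect_true(all(net$pairs$count >= 1))
  expect_false(any(duplicated(paste(net$pairs$frag_a, net$pairs$frag_b))))
  # binned mean count decreases with distance
  cls <- classify_interactions(net, g$map, threshold = 800)
  bins <- cut(cls$distance, c(0, 2000, 8000, 30000), include.lowest = TRUE)
  mean_by_bin <- tapply(cls$count, bins, mean)
  expect_true(all(diff(mean_by_bin) < 0))
})

test_that("the Ori-domain enrichment factor is recovered from simulated contacts", {
  cfg <- synth_config(L = 100000, seed = 73, m_regions = 0, R = 1,
                      alpha = 4, ori_radius = 25000, gamma = 1,
                      lambda0 = 2000)
  g <- simulate_genome(cfg)
  net <- simulate_network(cfg, g$map)
  tr <- net$truth$fragments
  # per-pair mean over ALL fragment pairs (zeros included) at matched
  # distances 4-16 kb, inside vs outside the Ori domain
  n <- nrow(tr)
  mids <- fragments(g$map)$midpoint
  fa <- rep.int(seq_len(n), rev(seq_len(n)))
  fb <- sequence(rev(seq_len(n)), from = seq_len(n))
  d <- circular_distance(mids[fa], mids[fb], cfg$L)
  sel <- d > 4000 & d < 16000
  cnt <- numeric(length(fa))
  key <- paste(fa, fb)
  hit <- match(paste(net$pairs$frag_a, net$pairs$frag_b), key)
  cnt[hit] <- net$pairs$count
  both_ori <- tr$ori_domain[fa] & tr$ori_domain[fb]
  ratio <- mean(cnt[sel & both_ori]) / mean(cnt[sel & !both_ori])
  expect_equal(ratio, 4, tolerance = 0.35)
})

test_that("simulated ligation controls drive the cutoff", {
  cfg <- synth_config(L = 30000, seed = 74, control_pairs = 100,
                      control_rate = 1)
  g <- simulate_genome(cfg)
  ctrl_pairs <- simulate_controls(cfg, g$map)
  expect_true(all(ctrl_pairs$is_control))
  net <- assemble_network(ctrl_pairs, g$map, condition = "EXP")
  expect_equal(nrow(net$pairs), 0)  # everything routed to the control side
  k <- max(net$control$pairs$count)
  expect_equal(derive_cutoff(net$control), k)
  # zero rate: no controls, cutoff 0 with a warning
  cfg0 <- synth_config(L = 30000, seed = 74, control_rate = 0)
  ctrl0 <- simulate_controls(cfg0, g$map)
  expect_equal(nrow(ctrl0), 0)
})

test_that("control pairs are close to uniform over fragments", {
  cfg <- synth_config(L = 50000, seed = 75, control_pairs = 4000,
                      control_rate = 1)
  g <- simulate_genome(cfg)
  ctrl <- dplyr::distinct(simulate_controls(cfg, g$map),
                          pos1, pos2)  # pair slots, not read multiplicity
  ends <- c(locate_position(ctrl$pos1, g$map),
            locate_position(ctrl$pos2, g$map))
  n <- nrow(fragments(g$map))
  tab <- tabulate(ends, n)
  chisq <- sum((tab - mean(tab))^2 / mean(tab))
  # generous bound: 99.9% quantile of chi-square with n-1 df
  expect_lt(chisq, qchisq(0.999, n - 1))
})

test_that("simulated depth recovers the copy-number gradient", {
  base <- list(L = 200000, depth_mean = 50, seed = 76)
  for (R in c(1, 3)) {
    cfg <- do.call(synth_config, c(base, list(R = R)))
    g <- simulate_genome(cfg)
    dep <- simulate_depth(cfg, g$map)
    cn <- copy_number_profile(depth_windows(dep$starts, seq = g$seq,
                                            window = cfg$cn_window))
    ratio <- ori_ter_ratio(cn, cfg$ori, cfg$ter, flank = cfg$L / 50)
    target <- if (R == 1) 1 else {
      # flank-averaged gradient, computed from the generating law
      mean(dep$truth$cn[circular_distance((dep$truth$start +
        dep$truth$end) / 2, cfg$ori, cfg$L) <= cfg$L / 50]) /
        mean(dep$truth$cn[circular_distance((dep$truth$start +
          dep$truth$end) / 2, cfg$ter, cfg$L) <= cfg$L / 50])
    }
    expect_equal(ratio, target, tolerance = 0.1)
  }
})

test_that("GC coverage bias is cancelled by GC normalization", {
  cfg <- synth_config(L = 200000, seed = 77, R = 1, gc_bias = 2,
                      depth_mean = 80)
  g <- simulate_genome(cfg)
  dep <- simulate_depth(cfg, g$map, seq = g$seq)
  dw <- depth_windows(dep$starts, seq = g$seq, window = cfg$cn_window)
  # raw counts track GC strongly; normalized copy number does not
  expect_gt(cor(dw$count, dw$gc), 0.5)
  cn <- copy_number_profile(dw)
  expect_lt(abs(cor(cn$cn, cn$gc, use = "complete.obs")), 0.2)
  expect_lt(sd(cn$cn, na.rm = TRUE) / mean(cn$cn, na.rm = TRUE), 0.25)
})

test_that("simulated expression has the requested AR and block structure", {
  cfg <- synth_config(L = 400000, seed = 78, block_genes = 0,
                      n_genes = 2000)
  ex <- simulate_expression(cfg)
  expect_equal(nrow(ex$expression), 2000 * 2 * 2)
  lr <- log2_ratios(ex$expression)
  a <- expression_acf(lr, max_lag = 1)
  expect_equal(a$acf[2], cfg$ar_rho, tolerance = 0.06)
  # white noise when rho = 0
  cfg0 <- synth_config(L = 400000, seed = 79, block_genes = 0,
                       ar_rho = 0, n_genes = 2000)
  a0 <- expression_acf(log2_ratios(simulate_expression(cfg0)$expression),
                       max_lag = 1)
  expect_lt(abs(a0$acf[2]), 0.08)
  # planted block escapes the shuffle envelope in its modal bin for
  # most generator seeds (a block straddling a bin boundary can split
  # its signal, so this is a majority property, not a sure one)
  detected <- vapply(80:84, function(s) {
    cfgb <- synth_config(L = 400000, seed = s)
    exb <- simulate_expression(cfgb)
    lrb <- log2_ratios(exb$expression)
    be <- binned_expression_null(lrb, L = cfgb$L, n_shuffles = 300)
    up_starts <- exb$truth$start[exb$truth$block == "up"]
    up_bin <- as.integer(names(which.max(table(floor(up_starts / 50000) + 1))))
    be$observed[up_bin] > be$null_hi[up_bin]
  }, logical(1))
  expect_gte(sum(detected), 4)
})

test_that("truth records round-trip through serialization", {
  cfg <- synth_config(L = 30000, seed = 81, m_regions = 3,
                      region_min_gap = 5000)
  g <- simulate_genome(cfg)
  net <- simulate_network(cfg, g$map)
  tmp <- tempfile(fileext = ".tsv")
  write_network_tsv(net, tmp)
  back <- read_network_tsv(tmp)
  expect_equal(back$pairs, net$pairs)
  expect_equal(back$condition, net$condition)
  expect_equal(back$n_fragments, net$n_fragments)
})

test_that("the overdispersion knob widens count noise without moving the mean", {
  cfg0 <- synth_config(L = 40000, seed = 85, m_regions = 0, gamma = 0,
                       R = 1, alpha = 1, lambda0 = 0.5)
  cfg1 <- synth_config(L = 40000, seed = 85, m_regions = 0, gamma = 0,
                       R = 1, alpha = 1, lambda0 = 0.5, overdispersion = 2)
  g <- simulate_genome(cfg0)
  n <- nrow(fragments(g$map))
  n_pairs <- n * (n + 1) / 2
  tot0 <- sum(simulate_network(cfg0, g$map)$pairs$count)
  net1 <- simulate_network(cfg1, g$map)
  tot1 <- sum(net1$pairs$count)
  # same mean intensity per pair; dispersed counts concentrate on fewer pairs
  expect_equal(tot1 / tot0, 1, tolerance = 0.1)
  expect_lt(nrow(net1$pairs), n_pairs * 0.45)
})
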