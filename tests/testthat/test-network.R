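map10 <- regular_map(10, width = 100)  # L = 1000

test_that("assembly canonicalizes pairs, drops non-unique ends, routes controls", {
  pairs <- tibble::tibble(
    pos1 = c(150, 550, 250, 350, 10),
    pos2 = c(550, 150, 250, 850, 20),
    unique1 = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    unique2 = TRUE,
    is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  net <- assemble_network(pairs, map10, condition = "EXP")
  # (2,6) twice regardless of end order; (3,3) self
  expect_equal(net$pairs,
               tibble::tibble(frag_a = c(2L, 3L), frag_b = c(6L, 3L),
                              count = c(2L, 1L)) |>
                 dplyr::arrange(frag_a, frag_b))
  expect_equal(net$tally$n_dropped, 1)
  expect_equal(net$control$pairs$count, 1)
  # conservation: retained + dropped + control = input
  expect_equal(sum(net$pairs$count) + net$tally$n_dropped +
                 net$tally$n_control, nrow(pairs))
  expect_error(assemble_network(pairs |> dplyr::mutate(condition = "EXP"),
                                map10, condition = "SHX"), "unknown condition")
  expect_error(assemble_network(dplyr::mutate(pairs, pos1 = 2000), map10),
               "outside genome")
})

test_that("count conservation holds on simulated read pairs", {
  withr::with_seed(21, {
    n <- 500
    pairs <- tibble::tibble(
      pos1 = sample(0:999, n, replace = TRUE),
      pos2 = sample(0:999, n, replace = TRUE),
      unique1 = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.9, 0.1)),
      unique2 = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.9, 0.1)),
      is_control = sample(c(FALSE, TRUE), n, TRUE, prob = c(0.8, 0.2)))
    net <- assemble_network(pairs, map10)
    expect_equal(sum(net$pairs$count) + net$tally$n_dropped +
                   net$tally$n_control, n)
  })
})

test_that("the ligation-control cutoff is the maximum control count", {
  ctrl <- make_test_network(
    tibble::tibble(frag_a = c(1, 2, 4), frag_b = c(3, 5, 6),
                   count = c(1, 2, 1)), map10)
  expect_equal(derive_cutoff(ctrl), 2)
  gen <- make_test_network(
    tibble::tibble(frag_a = c(1, 2, 3), frag_b = c(5, 6, 7),
                   count = c(3, 2, 1)), map10, cutoff_applied = FALSE)
  kept <- apply_cutoff(gen, derive_cutoff(ctrl))
  expect_equal(kept$pairs$count, 3)  # only the count-3 interaction survives
  expect_true(kept$cutoff_applied)

  empty <- make_test_network(
    tibble::tibble(frag_a = integer(), frag_b = integer(),
                   count = integer()), map10)
  expect_warning(co <- derive_cutoff(empty), "cutoff set to 0")
  expect_equal(co, 0)
  # all below cutoff: explicit empty network, not an error
  all_gone <- apply_cutoff(gen, 10)
  expect_equal(nrow(all_gone$pairs), 0)
  # quantile alternative
  expect_equal(derive_cutoff(ctrl, method = "quantile", q = 0.5), 1)
})

test_that("raising the cutoff never adds interactions", {
  withr::with_seed(22, {
    gen <- make_test_network(
      tibble::tibble(frag_a = sample(1:10, 30, TRUE),
                     frag_b = sample(1:10, 30, TRUE),
                     count = rpois(30, 3) + 1) |>
        dplyr::distinct(pmin(frag_a, frag_b), pmax(frag_a, frag_b),
                        .keep_all = TRUE),
      map10, cutoff_applied = FALSE)
    sizes <- vapply(0:8, function(co) nrow(apply_cutoff(gen, co)$pairs),
                    numeric(1))
    expect_true(all(diff(sizes) <= 0))
  })
})

test_that("interactions classify as self / adjacent / short / long", {
  net <- make_test_network(
    tibble::tibble(frag_a = c(4, 4, 1, 1, 1, 1),
                   frag_b = c(4, 5, 10, 3, 6, 4),
                   count = 1), map10)
  cls <- classify_interactions(net, map10, threshold = 300)
  got <- setNames(as.character(cls$class), paste(cls$frag_a, cls$frag_b))
  expect_equal(got[["4 4"]], "self")
  expect_equal(got[["4 5"]], "adjacent")
  expect_equal(got[["1 10"]], "adjacent")  # circular neighbours
  expect_equal(got[["1 3"]], "short")      # midpoints 200 apart
  expect_equal(got[["1 6"]], "long")       # midpoints 500 apart
  expect_equal(got[["1 4"]], "long")       # exactly at threshold: >= is long
  expect_error(classify_interactions(net, map10, threshold = 600),
               "half the genome")
})

test_that("condition comparison partitions the union of keys", {
  a <- make_test_network(tibble::tibble(frag_a = c(1, 2), frag_b = c(2, 5),
                                        count = c(5, 2)), map10)
  b <- make_test_network(tibble::tibble(frag_a = c(1, 3), frag_b = c(2, 7),
                                        count = c(3, 4)), map10)
  cmp <- compare_conditions(a, b)
  shared <- cmp[cmp$status == "shared", ]
  expect_equal(nrow(shared), 1)
  expect_equal(c(shared$count_a, shared$count_b), c(5, 3))
  expect_equal(sum(cmp$status == "specific_a"), 1)
  expect_equal(sum(cmp$status == "specific_b"), 1)
  # randomized partition property
  withr::with_seed(23, {
    for (k in 1:5) {
      pa <- tibble::tibble(frag_a = sample(10, 6, TRUE),
                           frag_b = sample(10, 6, TRUE), count = 1) |>
        dplyr::distinct(pmin(frag_a, frag_b), pmax(frag_a, frag_b),
                        .keep_all = TRUE)
      pb <- tibble::tibble(frag_a = sample(10, 6, TRUE),
                           frag_b = sample(10, 6, TRUE), count = 1) |>
        dplyr::distinct(pmin(frag_a, frag_b), pmax(frag_a, frag_b),
                        .keep_all = TRUE)
      na <- make_test_network(pa, map10)
      nb <- make_test_network(pb, map10)
      cmp <- compare_conditions(na, nb)
      key <- paste(cmp$frag_a, cmp$frag_b)
      ka <- paste(na$pairs$frag_a, na$pairs$frag_b)
      kb <- paste(nb$pairs$frag_a, nb$pairs$frag_b)
      expect_setequal(key, union(ka, kb))
      expect_false(any(duplicated(key)))
    }
  })
  # empty A: everything specific to B
  empty <- make_test_network(tibble::tibble(frag_a = integer(),
                                            frag_b = integer(),
                                            count = integer()), map10)
  cmp2 <- compare_conditions(empty, b)
  expect_true(all(cmp2$status == "specific_b"))
})

test_that("Cohen's kappa matches the closed form", {
  expect_equal(replicate_kappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  # 2x2 cells a=20, b=5, c=10, d=15: p_o = 0.7, p_e = 0.5, kappa = 0.4
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 5, 10, 15))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 10, 15))
  expect_equal(replicate_kappa(a, b), 0.4)
  # complementary vectors with balanced margins
  x <- rep(c(TRUE, FALSE), 10)
  expect_equal(replicate_kappa(x, !x), -1)
  expect_warning(k <- replicate_kappa(rep(TRUE, 5), rep(TRUE, 5)),
                 "undefined")
  expect_true(is.na(k))
})

test_that("the kappa pair universe is explicit", {
  a <- make_test_network(tibble::tibble(frag_a = 1, frag_b = 2, count = 1),
                         map10)
  b <- make_test_network(tibble::tibble(frag_a = 1, frag_b = 2, count = 3),
                         map10)
  u <- network_presence(a, b, universe = "union")
  expect_equal(length(u$a), 1)            # only the detected pair
  expect_equal(replicate_kappa(u$a, u$b), NA_real_) |> suppressWarnings()
  all_u <- network_presence(a, b, universe = "all")
  expect_equal(length(all_u$a), 10 * 11 / 2)  # all unordered pairs incl. self
  # absent-absent cells inflate agreement under the "all" universe
  expect_gt(suppressWarnings(replicate_kappa(all_u$a, all_u$b)), 0.9)
})

test_that("the per-million cutoff variant rescales by library size", {
  ctrl <- make_test_network(
    tibble::tibble(frag_a = c(1, 2), frag_b = c(3, 5), count = c(2, 8)),
    map10)
  co <- derive_cutoff(ctrl, per_million = TRUE)
  expect_equal(co, 8 * 1e6 / 10)
  gen <- make_test_network(
    tibble::tibble(frag_a = 1:3, frag_b = 5:7, count = c(30, 20, 10)),
    map10, cutoff_applied = FALSE)
  # cutoff 8/10 of the library: with library 60, threshold is 48
  kept <- apply_cutoff(gen, co, per_million = TRUE)
  expect_equal(nrow(kept$pairs), 0)
  kept2 <- apply_cutoff(gen, co, per_million = TRUE, library_size = 30)
  expect_equal(kept2$pairs$count, 30)  # threshold 24: only count 30 survives
})
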