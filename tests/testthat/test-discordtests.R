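test_that("the discordant-count test matches hand chi-square arithmetic", {
  r0 <- dct(50, 50)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_raw, 1)
  r1 <- dct(60, 40)
  expect_equal(r1$chi2, 4)
  expect_equal(r1$p_raw, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(r1$p_raw, 4), 0.0455)
  # reconstructed discordant-class counts: e = 3698.5, 2 * 895.5^2 / e
  r2 <- dct(4594, 2803)
  expect_equal(r2$chi2, 2 * 895.5^2 / 3698.5, tolerance = 1e-12)
  expect_equal(round(r2$chi2, 2), 433.65)
  expect_true(is.na(dct(0, 0)$chi2))
})

test_that("all-pairs DCT is Holm-adjusted jointly and flags the excess", {
  eq <- dct_all_pairs(c(RES_AB = 100, RES_AC = 100, RES_BC = 100))
  expect_true(all(eq$p_adj == 1))

  census13k <- dct_all_pairs(c(RES_AB = 4682, RES_AC = 4594, RES_BC = 2803))
  expect_equal(round(census13k$chi2[1], 3), round(2 * 44^2 / 4638, 3))
  expect_gt(census13k$p_adj[1], 0.05)          # AB vs AC indistinguishable
  expect_lt(census13k$p_adj[2], 1e-6)
  expect_lt(census13k$p_adj[3], 1e-6)
  expect_equal(census13k$excess_class[3], "RES_AC")

  ten <- dct_all_pairs(c(RES_AB = 10, RES_AC = 0, RES_BC = 0))
  expect_equal(ten$chi2[1], 10)
})

test_that("Holm adjustment is step-down with monotonicity and a cap", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1, 1))
  # bounds: >= raw, <= Bonferroni, order preserving
  set.seed(1)
  for (k in 1:20) {
    p <- stats::runif(sample(2:8, 1))
    h <- holm_adjust(p)
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(1, p * length(p)) + 1e-12))
    expect_equal(order(h[order(p)]), seq_along(p))
  }
})

test_that("the branch-length test detects shifted coalescence depths", {
  same <- blt(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_gt(same$p_raw, 0.99)

  # exact Mann-Whitney: complete separation of two samples of five
  sep <- blt(1:5, 6:10, scaled = TRUE)
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_raw, 2 / choose(10, 5), tolerance = 1e-10)
  expect_equal(round(sep$p_raw, 4), 0.0079)
  expect_equal(sep$direction, "class1")

  tied <- blt(rep(1, 5), rep(1, 5))
  expect_equal(tied$p_raw, 1)
  expect_true(is.na(tied$direction))

  short <- blt(1, c(1, 2))
  expect_true(is.na(short$p_raw))
})

test_that("pairwise BLT flags only the shifted class", {
  calls <- calls_of_counts(ab = 40, ac = 40, bc = 40)
  set.seed(11)
  calls$pair_depth_AB[calls$category == "RES_AB"] <- stats::rlnorm(40, 0, 0.2)
  calls$pair_depth_AC[calls$category == "RES_AC"] <-
    stats::rlnorm(40, -1.5, 0.2)   # strongly more recent
  calls$pair_depth_BC[calls$category == "RES_BC"] <- stats::rlnorm(40, 0, 0.2)
  res <- blt_pairwise(calls)
  expect_lt(res$p_adj[res$label == "RES_AB vs RES_AC"], 0.01)
  expect_lt(res$p_adj[res$label == "RES_AC vs RES_BC"], 0.01)
  expect_gt(res$p_adj[res$label == "RES_AB vs RES_BC"], 0.05)
  expect_equal(res$direction[res$label == "RES_AC vs RES_BC"], "RES_AC")

  # a class with fewer than two depths yields NA rows, others survive
  calls2 <- calls_of_counts(ab = 10, ac = 1, bc = 10)
  calls2$pair_depth_AB[calls2$category == "RES_AB"] <- 1:10
  calls2$pair_depth_AC[calls2$category == "RES_AC"] <- 1
  calls2$pair_depth_BC[calls2$category == "RES_BC"] <- 1:10
  res2 <- blt_pairwise(calls2)
  expect_true(is.na(res2$p_raw[res2$label == "RES_AB vs RES_AC"]))
  expect_false(is.na(res2$p_raw[res2$label == "RES_AB vs RES_BC"]))
})

test_that("trio runs reduce to the lineage run for singleton lineages", {
  cfg <- simulation_config(T_internal = 0.3, n_genes = 120, seed = 21,
                           taxa = abc_taxa())
  d <- simulate_dataset(cfg, trees = TRUE)
  gts <- lapply(d$genes, `[[`, "gene_tree")
  m <- abc_map()
  tr <- run_trios(gts, m)
  expect_length(tr, 1L)
  direct <- dct_all_pairs(classify_gene_trees(gts, m))
  expect_equal(tr[[1]]$dct$chi2, direct$chi2)

  # two hyrax species -> exactly two trios
  cfg2 <- simulation_config(T_internal = 0.3, n_genes = 40, seed = 22)
  d2 <- simulate_dataset(cfg2, trees = TRUE)
  tr2 <- run_trios(lapply(d2$genes, `[[`, "gene_tree"), paen_map())
  expect_length(tr2, 2L)
})

test_that("the verdict rules name the introgressed pair or ILS alone", {
  dct_res <- dct_all_pairs(c(RES_AB = 500, RES_AC = 700, RES_BC = 400))
  blt_res <- blt_pairwise(calls_of_counts(ab = 2, ac = 2, bc = 2))
  v <- interpret(dct_res, blt_res, reference = "RES_AB")
  expect_true(any(grepl("A-C introgression \\(DCT", v)))

  none <- interpret(dct_all_pairs(c(RES_AB = 100, RES_AC = 100,
                                    RES_BC = 100)),
                    blt_res, reference = "RES_AB")
  expect_match(none, "ILS alone")

  # conflicting DCT and BLT signals are both reported and flagged
  calls <- calls_of_counts(ab = 30, ac = 30, bc = 30)
  set.seed(4)
  calls$pair_depth_AB[calls$category == "RES_AB"] <- stats::rlnorm(30, 0, .1)
  calls$pair_depth_AC[calls$category == "RES_AC"] <- stats::rlnorm(30, 0, .1)
  calls$pair_depth_BC[calls$category == "RES_BC"] <-
    stats::rlnorm(30, -2, .1)
  v2 <- interpret(dct_res, blt_pairwise(calls), reference = "RES_AB")
  expect_true(any(grepl("different pairs", v2)))
})
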