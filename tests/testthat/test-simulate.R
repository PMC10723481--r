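test_that("datasets are reproducible bit-for-bit from the seed", {
  cfg <- simulation_config(T_internal = 0.2, n_genes = 15, seed = 11)
  d1 <- simulate_dataset(cfg, trees = TRUE)
  d2 <- simulate_dataset(cfg, trees = TRUE)
  nw1 <- vapply(Filter(function(g) !is.null(g$gene_tree), d1$genes),
                function(g) write_gene_tree(g$gene_tree), character(1))
  nw2 <- vapply(Filter(function(g) !is.null(g$gene_tree), d2$genes),
                function(g) write_gene_tree(g$gene_tree), character(1))
  expect_identical(nw1, nw2)
  expect_identical(d1$calls, d2$calls)
  # a different seed gives different data
  d3 <- simulate_dataset(simulation_config(T_internal = 0.2, n_genes = 15,
                                           seed = 12), trees = TRUE)
  expect_false(identical(d1$calls$stem_length, d3$calls$stem_length))
})

test_that("an overwhelming internal branch fixes the concordant topology", {
  cfg <- simulation_config(T_internal = 50, n_genes = 200, seed = 3,
                           taxa = abc_taxa())
  d <- simulate_dataset(cfg, trees = FALSE, supports = FALSE)
  expect_true(all(d$calls$category == "RES_AB"))
})

test_that("simulated calls match the classifier on the rendered trees", {
  m <- paen_map()
  cfg <- simulation_config(T_internal = 0.15, gamma = 0.2, poly_noise = 0.15,
                           missing_rate = 0.05, rate_sigma = 0.3,
                           n_genes = 150, seed = 13)
  d <- simulate_dataset(cfg, trees = TRUE)
  eqna <- function(a, b) (is.na(a) && is.na(b)) ||
    (!is.na(a) && !is.na(b) && abs(a - b) < 1e-6)
  checked <- 0L
  for (i in seq_along(d$genes)) {
    g <- d$genes[[i]]
    if (is.null(g$gene_tree) || length(g$gene_tree$phy$tip.label) < 4) next
    cl <- classify_gene_tree(g$gene_tree, m)
    s <- d$calls[i, ]
    expect_equal(cl$category, s$category)
    expect_true(eqna(cl$stem_length, s$stem_length))
    expect_true(eqna(cl$stem_support, s$stem_support))
    expect_true(eqna(cl$pair_depth_AB, s$pair_depth_AB))
    expect_true(eqna(cl$pair_depth_AC, s$pair_depth_AC))
    expect_true(eqna(cl$pair_depth_BC, s$pair_depth_BC))
    expect_true(eqna(cl$total_tree_length, s$total_tree_length))
    checked <- checked + 1L
  }
  expect_gt(checked, 100L)
})

test_that("discordant classes are symmetric without gene flow", {
  # equal AC/BC counts and equal mean coalescence depths at gamma = 0
  n_sig <- 0L
  depth_diffs <- numeric(40)
  for (r in 1:40) {
    cfg <- simulation_config(T_internal = 0.2, n_genes = 800,
                             seed = 7000 + r, taxa = abc_taxa())
    d <- simulate_dataset(cfg, trees = FALSE, supports = FALSE)
    nac <- sum(d$calls$category == "RES_AC")
    nbc <- sum(d$calls$category == "RES_BC")
    if (stats::binom.test(nac, nac + nbc)$p.value < 0.05) n_sig <- n_sig + 1L
    depth_diffs[r] <-
      mean(d$calls$pair_depth_AC[d$calls$category == "RES_AC"]) -
      mean(d$calls$pair_depth_BC[d$calls$category == "RES_BC"])
  }
  expect_lte(n_sig, 4L)       # >= 90% of replicates non-significant
  expect_lt(abs(mean(depth_diffs)), 3 * stats::sd(depth_diffs) / sqrt(40))
})

test_that("introgressed genes coalesce more recently in the donor pair", {
  cfg <- simulation_config(T_internal = 0.2, gamma = 0.3, donor = "C",
                           recipient = "A", t_m = 0.1, n_genes = 3000,
                           seed = 17, taxa = abc_taxa())
  d <- simulate_dataset(cfg, trees = FALSE, supports = FALSE)
  ac <- d$calls$pair_depth_AC[d$calls$category == "RES_AC"]
  bc <- d$calls$pair_depth_BC[d$calls$category == "RES_BC"]
  expect_lt(stats::median(ac), stats::median(bc))
  expect_gt(sum(d$calls$category == "RES_AC"),
            sum(d$calls$category == "RES_BC"))
})

test_that("coalescent units convert to substitutions per site via mu", {
  cfg <- simulation_config(T_internal = 1, mu = 0.01, rate_sigma = 0,
                           n_genes = 40, seed = 19, taxa = abc_taxa())
  d <- simulate_dataset(cfg, trees = TRUE)
  for (g in d$genes[1:5]) {
    phy <- g$gene_tree$phy
    # with no rate variation the (unrooted) tree is ultrametric: every
    # tip triple satisfies the three-point condition
    dm <- ape::cophenetic.phylo(phy)
    tips <- phy$tip.label
    for (tri in utils::combn(tips, 3L, simplify = FALSE)) {
      dd <- sort(c(dm[tri[1], tri[2]], dm[tri[1], tri[3]],
                   dm[tri[2], tri[3]]))
      expect_lt(dd[3] - dd[2], 1e-8)
    }
  }
  # total length scales linearly with mu on the same seed
  cfg2 <- simulation_config(T_internal = 1, mu = 0.02, rate_sigma = 0,
                            n_genes = 40, seed = 19, taxa = abc_taxa())
  d2 <- simulate_dataset(cfg2, trees = FALSE, supports = FALSE)
  expect_equal(d2$calls$total_tree_length, 2 * d$calls$total_tree_length,
               tolerance = 1e-9)
})

test_that("sequence simulation matches the JC expected divergence", {
  gt <- polytomyprobe:::new_gene_tree(
    "g", ape::read.tree(text = "(a:0.375,b:0.375);"))
  set.seed(23)
  aln <- simulate_alignment(gt, 30000L)   # 90 kb, total distance 0.75
  pdiff <- mean(aln$mat["a", ] != aln$mat["b", ])
  expected <- 0.75 * (1 - exp(-4 * 0.75 / 3))
  se <- sqrt(expected * (1 - expected) / 90000)
  expect_lt(abs(pdiff - expected), 3 * se)
  # base composition is near uniform under the symmetric model
  expect_lt(max(abs(table(aln$mat) / length(aln$mat) - 0.25)), 0.01)
  # a zero-length tree copies the root sequence everywhere
  gt0 <- polytomyprobe:::new_gene_tree(
    "g", ape::read.tree(text = "(a:0,b:0);"))
  aln0 <- simulate_alignment(gt0, 100L)
  expect_identical(aln0$mat["a", ], aln0$mat["b", ])
})

test_that("noise and missingness produce the intended call categories", {
  cfg <- simulation_config(T_internal = 0.1, poly_noise = 0.1,
                           n_genes = 4000, seed = 29)
  d <- simulate_dataset(cfg, trees = FALSE, supports = FALSE)
  frac_poly <- mean(d$calls$category == "NONMONOPHYLETIC")
  expect_lt(abs(frac_poly - 0.1), 0.015)

  cfg2 <- simulation_config(T_internal = 0.1, missing_rate = 0.3,
                            n_genes = 500, seed = 31, taxa = abc_taxa())
  d2 <- simulate_dataset(cfg2, trees = FALSE, supports = FALSE)
  expect_gt(sum(d2$calls$category == "NONDECISIVE"), 0)

  # poly noise is impossible with singleton lineages only
  expect_error(simulate_dataset(
    simulation_config(poly_noise = 0.5, n_genes = 5, seed = 1,
                      taxa = abc_taxa()), trees = FALSE),
    "two species")
})

test_that("the Paenungulata preset shows the motivating dataset's signatures", {
  cfg <- preset_paenungulata(n_genes = 4000, seed = 37)
  d <- simulate_dataset(cfg, trees = FALSE)
  cen <- census(d$calls)
  ord <- order(cen$percent_decisive, decreasing = TRUE)
  expect_equal(names(cen$percent_decisive)[ord[1]], "RES_AB")
  expect_equal(names(cen$percent_decisive)[ord[2]], "RES_AC")
  # mostly short stems and mostly moderate supports
  expect_lt(cen$frac_stem_gt, 0.15)
  expect_lt(mean(d$calls$stem_support >= 95, na.rm = TRUE), 0.1)
  # the discordant count test on the preset favours the simulated C->A pulse
  dcts <- dct_all_pairs(d$calls)
  expect_equal(dcts$excess_class[dcts$label == "RES_AC vs RES_BC"], "RES_AC")
})
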