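test_that("gene trees classify onto the three resolutions", {
  m <- paen_map()
  c1 <- classify_gene_tree(gt_from_newick(
    "(((Elephant:1,(Procavia:1,Heterohyrax:1):1):0.5,Manatee:1):1,Outgroup:1);"), m)
  expect_equal(c1$category, "RES_AB")
  expect_equal(c1$stem_length, 0.5)
  expect_true(c1$group_monophyletic)

  c2 <- classify_gene_tree(gt_from_newick(
    "(((Elephant:1,Manatee:1)97:0.02,Procavia:1):1,Outgroup:1);"), m)
  expect_equal(c2$category, "RES_AC")
  expect_equal(c2$stem_support, 97)
  expect_equal(c2$stem_length, 0.02)

  # all Sirenia taxa absent -> not decisive
  c3 <- classify_gene_tree(gt_from_newick(
    "((Elephant:1,Procavia:1):1,Outgroup:1);"), m)
  expect_equal(c3$category, "NONDECISIVE")

  # hyraxes split across the tree -> polyphyletic lineage
  c4 <- classify_gene_tree(gt_from_newick(
    "((Elephant:1,Procavia:1):1,(Heterohyrax:1,Manatee:1):1,Outgroup:1);"), m)
  expect_equal(c4$category, "NONMONOPHYLETIC")
})

test_that("classification is invariant to rotation and re-rooting", {
  m <- paen_map()
  nwk <- "(((Elephant:1,(Procavia:1,Heterohyrax:1)88:0.3)91:0.5,Manatee:1):1,Outgroup:2);"
  base <- classify_gene_tree(gt_from_newick(nwk), m)
  phy <- ape::read.tree(text = nwk)
  set.seed(3)
  for (k in 1:6) {
    p2 <- ape::rotateConstr(phy, sample(phy$tip.label))
    p2 <- ape::root(ape::unroot(p2), outgroup = sample(phy$tip.label, 1),
                    resolve.root = TRUE, edgelabel = TRUE)
    alt <- classify_gene_tree(polytomyprobe:::new_gene_tree(
      "g", p2, polytomyprobe:::parse_supports(p2$node.label,
                                              support_rule())), m)
    expect_equal(alt$category, base$category)
    expect_equal(alt$stem_length, base$stem_length)
    expect_equal(alt$stem_support, base$stem_support)
    expect_equal(alt$pair_depth_AB, base$pair_depth_AB)
  }
})

test_that("pair depth is half the anchor-to-anchor patristic distance", {
  m <- lineage_map(A = "A", B = "B", C = "C", outgroup = "O")
  gt <- gt_from_newick("(((A:0.02,C:0.03):0.01,B:0.05):0.01,O:0.1);")
  expect_equal(pair_depth(gt, m, "AC"), 0.025)
  expect_equal(pair_depth(gt, m, "AB"), 0.04)   # (0.02+0.01+0.05)/2
  # ultrametric tree: depth equals node height
  gtu <- gt_from_newick("(((A:1,C:1):2,B:3):1,O:4);")
  expect_equal(pair_depth(gtu, m, "AC"), 1)
  expect_equal(pair_depth(gtu, m, "AB"), 3)
})

test_that("census counts partition the genes and percentages are decisive-based", {
  calls <- calls_of_counts(ab = 3, ac = 2, bc = 1)
  cen <- census(calls)
  expect_equal(sum(cen$counts), nrow(calls))
  expect_equal(unname(cen$percent_decisive), c(50.0, 33.3, 16.7))

  mixed <- calls_of_counts(ab = 5, ac = 2, bc = 1, poly = 3, nondec = 4)
  cm <- census(mixed)
  expect_equal(sum(cm$counts), 15L)
  expect_equal(cm$n_decisive, 8L)

  all_nd <- calls_of_counts(nondec = 6)
  all_nd$group_monophyletic <- NA
  cnd <- census(all_nd)
  expect_equal(cnd$n_decisive, 0L)
  expect_true(all(is.na(cnd$percent_decisive)))
  expect_true(is.na(cnd$monophyly_rate))
})

test_that("support-length correlation matches a hand Pearson computation", {
  calls <- calls_of_counts(ab = 4)
  calls$stem_length <- c(0.01, 0.02, 0.03, 0.04)
  calls$stem_support <- c(50, 60, 70, 95)
  res <- support_length_correlation(calls)
  # hand Pearson: r = cov(x, y) / (sd(x) sd(y))
  x <- calls$stem_length; y <- calls$stem_support
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r[res$category == "RES_AB"], r_hand, tolerance = 1e-10)
  expect_equal(round(r_hand, 4), 0.9694)

  # exactly linear -> r = 1; constant support -> undefined
  calls$stem_support <- 100 * calls$stem_length
  expect_equal(support_length_correlation(calls)$r[1], 1)
  calls$stem_support <- rep(50, 4)
  expect_true(is.na(support_length_correlation(calls)$r[1]))
})

test_that("a taxon in two lineages is a configuration error", {
  expect_error(lineage_map(A = "x", B = c("x", "y"), C = "z", outgroup = "o"),
               "two lineages")
})
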