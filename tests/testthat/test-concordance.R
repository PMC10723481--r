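test_that("internode certainty has its closed-form limits and symmetry", {
  expect_equal(internode_certainty(10, 0), 1)
  expect_equal(internode_certainty(7, 7), 0)
  expect_equal(internode_certainty(4682, 4594),
               internode_certainty(4594, 4682))
  # strictly increasing in the margin at fixed total
  tot <- 1000
  ics <- vapply(0:100, function(d) internode_certainty(tot / 2 + d,
                                                       tot / 2 - d),
                numeric(1))
  expect_true(all(diff(ics) > 0))
  # small-margin quadratic approximation: IC ~ (2/ln 2) (p1 - 1/2)^2
  for (p1 in c(0.501, 0.505, 0.509)) {
    approx <- (2 / log(2)) * (p1 - 0.5)^2
    expect_equal(internode_certainty(p1 * 1e6, (1 - p1) * 1e6), approx,
                 tolerance = 0.01)
  }
  expect_true(is.na(internode_certainty(0, 0)))
})

test_that("ICA is zero at equal frequencies and reduces to IC for k = 2", {
  expect_equal(internode_certainty_all(c(0.5, 0.5)), 0)
  expect_equal(internode_certainty_all(rep(1 / 5, 5)), 0)
  for (pr in list(c(0.6, 0.4), c(0.9, 0.1))) {
    expect_equal(internode_certainty_all(pr),
                 internode_certainty(pr[1] * 100, pr[2] * 100))
  }
  # a dominant split drives ICA towards 1
  expect_gt(internode_certainty_all(c(0.999, 5e-4, 5e-4)), 0.98)
  expect_true(is.na(internode_certainty_all(0.7)))
})

test_that("gene concordance factors reproduce the reconstructed census", {
  # 13,388 trees: 34.97% on the leading split and an 88-tree margin give
  # 4,682 / 4,594 / 2,803 resolved trees, leaving 1,309 polyphyletic (the
  # printed four percentages sum to 99.99, so one of them is off by 0.01
  # from any exactly consistent reconstruction; it lands on gDFP)
  bc <- concordance_factors(c(RES_AB = 4682, RES_AC = 4594, RES_BC = 2803,
                              NONMONOPHYLETIC = 1309))
  expect_equal(round(bc$gCF, 2), 34.97)
  expect_equal(round(bc$gDF1, 2), 34.31)
  expect_equal(round(bc$gDF2, 2), 20.94)
  expect_lt(abs(bc$gDFP - 9.77), 0.015)
  expect_equal(bc$gCF + bc$gDF1 + bc$gDF2 + bc$gDFP, 100)
  expect_equal(sum(bc$quartet_support), 1)
  expect_equal(round(unname(bc$quartet_support), 2), c(0.39, 0.38, 0.23))

  expect_equal(concordance_factors(c(RES_AB = 10, RES_AC = 0, RES_BC = 0,
                                     NONMONOPHYLETIC = 0))$gCF, 100)
  b3 <- concordance_factors(c(RES_AB = 1, RES_AC = 1, RES_BC = 1,
                              NONMONOPHYLETIC = 0))
  expect_equal(round(b3$gCF, 1), 33.3)
  expect_equal(round(b3$gDFP, 1), 0)
  # no decisive trees -> everything undefined
  expect_true(is.na(concordance_factors(
    c(RES_AB = 0, RES_AC = 0, RES_BC = 0, NONMONOPHYLETIC = 5))$gCF))
})

test_that("site support counts decisive patterns per quartet", {
  m <- abc_map()
  aln <- codon_alignment("g", c(A = "AAAA", B = "AAAA", C = "CCCC",
                                O = "CCCC"))
  ss <- site_support(aln, m)
  expect_equal(ss$sCF_AB, 100)
  expect_equal(ss$s_AB, 4)

  # hand enumeration: a=ACAC b=CAAC c=ACCA o=CACA
  # col1 A,C,A,C -> ac|bo decisive; col2 C,A,C,A -> ac|bo; col3 A,A,C,C ->
  # ab|co; col4 C,C,A,A -> ab|co
  aln2 <- codon_alignment("g", c(A = "ACAC", B = "CAAC", C = "ACCA",
                                 O = "CACA"))
  ss2 <- site_support(aln2, m)
  expect_equal(unname(c(ss2$s_AB, ss2$s_AC, ss2$s_BC)), c(2, 2, 0))
  expect_equal(ss2$sCF_AB, 50)

  # columns containing a gap are excluded from all counts
  aln3 <- codon_alignment("g", c(A = "A-AA", B = "AAAA", C = "CCCC",
                                 O = "CCCC"))
  expect_equal(site_support(aln3, m)$s_AB, 3)
})

test_that("sCF distribution summarises the reference split across genes", {
  sup <- lapply(c(30, 32, 40), function(v)
    structure(list(gene_id = "g", sCF_AB = v), class = "site_support"))
  d <- scf_distribution(sup, "AB")
  expect_equal(d$median, 32)
  expect_equal(d$mean, 34)
  one <- scf_distribution(sup[2], "AB")
  expect_equal(one$median, one$mean)
})

test_that("long simulated stems drive the reference sCF towards 100", {
  cfg <- simulation_config(T_internal = 50, mu = 0.05, n_genes = 3,
                           seq_len = 400, seed = 5, taxa = abc_taxa())
  d <- simulate_dataset(cfg, alignments = TRUE)
  m <- abc_map()
  scfs <- vapply(d$genes, function(g) site_support(g$alignment, m)$sCF_AB,
                 numeric(1))
  expect_true(all(scfs > 80))
})
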