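test_that("site likelihoods match two-taxon analytic values", {
  aln_same <- codon_alignment("g", c(a = "A", b = "A"))
  zero <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(site_loglik(aln_same, zero), log(0.25), tolerance = 1e-10)

  d01 <- ape::read.tree(text = "(a:0.05,b:0.05);")
  expect_equal(site_loglik(aln_same, d01),
               log(0.25 * (0.25 + 0.75 * exp(-4 * 0.1 / 3))),
               tolerance = 1e-10)
  expect_equal(round(site_loglik(aln_same, d01), 4), -1.4846)

  aln_diff <- codon_alignment("g", c(a = "A", b = "C"))
  expect_equal(site_loglik(aln_diff, d01),
               log(0.25 * 0.25 * (1 - exp(-4 * 0.1 / 3))),
               tolerance = 1e-10)
  expect_equal(round(site_loglik(aln_diff, d01), 4), -4.8534)
})

test_that("the engine agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  set.seed(2)
  tr <- ape::rtree(6)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.6)
  m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 6 * 80, TRUE,
                     prob = c(.23, .23, .23, .23, .04, .04)), 6)
  rownames(m) <- tr$tip.label
  aln <- codon_alignment("g", m)
  pd <- phangorn::phyDat(m, type = "DNA")
  expect_equal(sum(site_loglik(aln, tr, model_jc69())),
               phangorn::pml(tr, pd)$logLik, tolerance = 1e-6)
  # phangorn Q order: ac, ag, at, cg, ct, gt
  expect_equal(sum(site_loglik(aln, tr,
                               model_hky85(2.5, c(0.3, 0.2, 0.3, 0.2),
                                           gamma_alpha = 0.5))),
               phangorn::pml(tr, pd, Q = c(1, 2.5, 1, 1, 2.5, 1),
                             bf = c(0.3, 0.2, 0.3, 0.2), k = 4,
                             shape = 0.5)$logLik,
               tolerance = 1e-6)
})

test_that("branch-length optimisation collapses identical sequences", {
  aln <- codon_alignment("g", c(a = strrep("ACGT", 10),
                                b = strrep("ACGT", 10),
                                c = strrep("ACGT", 10),
                                o = strrep("ACGT", 10)))
  fit <- optimize_branch_lengths(aln, ape::read.tree(text = "((a,b),c,o);"))
  expect_true(all(fit$phy$edge.length <= 1e-6))
  expect_equal(fit$lnL, 40 * log(0.25), tolerance = 1e-5)
})

test_that("optimisation recovers the generating branch lengths", {
  true <- ape::read.tree(text = "((a:0.08,b:0.12):0.15,c:0.05,o:0.3);")
  gt <- polytomyprobe:::new_gene_tree("g", true)
  set.seed(9)
  aln <- simulate_alignment(gt, 20000L)   # 60 kb
  fit <- optimize_branch_lengths(aln, ape::read.tree(text = "((a,b),c,o);"))
  est <- fit$phy$edge.length[match(
    paste(fit$phy$edge[, 1], fit$phy$edge[, 2]),
    paste(true$edge[, 1], true$edge[, 2]))]
  expect_equal(est, true$edge.length, tolerance = 0.05)
})

test_that("RELL bootstrap proportions and weights behave at the extremes", {
  m <- rbind(t1 = rep(-1, 50), t2 = rep(-1.2, 50))
  rs <- rell_suite(m, n_boot = 2000, seed = 1)
  expect_equal(unname(rs$bp_RELL), c(1, 0))
  expect_lt(rs$p_KH[2], 5e-4)

  ident <- rbind(t1 = rnorm(40, -2), t2 = 0)
  ident[2, ] <- ident[1, ]
  rs2 <- rell_suite(ident, n_boot = 1000, seed = 1)
  expect_equal(unname(rs2$c_ELW), c(0.5, 0.5))
  expect_equal(unname(rs2$bp_RELL), c(0.5, 0.5))
  expect_equal(rs2$p_KH[[2]], 1)

  # mean-zero symmetric per-site differences: no evidence either way
  set.seed(8)
  d <- rnorm(200)
  m3 <- rbind(t1 = rep(-2, 200), t2 = -2 + (d - mean(d)))
  rs3 <- rell_suite(m3, n_boot = 5000, seed = 2)
  expect_gt(rs3$p_KH[2], 0.9)
})

test_that("the KH p-value agrees with exhaustive resampling enumeration", {
  # with S sites, the RELL null is the distribution of the centred delta
  # over all S^S ordered site resamples; S = 5 and 6 are fully enumerable
  for (S in c(5L, 6L)) {
    set.seed(S)
    d <- round(stats::rnorm(S, 0.3, 1.2), 2)
    m <- rbind(ref = rep(-2, S), alt = -2 + d)
    idx <- as.matrix(expand.grid(rep(list(seq_len(S)), S)))
    sums <- matrix(d[idx], nrow(idx), S)
    delta_b <- rowSums(sums)
    d_obs <- sum(d)
    p_exact <- mean(abs(delta_b - mean(delta_b)) >= abs(d_obs))
    rs <- rell_suite(m, n_boot = 20000, seed = 3, reference = 1)
    expect_equal(unname(rs$p_KH[2]), p_exact, tolerance = 0.02)
  }
})

test_that("RELL p-values ignore per-site constants shared by all trees", {
  set.seed(5)
  m <- rbind(a = rnorm(100, -3), b = rnorm(100, -3), c = rnorm(100, -3))
  shift <- rnorm(100, 0, 2)
  m2 <- sweep(m, 2, shift, "+")
  r1 <- rell_suite(m, n_boot = 3000, seed = 9)
  r2 <- rell_suite(m2, n_boot = 3000, seed = 9)
  expect_equal(r1$p_KH, r2$p_KH, tolerance = 1e-12)
  expect_equal(r1$p_SH, r2$p_SH, tolerance = 1e-12)
  expect_equal(r1$p_WSH, r2$p_WSH, tolerance = 1e-12)
})

test_that("the AU test tracks the plain bootstrap for separated trees", {
  set.seed(12)
  m <- rbind(good = rnorm(300, -2), bad = rnorm(300, -2.05))
  m["good", ] <- m["bad", ] + abs(rnorm(300, 0.05, 0.05))
  au <- au_test(m, n_boot = 2000, seed = 4)
  expect_gt(au[["good"]], 0.95)
  expect_lt(au[["bad"]], 0.05)

  ident <- rbind(a = rnorm(200, -2), b = 0)
  ident["b", ] <- ident["a", ]
  au2 <- au_test(ident, n_boot = 1000, seed = 4)
  expect_equal(unname(c(au2)), c(0.5, 0.5), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("a long focal stem rejects the polytomy, a collapsed one never", {
  taxa <- abc_taxa()
  m <- abc_map()
  cfg_null <- simulation_config(T_internal = 0, t_out = 3, n_genes = 2,
                                seq_len = 120, seed = 31, taxa = taxa)
  d0 <- simulate_dataset(cfg_null, alignments = TRUE)
  r0 <- polytomy_test_gene(d0$genes[[1]]$alignment, m, n_boot = 3000,
                           au_n_boot = 1000, seed = 1)
  expect_gte(max(r0$deltaL_AB, r0$deltaL_AC, r0$deltaL_BC), -1e-6)

  # a 0.1 subs/site focal stem with unsaturated pendant branches
  cfg_strong <- simulation_config(T_internal = 10, t_out = 11.5, mu = 0.01,
                                  n_genes = 1, seq_len = 500, seed = 32,
                                  taxa = taxa)
  d1 <- simulate_dataset(cfg_strong, alignments = TRUE)
  r1 <- polytomy_test_gene(d1$genes[[1]]$alignment, m, n_boot = 5000,
                           au_n_boot = 1000, seed = 1)
  expect_true(r1$reject_polytomy)
  expect_lt(r1$p_KH_AB, 0.01)
  expect_lt(r1$c_ELW_poly, 0.05)
  expect_gt(r1$deltaL_AB, 5)
  # weights are distributions
  expect_equal(r1$bp_RELL_poly + r1$bp_RELL_AB + r1$bp_RELL_AC +
                 r1$bp_RELL_BC, 1, tolerance = 1e-9)
  expect_equal(r1$c_ELW_poly + r1$c_ELW_AB + r1$c_ELW_AC + r1$c_ELW_BC, 1,
               tolerance = 1e-9)
})

test_that("rejection summaries count genes per test", {
  taxa <- abc_taxa()
  m <- abc_map()
  cfg <- simulation_config(T_internal = 0.1, n_genes = 4, seq_len = 80,
                           seed = 33, taxa = taxa)
  d <- simulate_dataset(cfg, alignments = TRUE)
  rows <- do.call(rbind, lapply(d$genes[1:3], function(g)
    polytomy_test_gene(g$alignment, m, n_boot = 2000, au_n_boot = 1000,
                       seed = 2)))
  s <- summarize_rejections(rows)
  expect_equal(s$n, 3)
  expect_true(all(s$percent_reject >= 0 & s$percent_reject <= 100))
  expect_named(s$deltaL_summary, c("deltaL_AB", "deltaL_AC", "deltaL_BC"))
})
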