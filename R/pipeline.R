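#' Probe whether a contested triplet branch is resolvable
#'
#' The package's main entry point: takes per-gene trees (and optionally
#' codon alignments), classifies every gene onto the focal triplet, and
#' assembles the full evidence table — census, concordance factors with
#' internode certainty, the coalescent triplet summary, the
#' discordant-count and branch-length introgression tests with a rule-based
#' verdict, per-gene covariate summaries and, optionally, the per-gene
#' polytomy topology tests.
#'
#' @param trees List of `gene_tree` objects (e.g. from
#'   [read_gene_trees()]) or a `sim_dataset`.
#' @param lineages A [lineage_map()]; taken from the simulator's taxa when
#'   `trees` is a `sim_dataset` and `lineages` is missing.
#' @param alignments Optional named list of `codon_alignment` objects
#'   keyed by gene id; enables site concordance, covariates and topology
#'   tests.
#' @param run_topotests Run the per-gene polytomy tests (slow; requires
#'   alignments).
#' @param mode Classification mode, see [classify_gene_tree()].
#' @param alpha Significance level.
#' @param n_boot RELL replicates for topology tests.
#' @param boot_reps Gene-tree bootstrap pseudo-replicates.
#' @param lambda Prior rate for the local posterior.
#' @param seed Seed for every stochastic step (bootstrap, quartet
#'   subsampling, RELL).
#' @param max_scf_quartets Per-gene quartet cap for site concordance.
#' @return An object of class `polytomy_probe`.
#' @export
polytomy_probe <- function(trees, lineages = NULL, alignments = NULL,
                           run_topotests = FALSE,
                           mode = c("stem", "representative"),
                           alpha = 0.05, n_boot = 10000L, boot_reps = 100L,
                           lambda = 0.5, seed = 1L,
                           max_scf_quartets = 100L) {
  mode <- match.arg(mode)
  failed <- character(0)
  calls <- NULL
  if (inherits(trees, "sim_dataset")) {
    if (is.null(lineages))
      lineages <- lineage_map(A = trees$cfg$taxa$A, B = trees$cfg$taxa$B,
                              C = trees$cfg$taxa$C,
                              outgroup = trees$cfg$taxa$outgroup)
    if (is.null(alignments)) {
      alignments <- lapply(trees$genes, `[[`, "alignment")
      names(alignments) <- vapply(trees$genes, `[[`, character(1), "gene_id")
      alignments <- Filter(Negate(is.null), alignments)
      if (length(alignments) == 0L) alignments <- NULL
    }
    # the simulator records each gene's classification exactly as the
    # classifier would produce it (a tested equivalence), so reuse it
    calls <- trees$calls
  }
  stopifnot(inherits(lineages, "lineage_map"), alpha > 0, alpha < 1)

  if (is.null(calls)) {
    calls <- vector("list", length(trees))
    for (i in seq_along(trees)) {
      calls[[i]] <- tryCatch(classify_gene_tree(trees[[i]], lineages, mode),
                             error = function(e) {
                               failed <<- c(failed, conditionMessage(e))
                               NULL
                             })
    }
    calls <- do.call(rbind, c(Filter(Negate(is.null), calls),
                              list(make.row.names = FALSE)))
    class(calls) <- c("triplet_calls", "data.frame")
  }
  if (nrow(calls) == 0L) stop("no gene tree could be classified")

  cen <- census(calls)
  conc <- concordance_factors(calls)
  sptree <- triplet_species_tree(calls, lambda = lambda, n_reps = boot_reps,
                                 seed = seed)
  dct_res <- dct_all_pairs(calls)
  blt_res <- blt_pairwise(calls, scaled = FALSE)
  blt_scaled <- blt_pairwise(calls, scaled = TRUE)
  verdict <- interpret(dct_res, rbind(blt_res, blt_scaled),
                       reference = sptree$topology, alpha = alpha)
  slc <- support_length_correlation(calls)

  scf <- covar <- topo <- NULL
  if (!is.null(alignments)) {
    supports <- list()
    covrows <- list()
    for (gid in names(alignments)) {
      aln <- alignments[[gid]]
      ss <- tryCatch(site_support(aln, lineages,
                                  max_quartets = max_scf_quartets,
                                  seed = seed),
                     error = function(e) NULL)
      if (!is.null(ss)) supports[[gid]] <- ss
      cl <- calls[calls$gene_id == gid, ]
      covrows[[gid]] <- gene_covariates(aln,
                                        call = if (nrow(cl)) cl[1L, ] else NULL,
                                        sitesupport = ss,
                                        reference = sub("RES_", "",
                                                        sptree$topology))
    }
    if (length(supports) > 0L)
      scf <- scf_distribution(supports,
                              reference = sub("RES_", "", sptree$topology))
    covar <- do.call(rbind, covrows)
    covar_tests <- list(
      length_by_class = group_compare(covar$length_bp, covar$category),
      gc_by_class = group_compare(covar$gc_content, covar$category),
      correlations = covariate_correlations(covar),
      gc_bins = tryCatch(gc_bins(covar), error = function(e) NULL))
    covar <- list(table = covar, tests = covar_tests)
    if (run_topotests) {
      rows <- list()
      for (gid in names(alignments)) {
        r <- tryCatch(polytomy_test_gene(alignments[[gid]], lineages,
                                         n_boot = n_boot, seed = seed,
                                         alpha = alpha),
                      error = function(e) {
                        failed <<- c(failed, paste0(gid, ": ",
                                                    conditionMessage(e)))
                        NULL
                      })
        if (!is.null(r)) rows[[gid]] <- r
      }
      if (length(rows) > 0L) {
        results <- do.call(rbind, rows)
        topo <- list(results = results,
                     summary = summarize_rejections(results, alpha = alpha))
      }
    }
  }

  structure(list(calls = calls, census = cen, concordance = conc,
                 species_tree = sptree, dct = dct_res, blt = blt_res,
                 blt_scaled = blt_scaled, verdict = verdict,
                 support_length = slc, scf = scf, covariates = covar,
                 topotests = topo, lineages = lineages, alpha = alpha,
                 seed = seed, n_failed = length(failed),
                 failures = failed),
            class = "polytomy_probe")
}

#' @export
print.polytomy_probe <- function(x, ...) {
  cat("Polytomy probe:", x$census$n, "gene trees,",
      x$census$n_decisive, "decisive\n")
  if (!anyNA(x$census$percent_decisive))
    cat("  resolutions:",
        paste(sprintf("%s %.1f%%", names(x$census$percent_decisive),
                      x$census$percent_decisive), collapse = ", "), "\n")
  cat(sprintf("  species tree %s, T = %.3f cu, local PP %.3f, IC %.3g, ICA %.3g\n",
              x$species_tree$topology, x$species_tree$T_hat,
              max(x$species_tree$local_pp), x$concordance$IC,
              x$concordance$ICA))
  cat("  verdict:", x$verdict[1L], "\n")
  if (!is.null(x$topotests))
    cat(sprintf("  polytomy rejected by %.1f%% of genes (KH, alpha = %g)\n",
                x$topotests$summary$percent_reject[["KH"]], x$alpha))
  invisible(x)
}

#' @export
summary.polytomy_probe <- function(object, ...) {
  x <- object
  print(x)
  cat("\n-- census --\n"); print(x$census)
  cat("\n-- concordance --\n"); print(x$concordance)
  cat("\n-- species tree --\n"); print(x$species_tree)
  cat("\n-- DCT --\n")
  print(x$dct[, c("label", "c1", "c2", "delta", "chi2", "p_raw", "p_adj")])
  cat("\n-- BLT (unscaled) --\n")
  print(x$blt[, c("label", "n1", "n2", "statistic", "p_raw", "p_adj",
                  "direction")])
  cat("\n-- BLT (scaled) --\n")
  print(x$blt_scaled[, c("label", "n1", "n2", "statistic", "p_raw", "p_adj",
                         "direction")])
  if (!is.null(x$scf))
    cat(sprintf("\nreference sCF: median %.1f%%, mean %.1f%% over %d genes\n",
                x$scf$median, x$scf$mean, x$scf$n))
  cat("\nverdict:\n")
  for (v in x$verdict) cat("  -", v, "\n")
  invisible(x)
}

#' @export
plot.polytomy_probe <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$scf)) 1 else 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cn <- x$concordance$counts[c("RES_AB", "RES_AC", "RES_BC",
                               "NONMONOPHYLETIC")]
  graphics::barplot(cn, names.arg = c("AB", "AC", "BC", "poly"),
                    ylab = "gene trees", main = "Triplet resolutions", ...)
  if (!is.null(x$scf))
    graphics::hist(x$scf$values, breaks = 20,
                   xlab = "reference sCF (%)", main = "Site concordance")
  invisible(x)
}

#' Simulate gene-tree datasets from a fitted probe
#'
#' Generates datasets under the multispecies coalescent with the internal
#' branch length estimated from the fitted object (no introgression; the
#' probe does not estimate a gene-flow rate).
#'
#' @param object A `polytomy_probe`.
#' @param nsim Number of datasets.
#' @param seed Base seed.
#' @param n_genes Genes per dataset; defaults to the fitted gene count.
#' @param ... Unused.
#' @return A list of `sim_dataset` objects.
#' @export
simulate.polytomy_probe <- function(object, nsim = 1L, seed = 1L,
                                    n_genes = NULL, ...) {
  n_genes <- n_genes %||% object$census$n
  lapply(seq_len(nsim), function(k) {
    cfg <- simulation_config(T_internal = object$species_tree$T_hat,
                             n_genes = n_genes,
                             seed = seed + k - 1L)
    simulate_dataset(cfg, trees = FALSE)
  })
}

#' Flatten a probe into a plain report list (JSON-ready)
#' @param x A `polytomy_probe`.
#' @return Nested list mirroring the object.
#' @export
as_report <- function(x) {
  stopifnot(inherits(x, "polytomy_probe"))
  rep <- list(
    n_genes = x$census$n,
    n_failed = x$n_failed,
    census = list(counts = as.list(x$census$counts),
                  percent_decisive = as.list(x$census$percent_decisive),
                  monophyly_rate = x$census$monophyly_rate,
                  frac_stem_gt = x$census$frac_stem_gt),
    concordance = list(gCF = x$concordance$gCF, gDF1 = x$concordance$gDF1,
                       gDF2 = x$concordance$gDF2, gDFP = x$concordance$gDFP,
                       quartet_support = as.list(x$concordance$quartet_support),
                       IC = x$concordance$IC, ICA = x$concordance$ICA,
                       reference = x$concordance$reference),
    species_tree = list(topology = x$species_tree$topology,
                        T_hat = x$species_tree$T_hat,
                        local_pp = as.list(x$species_tree$local_pp),
                        bootstrap_bp = as.list(x$species_tree$bootstrap_bp),
                        n_decisive = x$species_tree$n_decisive),
    dct = x$dct, blt = x$blt, blt_scaled = x$blt_scaled,
    verdict = x$verdict, alpha = x$alpha, seed = x$seed)
  if (!is.null(x$scf))
    rep$scf <- list(median = x$scf$median, mean = x$scf$mean, n = x$scf$n)
  if (!is.null(x$topotests))
    rep$topotests <- list(
      percent_reject = as.list(x$topotests$summary$percent_reject),
      n = x$topotests$summary$n)
  rep
}

#' Write a probe report as JSON
#' @param x A `polytomy_probe`.
#' @param path Output file.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(as_report(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a report's internal invariants
#'
#' Checks that concordance percentages sum to 100, local posteriors sum to
#' 1, IC lies in `[0, 1]`, p-values lie in `[0, 1]` and Holm-adjusted
#' p-values are at least the raw ones.
#'
#' @param report A report list (from [as_report()]) or a `polytomy_probe`.
#' @return List: `pass` (logical), `violations` (character).
#' @export
validate_report <- function(report) {
  if (inherits(report, "polytomy_probe")) report <- as_report(report)
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  if (length(report) == 0L) {
    return(list(pass = FALSE, violations = "empty report"))
  }
  co <- report$concordance
  if (!is.null(co) && !anyNA(unlist(co[c("gCF", "gDF1", "gDF2", "gDFP")]))) {
    chk(abs(co$gCF + co$gDF1 + co$gDF2 + co$gDFP - 100) < 0.05,
        "gCF + gDF1 + gDF2 + gDFP != 100")
    chk(co$IC >= 0 && co$IC <= 1, "IC outside [0,1]")
    chk(abs(sum(unlist(co$quartet_support)) - 1) < 1e-6,
        "quartet_support does not sum to 1")
  }
  st <- report$species_tree
  if (!is.null(st))
    chk(abs(sum(unlist(st$local_pp)) - 1) < 1e-6, "local_pp does not sum to 1")
  for (nm in c("dct", "blt", "blt_scaled")) {
    tb <- report[[nm]]
    if (is.null(tb)) next
    p <- tb$p_raw; pa <- tb$p_adj
    ok <- !is.na(p) & !is.na(pa)
    chk(all(p[ok] >= 0 & p[ok] <= 1 & pa[ok] <= 1), paste(nm, "p outside [0,1]"))
    chk(all(pa[ok] >= p[ok] - 1e-12), paste(nm, "Holm p_adj below p_raw"))
  }
  list(pass = length(v) == 0L, violations = v)
}

#' Run the pipeline from a configuration list
#'
#' Thin orchestration for scripted use: reads gene trees (and alignments if
#' given), builds the lineage map, runs [polytomy_probe()], writes the JSON
#' report and per-gene TSVs.
#'
#' @param config Named list (or YAML file path, parsed if the yaml package
#'   is installed) with elements `trees` (path), optional `alignments`
#'   (directory of FASTA), `lineages` (list with A, B, C, outgroup),
#'   optional `out_dir`, `alpha`, `seed`, `topotests`.
#' @return The `polytomy_probe` object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$trees) || is.null(config$lineages))
    stop("config must name 'trees' and 'lineages'")
  lm <- lineage_map(A = config$lineages$A, B = config$lineages$B,
                    C = config$lineages$C,
                    outgroup = config$lineages$outgroup)
  gts <- read_gene_trees(config$trees)
  alns <- NULL
  if (!is.null(config$alignments)) {
    files <- list.files(config$alignments, pattern = "\\.(fa|fasta)$",
                        full.names = TRUE)
    alns <- lapply(files, read_fasta_codon)
    names(alns) <- vapply(alns, `[[`, character(1), "gene_id")
  }
  probe <- polytomy_probe(gts, lm, alignments = alns,
                          run_topotests = isTRUE(config$topotests),
                          alpha = config$alpha %||% 0.05,
                          seed = config$seed %||% 1L)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(probe, file.path(config$out_dir, "report.json"))
    write_calls_tsv(probe$calls, file.path(config$out_dir, "calls.tsv"))
    if (!is.null(probe$topotests))
      utils::write.table(probe$topotests$results,
                         file.path(config$out_dir, "topotests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(probe)
}
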