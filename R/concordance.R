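#' Internode certainty of the two leading conflicting splits
#'
#' `IC = 1 + p1*log2(p1) + p2*log2(p2)` with `p_i = n_i/(n1+n2)`: 1 when one
#' split is unopposed, 0 when the two most frequent conflicting splits are
#' equally supported. Frequencies are counts of gene trees supporting each
#' split.
#'
#' @param n1,n2 Counts of gene trees supporting the two most frequent
#'   conflicting splits (`n1 >= n2`).
#' @return IC in `[0, 1]`, or `NA` if both counts are zero.
#' @examples
#' internode_certainty(4682, 4594)   # ~6.49e-5: near-maximal conflict
#' @export
internode_certainty <- function(n1, n2) {
  stopifnot(n1 >= 0, n2 >= 0)
  tot <- n1 + n2
  if (tot == 0) return(NA_real_)
  p <- c(n1, n2) / tot
  terms <- ifelse(p > 0, p * log2(p), 0)
  1 + sum(terms)
}

#' Internode certainty over all conflicting splits (ICA)
#'
#' Frequencies are renormalised and scored with base-k entropy:
#' `ICA = 1 + sum(p_i * log_k(p_i))`. Zero when all k splits are equally
#' frequent; tends to 1 when one split dominates. Equals IC when `k = 2`.
#'
#' @param freqs Numeric vector (length >= 2) of positive split frequencies
#'   or counts.
#' @return ICA in `[-1, 1]`, `NA` when fewer than two splits are given.
#' @examples
#' internode_certainty_all(c(0.3497, 0.3431, 0.2094))  # ~0.02
#' @export
internode_certainty_all <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  k <- length(freqs)
  if (k < 2L) return(NA_real_)
  stopifnot(all(freqs > 0))
  p <- freqs / sum(freqs)
  1 + sum(p * log(p) / log(k))
}

#' Gene concordance factors for the focal branch
#'
#' From classified gene trees: gCF is the percentage supporting the species
#' tree's resolution, gDF1/gDF2 the two discordant resolutions (gDF1 the
#' more frequent), and gDFP the percentage discordant through lineage
#' polyphyly. The denominator is decisive + polyphyletic trees. Quartet
#' support is the normalised frequency of each resolution among resolved
#' trees only. IC is computed from the gCF/gDF1 counts and ICA from the
#' three resolved-class counts.
#'
#' @param calls A `triplet_calls` data.frame, or a named count vector with
#'   elements `RES_AB`, `RES_AC`, `RES_BC`, `NONMONOPHYLETIC` (and
#'   optionally `NONDECISIVE`).
#' @param reference Species-tree resolution the gCF attaches to; default the
#'   most frequent class (see [msc_topology()]).
#' @return List of class `branch_concordance`.
#' @export
concordance_factors <- function(calls, reference = NULL) {
  cn <- call_counts(calls)
  res <- cn[c("RES_AB", "RES_AC", "RES_BC")]
  if (sum(res) == 0L)
    return(structure(list(counts = cn, reference = NA_character_,
                          gCF = NA_real_, gDF1 = NA_real_, gDF2 = NA_real_,
                          gDFP = NA_real_, quartet_support = rep(NA_real_, 3),
                          IC = NA_real_, ICA = NA_real_),
                     class = "branch_concordance"))
  if (is.null(reference)) reference <- msc_topology(res)$topology
  stopifnot(reference %in% names(res))
  denom <- sum(res) + cn[["NONMONOPHYLETIC"]]
  disc <- sort(res[setdiff(names(res), reference)], decreasing = TRUE)
  qs <- res / sum(res)
  structure(list(
    counts = cn, reference = reference,
    gCF = 100 * res[[reference]] / denom,
    gDF1 = 100 * disc[[1L]] / denom,
    gDF2 = 100 * disc[[2L]] / denom,
    gDFP = 100 * cn[["NONMONOPHYLETIC"]] / denom,
    quartet_support = qs,
    IC = internode_certainty(max(res[[reference]], disc[[1L]]),
                             min(res[[reference]], disc[[1L]])),
    ICA = internode_certainty_all(res[res > 0])),
    class = "branch_concordance")
}

call_counts <- function(calls) {
  if (inherits(calls, "data.frame")) {
    vapply(CATEGORIES, function(k) sum(calls$category == k), integer(1))
  } else {
    cn <- stats::setNames(integer(length(CATEGORIES)), CATEGORIES)
    cn[names(calls)] <- as.integer(calls)
    cn
  }
}

#' @export
print.branch_concordance <- function(x, ...) {
  cat("Branch concordance (reference split:", x$reference, ")\n")
  cat(sprintf("  gCF %.2f%%  gDF1 %.2f%%  gDF2 %.2f%%  gDFP %.2f%%\n",
              x$gCF, x$gDF1, x$gDF2, x$gDFP))
  cat("  quartet support:",
      paste(sprintf("%s %.3f", names(x$quartet_support), x$quartet_support),
            collapse = ", "), "\n")
  cat(sprintf("  IC %.3g   ICA %.3g\n", x$IC, x$ICA))
  invisible(x)
}

#' Site support for the three triplet resolutions in one alignment
#'
#' Counts decisive sites over sampled quartets (one taxon from each focal
#' lineage plus one outgroup taxon). A site is decisive for a quartet when
#' it shows exactly two nucleotide states, each in two taxa, with no gap or
#' N: the taxon pairing then supports exactly one resolution. Site
#' concordance factors are percentages over decisive sites, averaged across
#' quartets.
#'
#' @param aln A `codon_alignment`.
#' @param map A [lineage_map()].
#' @param max_quartets Cap on sampled quartets (exhaustive when the number
#'   of combinations is below the cap).
#' @param seed Seed for quartet subsampling.
#' @return List of class `site_support`: decisive-site counts `s_AB`,
#'   `s_AC`, `s_BC`, `n_uninformative`, and mean `sCF_AB`, `sCF_AC`,
#'   `sCF_BC` percentages.
#' @export
site_support <- function(aln, map, max_quartets = 100L, seed = 1L) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(map, "lineage_map"))
  rn <- rownames(aln$mat)
  sets <- list(A = intersect(map$A, rn), B = intersect(map$B, rn),
               C = intersect(map$C, rn), O = intersect(map$outgroup, rn))
  if (any(lengths(sets) == 0L))
    stop("alignment must contain at least one taxon per lineage and outgroup")
  grid <- expand.grid(a = sets$A, b = sets$B, c = sets$C, o = sets$O,
                      stringsAsFactors = FALSE)
  if (nrow(grid) > max_quartets) {
    set.seed(seed)
    grid <- grid[sample.int(nrow(grid), max_quartets), , drop = FALSE]
  }
  tot <- c(AB = 0L, AC = 0L, BC = 0L)
  scf <- matrix(NA_real_, nrow(grid), 3L,
                dimnames = list(NULL, c("AB", "AC", "BC")))
  n_uninf <- 0L
  for (q in seq_len(nrow(grid))) {
    m <- aln$mat[unlist(grid[q, ]), , drop = FALSE]
    good <- colSums(matrix(m %in% c("A", "C", "G", "T"), 4L)) == 4L
    a <- m[1L, ]; b <- m[2L, ]; cc <- m[3L, ]; o <- m[4L, ]
    dAB <- good & a == b & cc == o & a != cc
    dAC <- good & a == cc & b == o & a != b
    dBC <- good & b == cc & a == o & a != b
    s <- c(AB = sum(dAB), AC = sum(dAC), BC = sum(dBC))
    tot <- tot + s
    n_uninf <- n_uninf + (aln$length - sum(s))
    if (sum(s) > 0L) scf[q, ] <- 100 * s / sum(s)
  }
  structure(list(gene_id = aln$gene_id, s_AB = tot[["AB"]], s_AC = tot[["AC"]],
                 s_BC = tot[["BC"]], n_uninformative = n_uninf,
                 sCF_AB = mean(scf[, "AB"], na.rm = TRUE),
                 sCF_AC = mean(scf[, "AC"], na.rm = TRUE),
                 sCF_BC = mean(scf[, "BC"], na.rm = TRUE),
                 n_quartets = nrow(grid)),
            class = "site_support")
}

#' Distribution of per-gene site concordance factors
#'
#' @param supports List of `site_support` objects (one per gene).
#' @param reference Which resolution's sCF to summarise (`"AB"`, `"AC"`,
#'   `"BC"`).
#' @return List with `median`, `mean`, `n`, and the per-gene values.
#' @export
scf_distribution <- function(supports, reference = c("AB", "AC", "BC")) {
  reference <- match.arg(reference)
  v <- vapply(supports, function(s) s[[paste0("sCF_", reference)]], numeric(1))
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no gene with a defined sCF")
  list(median = stats::median(v), mean = mean(v), n = length(v), values = v)
}

#' Per-gene site-support table
#' @param supports List of `site_support` objects.
#' @return data.frame, one row per gene.
#' @export
site_support_table <- function(supports) {
  do.call(rbind, lapply(supports, function(s)
    data.frame(gene_id = s$gene_id, s_AB = s$s_AB, s_AC = s$s_AC,
               s_BC = s$s_BC, n_uninformative = s$n_uninformative,
               sCF_AB = s$sCF_AB, sCF_AC = s$sCF_AC, sCF_BC = s$sCF_BC,
               stringsAsFactors = FALSE)))
}
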