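#' Holm step-down multiple-testing correction
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "holm"`; kept as a
#' named operation so every test family in the pipeline adjusts through one
#' place.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Discordant-count test (DCT)
#'
#' Under incomplete lineage sorting alone the two discordant triplet
#' topologies are equally frequent; introgression skews the counts. A
#' two-cell chi-square test (df = 1, no continuity correction) against the
#' 50:50 null; optionally an exact binomial test for small counts.
#'
#' @param c1,c2 Gene-tree counts for the two topology classes.
#' @param labels Names of the two classes (for reporting).
#' @param exact Use `binom.test` instead of the chi-square approximation.
#' @return One-row data.frame of class `dct_result`: counts, `chi2`, `df`,
#'   `p_raw`, `excess_class`.
#' @examples
#' dct(60, 40)   # chi2 = 4, p ~ 0.0455
#' @export
dct <- function(c1, c2, labels = c("class1", "class2"), exact = FALSE) {
  stopifnot(c1 >= 0, c2 >= 0)
  if (c1 + c2 == 0)
    return(structure(data.frame(label = paste(labels, collapse = " vs "),
                                c1 = c1, c2 = c2, delta = NA_real_,
                                chi2 = NA_real_, df = 1L, p_raw = NA_real_,
                                excess_class = NA_character_,
                                stringsAsFactors = FALSE),
                     class = c("dct_result", "data.frame")))
  e <- (c1 + c2) / 2
  chi2 <- (c1 - e)^2 / e + (c2 - e)^2 / e
  p <- if (exact) stats::binom.test(c1, c1 + c2, p = 0.5)$p.value
       else stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(data.frame(label = paste(labels, collapse = " vs "),
                       c1 = c1, c2 = c2, delta = c1 - c2, chi2 = chi2,
                       df = 1L, p_raw = p,
                       excess_class = if (c1 == c2) NA_character_
                                      else labels[which.max(c(c1, c2))],
                       stringsAsFactors = FALSE),
            class = c("dct_result", "data.frame"))
}

#' DCT over all three topology-class pairs, Holm-adjusted jointly
#'
#' @param counts Named counts for `RES_AB`, `RES_AC`, `RES_BC`, or a
#'   `triplet_calls` data.frame.
#' @param exact Passed to [dct()].
#' @return data.frame with one row per pair and a `p_adj` column.
#' @export
dct_all_pairs <- function(counts, exact = FALSE) {
  cn <- resolved_counts(counts)
  pairs <- list(c("RES_AB", "RES_AC"), c("RES_AB", "RES_BC"),
                c("RES_AC", "RES_BC"))
  res <- do.call(rbind, lapply(pairs, function(pr)
    dct(cn[[pr[1L]]], cn[[pr[2L]]], labels = pr, exact = exact)))
  res$p_adj <- holm_adjust(res$p_raw)
  class(res) <- c("dct_result", "data.frame")
  res
}

#' Branch-length test (BLT) for one pair of topology classes
#'
#' Compares the distributions of most-recent-coalescence depths between two
#' gene-tree classes. ILS predicts identical depth distributions for the
#' two discordant classes; introgression makes the introgressed class
#' coalesce more recently. Unscaled depths are compared with a
#' Kruskal-Wallis one-way ANOVA; depths scaled by each gene's total tree
#' length with a two-sided Mann-Whitney U test.
#'
#' @param depths1,depths2 Coalescence depths (substitutions/site) of the
#'   topology-defining pair in each gene of the class; for the scaled
#'   variant, already divided by the gene's total tree length.
#' @param scaled Logical: Mann-Whitney (scaled) or Kruskal-Wallis
#'   (unscaled).
#' @param labels Class names for reporting.
#' @return One-row data.frame of class `blt_result`: statistic, `p_raw`,
#'   medians, `direction` (class coalescing more recently).
#' @export
blt <- function(depths1, depths2, scaled = FALSE,
                labels = c("class1", "class2")) {
  d1 <- depths1[is.finite(depths1)]
  d2 <- depths2[is.finite(depths2)]
  base <- data.frame(label = paste(labels, collapse = " vs "),
                     n1 = length(d1), n2 = length(d2),
                     statistic = NA_real_, p_raw = NA_real_,
                     median1 = NA_real_, median2 = NA_real_,
                     direction = NA_character_, scaled = scaled,
                     stringsAsFactors = FALSE)
  if (length(d1) < 2L || length(d2) < 2L)
    return(structure(base, class = c("blt_result", "data.frame")))
  base$median1 <- stats::median(d1)
  base$median2 <- stats::median(d2)
  if (stats::sd(c(d1, d2)) == 0) {
    base$statistic <- 0
    base$p_raw <- 1
    return(structure(base, class = c("blt_result", "data.frame")))
  }
  if (scaled) {
    # exact null for small tie-free samples, normal approximation otherwise
    wt <- suppressWarnings(stats::wilcox.test(d1, d2))
    base$statistic <- unname(wt$statistic)
    base$p_raw <- wt$p.value
  } else {
    kt <- stats::kruskal.test(list(d1, d2))
    base$statistic <- unname(kt$statistic)
    base$p_raw <- kt$p.value
  }
  if (base$median1 != base$median2)
    base$direction <- labels[which.min(c(base$median1, base$median2))]
  structure(base, class = c("blt_result", "data.frame"))
}

#' BLT over all three topology-class pairs, Holm-adjusted jointly
#'
#' Each resolved class contributes the coalescence depth of its
#' topology-defining pair (`pair_depth_AB` for `RES_AB` genes, and so on);
#' the scaled variant divides by each gene's total tree length first.
#'
#' @param calls A `triplet_calls` data.frame.
#' @param scaled Logical; see [blt()].
#' @return data.frame with one row per class pair and a `p_adj` column.
#' @export
blt_pairwise <- function(calls, scaled = FALSE) {
  depth_of <- function(class) {
    sub <- calls[calls$category == class, ]
    d <- sub[[paste0("pair_depth_", sub("RES_", "", class))]]
    if (scaled) d <- d / sub$total_tree_length
    d
  }
  dep <- lapply(c(RES_AB = "RES_AB", RES_AC = "RES_AC", RES_BC = "RES_BC"),
                depth_of)
  pairs <- list(c("RES_AB", "RES_AC"), c("RES_AB", "RES_BC"),
                c("RES_AC", "RES_BC"))
  res <- do.call(rbind, lapply(pairs, function(pr)
    blt(dep[[pr[1L]]], dep[[pr[2L]]], scaled = scaled, labels = pr)))
  res$p_adj <- holm_adjust(res$p_raw)
  class(res) <- c("blt_result", "data.frame")
  res
}

#' DCT and BLT for every species trio across the focal lineages
#'
#' For each combination of one species per focal lineage, gene trees are
#' re-classified on that trio plus the outgroup representative and the full
#' DCT and BLT batteries are run; Holm correction is applied within each
#' trio's test family.
#'
#' @param gts List of `gene_tree` objects.
#' @param map A [lineage_map()].
#' @param scaled Logical for the BLT variant.
#' @return List, one element per trio, each with `trio`, `calls` counts,
#'   `dct`, `blt`.
#' @export
run_trios <- function(gts, map, scaled = FALSE) {
  trios <- expand.grid(a = map$A, b = map$B, c = map$C,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    tm <- lineage_map(A = trios$a[i], B = trios$b[i], C = trios$c[i],
                      outgroup = map$outgroup,
                      outgroup_priority = map$outgroup_priority)
    calls <- classify_gene_trees(gts, tm)
    out[[i]] <- list(trio = unlist(trios[i, ]),
                     counts = call_counts(calls),
                     dct = dct_all_pairs(calls),
                     blt = blt_pairwise(calls, scaled = scaled))
  }
  names(out) <- apply(trios, 1L, paste, collapse = "|")
  out
}

#' Rule-based verdict from DCT and BLT results
#'
#' A significant DCT excess of a discordant class implicates introgression
#' between that class's taxon pair; a significant BLT with the smaller
#' median depth in a discordant class does the same. Conflicting signals
#' are both reported and flagged.
#'
#' @param dct_results Output of [dct_all_pairs()].
#' @param blt_results Output of [blt_pairwise()].
#' @param reference The species-tree (concordant) class.
#' @param alpha Significance level on the Holm-adjusted p-values.
#' @return Character vector of verdict lines.
#' @export
interpret <- function(dct_results, blt_results, reference = "RES_AB",
                      alpha = 0.05) {
  pair_of <- function(class) sub("RES_", "", class)
  verdicts <- character(0)
  dct_hits <- character(0)
  blt_hits <- character(0)
  for (i in seq_len(nrow(dct_results))) {
    r <- dct_results[i, ]
    if (!is.na(r$p_adj) && r$p_adj <= alpha && !is.na(r$excess_class) &&
        r$excess_class != reference) {
      pr <- pair_of(r$excess_class)
      dct_hits <- union(dct_hits, pr)
      verdicts <- c(verdicts, sprintf(
        "%s-%s introgression (DCT: excess %s, p_adj = %.3g)",
        substr(pr, 1, 1), substr(pr, 2, 2), r$excess_class, r$p_adj))
    }
  }
  for (i in seq_len(nrow(blt_results))) {
    r <- blt_results[i, ]
    if (!is.na(r$p_adj) && r$p_adj <= alpha && !is.na(r$direction) &&
        r$direction != reference) {
      pr <- pair_of(r$direction)
      blt_hits <- union(blt_hits, pr)
      verdicts <- c(verdicts, sprintf(
        "%s-%s introgression (BLT%s: %s coalesces more recently, p_adj = %.3g)",
        substr(pr, 1, 1), substr(pr, 2, 2),
        if (isTRUE(r$scaled[1])) " scaled" else "", r$direction, r$p_adj))
    }
  }
  if (length(verdicts) == 0L)
    return("consistent with ILS alone (no significant DCT or BLT signal)")
  if (length(dct_hits) && length(blt_hits) && !setequal(dct_hits, blt_hits))
    verdicts <- c(verdicts,
                  "note: DCT and BLT implicate different pairs; both reported")
  verdicts
}
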