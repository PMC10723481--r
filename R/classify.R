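#' Define the focal lineage triplet and outgroup
#'
#' Names the three focal lineages whose branching order is contested (for
#' the motivating dataset: A = Proboscidea, B = Hyracoidea with two hyrax
#' species, C = Sirenia) and the outgroup taxa used to orient the quartet.
#'
#' @param A,B,C Character vectors of taxon labels; pairwise disjoint and
#'   non-empty.
#' @param outgroup Outgroup taxon labels, disjoint from `A`, `B`, `C`.
#' @param outgroup_priority Order in which outgroup taxa are preferred as
#'   the single quartet representative; defaults to `outgroup` order.
#' @return An object of class `lineage_map`.
#' @examples
#' lineage_map(A = "Elephant", B = c("Procavia", "Heterohyrax"),
#'             C = "Manatee", outgroup = "Outgroup")
#' @export
lineage_map <- function(A, B, C, outgroup, outgroup_priority = outgroup) {
  lin <- list(A = unique(A), B = unique(B), C = unique(C))
  all3 <- unlist(lin, use.names = FALSE)
  if (any(lengths(lin) == 0L) || length(outgroup) == 0L)
    stop("every lineage and the outgroup must be non-empty")
  if (anyDuplicated(all3)) {
    dup <- all3[duplicated(all3)][1L]
    stop("taxon '", dup, "' appears in two lineages", call. = FALSE)
  }
  if (length(intersect(all3, outgroup)) > 0L)
    stop("outgroup overlaps a focal lineage: ",
         intersect(all3, outgroup)[1L], call. = FALSE)
  structure(list(A = lin$A, B = lin$B, C = lin$C,
                 outgroup = unique(outgroup),
                 outgroup_priority = unique(outgroup_priority)),
            class = "lineage_map")
}

#' @export
print.lineage_map <- function(x, ...) {
  cat("<lineage_map>\n")
  for (nm in c("A", "B", "C"))
    cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  cat("  outgroup: ", paste(x$outgroup, collapse = ", "), "\n", sep = "")
  invisible(x)
}

CATEGORIES <- c("RES_AB", "RES_AC", "RES_BC", "NONMONOPHYLETIC", "NONDECISIVE")

clade_tips <- function(phy, node) {
  if (node <= length(phy$tip.label)) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

is_clade <- function(phy, tips) {
  if (length(tips) == 1L) return(TRUE)
  m <- ape::getMRCA(phy, tips)
  setequal(clade_tips(phy, m), tips)
}

node_support <- function(phy, node) {
  ntip <- length(phy$tip.label)
  lab <- phy$node.label
  if (is.null(lab)) return(NA_real_)
  v <- suppressWarnings(as.numeric(lab[node - ntip]))
  if (length(v) != 1L || !is.finite(v)) NA_real_ else v
}

empty_call <- function(gene_id, n_taxa, category = "NONDECISIVE",
                       total_len = NA_real_) {
  data.frame(gene_id = gene_id, category = category,
             group_monophyletic = NA, stem_length = NA_real_,
             stem_support = NA_real_, pair_depth_AB = NA_real_,
             pair_depth_AC = NA_real_, pair_depth_BC = NA_real_,
             total_tree_length = total_len, n_taxa = n_taxa,
             stringsAsFactors = FALSE)
}

#' Classify one gene tree onto the focal triplet
#'
#' Restricts the gene tree to the focal taxa plus a single outgroup
#' representative, checks that each focal lineage is a clade there, and reads
#' the resulting unrooted quartet: `RES_AB` (A and B sisters), `RES_AC`,
#' `RES_BC`. Trees where a lineage is split are `NONMONOPHYLETIC`; trees
#' missing a whole lineage or outgroup, or whose restricted quartet is
#' unresolved, are `NONDECISIVE`. Also records the focal stem length and
#' support, pairwise coalescence depths (half patristic distance between
#' lineage anchors), total tree length, and whether the whole focal group
#' is monophyletic against all sampled outgroup taxa.
#'
#' @param gt A `gene_tree`.
#' @param map A [lineage_map()].
#' @param mode `"stem"` keeps all lineage taxa and reads the collapsed
#'   lineage-stem quartet (the default); `"representative"` first prunes each
#'   lineage to one taxon.
#' @return One-row data.frame (class `triplet_call`).
#' @export
classify_gene_tree <- function(gt, map, mode = c("stem", "representative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "gene_tree"), inherits(map, "lineage_map"))
  phy <- gt$phy
  tl <- phy$tip.label
  total_len <- if (is.null(phy$edge.length)) NA_real_ else sum(phy$edge.length)
  pres <- lapply(map[c("A", "B", "C")], intersect, y = tl)
  out_pres <- intersect(map$outgroup_priority, tl)
  out_pres <- c(out_pres, setdiff(intersect(map$outgroup, tl), out_pres))
  if (any(lengths(pres) == 0L) || length(out_pres) == 0L)
    return(structure(empty_call(gt$gene_id, length(tl), total_len = total_len),
                     class = c("triplet_call", "data.frame")))
  rep_out <- out_pres[1L]
  if (mode == "representative")
    pres <- lapply(pres, `[`, 1L)

  # carry supports as node labels through pruning/rerooting
  phy$node.label <- ifelse(is.na(gt$support), "", as.character(gt$support))

  focal <- unlist(pres, use.names = FALSE)
  restr <- ape::keep.tip(phy, c(focal, rep_out))
  rt <- ape::root(ape::unroot(restr), outgroup = rep_out,
                  resolve.root = TRUE, edgelabel = TRUE)

  # whole-group monophyly is judged against every sampled outgroup taxon
  grp_tree <- ape::root(ape::unroot(ape::keep.tip(phy, c(focal, out_pres))),
                        outgroup = rep_out, resolve.root = TRUE)
  group_mono <- is_clade(grp_tree, focal)

  lin_mono <- vapply(pres, function(tp) is_clade(rt, tp), logical(1))

  call <- empty_call(gt$gene_id, length(tl), total_len = total_len)
  call$group_monophyletic <- group_mono

  # pairwise coalescence depths: half patristic distance between anchors
  anchors <- vapply(pres, function(tp) {
    if (length(tp) == 1L) match(tp, rt$tip.label)
    else if (is_clade(rt, tp)) ape::getMRCA(rt, tp) else NA_integer_
  }, integer(1))
  if (!is.null(rt$edge.length) && !anyNA(rt$edge.length)) {
    dn <- ape::dist.nodes(rt)
    dep <- function(i, j) {
      if (is.na(anchors[i]) || is.na(anchors[j])) return(NA_real_)
      dn[anchors[i], anchors[j]] / 2
    }
    call$pair_depth_AB <- dep(1L, 2L)
    call$pair_depth_AC <- dep(1L, 3L)
    call$pair_depth_BC <- dep(2L, 3L)
  }

  if (!all(lin_mono)) {
    call$category <- "NONMONOPHYLETIC"
    return(structure(call, class = c("triplet_call", "data.frame")))
  }

  pair_sets <- list(RES_AB = c(pres$A, pres$B),
                    RES_AC = c(pres$A, pres$C),
                    RES_BC = c(pres$B, pres$C))
  hit <- names(pair_sets)[vapply(pair_sets, function(tp) is_clade(rt, tp),
                                 logical(1))]
  if (length(hit) != 1L) {
    # unresolved quartet (basal polytomy of the three lineages)
    return(structure(call, class = c("triplet_call", "data.frame")))
  }
  call$category <- hit
  m <- ape::getMRCA(rt, pair_sets[[hit]])
  if (!is.null(rt$edge.length)) {
    e <- which(rt$edge[, 2L] == m)
    if (length(e) == 1L) call$stem_length <- rt$edge.length[e]
  }
  call$stem_support <- node_support(rt, m)
  structure(call, class = c("triplet_call", "data.frame"))
}

#' Classify a set of gene trees
#' @param gts List of `gene_tree` objects.
#' @inheritParams classify_gene_tree
#' @return data.frame (class `triplet_calls`), one row per gene.
#' @export
classify_gene_trees <- function(gts, map, mode = c("stem", "representative")) {
  mode <- match.arg(mode)
  rows <- lapply(gts, classify_gene_tree, map = map, mode = mode)
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(df, class = c("triplet_calls", "data.frame"))
}

#' Coalescence depth of a lineage pair in one gene tree
#'
#' Half the patristic distance between the two lineage anchors on the tree
#' restricted to the focal taxa plus one outgroup representative (anchor =
#' the leaf for a single-taxon lineage, else the lineage clade root). On an
#' ultrametric tree this equals the height of the most recent common
#' ancestor of the pair, i.e. the age of their most recent coalescence in
#' substitutions per site.
#'
#' @inheritParams classify_gene_tree
#' @param pair One of `"AB"`, `"AC"`, `"BC"`.
#' @return Depth in substitutions/site, or `NA` if undefined.
#' @export
pair_depth <- function(gt, map, pair = c("AB", "AC", "BC"),
                       mode = c("stem", "representative")) {
  pair <- match.arg(pair)
  call <- classify_gene_tree(gt, map, mode = match.arg(mode))
  call[[paste0("pair_depth_", pair)]]
}

#' Census of triplet resolutions across genes
#'
#' Tabulates the five categories, reports percentages of the three resolved
#' classes among decisive genes (one decimal), and the rate at which the
#' whole focal group is monophyletic against the sampled outgroups.
#'
#' @param calls A `triplet_calls` data.frame.
#' @param stem_threshold Stems longer than this (substitutions/site) are
#'   counted in `frac_stem_gt`; default 0.02, the length below which short
#'   internal branches are prone to inference artifacts.
#' @return List of class `triplet_census`.
#' @export
census <- function(calls, stem_threshold = 0.02) {
  stopifnot(nrow(calls) > 0L)
  counts <- vapply(CATEGORIES, function(k) sum(calls$category == k), integer(1))
  n_decisive <- sum(counts[c("RES_AB", "RES_AC", "RES_BC")])
  pct <- if (n_decisive > 0L)
    round(100 * counts[c("RES_AB", "RES_AC", "RES_BC")] / n_decisive, 1)
  else rep(NA_real_, 3L)
  defined <- calls$category != "NONDECISIVE" & !is.na(calls$group_monophyletic)
  mono <- if (any(defined)) mean(calls$group_monophyletic[defined]) else NA_real_
  stems <- calls$stem_length[!is.na(calls$stem_length)]
  structure(list(
    n = nrow(calls), counts = counts, n_decisive = n_decisive,
    percent_decisive = pct,
    monophyly_rate = mono,
    frac_stem_gt = if (length(stems)) mean(stems > stem_threshold) else NA_real_,
    stem_threshold = stem_threshold), class = "triplet_census")
}

#' @export
print.triplet_census <- function(x, ...) {
  cat("Gene-tree census over", x$n, "genes\n")
  print(x$counts)
  if (!anyNA(x$percent_decisive)) {
    cat("Among", x$n_decisive, "decisive genes: ",
        paste(sprintf("%s %.1f%%", names(x$percent_decisive),
                      x$percent_decisive), collapse = ", "), "\n")
  }
  if (!is.na(x$monophyly_rate))
    cat(sprintf("Focal group monophyletic in %.1f%% of classifiable genes\n",
                100 * x$monophyly_rate))
  if (!is.na(x$frac_stem_gt))
    cat(sprintf("%.1f%% of focal stems exceed %g subs/site\n",
                100 * x$frac_stem_gt, x$stem_threshold))
  invisible(x)
}

#' Correlation between stem support and stem length
#'
#' Pearson product-moment correlation of (stem length, stem support) pairs,
#' per resolved class and pooled; long branches are expected to carry higher
#' approximate likelihood-ratio support.
#'
#' @param calls A `triplet_calls` data.frame.
#' @return data.frame with columns category, n, r, p.
#' @export
support_length_correlation <- function(calls) {
  grp <- c("all", "RES_AB", "RES_AC", "RES_BC")
  res <- lapply(grp, function(g) {
    sub <- if (g == "all") calls[calls$category %in% c("RES_AB", "RES_AC", "RES_BC"), ]
           else calls[calls$category == g, ]
    ok <- is.finite(sub$stem_length) & is.finite(sub$stem_support)
    x <- sub$stem_length[ok]; y <- sub$stem_support[ok]
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(category = g, n = length(x), r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(category = g, n = length(x), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write per-gene triplet calls as TSV
#' @param calls A `triplet_calls` data.frame.
#' @param file Output path.
#' @export
write_calls_tsv <- function(calls, file) {
  utils::write.table(calls, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
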