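#' Configure the triplet-plus-outgroup coalescent simulator
#'
#' Species tree ((A,B),C),O with an internal branch of `T_internal`
#' coalescent units (2N generations) between the A-B split at `t1` and the
#' join with C; the outgroup lineage joins at `t_out`. One lineage is
#' sampled per focal lineage; a lineage listed with two species (the hyrax
#' pair, by default) is rendered as a fixed cherry splitting at
#' `pair_split` and enters the coalescent as its stem lineage.
#' Introgression is a pulse: with probability `gamma` the recipient's
#' lineage migrates into the donor population at time `t_m` and may
#' coalesce there until the populations merge anyway. Coalescent-unit
#' branch lengths are converted to substitutions/site by `mu` times a
#' per-gene lognormal rate with mean 1 and log-sd `rate_sigma`.
#'
#' @param T_internal Internal branch, coalescent units (>= 0).
#' @param t1 A-B split time (coalescent units).
#' @param t_out Outgroup join time; default `t1 + T_internal + 2`.
#' @param gamma Introgression probability per gene, in `[0, 1]`.
#' @param donor,recipient Lineage letters (`"A"`, `"B"`, `"C"`).
#' @param t_m Introgression time, in `(0, t1)`.
#' @param mu Substitutions/site per coalescent unit.
#' @param rate_sigma Log-sd of the per-gene rate multiplier (>= 0).
#' @param n_genes Number of genes.
#' @param seq_len Alignment length in codons.
#' @param poly_noise Fraction of genes replaced by random trees in which a
#'   focal lineage is polyphyletic (requires a two-species lineage).
#' @param missing_rate Per-species probability of being absent from a gene.
#' @param seed Dataset seed; each gene gets its own reproducible stream
#'   derived from `(seed, i)`, so datasets are parallelisable per gene.
#' @param taxa Named list with species labels for `A`, `B`, `C`,
#'   `outgroup` (at most two species per focal lineage).
#' @param pair_split Split time of any two-species lineage's cherry.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(T_internal = 0.1, t1 = 1, t_out = NULL,
                              gamma = 0, donor = "C", recipient = "A",
                              t_m = 0.1, mu = 0.005, rate_sigma = 0,
                              n_genes = 1000L, seq_len = 100L,
                              poly_noise = 0, missing_rate = 0, seed = 1L,
                              taxa = list(A = "Elephant",
                                          B = c("Procavia", "Heterohyrax"),
                                          C = "Manatee",
                                          outgroup = "Outgroup"),
                              pair_split = 0.3) {
  if (is.null(t_out)) t_out <- t1 + T_internal + 2
  stopifnot(T_internal >= 0, t1 > 0, t_out >= t1 + T_internal,
            gamma >= 0, gamma <= 1, t_m > 0, t_m < t1, mu > 0,
            rate_sigma >= 0, n_genes >= 1, seq_len >= 1,
            poly_noise >= 0, poly_noise < 1,
            missing_rate >= 0, missing_rate < 1,
            donor %in% c("A", "B", "C"), recipient %in% c("A", "B", "C"),
            donor != recipient,
            all(c("A", "B", "C", "outgroup") %in% names(taxa)),
            all(lengths(taxa[c("A", "B", "C")]) %in% 1:2),
            pair_split > 0, pair_split < t1)
  structure(list(T_internal = T_internal, t1 = t1, t_out = t_out,
                 gamma = gamma, donor = donor, recipient = recipient,
                 t_m = t_m, mu = mu, rate_sigma = rate_sigma,
                 n_genes = as.integer(n_genes),
                 seq_len = as.integer(seq_len), poly_noise = poly_noise,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 taxa = taxa, pair_split = pair_split),
            class = "simulation_config")
}

#' Paenungulata-like simulator preset
#'
#' A configuration whose census resembles the motivating dataset: a short
#' internal branch, a modest introgression pulse from C into A so the two
#' discordant classes are unequal, per-gene rate variation, ten percent
#' polyphyletic noise, sporadic missing species, and a substitution scale
#' under which the large majority of focal stems are shorter than 0.02
#' substitutions/site.
#'
#' @param n_genes Number of genes (defaults to the motivating dataset's
#'   13,388).
#' @param seed Dataset seed.
#' @export
preset_paenungulata <- function(n_genes = 13388L, seed = 1L) {
  simulation_config(T_internal = 0.08, gamma = 0.08, donor = "C",
                    recipient = "A", t_m = 0.1, mu = 0.005,
                    rate_sigma = 0.3, n_genes = n_genes, seq_len = 150L,
                    poly_noise = 0.10, missing_rate = 0.01, seed = seed)
}

# per-gene RNG stream: two Lehmer rounds mix the dataset seed and the gene
# index so that nearby dataset seeds share no gene streams (a plain
# seed-xor-index scheme makes datasets with nearby seeds permutations of
# one another)
gene_seed <- function(seed, i) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 %% m
  x <- (x + as.numeric(i)) * 48271 %% m
  as.integer((x + as.numeric(i)) %% m)
}

# a node is list(time, tip = label) or list(time, children = list(n1, n2))
sim_tip <- function(label) list(time = 0, tip = label)

unit_lineage <- function(unit, species, pair_split) {
  if (length(species) == 2L) {
    node <- list(time = pair_split,
                 children = list(sim_tip(species[1L]), sim_tip(species[2L])))
  } else node <- sim_tip(species)
  list(set = unit, root = if (length(species) == 2L) pair_split else 0,
       node = node)
}

merge_lineage <- function(l1, l2, t) {
  list(set = c(l1$set, l2$set), root = t,
       node = list(time = t, children = list(l1$node, l2$node)))
}

# sequential pairwise coalescent in one pool; returns updated lineages and
# the merge log (set1, set2, time)
coalesce_pool <- function(lin, t_start, t_end, merges) {
  t <- t_start
  while (length(lin) >= 2L) {
    k <- length(lin)
    t <- t + stats::rexp(1L, k * (k - 1) / 2)
    if (t > t_end) break
    pr <- sample.int(k, 2L)
    merges[[length(merges) + 1L]] <- list(
      s1 = lin[[pr[1L]]]$set, s2 = lin[[pr[2L]]]$set, t = t,
      e = (t - lin[[pr[1L]]]$root) + (t - lin[[pr[2L]]]$root))
    lin[[pr[1L]]] <- merge_lineage(lin[[pr[1L]]], lin[[pr[2L]]], t)
    lin[[pr[2L]]] <- NULL
  }
  list(lin = lin, merges = merges)
}

# time at which each pair of units first shares a component (merges are
# generated in non-decreasing time order)
join_times <- function(merges, labels) {
  T <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (m in merges) {
    u1 <- intersect(unique(m$s1), labels)
    u2 <- intersect(unique(m$s2), labels)
    for (a in u1) for (b in u2) {
      if (is.na(T[a, b])) T[a, b] <- T[b, a] <- m$t
    }
  }
  T
}

count_tips <- function(node) {
  if (is.null(node$children)) return(1L)
  sum(vapply(node$children, count_tips, integer(1)))
}

collect_tips <- function(node) {
  if (is.null(node$children)) return(node$tip)
  unlist(lapply(node$children, collect_tips), use.names = FALSE)
}

# a coalescent genealogy has a binary root, but empirical gene trees are
# unrooted: the two root edges are one edge of the unrooted tree and must
# carry a single support.  Splice the root into a trifurcation, folding the
# removed edge length into the displaced child via `extra`.
deroot <- function(root) {
  if (is.null(root$children) || length(root$children) != 2L) return(root)
  internal <- vapply(root$children, function(ch) !is.null(ch$children),
                     logical(1))
  if (!any(internal)) return(root)
  k <- which(internal)[1L]
  pick <- root$children[[k]]
  other <- root$children[[3L - k]]
  other$extra <- (other$extra %||% 0) + 2 * (root$time - pick$time)
  pick$children <- c(pick$children, list(other))
  pick
}

# stylised branch support: increasing in substitution length, noisy, rarely
# reaching 95; emulates an approximate likelihood-ratio percentage
support_of_length <- function(len_subs) {
  s <- 100 * (1 - exp(-len_subs / 0.008)) + stats::rnorm(length(len_subs), 0, 8)
  round(pmin(100, pmax(0, s)), 1)
}

# assign a support to every internal non-root node, in fixed traversal
# order; scale converts coalescent units to substitutions/site
annotate_supports <- function(node, parent_t, scale, is_root = FALSE) {
  if (is.null(node$children)) return(node)
  if (!is_root) {
    len <- (parent_t - node$time + (node$extra %||% 0)) * scale
    node$support <- support_of_length(len)
  }
  node$children <- lapply(node$children, annotate_supports,
                          parent_t = node$time, scale = scale)
  node
}

# support of the edge realising the split sisters | rest (either side may
# carry the label)
find_split_support <- function(node, sisters, all_tips) {
  if (is.null(node$children)) return(NA_real_)
  tips <- collect_tips(node)
  if (!is.null(node$support) &&
      (setequal(tips, sisters) || setequal(tips, setdiff(all_tips, sisters))))
    return(node$support)
  for (ch in node$children) {
    v <- find_split_support(ch, sisters, all_tips)
    if (!is.na(v)) return(v)
  }
  NA_real_
}

render_newick <- function(node, parent_t, scale) {
  len <- (parent_t - node$time + (node$extra %||% 0)) * scale
  if (is.null(node$children))
    return(sprintf("%s:%.10g", node$tip, len))
  inner <- paste(vapply(node$children, render_newick, character(1),
                        parent_t = node$time, scale = scale),
                 collapse = ",")
  lab <- if (is.null(node$support)) "" else sprintf("%g", node$support)
  if (is.na(parent_t)) sprintf("(%s);", inner)
  else sprintf("(%s)%s:%.10g", inner, lab, len)
}

#' Simulate one gene genealogy under the MSC with an introgression pulse
#'
#' Exposed mainly for inspection; [simulate_dataset()] is the main entry.
#' Uses the current RNG state.
#'
#' @param cfg A [simulation_config()].
#' @param present Named logical for species presence; default all present.
#' @return List: `class` (topology category), `merges`, `root` (nested node
#'   structure), focal join times, and per-unit anchor heights.
#' @export
simulate_genealogy <- function(cfg, present = NULL) {
  taxa <- cfg$taxa
  all_sp <- unlist(taxa, use.names = FALSE)
  if (is.null(present))
    present <- stats::setNames(rep(TRUE, length(all_sp)), all_sp)
  sp_of <- function(u) {
    s <- if (u == "O") taxa$outgroup else taxa[[u]]
    s[present[s]]
  }
  units <- c("A", "B", "C")[vapply(c("A", "B", "C"),
                                   function(u) length(sp_of(u)) > 0L,
                                   logical(1))]
  o_sp <- sp_of("O")
  merges <- list()
  lin <- lapply(units, function(u) unit_lineage(u, sp_of(u), cfg$pair_split))
  names(lin) <- units
  heights <- vapply(lin, `[[`, numeric(1), "root")

  migrated <- FALSE
  if (cfg$gamma > 0 && all(c(cfg$donor, cfg$recipient) %in% units))
    migrated <- stats::runif(1L) < cfg$gamma

  t2 <- cfg$t1 + cfg$T_internal
  # phase 1-2: structured populations until t1 + T_internal
  if (migrated) {
    # recipient sits in the donor population over [t_m, t1+T)
    tc <- cfg$t_m + stats::rexp(1L)
    if (tc < t2) {
      merges[[1L]] <- list(s1 = lin[[cfg$recipient]]$set,
                           s2 = lin[[cfg$donor]]$set, t = tc,
                           e = (tc - lin[[cfg$recipient]]$root) +
                             (tc - lin[[cfg$donor]]$root))
      lin[[cfg$donor]] <- merge_lineage(lin[[cfg$recipient]],
                                        lin[[cfg$donor]], tc)
      lin[[cfg$recipient]] <- NULL
    }
  } else if (all(c("A", "B") %in% names(lin))) {
    tc <- cfg$t1 + stats::rexp(1L)
    if (tc < t2) {
      merges[[1L]] <- list(s1 = lin[["A"]]$set, s2 = lin[["B"]]$set, t = tc,
                           e = (tc - lin[["A"]]$root) + (tc - lin[["B"]]$root))
      lin[["A"]] <- merge_lineage(lin[["A"]], lin[["B"]], tc)
      lin[["B"]] <- NULL
    }
  }
  # phase 3: panmictic ancestral population until the outgroup joins
  res <- coalesce_pool(unname(lin), t2, cfg$t_out, merges)
  lin <- res$lin; merges <- res$merges
  # phase 4: outgroup joins
  if (length(o_sp) > 0L)
    lin <- c(lin, list(unit_lineage("O", o_sp, cfg$pair_split)))
  res <- coalesce_pool(lin, cfg$t_out, Inf, merges)
  lin <- res$lin; merges <- res$merges
  root <- if (length(lin) == 1L) deroot(lin[[1L]]$node) else NULL

  cls <- "NONDECISIVE"
  quartet <- NULL
  if (length(units) == 3L && length(o_sp) > 0L) {
    T <- join_times(merges, c("A", "B", "C", "O"))
    h <- stats::setNames(numeric(4L), c("A", "B", "C", "O"))
    h[names(heights)] <- heights
    # the earliest-joining pair is a cherry of the unrooted quartet
    pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"),
                  c("A", "O"), c("B", "O"), c("C", "O"))
    tj <- vapply(pairs, function(p) T[p[1L], p[2L]], numeric(1))
    cherry <- pairs[[which.min(tj)]]
    split_of <- c(AB = "RES_AB", CO = "RES_AB", AC = "RES_AC",
                  BO = "RES_AC", BC = "RES_BC", AO = "RES_BC")
    cls <- split_of[[paste(cherry, collapse = "")]]
    # quartet internal edge (coalescent units) by the four-point condition
    sis <- list(RES_AB = c("A", "B"), RES_AC = c("A", "C"),
                RES_BC = c("B", "C"))[[cls]]
    oth <- setdiff(c("A", "B", "C", "O"), sis)
    d <- function(u, v) 2 * T[u, v] - h[[u]] - h[[v]]
    stem_cu <- (d(sis[1L], oth[1L]) + d(sis[2L], oth[2L]) -
                  d(sis[1L], sis[2L]) - d(oth[1L], oth[2L])) / 2
    quartet <- list(sisters = sis, stem_cu = stem_cu,
                    cherry_is_focal = all(cherry %in% c("A", "B", "C")),
                    t_pair = T[sis[1L], sis[2L]], T = T)
  }
  n_cherry <- sum(vapply(c(units, if (length(o_sp) > 0L) "O"),
                         function(u) length(sp_of(u)) == 2L, logical(1)))
  total_cu <- sum(vapply(merges, `[[`, numeric(1), "e")) +
    2 * cfg$pair_split * n_cherry
  list(class = cls, merges = merges, root = root, units = units,
       has_outgroup = length(o_sp) > 0L, quartet = quartet,
       heights = heights, total_cu = total_cu)
}

sim_call_row <- function(gene_id, gen, scale, cfg) {
  row <- list(gene_id = gene_id, category = gen$class,
              group_monophyletic = NA, stem_length = NA_real_,
              stem_support = NA_real_, pair_depth_AB = NA_real_,
              pair_depth_AC = NA_real_, pair_depth_BC = NA_real_,
              total_tree_length = NA_real_,
              n_taxa = if (is.null(gen$root)) 0L else count_tips(gen$root))
  if (gen$class != "NONDECISIVE") row$group_monophyletic <- TRUE
  if (!is.null(gen$total_cu)) row$total_tree_length <- gen$total_cu * scale
  h <- function(u) if (u %in% names(gen$heights)) gen$heights[[u]] else 0
  T <- if (!is.null(gen$quartet)) gen$quartet$T
       else join_times(gen$merges, c("A", "B", "C", "O"))
  anchored <- function(u) {
    # multi-species lineages in noise trees are polyphyletic: no anchor
    gen$class != "NONMONOPHYLETIC" || length(cfg$taxa[[u]]) == 1L
  }
  dep <- function(u1, u2) {
    if (!anchored(u1) || !anchored(u2)) return(NA_real_)
    tj <- T[u1, u2]
    if (is.na(tj)) return(NA_real_)
    (tj - (h(u1) + h(u2)) / 2) * scale
  }
  if (gen$class %in% c("RES_AB", "RES_AC", "RES_BC", "NONMONOPHYLETIC")) {
    row$pair_depth_AB <- dep("A", "B")
    row$pair_depth_AC <- dep("A", "C")
    row$pair_depth_BC <- dep("B", "C")
  }
  if (!is.null(gen$quartet)) {
    row$stem_length <- gen$quartet$stem_cu * scale
    if (!is.null(gen$root) && !is.null(gen$root$support_done)) {
      all_tips <- collect_tips(gen$root)
      sis_tips <- intersect(all_tips,
                            unlist(cfg$taxa[gen$quartet$sisters],
                                   use.names = FALSE))
      row$stem_support <- find_split_support(gen$root, sis_tips, all_tips)
    }
  }
  row
}

# random-join genealogy with a polyphyletic focal lineage (noise component)
simulate_poly_genealogy <- function(cfg, present) {
  taxa <- cfg$taxa
  sp_of <- function(u) {
    s <- if (u == "O") taxa$outgroup else taxa[[u]]
    s[present[s]]
  }
  multi <- c("A", "B", "C")[vapply(c("A", "B", "C"),
                                   function(u) length(sp_of(u)) == 2L,
                                   logical(1))]
  # a lineage can only be polyphyletic if two of its species are sampled,
  # and only a decisive-capable gene (all three lineages + outgroup
  # present) can interleave it; otherwise fall back to the MSC draw (the
  # gene is non-decisive either way)
  n_units <- sum(vapply(c("A", "B", "C"), function(u) length(sp_of(u)) > 0L,
                        logical(1)))
  if (length(multi) == 0L || n_units < 3L || length(sp_of("O")) == 0L) {
    if (all(lengths(cfg$taxa[c("A", "B", "C")]) == 1L))
      stop("poly_noise requires a focal lineage with two species")
    return(simulate_genealogy(cfg, present))
  }
  for (try in 1:200) {
    tips <- lapply(c("A", "B", "C", "O"), function(u)
      lapply(sp_of(u), function(s) list(set = u, root = 0,
                                        node = sim_tip(s))))
    lin <- do.call(c, tips)
    merges <- list()
    res <- coalesce_pool(lin, 0, Inf, merges)
    # a lineage is monophyletic on the (unrooted) tree iff its two tips, or
    # their complement, form a component at some merge
    key <- function(v) paste(sort(v), collapse = "|")
    comps <- vapply(res$merges, function(m) key(c(m$s1, m$s2)), character(1))
    full <- unlist(lapply(res$merges[[length(res$merges)]][c("s1", "s2")],
                          identity), use.names = FALSE)
    ok <- FALSE
    for (u in multi) {
      compl <- full[-which(full == u)[1:2]]
      mono <- key(c(u, u)) %in% comps || key(compl) %in% comps
      if (!mono) ok <- TRUE
    }
    if (ok) {
      units <- c("A", "B", "C")[vapply(c("A", "B", "C"),
                                       function(u) length(sp_of(u)) > 0L,
                                       logical(1))]
      # without the full triplet and an outgroup the gene is non-decisive
      # whatever its shape
      cls <- if (length(units) == 3L && length(sp_of("O")) > 0L)
        "NONMONOPHYLETIC" else "NONDECISIVE"
      gen <- list(class = cls, merges = res$merges,
                  root = deroot(res$lin[[1L]]$node),
                  units = units,
                  has_outgroup = length(sp_of("O")) > 0L,
                  heights = numeric(0), quartet = NULL,
                  total_cu = sum(vapply(res$merges, `[[`, numeric(1), "e")))
      return(gen)
    }
  }
  stop("could not generate a polyphyletic tree in 200 attempts")
}

#' Convert a genealogy to a substitution-scale gene tree
#'
#' Multiplies every coalescent-unit edge by `mu` and the per-gene rate
#' factor; supports are attached to internal edges.
#'
#' @param gen Output of [simulate_genealogy()] with supports annotated.
#' @param gene_id Identifier.
#' @param scale `mu` times the gene's rate factor.
#' @return A `gene_tree`.
#' @export
to_substitution_tree <- function(gen, gene_id, scale) {
  nwk <- render_newick(gen$root, NA_real_, scale)
  phy <- ape::read.tree(text = nwk)
  new_gene_tree(gene_id, phy, parse_supports(phy$node.label, support_rule()))
}

#' Simulate an alignment on a gene tree
#'
#' Independent sites evolved root-to-tips under the model (uniform
#' stationary frequencies for JC69); no gaps are introduced.
#'
#' @param gt A `gene_tree` with branch lengths in substitutions/site.
#' @param seq_len Length in codons (3 sites each).
#' @param model A [subst_model()].
#' @return A `codon_alignment`.
#' @export
simulate_alignment <- function(gt, seq_len, model = model_jc69()) {
  phy <- gt$phy
  S <- 3L * seq_len
  ntot <- length(phy$tip.label) + phy$Nnode
  states <- matrix(NA_integer_, ntot, S)
  eo <- rev(ape::postorder(phy))
  root <- phy$edge[ape::postorder(phy)[length(ape::postorder(phy))], 1L]
  states[root, ] <- sample.int(4L, S, replace = TRUE, prob = model$pi)
  for (e in eo) {
    par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    P <- pmat(model, phy$edge.length[e])
    cum <- t(apply(P, 1L, cumsum))
    u <- stats::runif(S)
    states[ch, ] <- max.col(cum[states[par, ], , drop = FALSE] >= u,
                            ties.method = "first")
  }
  mat <- matrix(NUC[states[seq_along(phy$tip.label), ]],
                length(phy$tip.label), S)
  rownames(mat) <- phy$tip.label
  codon_alignment(gt$gene_id, mat)
}

#' Simulate a gene-tree dataset
#'
#' Draws `cfg$n_genes` genes: each gene gets its own RNG stream derived
#' from `(seed, gene index)`, species are dropped at `missing_rate`, a `poly_noise`
#' fraction is replaced by random polyphyletic trees, the genealogy is
#' converted to substitutions/site, and (optionally) alignments are
#' evolved. The classification of every gene is returned in a
#' `triplet_calls` data.frame computed directly from the genealogy, so
#' census-level analyses can run without tree reconstruction.
#'
#' @param cfg A [simulation_config()].
#' @param trees Build `gene_tree` objects (newick-capable) per gene.
#' @param alignments Also simulate codon alignments (implies `trees`).
#' @param supports Draw synthetic branch supports (implied by `trees`;
#'   turning it off skips the per-node draws for large census-only runs,
#'   leaving `stem_support` missing).
#' @return A `sim_dataset`: list with `genes` (per-gene lists), `calls`,
#'   and `cfg`.
#' @export
simulate_dataset <- function(cfg, trees = TRUE, alignments = FALSE,
                             supports = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (alignments) trees <- TRUE
  if (trees) supports <- TRUE
  all_sp <- unlist(cfg$taxa, use.names = FALSE)
  genes <- vector("list", cfg$n_genes)
  calls <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    set.seed(gene_seed(cfg$seed, i))
    gene_id <- sprintf("gene%05d", i)
    present <- stats::setNames(stats::runif(length(all_sp)) >= cfg$missing_rate,
                               all_sp)
    is_poly <- cfg$poly_noise > 0 && stats::runif(1L) < cfg$poly_noise
    gen <- if (is_poly) simulate_poly_genealogy(cfg, present)
           else simulate_genealogy(cfg, present)
    rate <- if (cfg$rate_sigma > 0)
      exp(stats::rnorm(1L, -cfg$rate_sigma^2 / 2, cfg$rate_sigma)) else 1
    scale <- cfg$mu * rate
    if (supports && !is.null(gen$root)) {
      gen$root <- annotate_supports(gen$root, NA_real_, scale, is_root = TRUE)
      gen$root$support_done <- TRUE
    }
    calls[[i]] <- sim_call_row(gene_id, gen, scale, cfg)
    g <- list(gene_id = gene_id, class = gen$class)
    if (trees && !is.null(gen$root) &&
        !is.null(gen$root$children)) {
      g$gene_tree <- to_substitution_tree(gen, gene_id, scale)
      if (alignments)
        g$alignment <- simulate_alignment(g$gene_tree, cfg$seq_len)
    }
    genes[[i]] <- g
  }
  df <- data.frame(
    gene_id = vapply(calls, `[[`, character(1), "gene_id"),
    category = vapply(calls, `[[`, character(1), "category"),
    group_monophyletic = vapply(calls, `[[`, logical(1),
                                "group_monophyletic"),
    stem_length = vapply(calls, `[[`, numeric(1), "stem_length"),
    stem_support = vapply(calls, `[[`, numeric(1), "stem_support"),
    pair_depth_AB = vapply(calls, `[[`, numeric(1), "pair_depth_AB"),
    pair_depth_AC = vapply(calls, `[[`, numeric(1), "pair_depth_AC"),
    pair_depth_BC = vapply(calls, `[[`, numeric(1), "pair_depth_BC"),
    total_tree_length = vapply(calls, `[[`, numeric(1),
                               "total_tree_length"),
    n_taxa = vapply(calls, `[[`, integer(1), "n_taxa"),
    stringsAsFactors = FALSE)
  class(df) <- c("triplet_calls", "data.frame")
  structure(list(genes = genes, calls = df, cfg = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", x$cfg$n_genes, " genes (T_internal = ",
      x$cfg$T_internal, ", gamma = ", x$cfg$gamma, ", seed = ",
      x$cfg$seed, ")\n", sep = "")
  print(table(x$calls$category))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' One newick file per gene (and optionally FASTA alignments), plus the
#' calls table as TSV.
#'
#' @param sims A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_sim_dataset <- function(sims, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in sims$genes) {
    if (!is.null(g$gene_tree))
      write_gene_tree(g$gene_tree, file.path(dir, paste0(g$gene_id, ".nwk")))
    if (!is.null(g$alignment))
      write_fasta_codon(g$alignment, file.path(dir, paste0(g$gene_id, ".fa")))
  }
  write_calls_tsv(sims$calls, file.path(dir, "calls.tsv"))
  invisible(dir)
}
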