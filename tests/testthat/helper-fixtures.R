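# shared fixtures: the Paenungulata-style lineage map and small trees built
# in code

paen_map <- function() {
  lineage_map(A = "Elephant", B = c("Procavia", "Heterohyrax"),
              C = "Manatee", outgroup = "Outgroup")
}

abc_map <- function() lineage_map(A = "A", B = "B", C = "C", outgroup = "O")

abc_taxa <- function() list(A = "A", B = "B", C = "C", outgroup = "O")

gt_from_newick <- function(nwk, gene_id = "g",
                           rule = support_rule()) {
  phy <- ape::read.tree(text = nwk)
  polytomyprobe:::new_gene_tree(gene_id, phy,
    polytomyprobe:::parse_supports(phy$node.label, rule))
}

# a calls data.frame with given category counts and optional depth columns
calls_of_counts <- function(ab = 0, ac = 0, bc = 0, poly = 0, nondec = 0) {
  cat <- rep(c("RES_AB", "RES_AC", "RES_BC", "NONMONOPHYLETIC",
               "NONDECISIVE"), c(ab, ac, bc, poly, nondec))
  n <- length(cat)
  df <- data.frame(gene_id = sprintf("g%04d", seq_len(n)), category = cat,
                   group_monophyletic = cat != "NONDECISIVE",
                   stem_length = NA_real_, stem_support = NA_real_,
                   pair_depth_AB = NA_real_, pair_depth_AC = NA_real_,
                   pair_depth_BC = NA_real_, total_tree_length = 1,
                   n_taxa = 4L, stringsAsFactors = FALSE)
  class(df) <- c("triplet_calls", "data.frame")
  df
}

# an all-consensus codon alignment with one perturbed species row
consensus_alignment <- function(n_species = 5, n_codons = 30,
                                codon = "ATG") {
  rows <- stats::setNames(rep(paste(rep(codon, n_codons), collapse = ""),
                              n_species),
                          paste0("sp", seq_len(n_species)))
  rows
}
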