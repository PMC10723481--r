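# 64-codon lookup (standard genetic code, stops as "*"), materialised once
# from seqinr so translation is a vectorised table lookup
GEN_CODE <- local({
  b <- c("T", "C", "A", "G")
  codons <- character(64); k <- 0L
  for (p1 in b) for (p2 in b) for (p3 in b) {
    k <- k + 1L; codons[k] <- paste0(p1, p2, p3)
  }
  stats::setNames(
    vapply(codons, function(cd) seqinr::translate(strsplit(cd, "")[[1L]]),
           character(1)),
    codons)
})

translate_codon <- function(codon) {
  aa <- unname(GEN_CODE[codon])
  aa[is.na(aa)] <- NA_character_
  aa
}

codon_strings <- function(mat) {
  ncod <- ncol(mat) %/% 3L
  out <- matrix("", nrow(mat), ncod, dimnames = list(rownames(mat), NULL))
  for (j in seq_len(ncod)) {
    cols <- (3L * j - 2L):(3L * j)
    out[, j] <- paste0(mat[, cols[1L]], mat[, cols[2L]], mat[, cols[3L]])
  }
  out
}

aa_matrix <- function(mat) {
  cs <- codon_strings(mat)
  aa <- matrix(translate_codon(cs), nrow(cs), ncol(cs),
               dimnames = dimnames(cs))
  aa
}

#' Drop codons left incomplete by per-species cleaning
#'
#' Any codon containing a residual gap or N in a species is replaced by
#' gaps for that species; codon-column triplets that end up gapped in every
#' species are removed so the alignment stays in frame.
#'
#' @param aln A `codon_alignment` whose length is a multiple of 3 (frame 0
#'   at the first column).
#' @return A cleaned `codon_alignment`.
#' @export
drop_incomplete_codons <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$length %% 3L != 0L)
    stop("alignment length ", aln$length, " is not a multiple of 3")
  mat <- aln$mat
  ncod <- aln$length %/% 3L
  for (j in seq_len(ncod)) {
    cols <- (3L * j - 2L):(3L * j)
    bad <- rowSums(matrix(mat[, cols] %in% c("-", "N"),
                          nrow(mat))) > 0L
    if (any(bad)) mat[bad, cols] <- "-"
  }
  cs <- codon_strings(mat)
  keep <- colSums(cs != "---") > 0L
  keep_cols <- as.vector(vapply(which(keep), function(j)
    (3L * j - 2L):(3L * j), integer(3L)))
  codon_alignment(aln$gene_id, mat[, keep_cols, drop = FALSE])
}

#' Consensus amino acid of one codon column
#'
#' The modal translated amino acid across species, with gap/incomplete
#' codons excluded; ties break to the first symbol in sort order (flagged),
#' and stop codons count as a 21st symbol.
#'
#' @param aln A `codon_alignment` (in frame).
#' @param codon_index 1-based codon column.
#' @return Single amino-acid character with attribute `tie`, or `NA` for an
#'   all-gap column.
#' @export
consensus_aa <- function(aln, codon_index) {
  aa <- aa_matrix(aln$mat)[, codon_index]
  consensus_from_col(aa)
}

consensus_from_col <- function(aa) {
  aa <- aa[!is.na(aa)]
  if (length(aa) == 0L) return(structure(NA_character_, tie = FALSE))
  tb <- table(aa)
  top <- sort(names(tb)[tb == max(tb)])
  structure(top[1L], tie = length(top) > 1L)
}

consensus_vector <- function(mat) {
  aa <- aa_matrix(mat)
  apply(aa, 2L, function(col) as.character(consensus_from_col(col)))
}

#' Trim misaligned codons flanking indels
#'
#' For each species and each side of every maximal gap run (at codon
#' granularity), examine flanking windows of x = 1..`x_max` codons: if more
#' than x/2 of the window's codons translate to an amino acid different
#' from the whole-alignment consensus for that column, the x codons are
#' removed (gapped out) for that species; the largest qualifying x wins.
#' The alignment is re-scanned once after removal (two passes at most),
#' with the consensus recomputed for the second pass.
#'
#' @param aln A `codon_alignment`, typically after
#'   [drop_incomplete_codons()].
#' @param x_max Largest window length in codons (default 20).
#' @return List: `aln` (trimmed), `log` (data.frame: gene_id, species,
#'   boundary_codon, side, x, mismatches, pass) with attribute `passes`.
#' @export
trim_indel_flanks <- function(aln, x_max = 20L) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$length %% 3L != 0L)
    stop("alignment length is not a multiple of 3")
  mat <- aln$mat
  log <- data.frame(gene_id = character(0), species = character(0),
                    boundary_codon = integer(0), side = character(0),
                    x = integer(0), mismatches = integer(0),
                    pass = integer(0), stringsAsFactors = FALSE)
  for (pass in 1:2) {
    cons <- consensus_vector(mat)
    aa <- aa_matrix(mat)
    cs <- codon_strings(mat)
    removed_any <- FALSE
    for (s in rownames(mat)) {
      gap <- cs[s, ] == "---"
      if (!any(gap) || all(gap)) next
      mism <- !is.na(aa[s, ]) & !is.na(cons) & aa[s, ] != cons
      r <- rle(gap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      to_remove <- integer(0)
      for (k in which(r$values)) {
        for (side in c("left", "right")) {
          positions <- if (side == "left") {
            if (starts[k] == 1L) next
            seq(starts[k] - 1L, max(1L, starts[k] - x_max))
          } else {
            if (ends[k] == ncol(cs)) next
            seq(ends[k] + 1L, min(ncol(cs), ends[k] + x_max))
          }
          mm <- cumsum(mism[positions])
          xs <- seq_along(positions)
          qual <- which(mm > xs / 2)
          if (length(qual) == 0L) next
          x <- max(qual)
          to_remove <- c(to_remove, positions[seq_len(x)])
          log <- rbind(log, data.frame(
            gene_id = aln$gene_id, species = s,
            boundary_codon = if (side == "left") starts[k] else ends[k],
            side = side, x = x, mismatches = mm[x], pass = pass,
            stringsAsFactors = FALSE))
          removed_any <- TRUE
        }
      }
      if (length(to_remove) > 0L) {
        cols <- as.vector(vapply(unique(to_remove), function(j)
          (3L * j - 2L):(3L * j), integer(3L)))
        mat[s, cols] <- "-"
      }
    }
    if (!removed_any) break
  }
  attr(log, "passes") <- pass
  attr(log, "consensus_recomputed") <- TRUE
  list(aln = codon_alignment(aln$gene_id, mat), log = log)
}
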