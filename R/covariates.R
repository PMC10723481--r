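#' Per-gene technical covariates
#'
#' Alignment length (columns with at least one unambiguous base), GC
#' content over unambiguous bases, and — when available — the gene's stem
#' support/length and reference-split site concordance factor.
#'
#' @param aln A `codon_alignment`.
#' @param call Optional one-row `triplet_call` for the gene.
#' @param sitesupport Optional `site_support` for the gene.
#' @param reference Which resolution's sCF to record.
#' @return One-row data.frame.
#' @export
gene_covariates <- function(aln, call = NULL, sitesupport = NULL,
                            reference = "AB") {
  m <- aln$mat
  base <- m %in% c("A", "C", "G", "T")
  dim(base) <- dim(m)
  gc <- sum(m %in% c("G", "C")) / max(1L, sum(base))
  data.frame(
    gene_id = aln$gene_id,
    length_bp = sum(colSums(base) > 0L),
    gc_content = gc,
    stem_support = if (is.null(call)) NA_real_ else call$stem_support,
    stem_length = if (is.null(call)) NA_real_ else call$stem_length,
    category = if (is.null(call)) NA_character_ else call$category,
    scf_reference = if (is.null(sitesupport)) NA_real_
                    else sitesupport[[paste0("sCF_", reference)]],
    stringsAsFactors = FALSE)
}

#' Compare a covariate across the three resolved classes
#'
#' Kruskal-Wallis test with the epsilon-squared effect size
#' `(H - k + 1)/(n - k)`.
#'
#' @param values Numeric covariate values.
#' @param groups Factor/character of `RES_*` classes (same length).
#' @return List: `H`, `p`, `epsilon_sq`, `n`, `k`.
#' @export
group_compare <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    return(list(H = NA_real_, p = NA_real_, epsilon_sq = NA_real_,
                n = length(values), k = length(tab)))
  kt <- stats::kruskal.test(values, groups)
  n <- length(values); k <- length(tab)
  list(H = unname(kt$statistic), p = kt$p.value,
       epsilon_sq = max(0, (unname(kt$statistic) - k + 1) / (n - k)),
       n = n, k = k)
}

#' Pairwise correlations among per-gene covariates
#'
#' Pearson correlations with two-sided p-values on pairwise-complete
#' observations, for the covariates whose associations with site
#' concordance and stem support are of interest.
#'
#' @param covariates data.frame of stacked [gene_covariates()] rows.
#' @param vars Columns to correlate.
#' @return List with matrices `r` and `p`.
#' @export
covariate_correlations <- function(covariates,
                                   vars = c("scf_reference", "length_bp",
                                            "gc_content", "stem_support",
                                            "stem_length")) {
  vars <- intersect(vars, names(covariates))
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- covariates[[vars[i]]]; y <- covariates[[vars[j]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}

#' Topology census within GC-content bins
#'
#' Splits genes into `n_bins` quantile bins of GC content and reports each
#' bin's resolved-class census and majority call; a systematic drift of the
#' majority across bins would implicate compositional bias.
#'
#' @param covariates data.frame with `gene_id`, `gc_content`, `category`.
#' @param n_bins Number of quantile bins (default quartiles).
#' @return data.frame: bin, n, counts, majority.
#' @export
gc_bins <- function(covariates, n_bins = 4L) {
  cov <- covariates[order(covariates$gene_id), ]
  stopifnot(nrow(cov) >= n_bins)
  if (n_bins == 1L) {
    br <- range(cov$gc_content) + c(-1, 1)
  } else {
    br <- stats::quantile(cov$gc_content, probs = seq(0, 1, length.out = n_bins + 1L))
    br[1L] <- -Inf; br[length(br)] <- Inf
    br <- unique(br)
  }
  bin <- cut(cov$gc_content, breaks = br, labels = FALSE, include.lowest = TRUE)
  # ties at boundaries: stable because genes were ordered by gene_id
  out <- lapply(sort(unique(bin)), function(b) {
    sub <- cov[bin == b, ]
    cn <- vapply(c("RES_AB", "RES_AC", "RES_BC"),
                 function(k) sum(sub$category == k, na.rm = TRUE), integer(1))
    data.frame(bin = b, n = nrow(sub), n_AB = cn[1L], n_AC = cn[2L],
               n_BC = cn[3L],
               majority = if (sum(cn) > 0L) msc_topology(cn)$topology
                          else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
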