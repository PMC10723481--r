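#' Support-label parsing rules
#'
#' Gene-tree files in the wild carry internal-node support either as a bare
#' number (`)95:`) or as a compound label such as IQ-TREE's `aLRT/UFboot`
#' pair (`)88.2/100:`). A support rule says how to reduce the label to the
#' single percentage used downstream.
#'
#' @param sep Field separator inside compound labels, or `NA` for bare
#'   numeric labels (the default).
#' @param field Which separated field holds the support (1-based).
#' @return An object of class `support_rule`.
#' @examples
#' support_rule()                  # bare numeric label
#' support_rule(sep = "/", field = 1)  # first field of "aLRT/UFboot"
#' @export
support_rule <- function(sep = NA_character_, field = 1L) {
  stopifnot(length(field) == 1L, field >= 1L)
  structure(list(sep = sep, field = as.integer(field)), class = "support_rule")
}

parse_supports <- function(labels, rule) {
  if (is.null(labels)) return(numeric(0))
  lab <- labels
  if (!is.na(rule$sep)) {
    lab <- vapply(strsplit(labels, rule$sep, fixed = TRUE), function(f) {
      if (length(f) >= rule$field) f[rule$field] else NA_character_
    }, character(1))
  }
  lab[!nzchar(lab) | is.na(lab)] <- NA_character_
  sup <- suppressWarnings(as.numeric(lab))
  sup[!is.finite(sup) | sup < 0 | sup > 100] <- NA_real_
  sup
}

new_gene_tree <- function(gene_id, phy, support = NULL) {
  if (anyDuplicated(phy$tip.label))
    stop("duplicate taxon '", phy$tip.label[duplicated(phy$tip.label)][1L],
         "' in tree '", gene_id, "'", call. = FALSE)
  if (!is.null(phy$edge.length)) {
    if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
      stop("non-finite or negative branch length in tree '", gene_id, "'",
           call. = FALSE)
  }
  if (is.null(support) || length(support) == 0L)
    support <- rep(NA_real_, phy$Nnode)
  stopifnot(length(support) == phy$Nnode)
  structure(list(gene_id = gene_id, phy = phy, support = support),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree> ", x$gene_id, ": ", length(x$phy$tip.label), " taxa, ",
      sum(!is.na(x$support)), "/", x$phy$Nnode,
      " supported internal nodes\n", sep = "")
  invisible(x)
}

# crude newick sanity check so malformed files get a character offset
newick_offset_of_error <- function(txt) {
  ch <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") depth <- depth + 1L
    if (ch[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(nchar(txt))
  if (!grepl(";", txt, fixed = TRUE)) return(nchar(txt))
  NA_integer_
}

#' Read per-gene newick trees
#'
#' Reads one file or every file in a directory; each file may hold one or
#' more newick strings. Internal-node labels are parsed into supports with
#' `support_field`; labels that do not parse are recorded as missing, never
#' as zero. Malformed files are logged (attribute `"errors"`) rather than
#' aborting the whole run.
#'
#' @param path A newick file or a directory of them.
#' @param support_field A [support_rule()].
#' @param pattern Filename filter used when `path` is a directory.
#' @return A list of `gene_tree` objects with attribute `errors`
#'   (data.frame: file, offset, message).
#' @export
read_gene_trees <- function(path, support_field = support_rule(),
                            pattern = "\\.(tre|tree|nwk|treefile|txt)$") {
  stopifnot(inherits(support_field, "support_rule"))
  files <- if (dir.exists(path)) {
    f <- list.files(path, pattern = pattern, full.names = TRUE)
    if (length(f) == 0L) f <- list.files(path, full.names = TRUE)
    sort(f)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    path
  }
  out <- list()
  errs <- data.frame(file = character(0), offset = integer(0),
                     message = character(0), stringsAsFactors = FALSE)
  for (f in files) {
    txt <- paste(readLines(f, warn = FALSE), collapse = "\n")
    base <- sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch({
      trs <- ape::read.tree(text = txt)
      if (is.null(trs)) stop("no parseable newick")
      if (inherits(trs, "phylo")) trs <- list(trs)
      trs
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- rbind(errs, data.frame(
        file = f, offset = newick_offset_of_error(txt),
        message = conditionMessage(res), stringsAsFactors = FALSE))
      next
    }
    for (k in seq_along(res)) {
      gid <- if (length(res) == 1L) base else sprintf("%s_%d", base, k)
      gt <- tryCatch(
        new_gene_tree(gid, res[[k]],
                      parse_supports(res[[k]]$node.label, support_field)),
        error = function(e) e)
      if (inherits(gt, "error")) {
        errs <- rbind(errs, data.frame(
          file = f, offset = NA_integer_, message = conditionMessage(gt),
          stringsAsFactors = FALSE))
      } else {
        out[[gid]] <- gt
      }
    }
  }
  if (nrow(errs) > 0L)
    warning(nrow(errs), " input tree(s) could not be read; see attr(,'errors')",
            call. = FALSE)
  if (length(out) == 0L && length(files) > 0L && nrow(errs) > 0L)
    stop("no gene tree could be parsed from ", path)
  attr(out, "errors") <- errs
  out
}

#' Write a gene tree as newick
#'
#' Supports are re-emitted as internal-node labels; branch lengths keep ten
#' significant digits so a read/write cycle is lossless at that precision.
#'
#' @param gt A `gene_tree`.
#' @param file Output path, or `NULL` to return the newick string.
#' @export
write_gene_tree <- function(gt, file = NULL) {
  stopifnot(inherits(gt, "gene_tree"))
  phy <- gt$phy
  lab <- ifelse(is.na(gt$support), "",
                formatC(gt$support, format = "fg", digits = 10))
  phy$node.label <- lab
  s <- ape::write.tree(phy, digits = 10)
  if (is.null(file)) return(s)
  writeLines(s, file, useBytes = TRUE)
  invisible(s)
}

#' Read an aligned codon FASTA
#'
#' Rows are uppercased, `U` is normalised to `T`, and IUPAC ambiguity codes
#' collapse to `N`. Ragged alignments are rejected with the offending
#' records named.
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param gene_id Identifier; defaults to the file stem.
#' @return A `codon_alignment`: list with `gene_id`, `mat` (character matrix,
#'   species x columns over A,C,G,T,N,-) and `length`.
#' @export
read_fasta_codon <- function(path, gene_id = sub("\\.[^.]*$", "", basename(path))) {
  # seqtype "AA" keeps the records verbatim (no DNA-alphabet coercion), so
  # RNA-style U and stray symbols survive to be normalised here
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  lens <- nchar(unlist(seqs))
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[lens != stats::median(lens)]
    stop("unequal row lengths in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ch <- do.call(rbind, strsplit(toupper(unlist(seqs)), ""))
  ch[ch == "U"] <- "T"
  ch[!(ch %in% c("A", "C", "G", "T", "N", "-"))] <- "N"
  rownames(ch) <- names(seqs)
  codon_alignment(gene_id, ch)
}

#' Construct a codon alignment from a character matrix or string vector
#' @param gene_id Identifier.
#' @param x Character matrix (species x columns) or named vector of
#'   equal-length sequence strings.
#' @export
codon_alignment <- function(gene_id, x) {
  if (is.character(x) && !is.matrix(x)) {
    if (length(unique(nchar(x))) > 1L) stop("unequal row lengths")
    nm <- names(x) %||% paste0("seq", seq_along(x))
    x <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(x) <- nm
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  structure(list(gene_id = gene_id, mat = x, length = ncol(x)),
            class = "codon_alignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", x$gene_id, ": ", nrow(x$mat), " sequences x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

#' Write a codon alignment to FASTA
#' @param aln A `codon_alignment`.
#' @param file Output path.
#' @export
write_fasta_codon <- function(aln, file) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", seqs), con, sep = "\n")
  invisible(file)
}

#' Read a per-site log-likelihood table (IQ-TREE `.sitelh` dialect)
#'
#' The format is a whitespace table: an optional header line with two counts
#' (trees, sites), then one row per tree, optionally starting with a tree
#' label (`Tree1` ...), followed by the per-site natural-log likelihoods.
#'
#' @param path Input file.
#' @param gene_id Identifier; defaults to the file stem.
#' @return A `sitelh`: list with `gene_id`, `tree_ids`, and `lnl`
#'   (trees x sites matrix).
#' @export
read_sitelh <- function(path, gene_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty sitelh file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  # optional "ntree nsites" header: two positive integers (log-likelihoods
  # are never positive, so data rows cannot be mistaken for it)
  first <- suppressWarnings(as.numeric(toks[[1L]]))
  if (length(first) == 2L && !anyNA(first) && all(first == round(first)) &&
      all(first > 0))
    toks <- toks[-1L]
  if (length(toks) == 0L) stop("no data rows in ", path)
  ids <- character(length(toks))
  rows <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    v <- suppressWarnings(as.numeric(tk))
    if (is.na(v[1L])) {
      ids[i] <- tk[1L]
      tk <- tk[-1L]
      v <- v[-1L]
    } else ids[i] <- paste0("Tree", i)
    if (anyNA(v)) {
      stop("non-numeric token '", tk[which(is.na(v))[1L]], "' at row ", i,
           ", column ", which(is.na(v))[1L], " of ", path, call. = FALSE)
    }
    rows[[i]] <- v
  }
  ns <- lengths(rows)
  if (length(unique(ns)) > 1L)
    stop("rows of unequal site counts in ", path, ": ",
         paste(ns, collapse = ", "), call. = FALSE)
  lnl <- do.call(rbind, rows)
  rownames(lnl) <- ids
  structure(list(gene_id = gene_id, tree_ids = ids, lnl = lnl),
            class = "sitelh")
}
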