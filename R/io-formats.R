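#' Read a FASTA file into a sequence set
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header line; the remainder of the header is discarded.  Multi-line
#' sequence entries are concatenated.
#'
#' @param path Path to a (multi-)FASTA file.
#' @param alphabet `"aa"` (default) or `"nt"`; used only for validation.
#' @return A named character vector of sequences with attribute
#'   `alphabet`; names are the identifiers, in file order.
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence for id(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  validate_alphabet(seqs, alphabet)
  attr(seqs, "alphabet") <- alphabet
  seqs
}

validate_alphabet <- function(seqs, alphabet) {
  ok <- if (alphabet == "aa") "ACDEFGHIKLMNPQRSTVWYX*-" else "ACGTUN-"
  bad <- grepl(sprintf("[^%s]", ok), seqs)
  if (any(bad)) stop("sequence(s) with characters outside the ", alphabet,
                     " alphabet: ", paste(names(seqs)[bad], collapse = ", "))
  invisible(TRUE)
}

#' Write a sequence set to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Multiple sequence alignment container
#'
#' A thin validated wrapper around a named character vector of equal-length
#' aligned amino-acid sequences.
#'
#' @param seqs Named character vector of aligned sequences (gap `-`,
#'   ambiguity `X` allowed).
#' @return An object of class `clock_msa` with elements `seqs` (named
#'   character vector) and `n_cols`.
#' @export
msa <- function(seqs) {
  if (is.list(seqs)) seqs <- unlist(seqs)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  if (anyDuplicated(names(seqs)))
    stop("duplicate ids in alignment: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("aligned sequences have unequal lengths: ", paste(w, collapse = ", "))
  if (w == 0L) stop("alignment has zero columns")
  structure(list(seqs = seqs, n_cols = w), class = "clock_msa")
}

#' @export
print.clock_msa <- function(x, ...) {
  cat("<clock_msa> ", length(x$seqs), " sequences x ", x$n_cols, " columns\n", sep = "")
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences, columns = sites)
#' @param x A `clock_msa`.
#' @return Character matrix with rownames = sequence ids.
#' @export
msa_matrix <- function(x) {
  stopifnot(inherits(x, "clock_msa"))
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- names(x$seqs)
  m
}

#' Read a Newick tree
#'
#' Accepts a Newick string or a file path.  Internal node labels and quoted
#' labels are tolerated; missing branch lengths are set to 0 with a warning.
#'
#' @param x Newick text (contains parentheses/semicolon) or a file path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  txt <- if (grepl("[(;]", x)) x else paste(readLines(x), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string: ", substr(txt, 1, 60))
  if (is.null(tr$edge.length)) {
    warning("Newick tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree")
  tr
}

#' Write a tree as Newick text
#' @param tree An [ape::phylo] tree.
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Truncate identifiers for PHYLIP output, preserving trailing gene numbers
#'
#' Identifiers longer than 10 characters are shortened by keeping the
#' trailing run of digits (the gene number) intact and as much of the
#' leading text as still fits in 10 characters.
#'
#' @param ids Character vector of identifiers.
#' @return Named character vector: truncated id -> original id.
#' @export
phylip_ids <- function(ids) {
  stopifnot(!anyDuplicated(ids))
  short <- vapply(ids, function(id) {
    if (nchar(id) <= 10L) return(id)
    num <- regmatches(id, regexpr("[0-9]+$", id))
    if (length(num) == 0L || nchar(num) >= 10L) return(substr(id, 1L, 10L))
    head_len <- 10L - nchar(num)
    paste0(substr(id, 1L, head_len), num)
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(short))
    stop("identifier truncation collision: ",
         paste(unique(short[duplicated(short)]), collapse = ", "),
         " (supply an explicit id_map)")
  stats::setNames(ids, short)
}

#' Write an alignment in relaxed sequential PHYLIP format
#'
#' @param x A `clock_msa`.
#' @param id_map Optional named character vector mapping short id -> original
#'   id (as returned by [phylip_ids()]); computed automatically when `NULL`.
#' @param path Optional output path.
#' @return The PHYLIP text as a character vector of lines, with the id map in
#'   attribute `id_map` for round-tripping.
#' @export
write_phylip <- function(x, id_map = NULL, path = NULL) {
  stopifnot(inherits(x, "clock_msa"))
  ids <- names(x$seqs)
  if (is.null(id_map)) id_map <- phylip_ids(ids)
  if (anyDuplicated(names(id_map)))
    stop("id_map short names are not unique")
  if (any(nchar(names(id_map)) > 10L))
    stop("id_map short names exceed 10 characters: ",
         paste(names(id_map)[nchar(names(id_map)) > 10L], collapse = ", "))
  if (!setequal(unname(id_map), ids))
    stop("id_map does not cover the alignment ids")
  rev_map <- stats::setNames(names(id_map), unname(id_map))
  lines <- c(paste(length(x$seqs), x$n_cols),
             paste(formatC(rev_map[ids], width = -10L), x$seqs))
  if (!is.null(path)) writeLines(lines, path)
  structure(lines, id_map = id_map)
}

#' Read the per-gene clock study table
#'
#' Reads a TSV with columns `gene`, `group` (TTFL or PTM), `model`,
#' `nucleotides` and optionally `relative_rate`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame, one row per gene.
#' @export
read_gene_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "group", "model", "nucleotides")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(d$group), c("TTFL", "PTM"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(d$gene)) stop("duplicate gene names in table")
  if (any(!is.finite(d$nucleotides)) || any(d$nucleotides <= 0))
    stop("nucleotide counts must be positive")
  d
}

#' The packaged 17-gene clock study table
#'
#' Gene names, TTFL/PTM group membership, best-fit substitution model,
#' transcript nucleotide counts and published per-gene relative rates for
#' the nine TTFL and eight PTM circadian clock genes of the focal mosquito
#' study.
#'
#' @return A 17-row data.frame (see [read_gene_table()]).
#' @export
clock_gene_table <- function() {
  read_gene_table(system.file("extdata", "table4_clock_genes.tsv",
                              package = "clockdiv", mustWork = TRUE))
}
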