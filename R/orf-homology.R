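#' Translate a nucleotide sequence in a given frame and strand
#'
#' Uses the standard genetic code.  Stop codons become `*`, codons containing
#' ambiguity characters become `X`, and a trailing partial codon is dropped.
#'
#' @param seq Nucleotide string (or length-1 named character vector).
#' @param frame 0, 1 or 2: offset from the 5' end of the chosen strand.
#' @param strand `"+"` or `"-"`; `"-"` translates the reverse complement.
#' @return Protein string.
#' @export
translate_seq <- function(seq, frame = 0L, strand = "+") {
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  s <- toupper(as.character(seq)[1])
  if (strand == "-") s <- revcomp(s)
  s <- substr(s, frame + 1L, nchar(s))
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return("")
  codons <- substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Find the longest open reading frame over both strands
#'
#' Scans all three frames on both strands for ORFs that start at `ATG`
#' (when `require_atg`) and end at a stop codon or, when
#' `allow_open_ended`, at the 3' end of the frame.  Ties are broken by
#' longer length, then `+` strand before `-`, then smaller start.
#'
#' @param seq Nucleotide string.
#' @param require_atg Must the ORF start with ATG? Default `TRUE`.
#' @param allow_open_ended Allow ORFs running off the 3' end without a stop
#'   codon? Default `TRUE`.
#' @return A list of class `orf` with elements `start`, `end` (0-based
#'   half-open on the input sequence), `frame`, `strand`, `length_nt` and
#'   `protein` (stop codon excluded), or `NULL` when no ORF exists.
#' @export
find_longest_orf <- function(seq, require_atg = TRUE, allow_open_ended = TRUE) {
  s <- toupper(as.character(seq)[1])
  L <- nchar(s)
  if (L < 3L) stop("sequence shorter than one codon")
  best <- NULL
  for (strand in c("+", "-")) {
    work <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3L
      if (n_codons == 0L) next
      codons <- substring(work, frame + 3L * seq_len(n_codons) - 2L,
                          frame + 3L * seq_len(n_codons))
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_start <- if (require_atg) codons == "ATG" else !is_stop
      # segment the codon run at stop codons
      seg <- cumsum(is_stop) - is_stop * 1L  # segment id per codon
      for (sg in unique(seg)) {
        idx <- which(seg == sg & !is_stop)
        if (!length(idx)) next
        starts <- idx[is_start[idx]]
        if (!length(starts)) next
        first <- min(starts)
        last <- max(idx)                       # last coding codon of segment
        has_stop <- (last < n_codons) && is_stop[last + 1L]
        if (!has_stop && !allow_open_ended) next
        # codon positions -> nt coords on the working strand (0-based)
        w_start <- frame + 3L * (first - 1L)
        w_end <- frame + 3L * last + (if (has_stop) 3L else 0L)
        len <- w_end - w_start
        cand <- list(w_start = w_start, w_end = w_end, frame = frame,
                     strand = strand, length_nt = len)
        if (is.null(best) ||
            len > best$length_nt ||
            (len == best$length_nt && best$strand == "-" && strand == "+")) {
          best <- cand
        } else if (len == best$length_nt && strand == best$strand) {
          if (orf_input_start(cand, L) < orf_input_start(best, L)) best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  start <- orf_input_start(best, L)
  end <- start + best$length_nt
  work <- if (best$strand == "+") s else revcomp(s)
  prot <- translate_seq(substr(work, best$w_start + 1L, best$w_end), 0L, "+")
  prot <- sub("\\*$", "", prot)
  structure(list(start = start, end = end, frame = best$frame,
                 strand = best$strand, length_nt = best$length_nt,
                 protein = prot),
            class = "orf")
}

# map working-strand coordinates back onto the input sequence
orf_input_start <- function(cand, L) {
  if (cand$strand == "+") cand$w_start else L - cand$w_end
}

#' Trim untranslated regions from a transcript using its ORF
#'
#' Returns the protein encoded by the ORF interval of the underlying
#' nucleotide record, i.e. the sequence with 5' and 3' UTRs removed and
#' translated.
#'
#' @param seq Named nucleotide sequence (length-1 named character vector).
#' @param orf An `orf` object from [find_longest_orf()] for the same record.
#' @return Named protein sequence; the id gains a `_cds` suffix.
#' @export
trim_utrs <- function(seq, orf) {
  stopifnot(inherits(orf, "orf"))
  s <- toupper(as.character(seq)[1])
  id <- names(seq)[1]
  if (is.null(id)) id <- "seq"
  if (orf$end > nchar(s) || orf$start < 0L)
    stop("ORF interval [", orf$start, ",", orf$end, ") out of bounds for ",
         id, " (length ", nchar(s), ")")
  cds <- substr(s, orf$start + 1L, orf$end)
  if (orf$strand == "-") cds <- revcomp(cds)
  prot <- sub("\\*$", "", translate_seq(cds, 0L, "+"))
  stats::setNames(prot, paste0(id, "_cds"))
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gap costs (a gap of length
#' `k` costs `gap_open + k * gap_extend`), by default under BLOSUM62 with
#' the standard protein-search penalties (open 11, extend 1).
#'
#' @param a,b Protein strings (optionally named; names become the ids).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A list of class `alignment_hit`: `query_id`, `subject_id`,
#'   `score`, `identity` (fraction of identical aligned non-gap columns),
#'   `query_span`, `subject_span` (0-based half-open).  A pair with no
#'   positive-scoring cell yields score 0 and empty spans.
#' @export
local_align <- function(a, b, matrix = NULL, gap_open = 11, gap_extend = 1) {
  if (is.null(matrix)) matrix <- blosum62()
  qa <- toupper(as.character(a)[1]); qb <- toupper(as.character(b)[1])
  if (!nzchar(qa) || !nzchar(qb)) stop("empty sequence in local_align")
  ids <- c(names(a)[1] %||% "query", names(b)[1] %||% "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qa), Biostrings::AAString(qb), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(query_id = ids[1], subject_id = ids[2], score = 0,
                          identity = NA_real_,
                          query_span = c(0L, 0L), subject_span = c(0L, 0L)),
                     class = "alignment_hit"))
  }
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cp <- strsplit(ap, "")[[1]]; cs <- strsplit(as_, "")[[1]]
  aligned <- cp != "-" & cs != "-"
  ident <- sum(cp[aligned] == cs[aligned]) / sum(aligned)
  p <- pa@pattern; s <- pa@subject
  structure(list(
    query_id = ids[1], subject_id = ids[2], score = sc, identity = ident,
    query_span = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
    subject_span = c(Biostrings::start(s) - 1L, Biostrings::end(s))),
    class = "alignment_hit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Rank local-alignment hits of a query against a target set
#'
#' @param query Named protein sequence (length-1 named character vector).
#' @param targets Named character vector of protein sequences.
#' @param min_score Minimum score to report (default 0: any positive hit).
#' @param delta Uniqueness margin as a fraction of the top score: the best
#'   hit is flagged `unique_best` only when it exceeds the runner-up by at
#'   least `delta * top_score`.  Default 0.1.
#' @return A data.frame of hits sorted by (score desc, subject asc) with an
#'   attribute `unique_best`; zero rows when nothing scores above
#'   `min_score`.
#' @export
best_hit <- function(query, targets, min_score = 0, delta = 0.1) {
  stopifnot(length(targets) >= 1L, !is.null(names(targets)))
  hits <- lapply(names(targets), function(id) {
    h <- local_align(query, stats::setNames(targets[id], id))
    data.frame(query = h$query_id, subject = id, score = h$score,
               identity = h$identity,
               q_start = h$query_span[1], q_end = h$query_span[2],
               s_start = h$subject_span[1], s_end = h$subject_span[2],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, hits)
  tab <- tab[tab$score > 0 & tab$score >= min_score, , drop = FALSE]
  tab <- tab[order(-tab$score, tab$subject), , drop = FALSE]
  rownames(tab) <- NULL
  unique_best <- nrow(tab) == 1L ||
    (nrow(tab) >= 2L && (tab$score[1] - tab$score[2]) >= delta * tab$score[1])
  attr(tab, "unique_best") <- isTRUE(unique_best) && nrow(tab) >= 1L
  tab
}

#' Assign single-copy orthologs by unique best local-alignment hit
#'
#' For each reference gene, the reference protein is searched against the
#' candidate set (a transcriptome stand-in).  A gene is `assigned` to its
#' top-scoring candidate when the best hit is unique by the margin rule and
#' does not belong to a declared multi-gene family; genes whose top hits are
#' ambiguous or fall in a multi-gene family are `deferred` to tree-based
#' clade assignment; genes with no hit at all are `absent`.
#'
#' @param query_set Named character vector of candidate protein sequences.
#' @param reference_orthologs Named character vector, one reference protein
#'   per gene (names are gene names).
#' @param multigene_families Optional list of character vectors of gene
#'   names forming multi-gene families (e.g. the cryptochrome family).
#' @param min_score,delta Passed to [best_hit()].
#' @return A data.frame with columns `gene`, `status`
#'   (`assigned`/`deferred`/`absent`) and `candidate` (NA unless assigned).
#' @export
assign_single_copy <- function(query_set, reference_orthologs,
                               multigene_families = list(),
                               min_score = 0, delta = 0.1) {
  stopifnot(length(reference_orthologs) >= 1L,
            !is.null(names(reference_orthologs)))
  fam_genes <- unlist(multigene_families, use.names = FALSE)
  out <- lapply(names(reference_orthologs), function(g) {
    hits <- best_hit(stats::setNames(reference_orthologs[g], g), query_set,
                     min_score = min_score, delta = delta)
    if (nrow(hits) == 0L)
      return(data.frame(gene = g, status = "absent", candidate = NA_character_))
    if (g %in% fam_genes || !attr(hits, "unique_best"))
      return(data.frame(gene = g, status = "deferred", candidate = NA_character_))
    data.frame(gene = g, status = "assigned", candidate = hits$subject[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
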