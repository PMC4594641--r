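#' Classify alignment columns by conservation
#'
#' A column is scored by the count of its most frequent residue (gaps and
#' `X` are not counted as residues): below `b1` it is `nonconserved`, at or
#' above `b2` it is `highly_conserved`, otherwise `conserved`.  Gap status
#' follows `gap_policy`: under `"none"` any gap flags the column, under
#' `"half"` only a column with more than half gaps is flagged, and under
#' `"all"` gap content is ignored.
#'
#' @param x A `clock_msa`.
#' @param b1 Minimum identical residues for a conserved column; default
#'   `floor(n_seqs/2) + 1`.
#' @param b2 Minimum identical residues for a highly conserved column;
#'   default `floor(0.85 * n_seqs)`, clamped up to `b1` with a warning.
#' @param gap_policy `"none"` (default), `"half"` or `"all"`.
#' @return A data.frame with columns `index` (0-based), `conservation`
#'   (factor: nonconserved/conserved/highly_conserved) and `has_gap`.
#' @export
classify_columns <- function(x, b1 = NULL, b2 = NULL,
                             gap_policy = c("none", "half", "all")) {
  stopifnot(inherits(x, "clock_msa"))
  gap_policy <- match.arg(gap_policy)
  n <- length(x$seqs)
  if (is.null(b1)) b1 <- n %/% 2L + 1L
  if (is.null(b2)) b2 <- max(floor(0.85 * n), b1)
  if (b2 < b1) stop("b2 (", b2, ") must be >= b1 (", b1, ")")
  m <- msa_matrix(x)
  res <- apply(m, 2L, function(col) {
    residues <- col[!col %in% c("-", "X")]
    top <- if (length(residues)) max(table(residues)) else 0L
    gaps <- sum(col == "-")
    c(top = top, gaps = gaps)
  })
  top <- res["top", ]; gaps <- res["gaps", ]
  conservation <- ifelse(top < b1, "nonconserved",
                         ifelse(top >= b2, "highly_conserved", "conserved"))
  has_gap <- switch(gap_policy,
                    none = gaps > 0L,
                    half = gaps > n / 2,
                    all = rep(FALSE, x$n_cols))
  data.frame(index = seq_len(x$n_cols) - 1L,
             conservation = factor(conservation,
                                   levels = c("nonconserved", "conserved",
                                              "highly_conserved")),
             has_gap = has_gap)
}

#' Select conserved alignment blocks from column classifications
#'
#' Applies, in order: (1) removal of stretches of more than `b3` contiguous
#' nonconserved columns; (2) trimming of each remaining segment's flanks up
#' to the first and last highly conserved column; (3) removal of columns
#' with disallowed gaps, re-splitting segments; (4) rejection of blocks
#' shorter than `b4`.
#'
#' @param statuses Output of [classify_columns()].
#' @param b3 Maximum allowed stretch of contiguous nonconserved columns
#'   inside a block (default 8).
#' @param b4 Minimum block length (default 10).
#' @return A list of class `block_selection`: `kept` (matrix of 0-based
#'   half-open intervals, columns `start`/`end`) and `params`.
#' @export
select_blocks <- function(statuses, b3 = 8L, b4 = 10L) {
  stopifnot(all(c("index", "conservation", "has_gap") %in% names(statuses)))
  n <- nrow(statuses)
  keep <- rep(TRUE, n)
  noncon <- statuses$conservation == "nonconserved"

  # (1) drop runs of > b3 contiguous nonconserved columns
  r <- rle(noncon)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] > b3) keep[starts[i]:ends[i]] <- FALSE

  # (2) trim flanks of each surviving segment back to highly conserved ends
  hc <- statuses$conservation == "highly_conserved"
  segs <- runs_of(keep)
  keep2 <- rep(FALSE, n)
  for (s in segs) {
    idx <- s[1]:s[2]
    h <- idx[hc[idx]]
    if (length(h)) keep2[min(h):max(h)] <- TRUE
  }

  # (3) drop gap-flagged columns and re-split
  keep3 <- keep2 & !statuses$has_gap

  # (4) enforce minimum block length
  blocks <- runs_of(keep3)
  blocks <- Filter(function(s) s[2] - s[1] + 1L >= b4, blocks)
  kept <- if (length(blocks)) {
    do.call(rbind, lapply(blocks, function(s) c(start = s[1] - 1L, end = s[2])))
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  structure(list(kept = kept, params = list(b3 = b3, b4 = b4)),
            class = "block_selection")
}

# maximal runs of TRUE as list of c(first, last), 1-based
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

#' Extract the selected columns from an alignment
#'
#' @param x A `clock_msa`.
#' @param selection A `block_selection` from [select_blocks()].
#' @return A `clock_msa` of the concatenated kept columns, with attribute
#'   `fraction_retained`.
#' @export
apply_blocks <- function(x, selection) {
  stopifnot(inherits(x, "clock_msa"), inherits(selection, "block_selection"))
  kept <- selection$kept
  if (nrow(kept) == 0L)
    stop("block selection is empty; consider relaxing b1-b4 or the gap policy")
  if (any(kept[, "start"] < 0L) || any(kept[, "end"] > x$n_cols))
    stop("block selection out of alignment bounds")
  cols <- unlist(lapply(seq_len(nrow(kept)),
                        function(i) (kept[i, "start"] + 1L):kept[i, "end"]))
  m <- msa_matrix(x)[, cols, drop = FALSE]
  out <- msa(stats::setNames(apply(m, 1L, paste, collapse = ""), names(x$seqs)))
  attr(out, "fraction_retained") <- length(cols) / x$n_cols
  out
}

#' One-call conserved-block trimming of an alignment
#'
#' Convenience wrapper chaining [classify_columns()], [select_blocks()] and
#' [apply_blocks()] with canonical default thresholds.
#'
#' @inheritParams classify_columns
#' @inheritParams select_blocks
#' @return Trimmed `clock_msa` (see [apply_blocks()]); the selection used is
#'   stored in attribute `selection`.
#' @export
trim_alignment <- function(x, b1 = NULL, b2 = NULL, b3 = 8L, b4 = 10L,
                           gap_policy = "none") {
  sel <- select_blocks(classify_columns(x, b1, b2, gap_policy), b3, b4)
  out <- apply_blocks(x, sel)
  attr(out, "selection") <- sel
  out
}
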