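#' Maximum-likelihood distance between two aligned sequences
#'
#' Finds the branch length `t` maximising the two-sequence likelihood
#' `sum_s log[pi(x_s) P_t(x_s, y_s)]` (with the model's gamma/invariant
#' mixture when present) by bounded 1-D optimisation on `[1e-8, 20]`.
#' Sites missing in either sequence are skipped.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @param model An `aa_model` (with `alpha`/`p_inv` set as applicable), or a
#'   prebuilt `model_machine`.
#' @return The ML distance in expected substitutions per site.
#' @export
ml_pairwise_distance <- function(a, b, model) {
  machine <- if (inherits(model, "model_machine")) model else model_machine(model)
  mod <- machine$model
  stopifnot(nchar(a) == nchar(b))
  lev <- aa_levels()
  ca <- match(strsplit(toupper(as.character(a)[1]), "")[[1]], lev)
  cb <- match(strsplit(toupper(as.character(b)[1]), "")[[1]], lev)
  rates <- if (mod$gamma) discrete_gamma_rates(mod$alpha, mod$k) else 1
  p_inv <- if (mod$inv) mod$p_inv else 0
  opt <- stats::optimize(function(t) -two_seq_loglik(ca, cb, machine, t,
                                                    rates, p_inv),
                         interval = c(1e-8, 20), tol = 1e-7)
  opt$minimum
}

#' All-pairs ML distance matrix of an alignment
#'
#' @param x A `clock_msa`.
#' @param model An `aa_model`.
#' @return Symmetric distance matrix with the alignment's ids.
#' @export
ml_distance_matrix <- function(x, model) {
  stopifnot(inherits(x, "clock_msa"))
  machine <- model_machine(model)
  ids <- names(x$seqs)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- ml_pairwise_distance(x$seqs[i], x$seqs[j], machine)
  }
  d
}

#' Neighbor-joining gene tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch-length
#' estimates are clamped to zero with the deficit transferred to the
#' sibling branch so patristic path lengths through the parent node are
#' preserved.
#'
#' @param dm Symmetric distance matrix with row/column names (>= 3 taxa; a
#'   2-taxon matrix returns the trivial one-branch tree).
#' @return Unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  check_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    txt <- sprintf("(%s:%f,%s:%f);", rownames(dm)[1], dm[1, 2] / 2,
                   rownames(dm)[2], dm[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(dm)
  clamp_negative_branches(tr)
}

clamp_negative_branches <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (i in neg) {
    deficit <- tr$edge.length[i]
    parent <- tr$edge[i, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), i)
    tr$edge.length[i] <- 0
    if (length(sibs)) {
      s <- sibs[order(tr$edge[sibs, 2])][1]
      tr$edge.length[s] <- tr$edge.length[s] + deficit
      if (tr$edge.length[s] < 0) tr$edge.length[s] <- 0
    }
  }
  tr
}

check_distance_matrix <- function(dm) {
  if (is.null(rownames(dm)) || is.null(colnames(dm)))
    stop("distance matrix needs row and column names")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  if (any(!is.finite(dm))) stop("non-finite distances")
  if (any(diag(dm) != 0)) stop("nonzero diagonal in distance matrix")
  if (any(dm < 0)) stop("negative distances")
  invisible(TRUE)
}

#' Optimise branch lengths by maximum likelihood on a fixed topology
#'
#' Coordinate-wise bounded 1-D optimisation of every branch, sweeping until
#' the log-likelihood improves by less than `tol` or `max_sweeps` is
#' reached.  The log-likelihood never decreases between sweeps.
#'
#' @param tree Starting [ape::phylo] with branch lengths.
#' @param x A `clock_msa` whose ids match the tree's tips.
#' @param model An `aa_model`.
#' @param max_sweeps,tol Convergence controls.
#' @return The tree with optimised branch lengths; the final log-likelihood
#'   is stored in attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, x, model, max_sweeps = 20L,
                                    tol = 1e-6) {
  ll <- prune_loglik(tree, x, model)$loglik
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_along(tree$edge.length)) {
      opt <- stats::optimize(function(t) {
        tr2 <- tree; tr2$edge.length[e] <- t
        -prune_loglik(tr2, x, model)$loglik
      }, interval = c(0, 10), tol = 1e-7)
      if (-opt$objective > ll - 1e-12) {
        tree$edge.length[e] <- opt$minimum
      }
    }
    new_ll <- prune_loglik(tree, x, model)$loglik
    if (new_ll < ll - 1e-8)
      stop("internal error: log-likelihood decreased during sweep")
    improved <- new_ll - ll
    ll <- new_ll
    if (improved < tol) break
  }
  if (sweep == max_sweeps && improved >= tol)
    warning("branch-length optimisation did not converge in ", max_sweeps,
            " sweeps; returning best tree so far")
  attr(tree, "loglik") <- ll
  tree
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of
#' leaves.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @return Symmetric matrix ordered by the tree's tip labels.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Root a tree on the branch leading to an outgroup
#'
#' The outgroup must be a single leaf or a set of leaves forming a clade of
#' the unrooted tree; the root is placed at the midpoint of the branch
#' separating the outgroup from the rest.  Patristic distances are
#' unchanged by rooting.
#'
#' @param tree Unrooted (or rooted) [ape::phylo].
#' @param outgroup_ids Character vector of leaf labels.
#' @param allow_extra Accept the smallest clade containing all
#'   `outgroup_ids` even if it holds additional leaves (e.g. a still
#'   unassigned candidate falling inside the rooting subfamily).  Default
#'   `FALSE`: the outgroup must be exactly a clade.
#' @return Rooted [ape::phylo].
#' @export
root_tree <- function(tree, outgroup_ids, allow_extra = FALSE) {
  missing_ids <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing_ids))
    stop("outgroup leaves not in tree: ", paste(missing_ids, collapse = ", "))
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  nt <- length(tr$tip.label)
  if (length(outgroup_ids) >= nt)
    stop("outgroup cannot contain every leaf")
  # find the edge whose bipartition separates the outgroup from the rest;
  # with allow_extra, the side holding the outgroup may carry extra leaves
  # and the edge minimising their number (smallest enclosing clade) wins
  sep <- NA_integer_
  best_extra <- Inf
  for (i in seq_len(nrow(tr$edge))) {
    child <- tr$edge[i, 2]
    below <- if (child <= nt) tr$tip.label[child]
             else ape::extract.clade(tr, child)$tip.label
    for (side in list(below, setdiff(tr$tip.label, below))) {
      if (!all(outgroup_ids %in% side)) next
      extra <- length(side) - length(outgroup_ids)
      if (extra == 0L || (allow_extra && extra < best_extra)) {
        best_extra <- extra
        sep <- i
      }
      if (extra == 0L) break
    }
    if (!is.na(sep) && best_extra == 0L) break
  }
  if (is.na(sep) || (!allow_extra && best_extra > 0))
    stop("outgroup is not monophyletic: ", paste(outgroup_ids, collapse = ", "))
  phytools::reroot(tr, tr$edge[sep, 2], position = tr$edge.length[sep] / 2)
}

#' Assign candidate leaves to genes by smallest enclosing reference clade
#'
#' Each reference gene is represented by labelled leaves in a rooted gene
#' tree.  A candidate is assigned to gene `g` when the smallest clade
#' containing the candidate and at least one reference leaf contains only
#' `g`'s reference leaves among all references; otherwise it is
#' `ambiguous`.  Reference genes must be mutually monophyletic (ignoring
#' candidate leaves).
#'
#' @param tree Rooted [ape::phylo].
#' @param candidate_ids Leaf labels of the candidates to place.
#' @param reference_map Named list: gene name -> character vector of
#'   reference leaf labels.
#' @return Data.frame with columns `candidate` and `gene` (`"ambiguous"`
#'   when unresolved).
#' @export
assign_by_clade <- function(tree, candidate_ids, reference_map) {
  stopifnot(all(candidate_ids %in% tree$tip.label))
  ref_leaves <- unlist(reference_map, use.names = FALSE)
  stopifnot(all(ref_leaves %in% tree$tip.label))
  leaf_gene <- rep(names(reference_map), lengths(reference_map))
  names(leaf_gene) <- ref_leaves
  # mutual monophyly among references: the MRCA clade of each gene's
  # leaves must contain no other gene's leaves
  for (g in names(reference_map)) {
    refs <- reference_map[[g]]
    if (length(refs) < 2L) next
    mr <- ape::getMRCA(tree, refs)
    below <- ape::extract.clade(tree, mr)$tip.label
    others <- intersect(below, setdiff(ref_leaves, refs))
    if (length(others))
      stop("reference genes are not mutually monophyletic; clade of ", g,
           " also contains: ", paste(others, collapse = ", "))
  }
  nt <- length(tree$tip.label)
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  res <- lapply(candidate_ids, function(cand) {
    node <- match(cand, tree$tip.label)
    gene <- "ambiguous"
    repeat {
      p <- parent_of(node)
      if (length(p) == 0L) break              # reached the root
      below <- ape::extract.clade(tree, p)$tip.label
      refs_below <- intersect(below, ref_leaves)
      if (length(refs_below)) {
        genes <- unique(leaf_gene[refs_below])
        if (length(genes) == 1L) gene <- genes
        break
      }
      node <- p
    }
    data.frame(candidate = cand, gene = gene, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
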