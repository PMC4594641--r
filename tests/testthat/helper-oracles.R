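# Independent oracles and small fixtures shared across tests.
# Each oracle is a deliberately naive implementation kept separate from the
# package code paths it checks.

# --- local alignment: brute force over all substring pairs, each scored by
#     a simple global affine-gap dynamic programme (gap of length k costs
#     open + k * extend)
global_affine_score <- function(a, b, mat, open, extend) {
  m <- nchar(a); n <- nchar(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  neg <- -1e9
  M <- matrix(neg, m + 1, n + 1)   # last move: match
  X <- matrix(neg, m + 1, n + 1)   # last move: gap in b (up)
  Y <- matrix(neg, m + 1, n + 1)   # last move: gap in a (left)
  M[1, 1] <- 0
  for (i in seq_len(m) + 1) X[i, 1] <- -(open + (i - 1) * extend)
  for (j in seq_len(n) + 1) Y[1, j] <- -(open + (j - 1) * extend)
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      s <- mat[ca[i - 1], cb[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

sw_brute <- function(a, b, mat, open = 11, extend = 1) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a)) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      sb <- substr(b, j1, j2)
      best <- max(best, global_affine_score(sa, sb, mat, open, extend))
    }
  }
  best
}

# --- pruning likelihood: exhaustive enumeration over internal-node states
brute_loglik <- function(tree, aln, model) {
  machine <- model_machine(model)
  lev <- aa_levels()
  m <- msa_matrix(aln)
  nt <- length(tree$tip.label)
  n_int <- tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  root <- post$edge[nrow(post$edge), 1]
  Ps <- lapply(seq_len(nrow(post$edge)),
               function(i) transition_probs(machine, post$edge.length[i]))
  per_site <- numeric(ncol(m))
  int_nodes <- sort(unique(post$edge[, 1]))
  grid <- do.call(expand.grid, rep(list(1:20), n_int))
  for (s in seq_len(ncol(m))) {
    tip_state <- match(m[, s], lev)[match(tree$tip.label, rownames(m))]
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(node) {
        if (node <= nt) tip_state[node]
        else grid[g, match(node, int_nodes)]
      }
      p <- machine$freq[assign_state(root)]
      for (i in seq_len(nrow(post$edge))) {
        a <- assign_state(post$edge[i, 1]); b <- assign_state(post$edge[i, 2])
        p <- p * if (is.na(b)) 1 else Ps[[i]][a, b]   # NA tip = missing
      }
      tot <- tot + p
    }
    per_site[s] <- log(tot)
  }
  sum(per_site)
}

# --- classic two-sided 2x2 Fisher p from the hypergeometric closed form
fisher_2x2_closed <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  sum(probs[probs <= stats::dhyper(x_obs, m, n, k) * (1 + 1e-7)])
}

# --- random additive tree + its exact patristic matrix
random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}

# quick random protein-like msa
random_msa <- function(n_seq, n_col, seed, alphabet = c("A", "R", "N", "D")) {
  set.seed(seed)
  seqs <- replicate(n_seq, paste(sample(alphabet, n_col, TRUE), collapse = ""))
  msa(stats::setNames(seqs, paste0("s", seq_len(n_seq))))
}

blosum62_test <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
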