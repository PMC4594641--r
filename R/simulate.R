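# Synthetic seven-taxon clock-gene studies with known ground truth.
# Taxon names and the species-tree shape mirror the focal-mosquito study
# design: the focal sabethine lineage sits inside the Culicidae next to an
# Aedes/Culex pair, with Anopheles, Drosophila, a butterfly and a wasp as
# progressively deeper outgroups.

#' Default seven-taxon species tree for synthetic studies
#'
#' Branch lengths are calibrated so the mean pairwise patristic distance is
#' about 1 substitution/site (a deep, partly saturated regime) with a focal
#' terminal branch of 0.1.
#'
#' @return Rooted [ape::phylo] with 7 tips; the focal taxon is
#'   `"Wsmithii"`.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((Wsmithii:0.1,(Aaegypti:0.15,Cquinquefasciatus:0.15):0.05):0.15,",
    "Agambiae:0.3):0.2,Dmelanogaster:0.55):0.15,Dplexippus:0.7):0.2,",
    "Nvitripennis:0.9);"))
}

#' Default 17-gene configuration for synthetic clock studies
#'
#' Nine TTFL and eight PTM genes with protein lengths matching the study's
#' transcript nucleotide counts (one residue per codon) and neutral focal
#' rate multipliers.
#'
#' @return Data.frame with columns `gene`, `group`, `n_sites`,
#'   `multiplier`.
#' @export
default_clock_genes <- function() {
  tab <- clock_gene_table()
  data.frame(gene = tab$gene, group = tab$group,
             n_sites = pmax(50L, round(tab$nucleotides / 3)),
             multiplier = 1, stringsAsFactors = FALSE)
}

#' Default taxon dropout for synthetic studies
#'
#' Mirrors the study's pattern of lineage-specific gene losses: one TTFL
#' gene absent in the Drosophila-like taxon, and two genes absent in the
#' wasp-like taxon.
#'
#' @return Named list: gene -> character vector of absent taxa.
#' @export
default_dropout <- function() {
  list(cry2 = c("Dmelanogaster", "Nvitripennis"),
       tim = "Nvitripennis")
}

#' Configuration object for [simulate_clock_study()]
#'
#' @param species_tree Rooted species tree with branch lengths.
#' @param genes Data.frame with columns `gene`, `group`, `n_sites`,
#'   `multiplier` (focal terminal-branch scaling, >= 0).
#' @param model `aa_model` used to simulate (default JTT).
#' @param dropout Named list gene -> taxa absent for that gene.
#' @param focal_id Focal taxon label (a tip of `species_tree`).
#' @param seed Integer seed fixing all randomness of the study.
#' @return List of class `clock_study_config`.
#' @export
clock_study_config <- function(species_tree = default_species_tree(),
                               genes = default_clock_genes(),
                               model = aa_model("JTT"),
                               dropout = default_dropout(),
                               focal_id = "Wsmithii",
                               seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"),
            all(c("gene", "group", "n_sites", "multiplier") %in% names(genes)),
            all(genes$n_sites >= 1L), all(genes$multiplier >= 0),
            inherits(model, "aa_model"),
            focal_id %in% species_tree$tip.label)
  for (g in names(dropout)) {
    if (!g %in% genes$gene) stop("dropout for unknown gene: ", g)
    if (focal_id %in% dropout[[g]])
      stop("dropout would remove the focal taxon for gene ", g)
    if (!all(dropout[[g]] %in% species_tree$tip.label))
      stop("dropout names unknown taxa for gene ", g)
  }
  structure(list(species_tree = species_tree, genes = genes, model = model,
                 dropout = dropout, focal_id = focal_id,
                 seed = as.integer(seed)),
            class = "clock_study_config")
}

#' Simulate an alignment along a tree under a substitution model
#'
#' Root states are drawn from the model's equilibrium frequencies and
#' evolved down every branch with the model's transition probabilities.
#' For `+G` models a discrete gamma category is drawn per site; for `+I`
#' models a site is invariant with probability `p_inv`.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param model An `aa_model` (with `alpha`/`p_inv` set as applicable).
#' @param n_sites Number of alignment columns.
#' @param seed Optional integer seed.
#' @return A `clock_msa` of the leaf sequences (gap-free).
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(n_sites >= 1L)
  if (!is.null(seed)) set.seed(seed)
  machine <- model_machine(model)
  site_rates <- rep(1, n_sites)
  if (model$gamma)
    site_rates <- sample(discrete_gamma_rates(model$alpha, model$k),
                         n_sites, replace = TRUE)
  if (model$inv)
    site_rates[stats::runif(n_sites) < model$p_inv] <- 0
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  pre <- ape::reorder.phylo(tree, "postorder")
  states <- matrix(NA_integer_, nn, n_sites)
  root <- pre$edge[nrow(pre$edge), 1]
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = machine$freq)
  rate_groups <- split(seq_len(n_sites), site_rates)
  for (i in rev(seq_len(nrow(pre$edge)))) {   # preorder: root -> tips
    parent <- pre$edge[i, 1]; child <- pre$edge[i, 2]
    t_edge <- pre$edge.length[i]
    for (rg in names(rate_groups)) {
      cols <- rate_groups[[rg]]
      r <- as.numeric(rg)
      if (t_edge * r == 0) {
        states[child, cols] <- states[parent, cols]
        next
      }
      P <- transition_probs(machine, t_edge * r)
      par_states <- states[parent, cols]
      for (s in 1:20) {
        sel <- which(par_states == s)
        if (length(sel))
          states[child, cols[sel]] <- sample.int(20L, length(sel),
                                                 replace = TRUE, prob = P[s, ])
      }
    }
  }
  lev <- aa_levels()
  seqs <- apply(states[seq_len(nt), , drop = FALSE], 1L,
                function(row) paste(lev[row], collapse = ""))
  msa(stats::setNames(seqs, tree$tip.label))
}

# scale the terminal branch of one tip by a multiplier
scale_focal_branch <- function(tree, focal_id, m) {
  tip <- match(focal_id, tree$tip.label)
  e <- which(tree$edge[, 2] == tip)
  tree$edge.length[e] <- tree$edge.length[e] * m
  tree
}

#' Simulate a full synthetic clock-gene study
#'
#' For each configured gene the focal terminal branch of the species tree
#' is scaled by the gene's multiplier, an alignment is simulated, and
#' dropout taxa are removed.  The ground-truth table contains each gene's
#' true relative rate computed from the true (scaled, pruned) gene trees.
#'
#' @param config A [clock_study_config()].
#' @return List of class `clock_study`: `families` (named list with
#'   elements `gene`, `group`, `msa`, `tree`, `multiplier`), `truth`
#'   (data.frame `gene`, `group`, `multiplier`, `true_rate`), `config`.
#' @export
simulate_clock_study <- function(config = clock_study_config()) {
  stopifnot(inherits(config, "clock_study_config"))
  set.seed(config$seed)
  genes <- config$genes
  families <- vector("list", nrow(genes))
  names(families) <- genes$gene
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]
    tr <- scale_focal_branch(config$species_tree, config$focal_id,
                             genes$multiplier[i])
    drop <- config$dropout[[g]]
    if (!is.null(drop)) tr <- ape::drop.tip(tr, drop)
    aln <- simulate_alignment(tr, config$model, genes$n_sites[i])
    families[[i]] <- list(gene = g, group = genes$group[i], msa = aln,
                          tree = tr, multiplier = genes$multiplier[i])
  }
  true_dms <- lapply(families, function(f) patristic_matrix(f$tree))
  truth <- relative_rates(true_dms, config$focal_id,
                          stats::setNames(genes$group, genes$gene))
  truth <- data.frame(gene = truth$gene, group = truth$group,
                      multiplier = genes$multiplier[match(truth$gene, genes$gene)],
                      true_rate = truth$relative_rate,
                      stringsAsFactors = FALSE)
  structure(list(families = families, truth = truth, config = config),
            class = "clock_study")
}

#' Simulate a paralogous gene family for clade-assignment tests
#'
#' The gene tree consists of `n_paralogs` copies of the species tree joined
#' by duplication stems of the given depths (oldest duplication first).  In
#' each paralog clade the focal taxon's leaf is renamed to an anonymous
#' candidate ("contig") label; the remaining leaves of the clade are the
#' paralog's reference leaves.
#'
#' @param species_tree Rooted species tree (default
#'   [default_species_tree()]).
#' @param n_paralogs Number of paralogs (>= 2).
#' @param duplication_depths Stem branch lengths of the `n_paralogs - 1`
#'   duplications (recycled if length 1; default 0.5).
#' @param seed Integer seed for the sequence simulation.
#' @param gene_names Paralog names; defaults to the cryptochrome-family
#'   names for 3 paralogs and the kinase pair for 2.
#' @param n_sites Alignment length to simulate (default 300).
#' @param model Simulation model (default JTT).
#' @param focal_id Focal taxon whose leaves become candidates.
#' @return List of class `paralog_family`: `tree` (true gene tree), `msa`,
#'   `candidates`, `reference_map`, `truth` (data.frame candidate ->
#'   gene), `outgroup_gene` (the paralog from the oldest duplication, a
#'   natural rooting clade).
#' @export
simulate_paralog_family <- function(species_tree = default_species_tree(),
                                    n_paralogs = 3L,
                                    duplication_depths = 0.5,
                                    seed = 1L,
                                    gene_names = NULL,
                                    n_sites = 300L,
                                    model = aa_model("JTT"),
                                    focal_id = "Wsmithii") {
  if (n_paralogs < 2L) stop("need at least 2 paralogs")
  if (any(duplication_depths <= 0)) stop("duplication depths must be > 0")
  depths <- rep_len(duplication_depths, n_paralogs - 1L)
  if (is.null(gene_names)) {
    gene_names <- if (n_paralogs == 3L) c("phr6-4", "cry1", "cry2")
    else if (n_paralogs == 2L) c("dbt", "Ck1a")
    else paste0("paralog", seq_len(n_paralogs))
  }
  stopifnot(length(gene_names) == n_paralogs)
  copies <- lapply(seq_len(n_paralogs), function(i) {
    tr <- species_tree
    tr$tip.label <- paste(tr$tip.label, gene_names[i], sep = "|")
    tr
  })
  # join copies: gene_names[1] is the oldest (outgroup-like) paralog
  sub_newick <- function(tr) sub(";$", "", ape::write.tree(tr))
  tree <- copies[[n_paralogs]]
  for (i in rev(seq_len(n_paralogs - 1L))) {
    txt <- sprintf("(%s:%f,%s:%f);", sub_newick(copies[[i]]), depths[i],
                   sub_newick(tree), depths[i])
    tree <- ape::read.tree(text = txt)
  }
  # rename focal leaves to anonymous candidates
  focal_leaves <- paste(focal_id, gene_names, sep = "|")
  candidates <- sprintf("contig%02d", seq_len(n_paralogs))
  tree$tip.label[match(focal_leaves, tree$tip.label)] <- candidates
  reference_map <- lapply(gene_names, function(g)
    grep(paste0("\\|", g, "$"), tree$tip.label, value = TRUE))
  names(reference_map) <- gene_names
  aln <- simulate_alignment(tree, model, n_sites, seed = seed)
  structure(list(tree = tree, msa = aln, candidates = candidates,
                 reference_map = reference_map,
                 truth = data.frame(candidate = candidates, gene = gene_names,
                                    stringsAsFactors = FALSE),
                 outgroup_gene = gene_names[1]),
            class = "paralog_family")
}
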