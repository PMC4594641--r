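test_that("ML pairwise distances hit their boundary and closed-form values", {
  m <- aa_model("JTT")
  expect_lte(ml_pairwise_distance("ARNDARND", "ARNDARND", m), 1e-6)
  # saturation: every site different drives the estimate to the bound
  expect_gt(ml_pairwise_distance(strrep("A", 30), strrep("R", 30), m), 5)
  # equal-rates model has an analytic distance correction
  pois <- aa_model("Poisson")
  d <- ml_pairwise_distance("AAAAAAAAAA", "RRAAAAAAAA", pois)
  expect_equal(d, -(19 / 20) * log(1 - (20 / 19) * 0.2), tolerance = 1e-4)
})

test_that("neighbor joining solves the three-point formulas", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  term <- stats::setNames(tr$edge.length[tr$edge[, 2] <= 3],
                          tr$tip.label[tr$edge[, 2][tr$edge[, 2] <= 3]])
  expect_equal(term[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("neighbor joining recovers additive matrices exactly", {
  tr <- read_newick("((A:1,B:2):0.5,(C:0.7,D:1.3):0.4);")
  dm <- patristic_matrix(tr)
  rec <- nj_tree(dm)
  expect_equal(patristic_matrix(rec)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-12)
})

test_that("NJ is consistent on random additive 5-7 taxon trees", {
  for (s in 1:100) {
    n <- 5 + s %% 3
    tr <- random_additive_tree(n, seed = s)
    dm <- patristic_matrix(tr)
    rec <- nj_tree(dm)
    expect_equal(patristic_matrix(rec)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
})

test_that("degenerate equal distances are handled deterministically", {
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("two-taxon matrices give the trivial one-branch tree", {
  dm <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- nj_tree(dm)
  expect_equal(patristic_matrix(tr)["A", "B"], 0.8)
})

test_that("patristic distances are path sums with metric and clock properties", {
  tr <- read_newick("((A:1,B:2):0.5,C:3);")
  dm <- patristic_matrix(tr)
  expect_equal(dm["A", "B"], 3)
  expect_equal(dm["A", "C"], 4.5)
  expect_equal(dm["B", "C"], 5.5)
  # triangle inequality on a random tree
  rt <- random_additive_tree(7, seed = 9)
  d <- patristic_matrix(rt)
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # ultrametric tree: all tip pairs across the root are equidistant
  cl <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  dc <- patristic_matrix(cl)
  expect_true(all(abs(dc[c("A", "B"), c("C", "D")] - 4) < 1e-12))
})

test_that("branch-length optimisation matches the pairwise optimiser and is idempotent", {
  m <- aa_model("JTT")
  tr <- default_species_tree()
  x <- simulate_alignment(tr, m, 150, seed = 3)
  x2 <- msa(x$seqs[c("Wsmithii", "Nvitripennis")])
  d12 <- ml_pairwise_distance(x2$seqs[1], x2$seqs[2], m)
  dm <- matrix(c(0, d12, d12, 0), 2,
               dimnames = list(names(x2$seqs), names(x2$seqs)))
  t2 <- optimize_branch_lengths(nj_tree(dm), x2, m)
  expect_equal(sum(t2$edge.length), d12, tolerance = 1e-5)
  ll1 <- attr(t2, "loglik")
  t3 <- optimize_branch_lengths(t2, x2, m)
  expect_lt(abs(attr(t3, "loglik") - ll1), 1e-6)
})

test_that("branch lengths are recovered from data simulated on a known tree", {
  m <- aa_model("JTT")
  tr <- default_species_tree()
  x <- simulate_alignment(tr, m, 400, seed = 21)
  est <- optimize_branch_lengths(nj_tree(ml_distance_matrix(x, m)), x, m)
  truth <- patristic_matrix(ape::unroot(tr))
  got <- patristic_matrix(est)[rownames(truth), colnames(truth)]
  rel <- (got - truth)[upper.tri(truth)] / truth[upper.tri(truth)]
  expect_lt(sqrt(mean(rel^2)), 0.15)
})

test_that("rooting places the root on the outgroup branch and preserves distances", {
  tr <- read_newick("((A:1,B:2):0.5,C:3);")
  rt <- root_tree(tr, "C")
  expect_true(ape::is.rooted(rt))
  # C hangs off the root on its own
  root_children <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1, 2]
  expect_true(match("C", rt$tip.label) %in% root_children)
  expect_equal(patristic_matrix(rt)[c("A", "B", "C"), c("A", "B", "C")],
               patristic_matrix(tr)[c("A", "B", "C"), c("A", "B", "C")],
               tolerance = 1e-9)
  tr5 <- read_newick("(((A:1,B:1):1,C:2):0.5,(D:1,E:1):0.8);")
  expect_error(root_tree(tr5, c("A", "D")), "not monophyletic")
})

test_that("clade assignment resolves synthetic paralog families on true trees", {
  pf3 <- simulate_paralog_family(n_paralogs = 3, seed = 6)
  rt <- root_tree(pf3$tree, pf3$reference_map[[pf3$outgroup_gene]],
                  allow_extra = TRUE)
  asn <- assign_by_clade(rt, pf3$candidates, pf3$reference_map)
  expect_identical(asn$gene[match(pf3$truth$candidate, asn$candidate)],
                   pf3$truth$gene)
  pf2 <- simulate_paralog_family(n_paralogs = 2, seed = 7)
  rt2 <- root_tree(pf2$tree, pf2$reference_map[[pf2$outgroup_gene]],
                   allow_extra = TRUE)
  asn2 <- assign_by_clade(rt2, pf2$candidates, pf2$reference_map)
  expect_identical(asn2$gene[match(pf2$truth$candidate, asn2$candidate)],
                   pf2$truth$gene)
})

test_that("a candidate sister to all references is ambiguous and bad references error", {
  tr <- read_newick("((r1a:1,r1b:1):1,((r2a:1,r2b:1):1,cand:2):0.5);")
  rt <- root_tree(tr, c("r1a", "r1b"))
  ref <- list(g1 = c("r1a", "r1b"), g2 = c("r2a", "r2b"))
  # cand attaches above g2: smallest reference-containing clade holds g2 only
  expect_identical(assign_by_clade(rt, "cand", ref)$gene, "g2")
  # candidate sister to the whole reference set
  tr2 <- read_newick("(((r1a:1,r1b:1):1,(r2a:1,r2b:1):1):1,cand:2);")
  rt2 <- root_tree(tr2, "cand")
  expect_identical(assign_by_clade(rt2, "cand", ref)$gene, "ambiguous")
  # interleaved references are not mutually monophyletic
  tr3 <- read_newick("(((r1a:1,r2a:1):1,(r1b:1,r2b:1):1):1,cand:2);")
  rt3 <- root_tree(tr3, "cand")
  expect_error(assign_by_clade(rt3, "cand", ref), "monophyletic")
})
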