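---
title: "Measuring relative divergence of circadian clock genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring relative divergence of circadian clock genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question and the statistic

Insect circadian clocks are built from two functional layers: the core
transcription–translation feedback loop (TTFL: *per*, *tim*, *Clk*, *cyc*,
*cry2*, *vri*, *Pdp1*, *cwo*, *kayα*) and the post-translational modifiers
(PTM: *dbt*, *CkIIα*, *sgg*, *nmo*, *slimb*, *jet*, *Cul3*, *PP2A-B′*) that
tune the ~24 h period by controlling clock-protein stability and
localisation. clockdiv asks, for a designated focal lineage, whether either
layer of clock proteins has diverged unusually fast or slowly relative to a
panel of comparison taxa.

The core quantity is a per-gene **relative rate**. For gene $g$ with
patristic distance matrix $d_g$ (path lengths on the gene tree, in expected
substitutions per site) and focal taxon $w$:

$$ R_g \;=\; \frac{\operatorname{mean}_{j \ne w}\, d_g(w, j)}
               {\operatorname{mean}_{h}\,\operatorname{mean}_{i<j}\, d_h(i, j)} $$

i.e. the focal taxon's mean distance to all other taxa present for that
gene, divided by the grand mean over genes of each gene's mean pairwise
distance. $R_g > 1$ means the protein evolves faster in the focal lineage
than the study-wide average; $R_g < 1$, slower. The statistic is invariant
to rescaling all distances by a common factor.

Two readings of the denominator were possible (all pairs including the
focal taxon, or focal pairs excluded; genes weighted equally or by pair
count). We use the unweighted mean over genes of *all* within-gene pairs,
with genes contributing their own taxon subsets when a taxon lacks the
gene — the most literal reading of "average branch length for all taxa
across all genes". Genes that lack the focal taxon are excluded entirely,
with a warning.

An important consequence of this definition: the statistic is **not
null-centered at 1**. Whether $R_g = 1$ under neutral, tree-wide evolution
depends on where the focal taxon sits — a shallow focal lineage (short
terminal branch, close relatives in the panel) has a focal mean below the
all-pairs mean, so $R_g < 1$ even with no rate change. Group *contrasts*
(TTFL vs PTM) are therefore more interpretable than deviations from 1, and
the synthetic-data tests check estimator accuracy against the generator's
true rates rather than against 1.

## Pipeline stages and their assumptions

1. **Ortholog assignment** (`assign_single_copy`). Reference proteins (one
   per gene, from a well-annotated relative) are searched against the
   candidate set by Smith–Waterman local alignment (BLOSUM62, gap open 11,
   extend 1 — the standard protein-search parameters). A gene is assigned
   to its best hit only when the hit is *unique*: the top score must exceed
   the runner-up by a margin `delta` (default 10% of the top score). No
   margin is stated in the practice this emulates — raw-score E-value-free
   ranking needs one, and 10% is our construction; genes in declared
   multi-gene families, or without a unique winner, are deferred to
   tree-based assignment.

2. **Clade assignment for paralogs** (`root_tree`, `assign_by_clade`). A
   gene tree of the whole family is inferred, rooted on the branch
   subtending the oldest paralog subfamily, and each anonymous candidate is
   assigned to the paralog whose reference leaves alone populate the
   smallest clade enclosing the candidate. Rooting accepts the smallest
   clade *containing* the rooting subfamily (`allow_extra = TRUE`) because
   the focal candidate that belongs to that subfamily is, at this point,
   still unassigned and sits inside it. References must be mutually
   monophyletic; anything else aborts, since clade assignment is then
   meaningless.

3. **Conserved-block trimming** (`trim_alignment`). A Gblocks-style column
   filter: columns are conserved when their most frequent residue reaches
   `b1` copies (default `floor(n/2) + 1`) and highly conserved at `b2`
   (default `floor(0.85 n)`); stretches of more than `b3 = 8` contiguous
   nonconserved columns are removed, block flanks are trimmed back to
   highly conserved columns, gapped columns are dropped (`gap_policy =
   "none"`), and blocks shorter than `b4 = 10` are discarded. These are the
   canonical defaults; no overrides are assumed, and every run's manifest
   records the effective values.

4. **Model selection** (`select_model`). Empirical amino-acid replacement
   families JTT, LG, Dayhoff and WAG, with `+G` (discrete gamma, `k = 4`
   mean-of-bin categories), `+I` (invariant-site proportion) and `+F`
   (observed frequencies, one pseudo-count per residue) extensions. The
   per-site likelihood is
   $L_s = p_{inv}\, I(\text{site constant})\, \pi_{x_s} +
   (1 - p_{inv}) \tfrac1k \sum_c L_{\text{pruning}}(r_c)$ — note the
   variable-site rates are *not* rescaled by $1/(1-p_{inv})$; libraries
   that rescale will report slightly different `+I` likelihoods. Shape and
   invariant proportion are optimised by bounded search (alpha in
   [0.02, 1e6], so a `+G` model can collapse onto its base model), and
   candidates are ranked by AIC ($2k - 2\log L$, with $k$ counting alpha,
   $p_{inv}$, and 19 free frequencies for `+F`). AIC is assumed since the
   selection criterion used in the emulated practice is unstated. Ties
   break by fewer parameters, then name.

5. **Gene trees and distances** (`nj_tree`, `optimize_branch_lengths`,
   `patristic_matrix`). Topology by Saitou–Nei neighbor joining on
   maximum-likelihood pairwise distances (two-sequence likelihood optimised
   over $t \in [10^{-8}, 20]$), optionally followed by coordinate-wise ML
   branch-length refinement on the fixed topology. This NJ-plus-ML-lengths
   combination is a deliberate, documented stand-in for a full ML topology
   search: the divergence statistic consumes only patristic distances, the
   NJ stage is provably consistent on additive matrices, and externally
   built trees can be imported as Newick at any time. Negative NJ branch
   estimates are clamped to zero with the deficit moved to the sibling
   branch, preserving path lengths through the parent; patristic distances
   are rooting-invariant, so all distance computations use the unrooted
   metric.

6. **Group statistics** (`group_summaries`, `fisher_exact_2xk`,
   `regress_rate_on_length`, `ancova_group_effect`, `residual_anova`).
   One-sample two-sided t tests of the mean rate against 1 (combined,
   TTFL-only, PTM-only); a two-sided Fisher exact test on the 2×k table of
   best-fit model counts (columns are distinct *full* model strings, so
   `LG+G` ≠ `LG+G+F`), computed by full enumeration of tables with the
   observed margins under probability-mass ordering; OLS of rate on
   transcript length; ANCOVA of rate on group plus length (the group t is
   coding-invariant in magnitude); and a one-way ANOVA of the
   length-regression residuals by group. All tests are two-sided at
   α = 0.05 with no multiple-testing correction, matching the emulated
   analysis.

## The synthetic-data generator

`simulate_clock_study()` emulates the study design so every stage is
testable without sequence downloads: a seven-taxon species tree (focal
sabethine mosquito next to an *Aedes*/*Culex* pair, then *Anopheles*,
*Drosophila*, a butterfly and a wasp as progressively deeper outgroups)
with branch lengths calibrated to a mean pairwise distance near 1
substitution/site — the deep, partly saturated regime of 100–400 My
divergences — and a focal terminal branch of 0.1. The 17 default genes
carry the study's TTFL/PTM labels and protein lengths (one residue per
transcript codon, 150–1028 sites); per-gene focal multipliers scale the
focal terminal branch before simulation; the default dropout removes
*cry2* from the fly-like and wasp-like taxa and *tim* from the wasp-like
taxon, mirroring the one-gene/one-taxon and two-genes/one-taxon absence
pattern of the real panel (the study's second absent gene, *cry1*, is not
itself one of the 17 study genes). Sequences evolve site-independently
from equilibrium root states under the configured model; a single seed
fixes all randomness, and equal seeds give byte-identical studies.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: indels and alignment error (alignments
are simulated gap-free; dropout is the only source of missingness),
model misspecification (data are simulated under the same family used for
inference in most tests), rate autocorrelation along sites, codon-level
effects, and assembly artifacts in real transcriptomes.
`simulate_paralog_family()` builds duplicated species trees (stems 0.5
substitutions/site per duplication) with one anonymous focal candidate
per paralog clade for testing the disambiguation procedure.

## Numerical choices

Transition probabilities use the symmetrised eigendecomposition of the
reversible generator (exact for these models), with tiny negative
round-off clamped and rows renormalised. Rate matrices are normalised to
one expected substitution per unit branch length at equilibrium. The
pruning algorithm rescales partial likelihoods per node and site, so deep
trees cannot underflow. Pairwise ML distances use Brent optimisation at
tolerance 1e-7; branch-length refinement sweeps all branches (bound
[0, 10]) until the log-likelihood gain drops below 1e-6 or 20 sweeps, and
asserts monotone non-decreasing likelihood across sweeps. Gaps, `X` and
out-of-alphabet characters are missing data (partial-likelihood vectors of
ones). The Fisher enumeration tolerates ties with a 1e-7 relative slack on
log-probabilities, matching standard implementations.

## Problem sizes used in the tests

The suite exercises the estimator at sizes chosen to balance statistical
resolution against a desk-scale runtime: oracle equivalence on 3–6 taxon
trees and strings up to 6 residues (exact comparisons); frequency and
saturation checks at 2000–10000 simulated sites; branch-length recovery on
the 7-taxon tree at 400 sites (patristic RMS relative error checked
against a 15% bound); group-ordering recovery with multipliers 2 vs 0.5
over 100 seeded replicates at the default gene lengths; paralog
disambiguation over 20 replicates per family shape at 300 sites. The
acceptance script repeats the ordering experiment at 50 replicates.

## Known limitations

* Topologies come from neighbor joining, not a full ML search; on finite
  data the inferred topology can differ from an ML program's, although the
  patristic distances the statistic consumes are robust to this in the
  tested regimes. Externally inferred trees can be supplied as Newick.
* The relative-rate statistic confounds focal-lineage placement with rate
  (see above); compare groups, or compare against the generator's truth,
  rather than reading deviations from 1 as rate changes.
* `+I` likelihoods follow the unrescaled mixture given above; exchange
  with tools that rescale requires refitting.
* The E-value-free uniqueness margin (`delta`) is a design choice with no
  counterpart in the emulated practice; sensitivity to it should be
  checked when hit scores are close.
* Exchangeability matrices are fixed empirical constants; no ML
  optimisation of exchangeabilities, codon models, or mixtures beyond
  `+I+G` is provided.
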