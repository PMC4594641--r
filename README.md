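# clockdiv

Relative evolutionary rates of insect circadian clock genes.

Insect circadian clocks combine a core transcription–translation feedback
loop (TTFL genes: *per*, *tim*, *Clk*, *cyc*, *cry2*, *vri*, *Pdp1*,
*cwo*, *kayα*) with post-translational modifiers (PTM genes: *dbt*,
*CkIIα*, *sgg*, *nmo*, *slimb*, *jet*, *Cul3*, *PP2A-B′*) that set the
~24 h period. clockdiv is an analysis pipeline for asking whether either
layer of clock proteins has diverged unusually fast or slowly in a focal
lineage (here, a sabethine mosquito) relative to a panel of comparison
insects — and for making every stage of that analysis reproducible and
testable without external sequence data.

For gene $g$ with patristic distance matrix $d_g$ and focal taxon $w$, the
per-gene **relative rate** is

```
R_g = mean_{j != w} d_g(w, j)  /  mean_h mean_{i<j} d_h(i, j)
```

— the focal taxon's mean tree distance to all other taxa for that gene,
divided by the grand mean pairwise distance over all taxa and genes.
`R_g > 1`: the protein evolves faster in the focal lineage than the
study-wide average; `R_g < 1`: slower.

The pipeline stages, each an exported function with tests:

* ortholog assignment by unique best Smith–Waterman hit
  (`assign_single_copy`), with paralog families resolved on rooted gene
  trees (`root_tree`, `assign_by_clade`);
* ORF finding and UTR trimming (`find_longest_orf`, `trim_utrs`);
* Gblocks-style conserved-block trimming (`trim_alignment`);
* AIC selection among empirical amino-acid models JTT/LG/Dayhoff/WAG with
  +I/+G/+F, on a pruning-algorithm likelihood written for this package
  (`select_model`, `prune_loglik`);
* gene trees by neighbor joining on ML pairwise distances with optional ML
  branch-length refinement, and patristic matrices (`nj_tree`,
  `optimize_branch_lengths`, `patristic_matrix`);
* the relative-rate statistic and all group comparisons
  (`relative_rates`, `group_summaries`, `fisher_exact_2xk`,
  `ancova_group_effect`, `residual_anova`);
* a synthetic-data generator producing full seven-taxon studies with known
  ground truth (`simulate_clock_study`, `simulate_paralog_family`).

## Worked example

The package ships the 17-gene study table (gene, TTFL/PTM group, best-fit
model, transcript length, published relative rate). The statistics stage
reproduces the study's group comparison:

```r
library(clockdiv)
tab <- clock_gene_table()
group_summaries(tab)
#>   category  n      mean        se           t df          p
#> 1 combined 17 0.7960000 0.1314150 -1.55233477 16 0.14013626
#> 2     TTFL  9 0.9903333 0.1860034 -0.05197039  8 0.95982655
#> 3      PTM  8 0.5773750 0.1627961 -2.59603890  7 0.03563005
```

Combined, the focal lineage's clock genes do not diverge faster than the
study-wide average (mean rate 0.80, p = 0.14); the TTFL genes sit at the
average (0.99) while the PTM genes diverge significantly more slowly
(0.58, p = 0.04) — the period-setting machinery is the conserved layer.

A fully synthetic study with known truth, end to end:

```r
study <- simulate_clock_study(clock_study_config(seed = 101))
res <- run_pipeline(pipeline_config(
  families = lapply(study$families, function(f) f$msa),
  groups   = with(study$config$genes, setNames(group, gene)),
  focal_id = "Wsmithii", model = "JTT"))
cor(res$rates$relative_rate,
    study$truth$true_rate[match(res$rates$gene, study$truth$gene)])
#> [1] 0.9352858
```

The numbered scripts under `analysis/` run the full set of analyses
(table statistics, synthetic end-to-end study, paralog disambiguation,
rate-recovery power experiment) and write their tables under `results/`.

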