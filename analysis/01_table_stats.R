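#!/usr/bin/env Rscript
# Group divergence statistics from the packaged 17-gene study table.
#
# Reproduces the study's headline comparison: do the focal lineage's core
# clock (TTFL) genes diverge faster than its post-translational modifier
# (PTM) genes, and does either group deviate from the study-wide average
# (relative rate 1)?  Findings with the packaged table: combined mean rate
# 0.80 (|t| = 1.55, df 16, p = 0.14), TTFL mean 0.99 (indistinguishable
# from 1), PTM mean 0.58 (significantly below 1, p = 0.04); no group
# difference after accounting for transcript length.

suppressMessages(library(clockdiv))
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(pipeline_config(table = clock_gene_table(),
                                    out_dir = "results/table_stats"))
print(res$stats$groups)
cat("\nFisher exact p (model frequencies):", res$stats$fisher_p, "\n")
cat("Rate ~ length: r =", round(res$stats$regression$r, 3),
    " p =", round(res$stats$regression$p, 3), "\n")
cat("ANCOVA group term: |t| =", round(abs(res$stats$ancova$t), 3),
    " p =", round(res$stats$ancova$p, 3), "\n")
cat("Residual ANOVA: F =", round(res$stats$residual_anova$F, 3),
    " p =", round(res$stats$residual_anova$p, 3), "\n")
cat("\nwrote results/table_stats/{rates.tsv,stats.json,manifest.json}\n")
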