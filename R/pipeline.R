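#' Pipeline configuration
#'
#' Bundles inputs and stage parameters for [run_pipeline()].  Two input
#' modes exist: a per-gene study `table` (gene/group/model/nucleotides/
#' relative_rate) for the statistics stages alone, or aligned gene
#' `families` for the full sequence pipeline (trim, model selection, tree,
#' distances, rates, statistics).
#'
#' @param families Named list of `clock_msa` gene alignments (one per
#'   gene), or `NULL`.
#' @param groups Named character vector gene -> `"TTFL"`/`"PTM"`.
#' @param table Data.frame or TSV path of a per-gene study table, or
#'   `NULL`.
#' @param focal_id Focal taxon id (sequence mode).
#' @param trim Run conserved-block trimming? Default `TRUE`.
#' @param trim_params List of overrides for [trim_alignment()] (`b1`,
#'   `b2`, `b3`, `b4`, `gap_policy`).
#' @param model Fixed `aa_model` (or model name) used when
#'   `select_models = FALSE`.
#' @param select_models Run per-gene AIC model selection? Default `FALSE`.
#' @param candidates Candidate model names for selection.
#' @param optimize_branches Refine NJ branch lengths by ML? Default
#'   `FALSE` (the NJ tree on ML pairwise distances is used as-is).
#' @param out_dir Optional output directory for result files.
#' @param seed Optional integer seed recorded in the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(families = NULL, groups = NULL, table = NULL,
                            focal_id = "Wsmithii", trim = TRUE,
                            trim_params = list(), model = "JTT",
                            select_models = FALSE,
                            candidates = default_candidates(),
                            optimize_branches = FALSE,
                            out_dir = NULL, seed = NULL) {
  if (is.null(families) && is.null(table))
    stop("supply gene families or a study table")
  if (!is.null(families)) {
    if (length(families) == 0L) stop("empty gene list")
    stopifnot(!is.null(names(families)),
              all(vapply(families, inherits, logical(1), "clock_msa")))
  }
  if (is.character(model)) model <- aa_model(model, alpha = 1)
  structure(list(families = families, groups = groups, table = table,
                 focal_id = focal_id, trim = trim, trim_params = trim_params,
                 model = model, select_models = select_models,
                 candidates = candidates,
                 optimize_branches = optimize_branches,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the divergence pipeline
#'
#' Executes the configured stages in study order: conserved-block
#' trimming, substitution-model selection, gene-tree construction
#' (neighbor joining on ML pairwise distances, optional ML branch-length
#' refinement), patristic distance matrices, per-gene relative rates for
#' the focal taxon, and the group statistics.  In table mode only the
#' statistics stages run.  When `out_dir` is set, results are written as
#' plain files (`rates.tsv`, `stats.json`, `manifest.json`, per-gene
#' Newick trees and distance TSVs).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with (as applicable) `rates`,
#'   `stats`, `trees`, `matrices`, `model_tables`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  manifest <- list(mode = if (is.null(config$families)) "table" else "sequence",
                   focal_id = config$focal_id,
                   trim = config$trim,
                   trim_params = config$trim_params,
                   model = config$model$name,
                   select_models = config$select_models,
                   optimize_branches = config$optimize_branches,
                   seed = config$seed)

  if (is.null(config$families)) {
    tab <- if (is.character(config$table)) read_gene_table(config$table)
           else config$table
    if (!"relative_rate" %in% names(tab))
      stop("table mode needs a relative_rate column")
    stats_out <- divergence_statistics(tab)
    res <- structure(list(rates = tab, stats = stats_out,
                          manifest = manifest),
                     class = "pipeline_result")
    return(write_pipeline_outputs(res, config$out_dir))
  }

  families <- config$families
  trees <- list(); matrices <- list(); model_tables <- list()
  used_models <- character(0)
  n_nt <- vapply(families, function(f) 3L * f$n_cols, integer(1))
  for (g in names(families)) {
    aln <- families[[g]]
    if (config$trim) {
      aln <- do.call(trim_alignment, c(list(aln), config$trim_params))
    }
    if (!config$focal_id %in% names(aln$seqs))
      stop("focal taxon missing from gene family ", g)
    model <- config$model
    if (config$select_models) {
      guide <- nj_tree(ml_distance_matrix(aln, fit_frequencies(model, aln)))
      sel <- select_model(aln, guide, config$candidates)
      model <- sel$best
      model_tables[[g]] <- sel$table
    } else {
      model <- fit_frequencies(model, aln)
    }
    used_models[g] <- model$name
    tr <- nj_tree(ml_distance_matrix(aln, model))
    if (config$optimize_branches)
      tr <- optimize_branch_lengths(tr, aln, model)
    trees[[g]] <- tr
    matrices[[g]] <- patristic_matrix(tr)
  }
  rates <- relative_rates(matrices, config$focal_id, config$groups)
  rates$model <- unname(used_models[rates$gene])
  rates$nucleotides <- unname(n_nt[rates$gene])
  stats_out <- if (!is.null(config$groups) && !anyNA(rates$group))
    divergence_statistics(rates) else NULL
  res <- structure(list(rates = rates, stats = stats_out, trees = trees,
                        matrices = matrices, model_tables = model_tables,
                        manifest = manifest),
                   class = "pipeline_result")
  write_pipeline_outputs(res, config$out_dir)
}

write_pipeline_outputs <- function(res, out_dir) {
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$rates, file.path(out_dir, "rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$stats)) {
    s <- res$stats
    out <- list(groups = s$groups,
                fisher_p = s$fisher_p,
                regression = s$regression[c("slope", "r", "t", "df", "p")],
                ancova = s$ancova[c("t", "df", "p")],
                residual_anova = s$residual_anova)
    out <- Filter(Negate(is.null), out)
    jsonlite::write_json(out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  if (!is.null(res$trees)) {
    dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "matrices"), showWarnings = FALSE)
    for (g in names(res$trees)) {
      write_newick(res$trees[[g]], file.path(out_dir, "trees",
                                             paste0(g, ".nwk")))
      write_distance_tsv(res$matrices[[g]],
                         file.path(out_dir, "matrices", paste0(g, ".tsv")))
    }
  }
  res
}

#' Write a distance matrix as a square TSV with taxon header row/column
#' @param dm Symmetric named matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  utils::write.table(as.matrix(dm), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_tsv()]
#' @param path TSV path.
#' @return Symmetric named matrix.
#' @export
read_distance_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  check_distance_matrix(m)
  m
}
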