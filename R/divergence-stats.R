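#' Mean patristic distance from the focal taxon to all other taxa
#'
#' @param dm Symmetric patristic distance matrix with taxon names.
#' @param focal_id Focal taxon label (must be present).
#' @return Arithmetic mean of `d(focal, j)` over all other taxa in `dm`.
#' @export
focal_mean_distance <- function(dm, focal_id) {
  dm <- as.matrix(dm)
  check_distance_matrix(dm)
  if (!focal_id %in% rownames(dm))
    stop("focal taxon '", focal_id, "' absent from distance matrix")
  others <- setdiff(rownames(dm), focal_id)
  if (!length(others)) stop("no other taxa in distance matrix")
  mean(dm[focal_id, others])
}

#' Grand mean pairwise distance over a set of per-gene matrices
#'
#' The unweighted mean over genes of each gene's mean unordered pairwise
#' distance among the taxa present in that gene; genes with missing taxa
#' contribute the mean over their own taxon subset.
#'
#' @param matrices List of symmetric distance matrices (possibly with
#'   different taxon subsets).
#' @return A single grand mean distance.
#' @export
grand_mean_distance <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  per_gene <- vapply(matrices, function(dm) {
    dm <- as.matrix(dm)
    check_distance_matrix(dm)
    if (nrow(dm) < 2L) stop("distance matrix with fewer than 2 taxa")
    mean(dm[upper.tri(dm)])
  }, numeric(1))
  mean(per_gene)
}

#' Per-gene relative evolutionary rates of a focal taxon
#'
#' For each gene, the focal taxon's mean patristic distance to the other
#' taxa is divided by the grand mean pairwise distance over all taxa and
#' genes.  A rate above 1 indicates the protein evolves faster in the
#' focal lineage than the study-wide average; below 1, slower.  The
#' statistic is invariant to rescaling all distances by a common factor.
#'
#' @param matrices Named list of per-gene distance matrices.
#' @param focal_id Focal taxon label.  Genes lacking the focal taxon are
#'   excluded entirely (numerator and denominator) with a warning.
#' @param groups Optional named character vector gene -> group label
#'   (TTFL/PTM) attached to the output.
#' @return Data.frame with columns `gene`, `group` (NA when unknown),
#'   `focal_mean`, `relative_rate`; the grand mean is in attribute
#'   `grand_mean`.
#' @export
relative_rates <- function(matrices, focal_id, groups = NULL) {
  stopifnot(length(matrices) >= 1L)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("gene", seq_along(matrices))
  has_focal <- vapply(matrices, function(dm) focal_id %in% rownames(as.matrix(dm)),
                      logical(1))
  if (any(!has_focal)) {
    warning("dropping gene(s) lacking the focal taxon: ",
            paste(names(matrices)[!has_focal], collapse = ", "))
    matrices <- matrices[has_focal]
    if (!length(matrices)) stop("no gene retains the focal taxon")
  }
  grand <- grand_mean_distance(matrices)
  if (grand == 0) stop("grand mean distance is zero")
  focal <- vapply(matrices, focal_mean_distance, numeric(1), focal_id = focal_id)
  out <- data.frame(gene = names(matrices),
                    group = if (is.null(groups)) NA_character_
                            else unname(groups[names(matrices)]),
                    focal_mean = unname(focal),
                    relative_rate = unname(focal) / grand,
                    stringsAsFactors = FALSE)
  attr(out, "grand_mean") <- grand
  rownames(out) <- NULL
  out
}

#' One-sample t test summary against a reference mean
#'
#' @param values Numeric vector (n >= 2, nonzero spread).
#' @param mu0 Null mean (default 1, the no-divergence-excess value of the
#'   relative-rate statistic).
#' @return One-row data.frame: `n`, `mean`, `se`, `t`, `df`, `p`
#'   (two-sided).
#' @export
one_sample_t <- function(values, mu0 = 1) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("zero variance; t statistic undefined")
  ht <- stats::t.test(values, mu = mu0)
  data.frame(n = n, mean = mean(values),
             se = stats::sd(values) / sqrt(n),
             t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value)
}

#' Group-level relative-rate summaries (combined, TTFL, PTM)
#'
#' Applies [one_sample_t()] against mu0 = 1 to all genes, the TTFL subset
#' and the PTM subset.
#'
#' @param records Data.frame with columns `relative_rate` and `group`.
#' @param mu0 Null mean (default 1).
#' @return Data.frame with rows `combined`, `TTFL`, `PTM`.
#' @export
group_summaries <- function(records, mu0 = 1) {
  stopifnot(all(c("relative_rate", "group") %in% names(records)))
  if (anyNA(records$group)) stop("every record needs a group label")
  pieces <- list(combined = records$relative_rate,
                 TTFL = records$relative_rate[records$group == "TTFL"],
                 PTM = records$relative_rate[records$group == "PTM"])
  empty <- names(pieces)[lengths(pieces) == 0L]
  if (length(empty)) stop("empty group(s): ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(pieces, one_sample_t, mu0 = mu0))
  cbind(category = names(pieces), out, row.names = NULL)
}

#' Contingency table of best-fit model frequencies by group
#'
#' Columns are the distinct full model strings (so `"JTT+G"` and
#' `"JTT+G+F"` are different models).
#'
#' @param records Data.frame with columns `group` and `model`.
#' @return 2 x k integer table (rows TTFL, PTM).
#' @export
model_frequency_table <- function(records) {
  stopifnot(all(c("group", "model") %in% names(records)))
  table(factor(records$group, levels = c("TTFL", "PTM")), records$model)
}

#' Two-sided Fisher exact test for a 2 x k table by full enumeration
#'
#' Enumerates every table with the observed margins, computing exact
#' multivariate hypergeometric probabilities; the two-sided p-value is the
#' total probability of tables no more probable than the observed one
#' (with a small relative tolerance for ties).
#'
#' @param table 2 x k matrix of nonnegative integer counts (k >= 2).
#' @return Two-sided p-value.
#' @export
fisher_exact_2xk <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2L || ncol(tab) < 2L)
    stop("need a 2 x k table with k >= 2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (sum(tab) == 0) stop("all-zero table")
  col_sums <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  # log-probability of a first row x under fixed margins
  log_p <- function(x) {
    sum(lchoose(col_sums, x)) - lchoose(n, r1)
  }
  obs <- log_p(tab[1, ])
  total <- 0
  k <- length(col_sums)
  rec <- function(j, remaining, x) {
    if (j > k) {
      if (remaining == 0L) {
        lp <- log_p(x)
        if (lp <= obs + 1e-7) total <<- total + exp(lp)
      }
      return(invisible())
    }
    lo <- max(0L, remaining - sum(col_sums[j:k]) + col_sums[j])
    hi <- min(col_sums[j], remaining)
    if (lo > hi) return(invisible())
    for (v in lo:hi) rec(j + 1L, remaining - v, c(x, v))
  }
  rec(1L, r1, integer(0))
  min(total, 1)
}

#' Regression of relative rate on transcript length
#'
#' Ordinary least squares of rate on nucleotide count, with the Pearson
#' correlation and its t test.
#'
#' @param records Data.frame with columns `relative_rate` and
#'   `nucleotides`.
#' @return List: `slope`, `intercept`, `r`, `t`, `df`, `p` (two-sided),
#'   and the fitted `lm` object as `fit`.
#' @export
regress_rate_on_length <- function(records) {
  stopifnot(all(c("relative_rate", "nucleotides") %in% names(records)))
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 records")
  if (stats::var(records$nucleotides) == 0) stop("no variance in lengths")
  fit <- stats::lm(relative_rate ~ nucleotides, data = records)
  r <- stats::cor(records$relative_rate, records$nucleotides)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, t = tt, df = n - 2L,
       p = 2 * stats::pt(-abs(tt), n - 2L), fit = fit)
}

#' ANCOVA group effect on relative rate with length as covariate
#'
#' Fits `relative_rate ~ group + nucleotides` and reports the t statistic
#' of the group term (its magnitude does not depend on which group is the
#' baseline).
#'
#' @param records Data.frame with columns `relative_rate`, `group`,
#'   `nucleotides`; both groups must be present.
#' @return List: `t`, `df`, `p`, `fit`.
#' @export
ancova_group_effect <- function(records) {
  stopifnot(all(c("relative_rate", "group", "nucleotides") %in% names(records)))
  if (length(unique(records$group)) != 2L) stop("need exactly 2 groups")
  if (nrow(records) < 4L) stop("need at least 4 records")
  fit <- stats::lm(relative_rate ~ group + nucleotides, data = records)
  co <- summary(fit)$coefficients
  row <- grep("^group", rownames(co))
  if (any(is.na(stats::coef(fit)))) stop("singular design")
  list(t = co[row, "t value"], df = fit$df.residual,
       p = co[row, "Pr(>|t|)"], fit = fit)
}

#' One-way ANOVA of length-regression residuals by group
#'
#' Residuals from [regress_rate_on_length()] over all genes are compared
#' between groups by one-way ANOVA, factoring transcript-length effects
#' out of the group comparison.
#'
#' @param records As for [ancova_group_effect()].
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
residual_anova <- function(records) {
  stopifnot(all(c("relative_rate", "group", "nucleotides") %in% names(records)))
  if (length(unique(records$group)) != 2L) stop("need exactly 2 groups")
  res <- stats::resid(stats::lm(relative_rate ~ nucleotides, data = records))
  a <- stats::anova(stats::lm(res ~ factor(records$group)))
  list(F = a[1, "F value"], df1 = a[1, "Df"], df2 = a[2, "Df"],
       p = a[1, "Pr(>F)"])
}

#' All group-comparison statistics for a study table
#'
#' Convenience wrapper producing the group t-test summaries, the
#' model-frequency Fisher exact test, the rate-on-length regression, the
#' ANCOVA group test and the residual ANOVA from one per-gene table.
#'
#' @param records Data.frame with columns `gene`, `group`, `model`,
#'   `nucleotides`, `relative_rate` (as from [clock_gene_table()]).
#' @details Components whose preconditions a small table cannot meet (for
#'   instance a Fisher test with a single distinct model, or group t tests
#'   with one gene per group) are returned as `NULL` rather than failing
#'   the whole battery.
#' @return Named list of results (`groups`, `model_table`, `fisher_p`,
#'   `regression`, `ancova`, `residual_anova`).
#' @export
divergence_statistics <- function(records) {
  try_null <- function(expr) tryCatch(expr, error = function(e) NULL)
  mt <- try_null(model_frequency_table(records))
  list(
    groups = try_null(group_summaries(records)),
    model_table = mt,
    fisher_p = if (!is.null(mt) && ncol(mt) >= 2) try_null(fisher_exact_2xk(mt)),
    regression = try_null(regress_rate_on_length(records)),
    ancova = try_null(ancova_group_effect(records)),
    residual_anova = try_null(residual_anova(records))
  )
}
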