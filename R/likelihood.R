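# Felsenstein pruning over an ape tree, vectorised across sites.
# Gaps, 'X' and any character outside the 20-letter alphabet are treated as
# missing data (partial-likelihood vector of ones).

encode_alignment <- function(x) {
  m <- msa_matrix(x)
  idx <- match(m, aa_levels())
  matrix(idx, nrow = nrow(m), dimnames = list(rownames(m), NULL))
}

# conditional likelihoods at the root for one rate category;
# returns list(root = 20 x nsites matrix, log_scale = per-site log scaler)
prune_category <- function(tree, tipcodes, machine, rate) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  ns <- ncol(tipcodes)
  post <- ape::reorder.phylo(tree, "postorder")
  partial <- vector("list", nn)
  log_scale <- numeric(ns)
  for (tip in seq_len(nt)) {
    M <- matrix(0, 20L, ns)
    code <- tipcodes[tree$tip.label[tip], ]
    obs <- !is.na(code)
    M[cbind(code[obs], which(obs))] <- 1
    M[, !obs] <- 1
    partial[[tip]] <- M
  }
  parents <- unique(post$edge[, 1])
  Ps <- lapply(seq_len(nrow(post$edge)), function(i)
    transition_probs(machine, post$edge.length[i] * rate))
  for (node in parents) {
    rows <- which(post$edge[, 1] == node)
    M <- matrix(1, 20L, ns)
    for (i in rows) {
      child <- post$edge[i, 2]
      M <- M * (Ps[[i]] %*% partial[[child]])
    }
    sc <- apply(M, 2L, max)
    sc[sc == 0] <- 1
    log_scale <- log_scale + log(sc)
    partial[[node]] <- sweep(M, 2L, sc, "/")
  }
  root <- parents[length(parents)]   # postorder: root processed last
  list(root = partial[[root]], log_scale = log_scale)
}

#' Pruning-algorithm log-likelihood of an alignment on a tree
#'
#' Per-site likelihood under a reversible empirical amino-acid model with
#' optional discrete-gamma rate heterogeneity and a proportion of invariant
#' sites:
#' `L_s = p_inv * I(site constant) * pi(residue) +
#'  (1 - p_inv) * (1/k) * sum_c L_pruning(rate_c)`.
#'
#' @param tree [ape::phylo] whose tip labels exactly match the alignment ids.
#' @param x A `clock_msa`.
#' @param model An `aa_model`; a `+G` model needs `alpha` set, a `+I` model
#'   `p_inv`.
#' @return List of class `lik_result`: `loglik`, `per_site` (site
#'   log-likelihood vector) and `n_free_params` (alpha, p_inv and 19 free
#'   frequencies for `+F` models).
#' @export
prune_loglik <- function(tree, x, model) {
  stopifnot(inherits(x, "clock_msa"), inherits(model, "aa_model"))
  if (!setequal(tree$tip.label, names(x$seqs))) {
    d1 <- setdiff(tree$tip.label, names(x$seqs))
    d2 <- setdiff(names(x$seqs), tree$tip.label)
    stop("tree/alignment id mismatch; tree-only: {",
         paste(d1, collapse = ","), "} alignment-only: {",
         paste(d2, collapse = ","), "}")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  codes <- encode_alignment(x)
  machine <- model_machine(model)
  rates <- if (model$gamma) {
    if (is.null(model$alpha)) stop("+G model needs alpha")
    discrete_gamma_rates(model$alpha, model$k)
  } else 1
  p_inv <- if (model$inv) {
    if (is.null(model$p_inv)) stop("+I model needs p_inv")
    model$p_inv
  } else 0
  ns <- ncol(codes)
  lik <- matrix(0, length(rates), ns)
  for (c_i in seq_along(rates)) {
    pc <- prune_category(tree, codes, machine, rates[c_i])
    lik[c_i, ] <- as.numeric(machine$freq %*% pc$root) * exp(pc$log_scale)
  }
  var_lik <- colMeans(lik)
  inv_lik <- apply(codes, 2L, function(col) {
    obs <- col[!is.na(col)]
    if (!length(obs)) 1
    else if (all(obs == obs[1])) machine$freq[obs[1]]
    else 0
  })
  per_site <- log((1 - p_inv) * var_lik + p_inv * inv_lik)
  k_free <- (model$gamma) + (model$inv) + 19L * model$plus_F
  structure(list(loglik = sum(per_site), per_site = per_site,
                 n_free_params = k_free),
            class = "lik_result")
}

# two-sequence log-likelihood at separation t (used for ML pairwise distances)
two_seq_loglik <- function(codes_a, codes_b, machine, t, rates = 1, p_inv = 0) {
  ok <- !is.na(codes_a) & !is.na(codes_b)
  a <- codes_a[ok]; b <- codes_b[ok]
  if (!length(a)) stop("no shared non-missing sites between the two sequences")
  mix <- 0
  for (r in rates) {
    P <- transition_probs(machine, t * r)
    mix <- mix + P[cbind(a, b)] / length(rates)
  }
  lik <- (1 - p_inv) * machine$freq[a] * mix +
    p_inv * machine$freq[a] * (a == b)
  sum(log(lik))
}

#' Default candidate set for amino-acid model selection
#'
#' All combinations of the packaged empirical families with `+G`, `+I`,
#' `+I+G` and `+F` variants.
#'
#' @param families Character vector of base families.
#' @return Character vector of model names.
#' @export
default_candidates <- function(families = c("Dayhoff", "JTT", "LG", "WAG")) {
  as.vector(outer(
    as.vector(outer(families, c("", "+I", "+G", "+I+G"), paste0)),
    c("", "+F"), paste0))
}

#' AIC model selection over empirical amino-acid models (ProtTest style)
#'
#' Evaluates each candidate on a fixed tree, optimising the gamma shape
#' and/or invariant-site proportion by bounded 1-D or 2-D search, and ranks
#' by AIC = 2k - 2 logL where k counts alpha (+G), p_inv (+I) and 19 free
#' frequencies (+F).  Ties break by fewer parameters, then model name.
#'
#' @param x A `clock_msa`.
#' @param tree Fixed [ape::phylo] with branch lengths (the same tree for
#'   every candidate).
#' @param candidates Character vector of model names; default
#'   [default_candidates()].
#' @param k Gamma categories.
#' @return List: `best` (fitted `aa_model`), `table` (data.frame with
#'   `name`, `loglik`, `k`, `AIC`, `delta_AIC`, ordered by AIC).
#' @export
select_model <- function(x, tree, candidates = default_candidates(), k = 4L) {
  if (!length(candidates)) stop("empty candidate list")
  fits <- lapply(candidates, function(nm) fit_one_model(x, tree, nm, k))
  tab <- data.frame(
    name = vapply(fits, function(f) f$model$name, character(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    k = vapply(fits, function(f) f$n_free, integer(1)))
  tab$AIC <- 2 * tab$k - 2 * tab$loglik
  ord <- order(tab$AIC, tab$k, tab$name)
  tab <- tab[ord, ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  list(best = fits[[ord[1]]]$model, table = tab)
}

fit_one_model <- function(x, tree, name, k = 4L) {
  model <- aa_model(name, k = k)
  model <- fit_frequencies(model, x)
  obj <- function(alpha, p_inv) {
    m <- model; m$alpha <- alpha; m$p_inv <- p_inv
    prune_loglik(tree, x, m)$loglik
  }
  if (model$gamma && model$inv) {
    opt <- stats::optim(c(0, -2), function(par)
      -obj(exp(par[1]), stats::plogis(par[2])),
      method = "Nelder-Mead", control = list(reltol = 1e-7))
    model$alpha <- exp(opt$par[1])
    model$p_inv <- stats::plogis(opt$par[2])
    ll <- -opt$value
  } else if (model$gamma) {
    # upper bound far into the homogeneous regime so a +G model can always
    # collapse onto its base model (nesting)
    opt <- stats::optimize(function(la) -obj(exp(la), NULL),
                           interval = log(c(0.02, 1e6)), tol = 1e-4)
    model$alpha <- exp(opt$minimum)
    ll <- -opt$objective
  } else if (model$inv) {
    opt <- stats::optimize(function(p) -obj(NULL, p),
                           interval = c(0, 0.99), tol = 1e-5)
    model$p_inv <- opt$minimum
    ll <- -opt$objective
  } else {
    ll <- obj(NULL, NULL)
  }
  res <- prune_loglik(tree, x, model)
  list(model = model, loglik = ll, n_free = res$n_free_params)
}
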