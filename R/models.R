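#' Amino-acid alphabet used throughout (PAML residue order)
#' @return Character vector of the 20 amino-acid one-letter codes.
#' @export
aa_levels <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Empirical amino-acid exchangeabilities and frequencies
#'
#' Retrieves the published empirical replacement-matrix families shipped
#' with phangorn (JTT, LG, Dayhoff, WAG) plus the equal-rates Poisson
#' model, as a symmetric 20x20 exchangeability matrix and the model's
#' equilibrium frequencies.
#'
#' @param family One of `"JTT"`, `"LG"`, `"Dayhoff"`, `"WAG"`, `"Poisson"`.
#' @return List with `exch` (symmetric 20x20, zero diagonal) and `freq`
#'   (named 20-vector summing to 1), residues ordered as [aa_levels()].
#' @export
empirical_aa_rates <- function(family = c("JTT", "LG", "Dayhoff", "WAG", "Poisson")) {
  family <- match.arg(family)
  lev <- aa_levels()
  if (family == "Poisson") {
    exch <- matrix(1, 20L, 20L, dimnames = list(lev, lev))
    diag(exch) <- 0
    return(list(exch = exch, freq = stats::setNames(rep(1 / 20, 20L), lev)))
  }
  dat <- get(paste0(".", family), envir = asNamespace("phangorn"))
  exch <- matrix(0, 20L, 20L, dimnames = list(lev, lev))
  exch[lower.tri(exch)] <- dat$Q
  exch <- exch + t(exch)
  freq <- stats::setNames(as.numeric(dat$bf), lev)
  freq <- freq / sum(freq)
  list(exch = exch, freq = freq)
}

#' Construct an amino-acid substitution model
#'
#' @param name Model string such as `"JTT"`, `"LG+G"`, `"Dayhoff+G+F"` or
#'   `"JTT+I+G+F"`; spaces around `+` are tolerated.  `+G` adds discrete
#'   gamma rate heterogeneity, `+I` a proportion of invariant sites, `+F`
#'   replaces the model frequencies with (smoothed) observed alignment
#'   frequencies.
#' @param alpha Gamma shape (required to evaluate a `+G` model; may be set
#'   later by [select_model()]).
#' @param p_inv Proportion of invariant sites for `+I` models.
#' @param k Number of discrete gamma categories (default 4).
#' @param freq Optional replacement frequencies (e.g. observed ones for
#'   `+F`); must be a 20-vector summing to 1.
#' @return An object of class `aa_model`.
#' @export
aa_model <- function(name, alpha = NULL, p_inv = NULL, k = 4L, freq = NULL) {
  canon <- gsub(" ", "", name)
  parts <- strsplit(canon, "+", fixed = TRUE)[[1]]
  family <- parts[1]
  flags <- parts[-1]
  bad <- setdiff(flags, c("G", "I", "F"))
  if (length(bad)) stop("unknown model flag(s): ", paste(bad, collapse = ", "))
  base <- empirical_aa_rates(family)
  gamma <- "G" %in% flags
  inv <- "I" %in% flags
  plus_F <- "F" %in% flags
  if (!is.null(freq)) {
    stopifnot(length(freq) == 20L, abs(sum(freq) - 1) < 1e-8, all(freq > 0))
    base$freq <- stats::setNames(as.numeric(freq), aa_levels())
  }
  if (!is.null(p_inv) && (p_inv < 0 || p_inv >= 1))
    stop("p_inv must lie in [0, 1)")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be > 0")
  structure(list(name = canonical_model_name(family, gamma, inv, plus_F),
                 family = family, exch = base$exch, freq = base$freq,
                 gamma = gamma, inv = inv, plus_F = plus_F,
                 alpha = alpha, p_inv = p_inv, k = as.integer(k)),
            class = "aa_model")
}

canonical_model_name <- function(family, gamma, inv, plus_F) {
  paste0(family, if (inv) "+I", if (gamma) "+G", if (plus_F) "+F")
}

#' @export
print.aa_model <- function(x, ...) {
  cat("<aa_model> ", x$name,
      if (!is.null(x$alpha)) sprintf("  alpha=%.4g", x$alpha),
      if (!is.null(x$p_inv)) sprintf("  p_inv=%.4g", x$p_inv), "\n", sep = "")
  invisible(x)
}

#' Observed amino-acid frequencies of an alignment, smoothed
#'
#' Adds one pseudo-count per residue before normalising so no frequency is
#' zero on short alignments; gaps and `X` are ignored.
#'
#' @param x A `clock_msa`.
#' @return Named 20-vector summing to 1.
#' @export
observed_frequencies <- function(x) {
  stopifnot(inherits(x, "clock_msa"))
  lev <- aa_levels()
  counts <- table(factor(unlist(strsplit(x$seqs, "")), levels = lev))
  f <- (as.numeric(counts) + 1) / (sum(counts) + 20)
  stats::setNames(f, lev)
}

#' Apply a model's frequency policy to an alignment
#'
#' Returns the model unchanged unless it carries `+F`, in which case the
#' frequencies are replaced by [observed_frequencies()] of `x`.
#'
#' @param model An `aa_model`.
#' @param x A `clock_msa`.
#' @return An `aa_model`.
#' @export
fit_frequencies <- function(model, x) {
  if (!model$plus_F) return(model)
  model$freq <- observed_frequencies(x)
  model
}

#' Build the normalised instantaneous rate matrix of a model
#'
#' Off-diagonal `Q[i, j] = s[i, j] * pi[j]`, diagonal set so rows sum to
#' zero, and the whole matrix scaled so the expected substitution rate at
#' equilibrium, `-sum(pi * diag(Q))`, is exactly 1.
#'
#' @param model An `aa_model` (or a list with `exch` and `freq`).
#' @return 20x20 generator matrix.
#' @export
build_rate_matrix <- function(model) {
  s <- model$exch; pi_ <- model$freq
  if (any(pi_ <= 0)) stop("zero or negative equilibrium frequency")
  Q <- s * rep(pi_, each = nrow(s))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi_ * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero total rate)")
  Q / scale
}

#' Spectral machinery for fast transition probabilities
#'
#' Symmetrises the reversible generator with the usual
#' `diag(sqrt(pi)) Q diag(1/sqrt(pi))` similarity transform and caches its
#' eigendecomposition so `P(t)` costs two small matrix products.
#'
#' @param model An `aa_model`.
#' @return List of class `model_machine` with the eigensystem, frequencies
#'   and the source model.
#' @export
model_machine <- function(model) {
  Q <- build_rate_matrix(model)
  pi_ <- model$freq
  rs <- sqrt(pi_)
  A <- diag(rs) %*% Q %*% diag(1 / rs)
  A <- (A + t(A)) / 2   # exact symmetry despite round-off
  eig <- eigen(A, symmetric = TRUE)
  structure(list(values = eig$values,
                 U = diag(1 / rs) %*% eig$vectors,
                 Uinv = t(eig$vectors) %*% diag(rs),
                 freq = pi_, model = model),
            class = "model_machine")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param machine A `model_machine` (or an `aa_model`, converted on the fly).
#' @param t Branch length in expected substitutions per site; `t >= 0`.
#' @return 20x20 row-stochastic matrix (tiny negative round-off clamped to 0).
#' @export
transition_probs <- function(machine, t) {
  if (inherits(machine, "aa_model")) machine <- model_machine(machine)
  if (t < 0) stop("branch length t must be >= 0")
  P <- machine$U %*% (exp(machine$values * t) * machine$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma rate categories (mean-of-bin)
#'
#' Divides the mean-1 gamma(alpha, alpha) distribution into `k`
#' equal-probability bins and returns each bin's conditional mean, computed
#' in closed form from the incomplete-gamma identity, renormalised so the
#' category mean is exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of `k` relative rates with equal weights.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X; bin] = P(alpha+1 bin) / P(alpha bin) with equal bin mass 1/k
  mass_up <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  rates <- (mass_up[-1L] - mass_up[-(k + 1L)]) * k
  rates / mean(rates)
}
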