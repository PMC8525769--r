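# Random-effects Bayesian model selection: subjects are treated as random
# draws from a population distribution over models, with a Dirichlet prior
# on the model frequencies. The variational scheme alternates posterior
# model assignments with Dirichlet concentration updates; exceedance
# probabilities come from seeded Dirichlet Monte Carlo, and the protected
# exceedance probability corrects for the Bayes omnibus risk (BOR) that all
# frequencies are equal.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Variational free energy of the fitted random-effects model (ELBO), used
# against the equal-frequency null for the BOR.
bms_free_energy <- function(lme, g, alpha, alpha0) {
  k <- length(alpha)
  elogr <- digamma(alpha) - digamma(sum(alpha))
  elj <- lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum((alpha0 - 1) * elogr) +
    sum(g * (sweep(lme, 2, elogr, "+")))
  hdir <- sum(lgamma(alpha)) - lgamma(sum(alpha)) +
    (sum(alpha) - k) * digamma(sum(alpha)) -
    sum((alpha - 1) * digamma(alpha))
  hg <- -sum(g[g > 0] * log(g[g > 0]))
  elj + hdir + hg
}

#' Random-effects Bayesian model selection
#'
#' Fits a Dirichlet distribution over population model frequencies to a
#' subjects-by-models matrix of log evidences, and reports expected
#' frequencies, exceedance probabilities (EP), the Bayes omnibus risk (BOR)
#' and protected exceedance probabilities
#' `PXP = (1 - BOR) * EP + BOR / K`.
#'
#' @param evidence Numeric matrix, subjects in rows, models in columns
#'   (column names label the models). All entries must be finite.
#' @param alpha0 Dirichlet prior concentration per model (default 1,
#'   uniform).
#' @param tol Convergence tolerance on the concentration vector.
#' @param max_iter Iteration cap for the variational loop.
#' @param ep_draws Dirichlet Monte Carlo draws for the EPs.
#' @param ep_seed Seed for the EP draws (the caller's RNG state is left
#'   untouched).
#' @return Object of class `bms_report` with `alpha`, expected frequencies
#'   `r`, `ep`, `bor`, `pxp`, posterior assignments `g`, and the free
#'   energies of the fitted and null models.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, tol = 1e-6, max_iter = 500,
                    ep_draws = 1e5, ep_seed = 20210) {
  lme <- as.matrix(evidence)
  if (any(!is.finite(lme))) {
    bad <- which(!is.finite(lme), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite log evidence at subject %d, model %d",
                 bad[1], bad[2]))
  }
  n <- nrow(lme); k <- ncol(lme)
  if (n < 1 || k < 2) stop("need >= 1 subject and >= 2 models")
  labels <- colnames(lme) %||% paste0("m", seq_len(k))
  a0 <- rep(alpha0, k)
  alpha <- a0
  g <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    elogr <- digamma(alpha) - digamma(sum(alpha))
    lg <- sweep(lme, 2, elogr, "+")
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg) / rowSums(exp(lg))
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  r <- alpha / sum(alpha)
  ep <- with_seed(ep_seed, {
    draws <- rdirichlet(ep_draws, alpha)
    tabulate(max.col(draws, ties.method = "random"), k) / ep_draws
  })
  f1 <- bms_free_energy(lme, g, alpha, a0)
  f0 <- sum(apply(lme, 1, logsumexp) - log(k))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * ep + bor / k
  structure(list(alpha = setNames(alpha, labels), r = setNames(r, labels),
                 ep = setNames(ep, labels), bor = bor,
                 pxp = setNames(pxp, labels), g = g, F1 = f1, F0 = f0,
                 n_subjects = n), class = "bms_report")
}

#' @export
print.bms_report <- function(x, ...) {
  cat(sprintf("<bms_report> %d subjects, %d models, BOR = %.4f\n",
              x$n_subjects, length(x$alpha), x$bor))
  print(round(rbind(`expected freq` = x$r, EP = x$ep, PXP = x$pxp), 4))
  invisible(x)
}

#' Family-wise Bayesian model selection
#'
#' Pools the evidence of the models inside each family under a uniform
#' within-family prior -- `lme_family = logsumexp(lme_members) - log(size)`
#' -- and runs [rfx_bms()] over the families. The size correction makes the
#' comparison invariant to duplicating a model inside a family.
#'
#' @param evidence Subjects-by-models log-evidence matrix with column names.
#' @param families Named list mapping family name to a vector of model
#'   column names (or indices); every model must belong to exactly one
#'   family and no family may be empty.
#' @param ... Passed to [rfx_bms()].
#' @return A `bms_report` over families.
#' @export
family_bms <- function(evidence, families, ...) {
  lme <- as.matrix(evidence)
  if (length(families) < 2) stop("need >= 2 families")
  idx <- lapply(families, function(m) {
    i <- if (is.character(m)) match(m, colnames(lme)) else as.integer(m)
    if (length(i) == 0 || anyNA(i))
      stop("family with zero or unknown members")
    i
  })
  all_i <- unlist(idx)
  if (anyDuplicated(all_i) || length(all_i) != ncol(lme))
    stop("families must partition the model set")
  fam <- sapply(idx, function(i)
    apply(lme[, i, drop = FALSE], 1, logsumexp) - log(length(i)))
  fam <- matrix(fam, nrow = nrow(lme),
                dimnames = list(NULL, names(families)))
  rfx_bms(fam, ...)
}
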