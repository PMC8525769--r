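#' Laplace approximation of the log model evidence
#'
#' `log p(y|m) ~ log p(y, theta_MAP) + (d/2) log 2 pi - 1/2 log det(H)`,
#' where `H` is the Hessian of the negative log joint at the MAP in the
#' transformed parameter space. When `H` is not positive definite the
#' function falls back to the BIC approximation
#' `loglik - (d/2) log n` (requires `loglik` and `n_obs`).
#'
#' @param log_joint Log joint density at the MAP.
#' @param hessian Hessian matrix of the negative log joint at the MAP.
#' @param loglik Log-likelihood at the MAP (BIC fallback).
#' @param n_obs Number of observations (BIC fallback).
#' @return The approximate log evidence, with attribute `method` set to
#'   `"laplace"` or `"bic"`.
#' @export
laplace_evidence <- function(log_joint, hessian, loglik = NULL, n_obs = NULL) {
  d <- nrow(hessian)
  ch <- try(chol(hessian), silent = TRUE)
  if (!inherits(ch, "try-error") && all(is.finite(ch))) {
    lev <- log_joint + d / 2 * log(2 * pi) - sum(log(diag(ch)))
    return(structure(lev, method = "laplace"))
  }
  if (is.null(loglik) || is.null(n_obs))
    stop("Hessian not positive definite and no BIC fallback information")
  structure(loglik - d / 2 * log(n_obs), method = "bic")
}

#' MAP inversion of a model against one participant's choices
#'
#' Maximizes log-likelihood plus log-prior over the transformed parameters
#' with quasi-Newton (BFGS) searches from `n_restarts` jittered starts (the
#' first start is the prior mean; the others add Gaussian jitter of half a
#' prior standard deviation). The best optimum is kept; the log evidence is
#' the Laplace approximation at that optimum.
#'
#' @param trials Trial data frame (`scene_pct`, `bet_direction`,
#'   `bet_correct`) for the betting phase.
#' @param choices 0/1 vector, 1 = the classification agreed with the bet.
#' @param spec An [model_spec()].
#' @param n_restarts Number of optimizer starts (default 10).
#' @param seed Integer seed for the start jitter.
#' @param eps Likelihood clipping guard.
#' @return Object of class `hgf_fit`: transformed and natural MAP estimates,
#'   log joint, log-likelihood, Hessian, Laplace log evidence (plus the
#'   method used), a convergence flag and the number of restarts that
#'   finished. If every restart fails the result is flagged
#'   (`converged = FALSE`) rather than raising an error.
#' @export
fit_map <- function(trials, choices, spec, n_restarts = 10, seed = 1,
                    eps = 1e-10) {
  stopifnot(inherits(spec, "hgf_model_spec"))
  n <- nrow(trials)
  if (n < 1) stop("need at least one trial")
  if (length(choices) != n) stop("`choices` must match `trials`")
  pre <- prepare_inputs(trials)
  pm <- spec$params$mean
  psd <- spec$params$sd
  y <- as.numeric(choices)

  nlj <- function(xi) {
    th <- natural_params(spec, xi)
    p <- choice_prob_pre(spec, th, pre)
    ll <- log_likelihood(y, p, eps)
    lp <- sum(dnorm(xi, pm, psd, log = TRUE))
    if (!is.finite(ll + lp)) return(1e10)
    -(ll + lp)
  }

  d <- length(pm)
  starts <- with_seed(seed, {
    s <- matrix(rnorm((n_restarts - 1) * d, 0, 0.5 * psd),
                ncol = d, byrow = TRUE)
    rbind(rep(0, d), if (n_restarts > 1) s) + rep(pm, each = n_restarts)
  })

  best <- NULL
  ok <- 0L
  for (i in seq_len(n_restarts)) {
    res <- try(optim(starts[i, ], nlj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$value)) next
    ok <- ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }

  if (is.null(best)) {
    xi <- pm
    warning("all restarts failed; returning prior mode, flagged")
    best <- list(par = xi, value = nlj(xi), convergence = 99L)
  }
  xi <- setNames(best$par, spec$params$name)
  theta <- natural_params(spec, xi)
  p <- choice_prob_pre(spec, theta, pre)
  ll <- log_likelihood(y, p, eps)
  H <- try(optimHess(best$par, nlj), silent = TRUE)
  if (inherits(H, "try-error")) H <- diag(NA_real_, d)
  lev <- try(laplace_evidence(-best$value, H, loglik = ll, n_obs = n),
             silent = TRUE)
  if (inherits(lev, "try-error"))
    lev <- structure(ll - d / 2 * log(n), method = "bic")

  structure(list(
    spec = spec, estimates_transformed = xi, estimates = theta,
    log_joint = -best$value, loglik = ll, hessian = H,
    log_evidence = as.numeric(lev), evidence_method = attr(lev, "method"),
    converged = ok > 0 && isTRUE(best$convergence == 0),
    n_restarts_ok = ok, n_trials = n), class = "hgf_fit")
}

#' @export
print.hgf_fit <- function(x, ...) {
  cat(sprintf("<hgf_fit> %s: log evidence %.2f (%s), loglik %.2f, %s\n",
              x$spec$id, x$log_evidence, x$evidence_method, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  est <- unlist(x$estimates)
  cat("  ", paste(sprintf("%s = %.3g", names(est), est), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate-and-refit parameter recovery
#'
#' For each row of `true_params`, simulates choices from the model on the
#' given task, refits the model, and reports the Pearson correlation between
#' the true and recovered value of every free parameter on the estimation
#' (transformed) scale. If group labels are supplied the recovered group
#' mean difference per parameter is reported as well.
#'
#' @param spec An [model_spec()].
#' @param true_params Data frame of natural-scale parameter values, one row
#'   per simulated agent, columns named as in `natural_params()` output.
#' @param trials Trial data frame used for every agent.
#' @param seed Integer seed (per-agent simulation and fit seeds derive from
#'   it).
#' @param n_restarts Restarts per fit.
#' @param groups Optional factor/character vector of agent group labels.
#' @return Object of class `recovery_report`: per-parameter correlation
#'   table (with a `zero_variance` flag where the true values do not vary),
#'   the matrix of recovered transformed parameters, and the per-group
#'   recovered means when `groups` is given.
#' @export
recover <- function(spec, true_params, trials, seed = 1, n_restarts = 3,
                    groups = NULL) {
  n_agents <- nrow(true_params)
  if (n_agents < 2) stop("need at least two parameter sets")
  xi_true <- t(apply(true_params, 1, function(row)
    transformed_params(spec, as.list(row))))
  colnames(xi_true) <- spec$params$name
  xi_hat <- matrix(NA_real_, n_agents, nrow(spec$params),
                   dimnames = list(NULL, spec$params$name))
  converged <- logical(n_agents)
  for (i in seq_len(n_agents)) {
    th <- as.list(true_params[i, , drop = FALSE])
    p <- choice_prob(spec, th, trials)
    y <- simulate_responses(p, seed = child_seed(seed, 2L * i))
    fit <- fit_map(trials, y, spec, n_restarts = n_restarts,
                   seed = child_seed(seed, 2L * i + 1L))
    xi_hat[i, ] <- fit$estimates_transformed
    converged[i] <- fit$converged
  }
  cors <- lapply(spec$params$name, function(nm) {
    tv <- xi_true[, nm]
    if (stats::sd(tv) < 1e-12)
      return(data.frame(parameter = nm, r = NA_real_, p = NA_real_,
                        zero_variance = TRUE))
    ct <- cor.test(tv, xi_hat[, nm], alternative = "greater")
    data.frame(parameter = nm, r = unname(ct$estimate), p = ct$p.value,
               zero_variance = FALSE)
  })
  rep <- list(correlations = do.call(rbind, cors),
              true_transformed = xi_true, recovered_transformed = xi_hat,
              converged = converged)
  if (!is.null(groups)) {
    rep$group_means <- aggregate(xi_hat, by = list(group = groups), FUN = mean)
  }
  structure(rep, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
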