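# Model space: perceptual families P1 (logistic of eta*omega_s*mu2_s, the
# winning map), P2 (additive exponent bias), P3 (free multiplicative scale)
# and the Rescorla-Wagner baseline, crossed with response families R1
# (softmax beta only, the winner) and R2 (extra zeta weight on the social
# stream). Parameters are estimated in a transformed space (log for strictly
# positive quantities, logit for rates, identity for the social prior mean)
# under independent Gaussian priors.

default_prior_table <- function() {
  data.frame(
    name = c("log_omega_s", "log_omega_ns", "mu2s0", "log_eta", "kappa",
             "log_scale", "logit_alpha_s", "logit_alpha_ns", "log_beta",
             "log_zeta"),
    mean = c(-2, -2, 0, 0, 0, 0, 0, 0, 0, 0),
    sd = c(2, 2, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Specify one model of the perceptual/response space
#'
#' @param perceptual `"P1"` (winning map: `logistic(eta * omega_s * mu2_s)`),
#'   `"P2"` (additive exponent bias), `"P3"` (free multiplicative scale) or
#'   `"RW"` (Rescorla-Wagner baseline).
#' @param response `"R1"` (softmax with inverse decision noise `beta` only,
#'   the winner) or `"R2"` (adds the social stream weight `zeta`).
#' @param priors Optional named list overriding prior `c(mean, sd)` per
#'   transformed parameter, e.g. `list(log_beta = c(1, 0.5))`.
#' @param sigma2_0 Fixed initial level-2 variance for both streams.
#' @param mu2ns_0 Fixed initial non-social level-2 mean (the social initial
#'   mean is the free parameter `mu2s0`).
#' @return Object of class `hgf_model_spec` with a `params` table (name,
#'   transform, prior mean/sd in transformed space).
#' @export
model_spec <- function(perceptual = c("P1", "P2", "P3", "RW"),
                       response = c("R1", "R2"),
                       priors = NULL, sigma2_0 = 1, mu2ns_0 = 0) {
  perceptual <- match.arg(perceptual)
  response <- match.arg(response)
  pnames <- switch(perceptual,
    P1 = c("log_omega_s", "log_omega_ns", "mu2s0", "log_eta"),
    P2 = c("log_omega_s", "log_omega_ns", "mu2s0", "kappa"),
    P3 = c("log_omega_s", "log_omega_ns", "mu2s0", "log_scale"),
    RW = c("logit_alpha_s", "logit_alpha_ns"))
  rnames <- switch(response, R1 = "log_beta", R2 = c("log_beta", "log_zeta"))
  tab <- default_prior_table()
  tab <- tab[match(c(pnames, rnames), tab$name), , drop = FALSE]
  if (!is.null(priors)) {
    for (nm in names(priors)) {
      i <- match(nm, tab$name)
      if (is.na(i)) stop("unknown prior parameter: ", nm)
      if (length(priors[[nm]]) != 2 || priors[[nm]][2] <= 0)
        stop("priors must be c(mean, sd) with sd > 0")
      tab$mean[i] <- priors[[nm]][1]
      tab$sd[i] <- priors[[nm]][2]
    }
  }
  tab$transform <- ifelse(grepl("^log_", tab$name), "log",
                          ifelse(grepl("^logit_", tab$name), "logit",
                                 "identity"))
  rownames(tab) <- NULL
  structure(list(perceptual = perceptual, response = response, params = tab,
                 sigma2_0 = sigma2_0, mu2ns_0 = mu2ns_0,
                 id = paste0(perceptual, response)),
            class = "hgf_model_spec")
}

#' @export
print.hgf_model_spec <- function(x, ...) {
  cat(sprintf("<hgf_model_spec> %s: %d free parameters (%s)\n", x$id,
              nrow(x$params), paste(x$params$name, collapse = ", ")))
  invisible(x)
}

#' Map transformed parameters to the natural scale
#'
#' @param spec An [model_spec()].
#' @param xi Numeric vector in the estimation (transformed) space, ordered
#'   as `spec$params$name`.
#' @return Named list of natural-scale parameters (`omega_s`, `beta`, ...).
#' @export
natural_params <- function(spec, xi) {
  stopifnot(length(xi) == nrow(spec$params))
  val <- mapply(function(x, tr) switch(tr, log = exp(x), logit = plogis(x), x),
                xi, spec$params$transform)
  nat <- sub("^(log|logit)_", "", spec$params$name)
  nat[nat == "scale"] <- "scale"
  as.list(setNames(val, nat))
}

# Inverse of natural_params for a named list of natural values.
transformed_params <- function(spec, theta) {
  nat <- sub("^(log|logit)_", "", spec$params$name)
  x <- mapply(function(nm, tr) {
    v <- theta[[nm]]
    if (is.null(v)) stop("missing parameter: ", nm)
    switch(tr, log = log(v), logit = qlogis(v), v)
  }, nat, spec$params$transform)
  setNames(as.numeric(x), spec$params$name)
}

# Per-trial P(agree with bet) for a model at natural-scale parameters,
# given precomputed inputs (from prepare_inputs).
choice_prob_pre <- function(spec, theta, pre, eps = 1e-8) {
  n <- length(pre$u_ns)
  if (spec$perceptual == "RW") {
    out <- rw_filter_cpp(pre$u_s, pre$u_ns, pre$bet_scene,
                         theta$alpha_s, theta$alpha_ns, 0.5, 0.5,
                         has_social = TRUE, eps = eps)
  } else {
    variant <- match(spec$perceptual, c("P1", "P2", "P3"))
    bias <- switch(spec$perceptual, P1 = 0, P2 = theta$kappa,
                   P3 = theta$scale)
    out <- hgf_filter_cpp(pre$u_s, pre$u_ns, pre$rb, pre$bet_scene,
                          omega_s = theta$omega_s, omega_ns = theta$omega_ns,
                          eta = theta$eta %||% 1,
                          social_bias = bias, social_variant = variant,
                          mu2s0 = theta$mu2s0, sigma2s0 = spec$sigma2_0,
                          mu2ns0 = spec$mu2ns_0, sigma2ns0 = spec$sigma2_0,
                          has_social = TRUE, eps = eps)
  }
  b <- if (spec$response == "R2")
    weighted_combination_r2(out$mu1hat_s, out$a_ns, theta$zeta, eps = eps)
  else out$b
  softmax_prob(b, theta$beta)
}

#' Per-trial choice probabilities for a model
#'
#' Runs the model's filter over `trials` and applies its response model.
#'
#' @param spec An [model_spec()].
#' @param theta Named list of natural-scale parameters.
#' @param trials Trial data frame (`scene_pct`, `bet_direction`,
#'   `bet_correct`).
#' @return Per-trial probability of agreeing with the bet.
#' @export
choice_prob <- function(spec, theta, trials) {
  choice_prob_pre(spec, theta, prepare_inputs(trials))
}
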