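#' Softmax choice probability for a binary belief
#'
#' `P(agree) = b^beta / (b^beta + (1-b)^beta)`, computed stably as
#' `plogis(beta * qlogis(b))`. `beta` is the inverse decision noise: at
#' `beta = 1` the choice probability matches the belief, larger values
#' sharpen it toward a deterministic choice.
#'
#' @param b Combined belief(s) in (0, 1).
#' @param beta Inverse decision noise > 0.
#' @param eps Guard clipping `b` away from 0/1.
#' @return Probability of agreeing with the bet.
#' @export
softmax_prob <- function(b, beta, eps = 1e-10) {
  if (any(beta <= 0)) stop("`beta` must be > 0")
  b <- pmin(pmax(b, eps), 1 - eps)
  plogis(beta * qlogis(b))
}

#' Zeta-weighted stream combination (alternative response model)
#'
#' The rejected response variant re-weights the precision-weighted streams
#' with a free factor `zeta` on the social side before the softmax:
#' `b = (zeta pi_s mu_s + pi_ns a_ns) / (zeta pi_s + pi_ns)`. `zeta = 1`
#' reduces to the perceptual combination; `zeta -> Inf` follows the social
#' stream alone.
#'
#' @param mu1_hat_s Social prediction(s) in (0, 1).
#' @param a_ns Agreement-space non-social belief(s) in (0, 1).
#' @param zeta Social stream weight > 0.
#' @param eps Clipping guard.
#' @return Re-weighted combined belief.
#' @export
weighted_combination_r2 <- function(mu1_hat_s, a_ns, zeta, eps = 1e-8) {
  if (any(zeta <= 0)) stop("`zeta` must be > 0")
  mu1_hat_s <- pmin(pmax(mu1_hat_s, eps), 1 - eps)
  a_ns <- pmin(pmax(a_ns, eps), 1 - eps)
  pi_s <- 1 / (mu1_hat_s * (1 - mu1_hat_s))
  pi_ns <- 1 / (a_ns * (1 - a_ns))
  (zeta * pi_s * mu1_hat_s + pi_ns * a_ns) / (zeta * pi_s + pi_ns)
}

#' Bernoulli log-likelihood of a binary choice series
#'
#' @param choices 0/1 vector (1 = agrees with the bet).
#' @param probs Per-trial P(choice = 1), clipped to `(eps, 1 - eps)`.
#' @param eps Clipping guard.
#' @return Summed log-likelihood.
#' @export
log_likelihood <- function(choices, probs, eps = 1e-10) {
  if (length(choices) != length(probs))
    stop("`choices` and `probs` must have the same length")
  p <- pmin(pmax(probs, eps), 1 - eps)
  sum(choices * log(p) + (1 - choices) * log(1 - p))
}

#' Simulate binary responses from per-trial probabilities
#'
#' @param probs Per-trial P(choice = 1).
#' @param seed Integer seed.
#' @return Integer 0/1 vector.
#' @export
simulate_responses <- function(probs, seed = 1) {
  with_seed(seed, as.integer(runif(length(probs)) < probs))
}
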