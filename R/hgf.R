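#' Parameters of one HGF processing stream
#'
#' A stream tracks the tendency of a binary quantity (bet correctness for the
#' social stream, image category for the non-social stream) as a two-level
#' hierarchy: the level-2 tendency evolves as a Gaussian random walk with
#' variance `omega`, and the level-1 prediction is a logistic squash of the
#' previous level-2 mean. `eta` is the social stream's bias scale: in the
#' winning perceptual variant the level-1 social prediction is
#' `logistic(eta * omega_s * mu2_s)`, so a large `eta * omega_s` pushes the
#' predicted bet accuracy toward an extreme.
#'
#' @param omega Level-2 random-walk variance, > 0 (natural scale).
#' @param mu2_0 Initial level-2 mean.
#' @param sigma2_0 Initial level-2 variance, > 0.
#' @param eta Social bias scale, > 0; `NULL` for the non-social stream.
#' @return Object of class `stream_parameters`.
#' @export
stream_parameters <- function(omega, mu2_0 = 0, sigma2_0 = 1, eta = NULL) {
  if (!is.finite(omega) || omega <= 0) stop("`omega` must be > 0")
  if (!is.finite(sigma2_0) || sigma2_0 <= 0) stop("`sigma2_0` must be > 0")
  if (!is.null(eta) && (!is.finite(eta) || eta <= 0))
    stop("`eta` must be > 0 where present")
  structure(list(omega = omega, mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 eta = eta), class = "stream_parameters")
}

#' Rescorla-Wagner baseline parameters
#'
#' @param alpha_s,alpha_ns Learning rates in (0, 1].
#' @param V0_s,V0_ns Initial associative strengths in (0, 1).
#' @return Object of class `rw_parameters`.
#' @export
rw_parameters <- function(alpha_s, alpha_ns, V0_s = 0.5, V0_ns = 0.5) {
  for (a in c(alpha_s, alpha_ns))
    if (!is.finite(a) || a <= 0 || a > 1) stop("learning rates must be in (0, 1]")
  for (v in c(V0_s, V0_ns))
    if (!is.finite(v) || v <= 0 || v >= 1) stop("initial strengths must be in (0, 1)")
  structure(list(alpha_s = alpha_s, alpha_ns = alpha_ns,
                 V0_s = V0_s, V0_ns = V0_ns), class = "rw_parameters")
}

#' Recency bias carried over from the previous image
#'
#' Linear map of the previous image's scene percentage onto \[-1, 1\]:
#' `(scene_pct - 50) / 50`. A fully ambiguous 50/50 image carries no bias; an
#' unambiguous image carries the maximum bias toward its own category. The
#' first trial of a phase has no predecessor and gets bias 0 (handled by
#' [filter_trajectory()]).
#'
#' @param scene_pct_prev Scene percentage(s) of the preceding image, in
#'   \[0, 100\].
#' @return Bias value(s) in \[-1, 1\].
#' @export
recency_bias <- function(scene_pct_prev) {
  if (any(!is.finite(scene_pct_prev)) ||
      any(scene_pct_prev < 0 | scene_pct_prev > 100))
    stop("scene percentage must lie in [0, 100]")
  (scene_pct_prev - 50) / 50
}

#' Level-1 social prediction (winning perceptual map)
#'
#' `logistic(eta * omega_s * mu2_s_prev)`: the predicted probability that the
#' partner's next bet is correct, with the walk variance `omega_s` itself
#' scaling the steepness of the squash.
#'
#' @param mu2_s_prev Previous level-2 social mean.
#' @param eta Bias scale > 0.
#' @param omega_s Social walk variance > 0.
#' @return Probability in (0, 1).
#' @export
predict_social <- function(mu2_s_prev, eta, omega_s) {
  if (any(eta <= 0) || any(omega_s <= 0)) stop("`eta` and `omega_s` must be > 0")
  plogis(eta * omega_s * mu2_s_prev)
}

#' Level-1 non-social prediction
#'
#' `logistic(mu2_ns_prev + recency_bias)`: the predicted probability that the
#' next image is a scene, nudged toward the previous image's category in
#' proportion to how unambiguous it was.
#'
#' @param mu2_ns_prev Previous level-2 non-social mean.
#' @param recency_bias Carry-over term in \[-1, 1\], see [recency_bias()].
#' @return Probability in (0, 1).
#' @export
predict_nonsocial <- function(mu2_ns_prev, recency_bias) {
  if (any(recency_bias < -1 | recency_bias > 1))
    stop("`recency_bias` must lie in [-1, 1]")
  plogis(mu2_ns_prev + recency_bias)
}

#' One precision-weighted level-2 update
#'
#' The level-2 posterior is updated by the level-1 prediction error weighted
#' by the ratio of level-1 to level-2 precision: `pi2hat = 1/(sigma2 + omega)`,
#' `pi1hat = 1/(mu1hat (1 - mu1hat))`, `delta1 = u - mu1hat`,
#' `pi2 = pi2hat + 1/pi1hat`, `mu2 <- mu2 + delta1/pi2`, `sigma2 <- 1/pi2`.
#'
#' @param state_prev List with elements `mu2` and `sigma2` (previous posterior).
#' @param mu1_hat Level-1 prediction in (0, 1); values at the boundary are
#'   clipped to `[eps, 1 - eps]`.
#' @param input_u Observed input in \[0, 1\] (bet correctness or scene
#'   fraction).
#' @param omega Walk variance > 0.
#' @param eps Clipping guard for the level-1 prediction.
#' @return List with `mu2`, `sigma2`, `pi2`, `pi2_hat`, `pi1_hat`, `delta1`.
#' @export
update_level2 <- function(state_prev, mu1_hat, input_u, omega, eps = 1e-8) {
  if (input_u < 0 || input_u > 1) stop("`input_u` must lie in [0, 1]")
  mu1_hat <- min(max(mu1_hat, eps), 1 - eps)
  pi2_hat <- 1 / (state_prev$sigma2 + omega)
  pi1_hat <- 1 / (mu1_hat * (1 - mu1_hat))
  delta1 <- input_u - mu1_hat
  pi2 <- pi2_hat + 1 / pi1_hat
  list(mu2 = state_prev$mu2 + delta1 / pi2, sigma2 = 1 / pi2,
       pi2 = pi2, pi2_hat = pi2_hat, pi1_hat = pi1_hat, delta1 = delta1)
}

#' Precision-weighted combination of the two streams
#'
#' Maps the non-social (scene-space) prediction into bet-agreement space --
#' `a_ns = mu1_hat_ns` when the bet is "scene", `1 - mu1_hat_ns` otherwise --
#' and combines it with the social prediction by level-1 precision weights:
#' `b = (pi_s mu1_hat_s + pi_ns a_ns) / (pi_s + pi_ns)`. `b` is the combined
#' probability that agreeing with the bet is the right answer, and always
#' lies between the two stream beliefs.
#'
#' @param mu1_hat_s Social prediction(s) in (0, 1).
#' @param mu1_hat_ns Non-social scene-space prediction(s) in (0, 1).
#' @param bet_direction `"scene"`/`"face"` per trial.
#' @param eps Clipping guard keeping precisions finite.
#' @return List with `b` and `a_ns`.
#' @export
combine_beliefs <- function(mu1_hat_s, mu1_hat_ns, bet_direction, eps = 1e-8) {
  mu1_hat_s <- pmin(pmax(mu1_hat_s, eps), 1 - eps)
  mu1_hat_ns <- pmin(pmax(mu1_hat_ns, eps), 1 - eps)
  a_ns <- ifelse(bet_direction == "scene", mu1_hat_ns, 1 - mu1_hat_ns)
  pi_s <- 1 / (mu1_hat_s * (1 - mu1_hat_s))
  pi_ns <- 1 / (a_ns * (1 - a_ns))
  list(b = (pi_s * mu1_hat_s + pi_ns * a_ns) / (pi_s + pi_ns), a_ns = a_ns)
}

# Shared input preparation for the filter passes: inputs are the scene
# fraction (non-social) and bet correctness (social); the recency bias on
# trial t comes from the image shown on trial t-1 (0 on the first trial).
prepare_inputs <- function(trials, inputs = NULL, has_social = TRUE) {
  n <- nrow(trials)
  if (!is.null(inputs)) {
    if ((has_social && length(inputs$u_s) != n) || length(inputs$u_ns) != n)
      stop("`inputs` length does not match the number of trials")
    u_s <- inputs$u_s %||% rep(0, n)
    u_ns <- inputs$u_ns
  } else {
    u_ns <- trials$scene_pct / 100
    u_s <- if (has_social) as.numeric(trials$bet_correct) else rep(0, n)
  }
  rb <- c(0, recency_bias(trials$scene_pct[-n]))
  bet_scene <- if (has_social) trials$bet_direction == "scene" else rep(TRUE, n)
  if (has_social && anyNA(c(u_s, bet_scene)))
    stop("social inputs contain missing values")
  list(u_s = u_s, u_ns = u_ns, rb = rb, bet_scene = bet_scene)
}

#' Run the dual-stream HGF over a trial sequence
#'
#' Sequential predict -> combine -> update pass over the trials. Social
#' inputs are the bet-correctness indicators, non-social inputs the scene
#' fractions; both can be overridden through `inputs`. With `params_s =
#' NULL` only the non-social stream is run (the bet-free first phase) and
#' `b` is the scene-space prediction.
#'
#' @param params_s [stream_parameters()] for the social stream (needs `eta`
#'   under the default map), or `NULL`.
#' @param params_ns [stream_parameters()] for the non-social stream.
#' @param trials Trial data frame with `scene_pct` and, when social,
#'   `bet_direction` and `bet_correct`.
#' @param inputs Optional list with `u_s`, `u_ns` overriding the default
#'   inputs (each aligned with `trials`).
#' @param social_map `"eta_omega"` (winning variant), `"additive"` or
#'   `"multiplicative"`; the latter two read `social_bias`.
#' @param social_bias Additive exponent shift or free multiplicative scale
#'   for the alternative social maps.
#' @param eps Belief clipping guard.
#' @return A `belief_trajectory` data frame, one row per trial, with the
#'   level-1 predictions and precisions, prediction errors, level-2
#'   posteriors, the agreement-space non-social belief `a_ns`, the combined
#'   belief `b`, and the recency bias.
#' @export
filter_trajectory <- function(params_s, params_ns, trials, inputs = NULL,
                              social_map = c("eta_omega", "additive",
                                             "multiplicative"),
                              social_bias = 0, eps = 1e-8) {
  social_map <- match.arg(social_map)
  has_social <- !is.null(params_s)
  stopifnot(inherits(params_ns, "stream_parameters"))
  pre <- prepare_inputs(trials, inputs, has_social)
  variant <- match(social_map, c("eta_omega", "additive", "multiplicative"))
  if (has_social) {
    stopifnot(inherits(params_s, "stream_parameters"))
    if (variant == 1 && is.null(params_s$eta))
      stop("the eta_omega social map needs `eta` in `params_s`")
  }
  out <- hgf_filter_cpp(
    pre$u_s, pre$u_ns, pre$rb, pre$bet_scene,
    omega_s = if (has_social) params_s$omega else 1,
    omega_ns = params_ns$omega,
    eta = if (has_social) params_s$eta %||% 1 else 1,
    social_bias = social_bias, social_variant = variant,
    mu2s0 = if (has_social) params_s$mu2_0 else 0,
    sigma2s0 = if (has_social) params_s$sigma2_0 else 1,
    mu2ns0 = params_ns$mu2_0, sigma2ns0 = params_ns$sigma2_0,
    has_social = has_social, eps = eps)
  traj <- data.frame(trial_idx = seq_len(nrow(trials)) - 1L,
                     recency_bias = pre$rb, out,
                     stringsAsFactors = FALSE)
  class(traj) <- c("belief_trajectory", "data.frame")
  traj
}

#' Run the Rescorla-Wagner baseline over a trial sequence
#'
#' Each stream's associative strength follows the fixed-rate delta rule
#' `V <- V + alpha (u - V)`; the per-trial prediction is the pre-update `V`
#' and the streams are combined exactly as in [combine_beliefs()].
#'
#' @param params [rw_parameters()].
#' @param trials,inputs,eps As in [filter_trajectory()].
#' @return A `belief_trajectory` data frame with `V_s`/`V_ns` columns.
#' @export
rw_trajectory <- function(params, trials, inputs = NULL, eps = 1e-8) {
  stopifnot(inherits(params, "rw_parameters"))
  pre <- prepare_inputs(trials, inputs, has_social = TRUE)
  out <- rw_filter_cpp(pre$u_s, pre$u_ns, pre$bet_scene,
                       params$alpha_s, params$alpha_ns,
                       params$V0_s, params$V0_ns,
                       has_social = TRUE, eps = eps)
  traj <- data.frame(trial_idx = seq_len(nrow(trials)) - 1L, out,
                     stringsAsFactors = FALSE)
  class(traj) <- c("belief_trajectory", "data.frame")
  traj
}

#' Write a belief trajectory to CSV
#'
#' @param traj A `belief_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
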