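#' Configuration of a synthetic cohort
#'
#' Describes the generative population from which complete synthetic
#' datasets are drawn: group structure (paranoia fraction, condition
#' split), the parameter sampling distributions (log-normal for `omega_s`,
#' `omega_ns`, `eta`, `beta`; normal for the initial social mean `mu2s0`),
#' and the encoded group effects -- elevated `omega_ns` and `omega_s` under
#' high paranoia, elevated `mu2s0` under cooperation. Default effect sizes
#' are about 0.4 population standard deviations (small-to-moderate, in the
#' spirit of the reported partial eta squared magnitudes).
#'
#' @param n_participants Cohort size (default 200, the scale at which the
#'   full-circle direction checks are run).
#' @param experiment 1 or 2 (sets bet accuracy 0.5 or 0.75).
#' @param frac_high_paranoia Fraction of participants assigned high
#'   paranoia.
#' @param frac_cooperation Fraction assigned to the cooperation condition.
#' @param log_omega_ns_mean,log_omega_ns_sd Log-scale distribution of the
#'   non-social walk variance.
#' @param log_omega_s_mean,log_omega_s_sd Log-scale distribution of the
#'   social walk variance.
#' @param paranoia_omega_shift Additive log-scale shift of both walk
#'   variances under high paranoia.
#' @param mu2s0_mean,mu2s0_sd Distribution of the initial social mean
#'   (the baseline mean applies to the competition condition).
#' @param cooperation_mu2s0_shift Additive shift of `mu2s0` under
#'   cooperation.
#' @param log_eta_mean,log_eta_sd Log-scale distribution of the social bias
#'   scale.
#' @param log_beta_mean,log_beta_sd Log-scale distribution of the inverse
#'   decision noise.
#' @param confidence_gamma,confidence_noise Confidence map shape and noise
#'   (see [sample_cohort()]).
#' @param n_trials,scene_grid Task structure per phase.
#' @param seed Master seed; every random draw in the cohort derives from
#'   it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 200, experiment = 1,
                          frac_high_paranoia = 0.3, frac_cooperation = 0.5,
                          log_omega_ns_mean = -1, log_omega_ns_sd = 0.8,
                          log_omega_s_mean = 0, log_omega_s_sd = 0.8,
                          paranoia_omega_shift = 0.32,
                          mu2s0_mean = -0.2, mu2s0_sd = 1,
                          cooperation_mu2s0_shift = 0.4,
                          log_eta_mean = 0, log_eta_sd = 0.5,
                          log_beta_mean = 0.7, log_beta_sd = 0.3,
                          confidence_gamma = 1, confidence_noise = 0.5,
                          n_trials = 80, scene_grid = seq(0, 100, by = 10),
                          seed = 1) {
  if (n_participants < 1) stop("`n_participants` must be >= 1")
  if (!experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2")
  for (f in c(frac_high_paranoia, frac_cooperation))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  cfg <- as.list(environment())
  if (any(!vapply(cfg, function(x) all(is.finite(unlist(x))), TRUE)))
    stop("all configuration values must be finite")
  structure(cfg, class = "cohort_config")
}

# Monotone map from belief extremity to a 1-7 confidence rating:
# clip(round(1 + 6 * (2|b - 0.5|)^gamma + noise), 1, 7).
confidence_rating <- function(b, gamma, noise_sd) {
  raw <- 1 + 6 * (2 * abs(b - 0.5))^gamma + rnorm(length(b), 0, noise_sd)
  pmin(pmax(round(raw), 1), 7)
}

# Questionnaire scores drawn on the correct side of the published cutoffs
# (R-GPTS persecution >= 11 for high paranoia, BAI > 16 for high anxiety);
# only the side of the cutoff matters to any in-scope statistic.
sample_questionnaires <- function(high_paranoia) {
  n <- length(high_paranoia)
  gpts <- ifelse(high_paranoia,
                 pmin(11 + floor(rexp(n, 1 / 7)), 40),
                 floor(runif(n, 0, 11)))
  high_anx <- runif(n) < ifelse(high_paranoia, 0.6, 0.15)
  bai <- ifelse(high_anx,
                pmin(17 + floor(rexp(n, 1 / 8)), 63),
                floor(runif(n, 0, 17)))
  bdi <- pmin(pmax(round(rnorm(n, 8 + 8 * high_paranoia, 6)), 0), 63)
  data.frame(gpts_persecution = gpts, bai = bai, bdi = bdi)
}

#' Generate a complete synthetic cohort
#'
#' Draws per-participant parameters from the configured group-shifted
#' distributions, simulates both task phases and produces a trial table in
#' the package schema. C1 choices come from the non-social stream alone
#' (there are no bets in C1); C2 choices from the full dual-stream model.
#' Confidence ratings are a monotone map of belief extremity (`|b - 0.5|`
#' in C2, `|mu1hat_ns - 0.5|` in C1) plus Gaussian noise, discretized to
#' the 1--7 scale. All participants see the same stimulus sequence (as in
#' the experiment); bets are placed independently per participant at the
#' exact configured accuracy. C2 re-uses the C1 image order.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: `participants` (true
#'   parameters, group labels, questionnaire scores), `trials` (long trial
#'   table, see [read_trials()]) and the `config`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  bet_acc <- if (config$experiment == 1) 0.5 else 0.75

  parts <- with_seed(child_seed(config$seed, 1), {
    high <- sample(rep(c(TRUE, FALSE),
                       c(round(config$frac_high_paranoia * n),
                         n - round(config$frac_high_paranoia * n))))
    coop <- sample(rep(c(TRUE, FALSE),
                       c(round(config$frac_cooperation * n),
                         n - round(config$frac_cooperation * n))))
    q <- sample_questionnaires(high)
    data.frame(
      participant_id = sprintf("p%03d", seq_len(n)),
      condition = ifelse(coop, "cooperation", "competition"),
      high_paranoia = high, q,
      omega_ns = exp(rnorm(n, config$log_omega_ns_mean +
                             config$paranoia_omega_shift * high,
                           config$log_omega_ns_sd)),
      omega_s = exp(rnorm(n, config$log_omega_s_mean +
                            config$paranoia_omega_shift * high,
                          config$log_omega_s_sd)),
      mu2s0 = rnorm(n, config$mu2s0_mean +
                      config$cooperation_mu2s0_shift * coop,
                    config$mu2s0_sd),
      eta = exp(rnorm(n, config$log_eta_mean, config$log_eta_sd)),
      beta = exp(rnorm(n, config$log_beta_mean, config$log_beta_sd)),
      stringsAsFactors = FALSE)
  })

  task_cfg <- task_config(experiment = config$experiment,
                          n_trials = config$n_trials,
                          scene_grid = config$scene_grid,
                          seed = child_seed(config$seed, 2))
  stim <- generate_stimulus_sequence(task_cfg)

  trial_rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parts[i, ]
    trials <- generate_bets(stim, bet_acc,
                            seed = child_seed(config$seed, 100 + i))
    params_ns <- stream_parameters(p$omega_ns, mu2_0 = 0, sigma2_0 = 1)
    params_s <- stream_parameters(p$omega_s, mu2_0 = p$mu2s0, sigma2_0 = 1,
                                  eta = p$eta)

    # C1: non-social stream alone, choices in scene space
    tr1 <- filter_trajectory(NULL, params_ns, trials)
    p1_scene <- softmax_prob(tr1$b, p$beta)
    y1 <- simulate_responses(p1_scene, seed = child_seed(config$seed,
                                                         10000 + i))
    c1_choice <- ifelse(y1 == 1, "scene", "face")

    # C2: dual-stream model, choices in bet-agreement space
    tr2 <- filter_trajectory(params_s, params_ns, trials)
    p2_agree <- softmax_prob(tr2$b, p$beta)
    y2 <- simulate_responses(p2_agree, seed = child_seed(config$seed,
                                                          20000 + i))
    c2_choice <- ifelse(y2 == 1, trials$bet_direction,
                        ifelse(trials$bet_direction == "scene",
                               "face", "scene"))

    conf <- with_seed(child_seed(config$seed, 30000 + i), list(
      c1 = confidence_rating(tr1$mu1hat_ns, config$confidence_gamma,
                             config$confidence_noise),
      c2 = confidence_rating(tr2$b, config$confidence_gamma,
                             config$confidence_noise)))

    base <- data.frame(participant_id = p$participant_id,
                       trial_idx = trials$trial_idx,
                       scene_pct = trials$scene_pct,
                       condition = p$condition,
                       gpts_persecution = p$gpts_persecution,
                       bai = p$bai, bdi = p$bdi,
                       stringsAsFactors = FALSE)
    c1_rows <- cbind(base, phase = "C1", bet_direction = NA_character_,
                     bet_correct = NA_integer_, choice = c1_choice,
                     confidence = conf$c1)
    c2_rows <- cbind(base, phase = "C2",
                     bet_direction = trials$bet_direction,
                     bet_correct = trials$bet_correct, choice = c2_choice,
                     confidence = conf$c2)
    trial_rows[[i]] <- rbind(c1_rows, c2_rows)
  }

  trials_long <- do.call(rbind, trial_rows)
  cols <- c("participant_id", "phase", "trial_idx", "scene_pct",
            "bet_direction", "bet_correct", "choice", "confidence",
            "condition", "gpts_persecution", "bai", "bdi")
  trials_long <- trials_long[, cols]
  rownames(trials_long) <- NULL
  structure(list(participants = parts, trials = trials_long,
                 config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participants (%d high paranoia), experiment %d, seed %d\n",
    nrow(x$participants), sum(x$participants$high_paranoia),
    x$config$experiment, x$config$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes `trials.csv` (trial-level schema), `participants.csv` (true
#' parameters and group labels) and `provenance.json` (the generating
#' configuration including the seed) into `dir`.
#'
#' @param cohort A [sample_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Named list of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (nrow(cohort$trials) == 0) stop("cohort is empty")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(trials = file.path(dir, "trials.csv"),
                participants = file.path(dir, "participants.csv"),
                provenance = file.path(dir, "provenance.json"))
  write.csv(cohort$trials, paths$trials, row.names = FALSE, na = "")
  write.csv(cohort$participants, paths$participants, row.names = FALSE)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(c(list(schema_version = 1,
                              package_version =
                                as.character(packageVersion("dualhgf"))),
                         cfg),
                       paths$provenance, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
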