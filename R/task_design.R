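#' Task configuration for the chimeric face/scene betting task
#'
#' Describes one phase of the two-phase classification task: a sequence of
#' chimeric images whose scene percentage spans 0--100, plus (in the second
#' phase) a partner who bets on each upcoming image. Experiment 1 uses bets
#' that are correct exactly 50% of the time; experiment 2 raises the bet
#' accuracy to 75%. The payoff matrix differs between the cooperation and
#' competition conditions but never enters the belief model; it is task
#' metadata.
#'
#' @param experiment 1 or 2; sets the default `bet_accuracy` (0.5 or 0.75).
#' @param condition `"cooperation"` or `"competition"`.
#' @param n_trials Number of trials per phase (default 80).
#' @param scene_grid Scene percentages available to the stimulus sequence,
#'   each in \[0, 100\]. The default 11-level grid `{0, 10, ..., 100}` spans
#'   the full ambiguity range and keeps fully ambiguous 50/50 trials present.
#' @param bet_accuracy Fraction of trials on which the partner's bet matches
#'   the true category; any value in \[0, 1\]. `NULL` uses the experiment
#'   default.
#' @param seed Integer seed governing the stimulus shuffle and bet placement.
#' @param payoff_table Payoff lookup, see [payoff()].
#' @param classification_payment Cents paid per correct classification on top
#'   of the partner payoffs (default 0; its magnitude is task metadata).
#' @return An object of class `task_config`.
#' @export
task_config <- function(experiment = 1,
                        condition = c("cooperation", "competition"),
                        n_trials = 80,
                        scene_grid = seq(0, 100, by = 10),
                        bet_accuracy = NULL,
                        seed = 1,
                        payoff_table = default_payoff_table(),
                        classification_payment = 0) {
  condition <- match.arg(condition)
  if (!experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2")
  if (length(scene_grid) == 0) stop("`scene_grid` must not be empty")
  if (any(!is.finite(scene_grid)) || any(scene_grid < 0 | scene_grid > 100))
    stop("`scene_grid` values must lie in [0, 100]")
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  bet_accuracy <- bet_accuracy %||% if (experiment == 1) 0.5 else 0.75
  if (bet_accuracy < 0 || bet_accuracy > 1)
    stop("`bet_accuracy` must lie in [0, 1]")
  structure(
    list(experiment = experiment, condition = condition,
         n_trials = as.integer(n_trials), scene_grid = scene_grid,
         bet_accuracy = bet_accuracy, seed = as.integer(seed),
         payoff_table = payoff_table,
         classification_payment = classification_payment),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "<task_config> experiment %d, %s, %d trials, bet accuracy %.2f, seed %d\n",
    x$experiment, x$condition, x$n_trials, x$bet_accuracy, x$seed))
  invisible(x)
}

#' Generate the stimulus sequence for one phase
#'
#' Tiles the configured scene-percentage grid to `n_trials` stimuli and
#' shuffles them with the configured seed. The true category is `"scene"`
#' above 50% scene and `"face"` below; exactly ambiguous 50/50 images get a
#' seeded coin flip and are flagged `ambiguous_truth` so accuracy metrics can
#' exclude them.
#'
#' @param config A [task_config()].
#' @return A data frame with columns `trial_idx` (0-based), `scene_pct`,
#'   `true_category`, `ambiguous_truth`.
#' @export
generate_stimulus_sequence <- function(config) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_trials
  with_seed(config$seed, {
    pct <- rep(config$scene_grid, length.out = n)
    pct <- if (n > 1) sample(pct) else pct
    truth <- ifelse(pct > 50, "scene", "face")
    amb <- pct == 50
    if (any(amb))
      truth[amb] <- sample(c("scene", "face"), sum(amb), replace = TRUE)
    data.frame(trial_idx = seq_len(n) - 1L, scene_pct = pct,
               true_category = truth, ambiguous_truth = amb,
               stringsAsFactors = FALSE)
  })
}

#' Assign partner bets at an exact accuracy
#'
#' Places the partner's bets so that exactly `round(bet_accuracy * n)` of
#' them match the true category -- the published design fixes the count, it
#' is not a Bernoulli rate. Which trials receive a correct bet is a seeded
#' uniform draw without replacement.
#'
#' @param trials Data frame from [generate_stimulus_sequence()].
#' @param bet_accuracy Fraction in \[0, 1\].
#' @param seed Integer seed for the placement draw.
#' @return `trials` with `bet_direction` and `bet_correct` columns added.
#' @export
generate_bets <- function(trials, bet_accuracy, seed = 1) {
  if (bet_accuracy < 0 || bet_accuracy > 1)
    stop("`bet_accuracy` must lie in [0, 1]")
  n <- nrow(trials)
  k <- round(bet_accuracy * n)
  correct <- logical(n)
  if (k > 0)
    with_seed(seed, correct[sample.int(n, k)] <- TRUE)
  other <- ifelse(trials$true_category == "scene", "face", "scene")
  trials$bet_direction <- ifelse(correct, trials$true_category, other)
  trials$bet_correct <- as.integer(correct)
  trials
}

#' Default payoff matrix
#'
#' Cooperation pays +10 cents when both the participant's classification and
#' the partner's bet are correct. Competition deducts 4 cents when the bet is
#' correct and the classification is correct, 7 cents when the bet is correct
#' and the classification is wrong. All cells with an incorrect bet transfer
#' nothing.
#'
#' @return Data frame with columns `condition`, `participant_correct`,
#'   `bet_correct`, `cents`.
#' @export
default_payoff_table <- function() {
  tab <- expand.grid(condition = c("cooperation", "competition"),
                     participant_correct = 0:1, bet_correct = 0:1,
                     stringsAsFactors = FALSE)
  tab$cents <- 0
  tab$cents[tab$condition == "cooperation" &
              tab$participant_correct == 1 & tab$bet_correct == 1] <- 10
  tab$cents[tab$condition == "competition" &
              tab$participant_correct == 1 & tab$bet_correct == 1] <- -4
  tab$cents[tab$condition == "competition" &
              tab$participant_correct == 0 & tab$bet_correct == 1] <- -7
  tab
}

#' Payoff for a trial outcome
#'
#' @param condition `"cooperation"` or `"competition"` (vectorized).
#' @param participant_correct 0/1, whether the classification was correct.
#' @param bet_correct 0/1, whether the partner's bet was correct.
#' @param payoff_table Lookup table, see [default_payoff_table()].
#' @param classification_payment Cents added per correct classification.
#' @return Signed cents.
#' @export
payoff <- function(condition, participant_correct, bet_correct,
                   payoff_table = default_payoff_table(),
                   classification_payment = 0) {
  if (!all(condition %in% c("cooperation", "competition")))
    stop("unknown condition: ",
         paste(setdiff(condition, c("cooperation", "competition")),
               collapse = ", "))
  if (!all(participant_correct %in% 0:1) || !all(bet_correct %in% 0:1))
    stop("`participant_correct` and `bet_correct` must be 0/1")
  key <- paste(condition, participant_correct, bet_correct)
  tab_key <- paste(payoff_table$condition, payoff_table$participant_correct,
                   payoff_table$bet_correct)
  payoff_table$cents[match(key, tab_key)] +
    classification_payment * participant_correct
}

#' Simulate a full second-phase trial sequence
#'
#' Convenience wrapper: stimulus sequence plus bets at the configured
#' accuracy. Bet placement uses a child seed of the config seed so that a
#' single seed reproduces the whole sequence.
#'
#' @param config A [task_config()].
#' @return Trial data frame with stimulus and bet columns.
#' @export
simulate_task <- function(config) {
  trials <- generate_stimulus_sequence(config)
  generate_bets(trials, config$bet_accuracy, seed = child_seed(config$seed, 1))
}
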