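#' Classify a trial as self-deceptive
#'
#' A C2 classification is self-deceptive when it changed relative to C1 and
#' the change aligns with the partner's interests: toward the bet under
#' cooperation, away from the bet under competition.
#'
#' @param condition `"cooperation"`/`"competition"` (vectorized).
#' @param c1_choice,c2_choice `"scene"`/`"face"` classifications in the two
#'   phases.
#' @param bet_direction `"scene"`/`"face"` partner bet.
#' @return Logical vector.
#' @export
classify_self_deception <- function(condition, c1_choice, bet_direction,
                                    c2_choice) {
  stopifnot(all(condition %in% c("cooperation", "competition")),
            all(c(c1_choice, c2_choice, bet_direction) %in%
                  c("scene", "face")))
  changed <- c2_choice != c1_choice
  agrees <- c2_choice == bet_direction
  ifelse(condition == "cooperation", changed & agrees, changed & !agrees)
}

#' Confidence-weighted self-deception (CWSD)
#'
#' The raw self-deception score (self-deceptive trials over all C2 trials)
#' scaled by the participant's confidence while self-deceiving relative to
#' their baseline C1 confidence:
#' `CWSD = raw * mean(C2 confidence on SD trials) / mean(C1 confidence)`.
#' A participant with no self-deceptive trials scores 0.
#'
#' @param paired Data frame of paired phase rows for one participant with
#'   columns `condition`, `c1_choice`, `c2_choice`, `bet_direction`,
#'   `c1_confidence`, `c2_confidence` (ratings on the 1--7 scale).
#' @return List with `raw_sd_score`, `cwsd`, `n_sd_trials`,
#'   `mean_sd_confidence`.
#' @export
cwsd <- function(paired) {
  if (nrow(paired) < 1) stop("need at least one paired trial")
  sd_flag <- classify_self_deception(paired$condition, paired$c1_choice,
                                     paired$bet_direction, paired$c2_choice)
  raw <- sum(sd_flag) / nrow(paired)
  if (!any(sd_flag))
    return(list(raw_sd_score = 0, cwsd = 0, n_sd_trials = 0L,
                mean_sd_confidence = NA_real_))
  m_sd <- mean(paired$c2_confidence[sd_flag])
  m_c1 <- mean(paired$c1_confidence)
  list(raw_sd_score = raw, cwsd = raw * m_sd / m_c1,
       n_sd_trials = sum(sd_flag), mean_sd_confidence = m_sd)
}

#' Questionnaire-based group classification
#'
#' High paranoia is an R-GPTS persecution score of 11 or higher (the
#' recommended clinical cutoff); high anxiety is a BAI score strictly above
#' 16.
#'
#' @param gpts R-GPTS persecution score(s), >= 0.
#' @param bai Beck's Anxiety Inventory score(s), >= 0.
#' @return Data frame with `paranoia_group` and `anxiety_group`
#'   (`"high"`/`"low"`).
#' @export
classify_groups <- function(gpts, bai) {
  stopifnot(all(gpts >= 0), all(bai >= 0))
  data.frame(paranoia_group = ifelse(gpts >= 11, "high", "low"),
             anxiety_group = ifelse(bai > 16, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Motivational bias: the bet-by-condition interaction
#'
#' Fits a logistic mixed-effects regression of the C2 scene response on the
#' scene fraction, the bet direction, the condition, and their interaction,
#' with a random intercept per participant. Conformity under cooperation
#' plus defection under competition shows up as a positive
#' bet-by-cooperation interaction.
#'
#' @param trial_table Trial-level table in the package schema (see
#'   [read_trials()]); only C2 rows are used.
#' @param ... Passed to [lme4::glmer()].
#' @return List with the interaction `estimate`, Wald `z`, `p`, 95% `ci`,
#'   and the fitted `model`.
#' @export
motivational_bias <- function(trial_table, ...) {
  d <- trial_table[trial_table$phase == "C2", ]
  if (length(unique(d$condition)) < 2)
    stop("both conditions must be represented")
  d$y <- as.integer(d$choice == "scene")
  d$scene_prop <- d$scene_pct / 100
  d$bet_scene <- as.integer(d$bet_direction == "scene")
  d$condition <- factor(d$condition, levels = c("competition", "cooperation"))
  m <- lme4::glmer(y ~ scene_prop + bet_scene * condition +
                     (1 | participant_id),
                   data = d, family = binomial, ...)
  co <- summary(m)$coefficients
  row <- "bet_scene:conditioncooperation"
  est <- co[row, "Estimate"]; se <- co[row, "Std. Error"]
  list(estimate = est, z = co[row, "z value"], p = co[row, "Pr(>|z|)"],
       ci = est + c(-1, 1) * 1.96 * se, model = m)
}

#' Rank-difference insight score
#'
#' Ranks participants on perceived choice unreliability (fitted `omega_ns`,
#' ascending: rank 1 = most stable self-perception) and on objective C1
#' accuracy (descending: rank 1 = best performer), and returns the
#' difference `rank(omega_ns) - rank(accuracy)`. A large positive score
#' marks an overly pessimistic view of one's own performance. Ties get
#' average ranks; participants with a missing fit are excluded with a
#' message.
#'
#' @param omega_ns Fitted non-social walk variances.
#' @param c1_accuracy Objective first-phase accuracies in \[0, 1\].
#' @return Numeric vector of rank differences (NA where `omega_ns` is
#'   missing).
#' @export
insight_rank_difference <- function(omega_ns, c1_accuracy) {
  if (length(omega_ns) != length(c1_accuracy))
    stop("inputs must have equal length")
  if (length(omega_ns) < 2) stop("need >= 2 participants")
  keep <- !is.na(omega_ns) & !is.na(c1_accuracy)
  if (any(!keep))
    message(sum(!keep), " participant(s) without fits excluded")
  out <- rep(NA_real_, length(omega_ns))
  out[keep] <- rank(omega_ns[keep], ties.method = "average") -
    rank(-c1_accuracy[keep], ties.method = "average")
  out
}

#' Compare two independent correlations (Fisher z)
#'
#' Two-sided test of `r1 = r2` from independent samples via Fisher's
#' z-transform: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 Sample correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes, >= 4.
#' @return List with `z` and two-sided `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("sample sizes must be >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' First-phase classification accuracy
#'
#' Accuracy of the C1 classifications against the category implied by the
#' scene percentage; exactly ambiguous 50/50 images have no defined truth
#' and are excluded.
#'
#' @param scene_pct Scene percentages.
#' @param choice `"scene"`/`"face"` classifications.
#' @return Fraction correct over the unambiguous trials.
#' @export
c1_accuracy <- function(scene_pct, choice) {
  keep <- scene_pct != 50
  if (!any(keep)) return(NA_real_)
  truth <- ifelse(scene_pct[keep] > 50, "scene", "face")
  mean(choice[keep] == truth)
}

# Pair the C1 and C2 rows of a participant's trial table by trial index.
pair_phases <- function(rows) {
  c1 <- rows[rows$phase == "C1", ]
  c2 <- rows[rows$phase == "C2", ]
  m <- merge(c1[, c("trial_idx", "scene_pct", "choice", "confidence")],
             c2[, c("trial_idx", "choice", "confidence", "bet_direction",
                    "bet_correct", "condition")],
             by = "trial_idx", suffixes = c("_c1", "_c2"))
  data.frame(trial_idx = m$trial_idx, scene_pct = m$scene_pct,
             condition = m$condition, bet_direction = m$bet_direction,
             bet_correct = m$bet_correct,
             c1_choice = m$choice_c1, c2_choice = m$choice_c2,
             c1_confidence = m$confidence_c1,
             c2_confidence = m$confidence_c2,
             stringsAsFactors = FALSE)
}

#' Per-participant behavioral metrics
#'
#' Computes, for every participant in a trial table: the raw self-deception
#' score, CWSD, questionnaire groups, and C1 accuracy. If a fits table with
#' an `omega_ns` column is supplied, the rank-difference insight score is
#' added.
#'
#' @param trial_table Trial-level table in the package schema.
#' @param fits Optional data frame with `participant_id` and `omega_ns`.
#' @return Data frame, one row per participant.
#' @export
participant_metrics <- function(trial_table, fits = NULL) {
  ids <- unique(trial_table$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- trial_table[trial_table$participant_id == id, ]
    paired <- pair_phases(sub)
    sc <- cwsd(paired)
    g <- classify_groups(sub$gpts_persecution[1], sub$bai[1])
    data.frame(participant_id = id, condition = paired$condition[1],
               raw_sd_score = sc$raw_sd_score, cwsd = sc$cwsd,
               n_sd_trials = sc$n_sd_trials,
               mean_sd_confidence = sc$mean_sd_confidence,
               paranoia_group = g$paranoia_group,
               anxiety_group = g$anxiety_group,
               c1_accuracy = c1_accuracy(paired$scene_pct, paired$c1_choice),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(fits)) {
    out$omega_ns <- fits$omega_ns[match(out$participant_id,
                                        fits$participant_id)]
    out$insight_rank_diff <- insight_rank_difference(out$omega_ns,
                                                     out$c1_accuracy)
  }
  out
}
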