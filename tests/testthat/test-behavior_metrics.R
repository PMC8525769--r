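test_that("self-deception classification matches its defining cases", {
  expect_true(classify_self_deception("cooperation", "face", "scene", "scene"))
  expect_false(classify_self_deception("cooperation", "scene", "scene", "scene"))
  expect_true(classify_self_deception("competition", "scene", "scene", "face"))
  expect_false(classify_self_deception("competition", "face", "scene", "face"))
  # vectorized
  out <- classify_self_deception(c("cooperation", "competition"),
                                 c("face", "scene"), c("scene", "scene"),
                                 c("scene", "face"))
  expect_identical(out, c(TRUE, TRUE))
  expect_error(classify_self_deception("solo", "face", "scene", "scene"))
})

test_that("CWSD matches the hand-evaluated definition and degenerate cases", {
  # 5 self-deceptive trials of 80, mean SD confidence 6, mean C1 confidence 4
  paired <- data.frame(
    condition = "cooperation",
    c1_choice = c(rep("face", 5), rep("face", 75)),
    bet_direction = c(rep("scene", 5), rep("face", 75)),
    c2_choice = c(rep("scene", 5), rep("face", 75)),
    c1_confidence = rep(4, 80),
    c2_confidence = c(rep(6, 5), rep(2, 75)),
    stringsAsFactors = FALSE)
  sc <- cwsd(paired)
  expect_equal(sc$raw_sd_score, 5 / 80)
  expect_equal(sc$cwsd, (5 / 80) * 1.5, tolerance = 1e-12)
  expect_equal(sc$n_sd_trials, 5L)

  # no self-deceptive trials -> 0
  none <- paired[6:80, ]
  expect_equal(cwsd(none)$cwsd, 0)
  # SD confidence equal to the C1 mean -> cwsd equals the raw score
  paired$c2_confidence[1:5] <- 4
  expect_equal(cwsd(paired)$cwsd, cwsd(paired)$raw_sd_score)
  # order invariance
  perm <- paired[sample.int(80), ]
  expect_equal(cwsd(perm)[c("raw_sd_score", "cwsd")],
               cwsd(paired)[c("raw_sd_score", "cwsd")])
})

test_that("questionnaire cutoffs are honored at the boundary", {
  g <- classify_groups(c(11, 10, 0, 25), c(16, 17, 0, 30))
  expect_identical(g$paranoia_group, c("high", "low", "low", "high"))
  expect_identical(g$anxiety_group, c("low", "high", "low", "high"))
  expect_error(classify_groups(-1, 5))
})

test_that("motivational bias detects conformity/defection and respects nulls", {
  # direct construction with a known bet x condition interaction
  build <- function(bet_effect_coop, bet_effect_comp, seed) {
    set.seed(seed)
    rows <- lapply(seq_len(60), function(i) {
      cond <- if (i <= 30) "cooperation" else "competition"
      scene_pct <- rep(seq(0, 100, by = 10), length.out = 80)
      bet <- sample(c("scene", "face"), 80, replace = TRUE)
      eff <- if (cond == "cooperation") bet_effect_coop else bet_effect_comp
      lin <- -2 + 4 * scene_pct / 100 + eff * (bet == "scene") +
        rnorm(1, 0, 0.3)
      choice <- ifelse(runif(80) < plogis(lin), "scene", "face")
      data.frame(participant_id = paste0("p", i), phase = "C2",
                 trial_idx = 0:79, scene_pct = scene_pct,
                 bet_direction = bet,
                 bet_correct = as.integer(bet == ifelse(scene_pct > 50,
                                                        "scene", "face")),
                 choice = choice, confidence = 4, condition = cond,
                 gpts_persecution = 0, bai = 0, bdi = 0,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  tt <- build(0.9, -0.9, seed = 42)
  mb <- motivational_bias(tt)
  expect_gt(mb$estimate, 0)
  expect_gt(mb$ci[1], 0)
  # swapping the condition labels flips the sign
  tt_swap <- tt
  tt_swap$condition <- ifelse(tt$condition == "cooperation",
                              "competition", "cooperation")
  mb_swap <- motivational_bias(tt_swap)
  expect_equal(mb_swap$estimate, -mb$estimate, tolerance = 0.05)
  # agents that ignore the bet: interaction CI covers zero
  mb0 <- motivational_bias(build(0, 0, seed = 43))
  expect_true(mb0$ci[1] < 0 && mb0$ci[2] > 0)
  # single-condition data rejected
  expect_error(motivational_bias(tt[tt$condition == "cooperation", ]),
               "both conditions")
})

test_that("rank-difference insight behaves at its extremes", {
  # participant ranked 1st on both scales scores 0
  omega <- c(0.1, 0.5, 1, 2)
  acc <- c(0.95, 0.9, 0.8, 0.7)
  expect_equal(insight_rank_difference(omega, acc), rep(0, 4))
  # worst perceived reliability with best objective accuracy: maximum n - 1
  omega2 <- c(2, 0.5, 1)
  acc2 <- c(0.95, 0.9, 0.8)
  d <- insight_rank_difference(omega2, acc2)
  expect_equal(d[1], 3 - 1)
  # missing fits are excluded with a message
  expect_message(insight_rank_difference(c(1, NA, 2), c(0.9, 0.8, 0.7)),
                 "excluded")
  expect_error(insight_rank_difference(1, 0.5), ">= 2")
})

test_that("Fisher-z correlation comparison matches the hand evaluation", {
  expect_equal(compare_correlations(0.4, 50, 0.4, 80)$p, 1)
  hand_z <- atanh(0.5) / sqrt(2 / 100)
  res <- compare_correlations(0.5, 103, 0.0, 103)
  expect_equal(res$z, hand_z, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-hand_z), tolerance = 1e-12)
  sw <- compare_correlations(0.0, 103, 0.5, 103)
  expect_equal(sw$p, res$p)
  expect_equal(sw$z, -res$z)
  expect_error(compare_correlations(1, 10, 0.5, 10), "< 1")
  expect_error(compare_correlations(0.2, 3, 0.5, 10), ">= 4")
})

test_that("self-deception profiles peak at maximal ambiguity when the cohort encodes it", {
  # cohort constructed with flip propensity proportional to stimulus
  # ambiguity: change toward the bet (cooperation) with probability
  # 0.5 * (1 - |scene_pct - 50| / 50)
  set.seed(88)
  paired_list <- lapply(seq_len(60), function(i) {
    pct <- rep(seq(0, 100, by = 10), length.out = 80)
    bet <- sample(c("scene", "face"), 80, replace = TRUE)
    c1 <- sample(c("scene", "face"), 80, replace = TRUE)
    flip <- runif(80) < 0.5 * (1 - abs(pct - 50) / 50)
    c2 <- ifelse(flip, bet, c1)
    data.frame(scene_pct = pct, condition = "cooperation",
               bet_direction = bet, c1_choice = c1, c2_choice = c2,
               c1_confidence = 4, c2_confidence = 4,
               stringsAsFactors = FALSE)
  })
  names(paired_list) <- paste0("p", seq_len(60))
  paired <- do.call(rbind, paired_list)
  sd_flag <- classify_self_deception(paired$condition, paired$c1_choice,
                                     paired$bet_direction, paired$c2_choice)
  prof <- tapply(sd_flag, paired$scene_pct, mean)
  expect_equal(names(which.max(prof)), "50")
  expect_lt(prof["0"], prof["50"])
  expect_lt(prof["100"], prof["50"])
})

test_that("participant metrics assemble per-participant scores from the table", {
  paired <- list(
    a = data.frame(scene_pct = c(80, 20, 50, 50), condition = "cooperation",
                   bet_direction = c("scene", "face", "scene", "face"),
                   c1_choice = c("scene", "face", "face", "face"),
                   c2_choice = c("scene", "face", "scene", "face"),
                   c1_confidence = c(4, 4, 4, 4),
                   c2_confidence = c(5, 5, 6, 3), gpts = 15, bai = 20),
    b = data.frame(scene_pct = c(80, 20, 50, 50), condition = "competition",
                   bet_direction = c("scene", "face", "scene", "face"),
                   c1_choice = c("scene", "face", "scene", "face"),
                   c2_choice = c("face", "face", "scene", "face"),
                   c1_confidence = c(2, 2, 2, 2),
                   c2_confidence = c(6, 2, 2, 2), gpts = 5, bai = 5))
  tt <- make_trial_table(paired)
  m <- participant_metrics(tt, fits = data.frame(participant_id = c("a", "b"),
                                                 omega_ns = c(2, 0.5)))
  m <- m[order(m$participant_id), ]
  # a: one SD trial (50/50, changed toward the bet under cooperation)
  expect_equal(m$raw_sd_score, c(1 / 4, 1 / 4))
  expect_equal(m$cwsd[1], (1 / 4) * 6 / 4)
  # b: changed away from the bet under competition on trial 1
  expect_equal(m$cwsd[2], (1 / 4) * 6 / 2)
  expect_identical(m$paranoia_group, c("high", "low"))
  expect_identical(m$anxiety_group, c("high", "low"))
  # C1 accuracy excludes the ambiguous 50/50 trials
  expect_equal(m$c1_accuracy, c(1, 1))
  # a has worse perceived reliability (rank 2) and tied accuracy (avg 1.5)
  expect_equal(m$insight_rank_diff, c(2 - 1.5, 1 - 1.5))
})
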