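# Shared fixtures and independent oracles. The oracle implementations here
# are deliberately straight-line re-codings of the printed model equations,
# kept independent of the package's filter internals.

make_task <- function(seed = 1, n = 80, accuracy = 0.5, experiment = 1,
                      grid = seq(0, 100, by = 10)) {
  simulate_task(task_config(experiment = experiment, n_trials = n,
                            scene_grid = grid, bet_accuracy = accuracy,
                            seed = seed))
}

# Straight-line dual-stream HGF pass (winning social map), one assignment
# per printed equation, no vectorization, no shared helpers.
oracle_trajectory <- function(trials, omega_s, omega_ns, mu2s0, eta,
                              eps = 1e-8) {
  n <- nrow(trials)
  mu2s <- mu2s0; s2s <- 1
  mu2ns <- 0; s2ns <- 1
  out <- data.frame(mu1hat_s = numeric(n), mu1hat_ns = numeric(n),
                    a_ns = numeric(n), b = numeric(n),
                    mu2_s = numeric(n), mu2_ns = numeric(n),
                    sigma2_s = numeric(n), sigma2_ns = numeric(n))
  for (t in seq_len(n)) {
    rb <- if (t == 1) 0 else (trials$scene_pct[t - 1] - 50) / 50
    m1s <- 1 / (1 + exp(-eta * omega_s * mu2s))
    m1s <- min(max(m1s, eps), 1 - eps)
    m1ns <- 1 / (1 + exp(-(mu2ns + rb)))
    m1ns <- min(max(m1ns, eps), 1 - eps)
    a <- if (trials$bet_direction[t] == "scene") m1ns else 1 - m1ns
    pis <- 1 / (m1s * (1 - m1s))
    pins <- 1 / (a * (1 - a))
    bb <- (pis * m1s + pins * a) / (pis + pins)
    # social update
    pi2hat <- 1 / (s2s + omega_s)
    d1 <- trials$bet_correct[t] - m1s
    pi2 <- pi2hat + 1 / pis
    mu2s <- mu2s + d1 / pi2
    s2s <- 1 / pi2
    # non-social update
    pi2hat_ns <- 1 / (s2ns + omega_ns)
    d1ns <- trials$scene_pct[t] / 100 - m1ns
    pi2ns <- pi2hat_ns + 1 / pins
    mu2ns <- mu2ns + d1ns / pi2ns
    s2ns <- 1 / pi2ns
    out[t, ] <- c(m1s, m1ns, a, bb, mu2s, mu2ns, s2s, s2ns)
  }
  out
}

# Draw agents' natural-scale parameters from a model's default priors.
draw_from_priors <- function(spec, n_agents, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  xi <- matrix(rnorm(n_agents * nrow(spec$params),
                     rep(spec$params$mean, each = n_agents),
                     rep(spec$params$sd, each = n_agents)),
               nrow = n_agents)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  as.data.frame(t(apply(xi, 1, function(x)
    unlist(natural_params(spec, x)))))
}

# Small trial table in the package schema, built directly (not via the
# generator), for metrics tests with hand-controllable choices.
make_trial_table <- function(paired_list) {
  rows <- lapply(names(paired_list), function(id) {
    p <- paired_list[[id]]
    n <- nrow(p)
    rbind(
      data.frame(participant_id = id, phase = "C1",
                 trial_idx = seq_len(n) - 1L, scene_pct = p$scene_pct,
                 bet_direction = NA_character_, bet_correct = NA_integer_,
                 choice = p$c1_choice, confidence = p$c1_confidence,
                 condition = p$condition,
                 gpts_persecution = p$gpts %||% 0, bai = p$bai %||% 0,
                 bdi = 0, stringsAsFactors = FALSE),
      data.frame(participant_id = id, phase = "C2",
                 trial_idx = seq_len(n) - 1L, scene_pct = p$scene_pct,
                 bet_direction = p$bet_direction,
                 bet_correct = p$bet_correct %||%
                   as.integer(p$bet_direction ==
                                ifelse(p$scene_pct > 50, "scene", "face")),
                 choice = p$c2_choice, confidence = p$c2_confidence,
                 condition = p$condition,
                 gpts_persecution = p$gpts %||% 0, bai = p$bai %||% 0,
                 bdi = 0, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
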