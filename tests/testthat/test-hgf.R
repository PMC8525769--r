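test_that("level-1 prediction maps match hand evaluations and limits", {
  expect_equal(recency_bias(50), 0)
  expect_equal(recency_bias(100), 1)
  expect_equal(recency_bias(0), -1)
  expect_equal(recency_bias(75), 0.5)
  expect_error(recency_bias(101), "\\[0, 100\\]")

  expect_equal(predict_social(0, 3, 0.7), 0.5)
  expect_equal(predict_social(1, 1, 2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(predict_social(1e6, 1, 2), 1)
  expect_error(predict_social(1, -1, 2), "> 0")

  expect_equal(predict_nonsocial(0, 0), 0.5)
  expect_equal(predict_nonsocial(0.5, -0.5), 0.5)
  expect_equal(predict_nonsocial(1, 1), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_error(predict_nonsocial(0, 2), "\\[-1, 1\\]")
})

test_that("one level-2 update reproduces the stated closure", {
  up <- update_level2(list(mu2 = 0, sigma2 = 1), mu1_hat = 0.5,
                      input_u = 1, omega = 1)
  expect_equal(up$pi2_hat, 0.5, tolerance = 1e-12)
  expect_equal(up$pi1_hat, 4, tolerance = 1e-12)
  expect_equal(up$pi2, 0.75, tolerance = 1e-12)
  expect_equal(up$mu2, 0.5 / 0.75, tolerance = 1e-12)
  expect_equal(up$sigma2, 1 / 0.75, tolerance = 1e-12)
  # zero prediction error: mean unchanged, variance still shrinks
  up0 <- update_level2(list(mu2 = 0.3, sigma2 = 2), 0.4, 0.4, 0.5)
  expect_equal(up0$mu2, 0.3)
  expect_lt(up0$sigma2, 2)
  # |mu2 step| grows monotonically with omega (finite-difference sweep)
  steps <- sapply(c(0.1, 0.5, 1, 2, 5, 20), function(w)
    abs(update_level2(list(mu2 = 0, sigma2 = 1), 0.5, 1, w)$mu2))
  expect_true(all(diff(steps) > 0))
})

test_that("belief combination is a precision-weighted convex mixture", {
  cb <- combine_beliefs(0.5, 0.5, "scene")
  expect_equal(cb$b, 0.5)
  cb2 <- combine_beliefs(0.5, 0.9, "scene")
  expect_equal(cb2$b, (4 * 0.5 + (1 / 0.09) * 0.9) / (4 + 1 / 0.09),
               tolerance = 1e-12)
  # face bet flips the non-social belief into agreement space
  expect_equal(combine_beliefs(0.5, 0.9, "face")$a_ns, 0.1)
  # equal precisions reduce to the arithmetic mean
  cb3 <- combine_beliefs(0.3, 0.7, "scene")
  expect_equal(cb3$b, 0.5, tolerance = 1e-12)
})

test_that("the filter matches a straight-line re-implementation to 1e-12", {
  trials <- make_task(seed = 21)
  for (par in list(c(1, 0.4, 0.5, 1.2), c(0.1, 2, -1, 0.3),
                   c(3, 0.05, 0, 2))) {
    traj <- filter_trajectory(
      stream_parameters(par[1], mu2_0 = par[3], eta = par[4]),
      stream_parameters(par[2]), trials)
    orc <- oracle_trajectory(trials, par[1], par[2], par[3], par[4])
    for (col in names(orc))
      expect_equal(traj[[col]], orc[[col]], tolerance = 1e-12)
  }
})

test_that("the filter equals the composition of the exported step operations", {
  trials <- make_task(seed = 8, n = 30)
  ps <- stream_parameters(0.8, mu2_0 = 0.4, eta = 1.5)
  pn <- stream_parameters(0.3)
  traj <- filter_trajectory(ps, pn, trials)
  s <- list(mu2 = ps$mu2_0, sigma2 = ps$sigma2_0)
  ns <- list(mu2 = pn$mu2_0, sigma2 = pn$sigma2_0)
  for (t in seq_len(nrow(trials))) {
    rb <- if (t == 1) 0 else recency_bias(trials$scene_pct[t - 1])
    m1s <- predict_social(s$mu2, ps$eta, ps$omega)
    m1ns <- predict_nonsocial(ns$mu2, rb)
    cb <- combine_beliefs(m1s, m1ns, trials$bet_direction[t])
    expect_equal(traj$b[t], cb$b, tolerance = 1e-12)
    s <- update_level2(s, m1s, trials$bet_correct[t], ps$omega)
    ns <- update_level2(ns, m1ns, trials$scene_pct[t] / 100, pn$omega)
    expect_equal(traj$mu2_s[t], s$mu2, tolerance = 1e-12)
    expect_equal(traj$mu2_ns[t], ns$mu2, tolerance = 1e-12)
  }
})

test_that("filter invariants hold across seeded parameter draws", {
  set.seed(404)
  for (i in 1:20) {
    trials <- make_task(seed = i)
    traj <- filter_trajectory(
      stream_parameters(exp(rnorm(1, -1, 1.5)), mu2_0 = rnorm(1),
                        eta = exp(rnorm(1))),
      stream_parameters(exp(rnorm(1, -1, 1.5))), trials)
    vals <- c(traj$mu1hat_s, traj$mu1hat_ns, traj$a_ns, traj$b)
    expect_true(all(vals > 0 & vals < 1))
    expect_true(all(is.finite(c(traj$pi1hat_s, traj$pi1hat_ns,
                                traj$pi2hat_s, traj$pi2hat_ns))))
    expect_true(all(c(traj$pi1hat_s, traj$pi1hat_ns) >= 4 - 1e-9))
    # convexity: b lies between the stream beliefs
    lo <- pmin(traj$mu1hat_s, traj$a_ns); hi <- pmax(traj$mu1hat_s, traj$a_ns)
    expect_true(all(traj$b >= lo - 1e-12 & traj$b <= hi + 1e-12))
    # sigma2 = 1/pi2 consistency
    expect_equal(traj$sigma2_s,
                 1 / (traj$pi2hat_s + 1 / traj$pi1hat_s), tolerance = 1e-10)
  }
})

test_that("zero-information inputs leave level 2 stationary; runs are deterministic", {
  tc <- task_config(n_trials = 40, scene_grid = 50, seed = 2)
  trials <- simulate_task(tc)
  traj <- filter_trajectory(
    stream_parameters(1, mu2_0 = 0, eta = 1), stream_parameters(1), trials,
    inputs = list(u_s = rep(0.5, 40), u_ns = rep(0.5, 40)))
  expect_equal(traj$mu2_s, rep(0, 40))
  expect_equal(traj$mu2_ns, rep(0, 40))
  expect_equal(traj$b, rep(0.5, 40))

  tr2 <- make_task(seed = 77)
  args <- list(stream_parameters(0.6, mu2_0 = 1, eta = 2),
               stream_parameters(0.2), tr2)
  expect_identical(do.call(filter_trajectory, args),
                   do.call(filter_trajectory, args))
})

test_that("fully correct bets with a confident social prior push the social belief up", {
  trials <- make_task(seed = 10)
  trials <- generate_bets(trials, 1, seed = 1)
  traj <- filter_trajectory(stream_parameters(1, mu2_0 = 2, eta = 1),
                            stream_parameters(0.5), trials)
  expect_true(all(diff(traj$mu1hat_s) >= -1e-12))
  expect_gt(traj$mu1hat_s[80], traj$mu1hat_s[1])
})

test_that("larger omega_ns weakens the recency-bias signature in predictions", {
  trials <- make_task(seed = 31)
  cors <- sapply(c(0.05, 0.5, 5), function(w) {
    traj <- filter_trajectory(NULL, stream_parameters(w), trials)
    p <- softmax_prob(traj$mu1hat_ns, 4)
    cor(traj$recency_bias, p)
  })
  expect_true(all(diff(cors) < 0))
})

test_that("the Rescorla-Wagner baseline follows the delta rule exactly", {
  trials <- make_task(seed = 4, n = 2)
  # alpha = 0.5, V0 = 0.5, inputs 1,1 -> V = 0.75 then 0.875
  traj <- rw_trajectory(rw_parameters(0.5, 0.5), trials,
                        inputs = list(u_s = c(1, 1), u_ns = c(1, 1)))
  expect_equal(traj$V_s, c(0.75, 0.875))
  expect_equal(traj$V_ns, c(0.75, 0.875))
  # alpha = 1 tracks the previous input exactly
  tr10 <- make_task(seed = 4, n = 10)
  u <- runif(10)
  t1 <- rw_trajectory(rw_parameters(1, 1), tr10,
                      inputs = list(u_s = u, u_ns = u))
  expect_equal(t1$mu1hat_ns[-1], u[-10])
  # stationary input: geometric convergence at rate (1 - alpha)
  tr20 <- make_task(seed = 5, n = 20)
  t2 <- rw_trajectory(rw_parameters(0.3, 0.3), tr20,
                      inputs = list(u_s = rep(0.9, 20), u_ns = rep(0.9, 20)))
  expect_equal(t2$V_ns, 0.9 - (0.9 - 0.5) * 0.7^(1:20), tolerance = 1e-12)
})

test_that("input length mismatches are rejected", {
  trials <- make_task(seed = 1, n = 10)
  expect_error(filter_trajectory(stream_parameters(1, eta = 1),
                                 stream_parameters(1), trials,
                                 inputs = list(u_s = 1:3 / 3,
                                               u_ns = 1:10 / 10)),
               "length")
})
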