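test_that("learning configuration rejects degenerate values", {
  expect_error(learning_config(sigma = 0), "sigma")
  expect_error(learning_config(alpha_w = -0.1), "alpha_w")
  expect_error(learning_config(T = 0), "T must be")
})

test_that("TD error, critic and actor updates follow the defining arithmetic", {
  cfg <- fig_learning()
  s <- learner_state(w = 1.0, theta = 0.2)
  expect_equal(td_error(1.0, s), 0)
  expect_equal(td_error(3.0, s), 2.0)

  expect_equal(update_value(s, 0, cfg), s)
  expect_equal(update_value(s, 2.0, cfg)$w, 1.08)
  expect_equal(update_value(s, 2.0, cfg)$theta, 0.2)

  expect_equal(eligibility(0.2, s, cfg), 0)
  expect_equal(eligibility(0.25, s, cfg), 20.0)

  expect_equal(update_policy(s, 0, 5, cfg)$theta, 0.2)
  expect_equal(update_policy(s, 2.0, 20.0, cfg)$theta, 0.28)
  expect_equal(update_policy(s, 2.0, 20.0, cfg)$w, 1.0)
})

test_that("constant reward drives the critic geometrically to the reward", {
  cfg <- fig_learning()
  R <- 2.5
  w <- 1.0
  for (t in 1:200) w <- w + cfg$alpha_w * (R - w)
  # closed form: w_t = R + (w_0 - R) * (1 - alpha_w)^t
  expect_equal(w, R + (1.0 - R) * (1 - cfg$alpha_w)^200)
  expect_lt(abs(w - R), 1e-3)
})

test_that("the Gaussian policy samples centre on theta with zero-mean eligibility", {
  cfg <- fig_learning()
  s <- learner_state(w = 1, theta = 0.2)
  set.seed(123)
  draws <- vapply(1:1e5, function(i) sample_action(s, cfg), numeric(1))
  expect_lt(abs(mean(draws) - 0.2), 3 * cfg$sigma / sqrt(1e5))
  zeta <- (draws - 0.2) / cfg$sigma^2
  expect_lt(abs(mean(zeta)), 3 * sd(zeta) / sqrt(1e5))
})

test_that("actor and critic rates couple through sigma and the working ranges", {
  expect_equal(couple_rates(0.04, 0.05), 0.002)
  # traversal-time matching: alpha_theta = alpha_w * sigma * dtheta / dw
  expect_equal(couple_rates(0.04, 0.05, delta_w = 2, delta_theta = 1), 0.001)
  expect_equal(couple_rates(0.04, 0.1), 2 * couple_rates(0.04, 0.05))
  expect_error(couple_rates(0.04, -1), "positive")
})

test_that("a round replays exactly from recorded draws", {
  pp <- fig_params()
  cfg <- fig_learning()
  comp <- group_composition(q = c(0, 1))
  states <- list(learner_state(1, 0.2), learner_state(1, 0.2))
  set.seed(99)
  a <- rnorm(2, mean = 0.2, sd = cfg$sigma)       # the draws the round will use
  abar <- sum(a) / 2
  reward <- benefit(abar, pp) - cost(a, comp$p, pp)
  delta <- reward - 1
  zeta <- (a - 0.2) / cfg$sigma^2
  set.seed(99)
  out <- step_round(states, comp, pp, cfg)
  expect_equal(out$record$action, a)
  expect_equal(out$record$delta, delta)
  expect_equal(out$record$w, 1 + cfg$alpha_w * delta)
  expect_equal(out$record$theta, 0.2 + cfg$alpha_theta * delta * zeta)
})

test_that("rewards driving learning use perceived, not true, qualities", {
  pp <- fig_params()
  cfg <- fig_learning(T = 50L)
  comp <- group_composition(q = c(0.5, 1), p = c(0.1, 0.7))
  set.seed(5)
  traj <- run_learning(comp, pp, cfg)
  r <- traj$records
  expect_equal(r$fitness_payoff - r$reward, pp$K12 * (r$q - r$p) * r$action)
  expect_true(all(r$fitness_payoff != r$reward))
})

test_that("learning trajectories are deterministic given the seed", {
  pp <- fig_params()
  cfg <- fig_learning(T = 100L)
  comp <- group_composition(q = c(0, 1))
  set.seed(17)
  t1 <- run_learning(comp, pp, cfg)
  set.seed(17)
  t2 <- run_learning(comp, pp, cfg)
  expect_identical(t1$records, t2$records)
})

test_that("the compiled population kernel reproduces the R round loop bit for bit", {
  pp <- fig_params()
  for (case in list(list(q = c(0, 1), T = 400L),
                    list(q = c(0, 0.5, 1), T = 250L))) {
    g <- length(case$q)
    cfg <- fig_learning(T = case$T)
    set.seed(31)
    traj <- run_learning(group_composition(q = case$q), pp, cfg)
    set.seed(31)
    k <- pggbias:::learn_kernel(
      rep(cfg$w_init, g), rep(cfg$theta_init, g), case$q, case$q,
      g, case$T, pp$B0, pp$B1, pp$B2, pp$K1, pp$K11, pp$K12,
      cfg$sigma, cfg$alpha_w, cfg$alpha_theta, FALSE, pp$a_max, TRUE
    )
    last <- traj$records[traj$records$t == case$T, ]
    expect_identical(unname(last$theta), unname(k$theta))
    expect_identical(unname(last$w), unname(k$w))
    # kernel fitness equals the mean true-quality payoff over rounds
    per_ind <- split(traj$records, traj$records$individual)
    expect_equal(unname(k$fitness),
                 unname(vapply(per_ind, function(d) mean(d$fitness_payoff),
                               numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("learning settles near the one-shot equilibrium with vanishing TD error", {
  traj <- fig1_reference_run()
  smry <- trajectory_summary(traj, window = 500L)
  nash <- nash_investments(nash_coefficients(fig_params(), 2), c(0, 1))
  expect_lt(max(abs(smry$theta_mean - nash$a_star)), 0.05)
  # at stationarity the critic predicts the mean reward: time-averaged TD
  # error vanishes for every learner
  expect_true(all(abs(smry$delta_mean) < 0.02))
})

test_that("equilibrium tracking tightens as exploration and rates shrink", {
  pp <- fig_params()
  comp <- group_composition(q = c(0, 1))
  nash <- nash_investments(nash_coefficients(pp, 2), c(0, 1))$a_star
  dist_for <- function(sigma, scale, T) {
    cfg <- learning_config(sigma = sigma, alpha_w = 0.04 * scale,
                           alpha_theta = couple_rates(0.04 * scale, sigma),
                           T = T, w_init = 1, theta_init = 0.2)
    set.seed(555)
    smry <- trajectory_summary(run_learning(comp, pp, cfg), window = 500L)
    sqrt(sum((smry$theta_mean - nash)^2))
  }
  coarse <- dist_for(sigma = 0.2, scale = 2, T = 2000L)
  fine <- dist_for(sigma = 0.05, scale = 1, T = 3000L)
  expect_lt(fine, coarse)
})

test_that("the low-quality learner overshoots its eventual investment", {
  # qualitative pattern, reported rather than asserted strictly: the
  # low-quality individual's theta rises above its final value on the way
  # to equilibrium
  traj <- fig1_reference_run()
  th1 <- traj$records$theta[traj$records$individual == 1]
  final <- mean(tail(th1, 500))
  expect_gt(max(th1), final)
})
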