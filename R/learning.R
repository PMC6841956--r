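#' Configuration of the actor-critic learning process
#'
#' One-state actor-critic learning with a Gaussian policy: each learner keeps
#' an estimated value `w` (the critic) and a policy mean `theta` (the actor),
#' samples investments from Normal(theta, sigma^2), and updates both
#' parameters from the temporal-difference (TD) error between the perceived
#' reward and `w`. The exploration SD `sigma` is held constant; each round is
#' an independent episode with no discounting and no eligibility traces
#' across rounds.
#'
#' @param sigma Policy SD (action units); must be positive.
#' @param alpha_w Critic (value) learning rate; must be positive.
#' @param alpha_theta Actor (policy) learning rate; must be positive.
#' @param T Number of investment rounds per interaction; integer >= 1.
#' @param w_init Initial estimated value.
#' @param theta_init Initial policy mean.
#' @param clamp_actions If `TRUE`, sampled actions are clamped from above at
#'   the maximum-benefit investment `a_max = -B1/B2`, so that benefits never
#'   decrease in an action. Off by default: with the default payoff
#'   coefficients equilibrium investments lie well below `a_max`, so the
#'   clamp is a guard rather than a behaviour.
#'
#' @return An object of class `learning_config`.
#' @examples
#' learning_config()  # the reference configuration used throughout
#' @export
learning_config <- function(sigma = 0.05, alpha_w = 0.04, alpha_theta = 0.002,
                            T = 2000L, w_init = 1.0, theta_init = 0.2,
                            clamp_actions = FALSE) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.finite(alpha_w) || alpha_w <= 0) stop("alpha_w must be > 0", call. = FALSE)
  if (!is.finite(alpha_theta) || alpha_theta <= 0) {
    stop("alpha_theta must be > 0", call. = FALSE)
  }
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be an integer >= 1", call. = FALSE)
  structure(
    list(sigma = sigma, alpha_w = alpha_w, alpha_theta = alpha_theta, T = T,
         w_init = w_init, theta_init = theta_init,
         clamp_actions = isTRUE(clamp_actions)),
    class = "learning_config"
  )
}

#' @export
print.learning_config <- function(x, ...) {
  cat("Actor-critic learning configuration\n")
  cat(sprintf("  sigma = %g, alpha_w = %g, alpha_theta = %g, T = %d\n",
              x$sigma, x$alpha_w, x$alpha_theta, x$T))
  cat(sprintf("  initial state: w = %g, theta = %g; clamp_actions = %s\n",
              x$w_init, x$theta_init, x$clamp_actions))
  invisible(x)
}

#' One learner's state
#'
#' @param w Estimated value (critic), reward units.
#' @param theta Policy mean (actor), action units.
#' @return A list of class `learner_state`.
#' @export
learner_state <- function(w = 1.0, theta = 0.2) {
  if (!is.finite(w) || !is.finite(theta)) {
    stop("learner state must be finite", call. = FALSE)
  }
  structure(list(w = w, theta = theta), class = "learner_state")
}

#' Sample an investment from the Gaussian policy
#'
#' @param state A [learner_state].
#' @param config A [learning_config].
#' @param params Optional [payoff_params]; required when the configuration
#'   clamps actions at `a_max`.
#' @return A draw from Normal(theta, sigma^2).
#' @export
sample_action <- function(state, config, params = NULL) {
  a <- stats::rnorm(1L, mean = state$theta, sd = config$sigma)
  if (config$clamp_actions) {
    if (is.null(params)) stop("clamping requires payoff params", call. = FALSE)
    a <- min(a, params$a_max)
  }
  a
}

#' Temporal-difference (prediction) error
#'
#' The difference between the reward just received and the critic's current
#' estimate; the reinforcement that drives both value and policy updates.
#'
#' @param reward Perceived reward from the round.
#' @param state A [learner_state].
#' @return `reward - w`.
#' @export
td_error <- function(reward, state) {
  reward - state$w
}

#' Critic update
#'
#' @param state A [learner_state].
#' @param delta TD error.
#' @param config A [learning_config].
#' @return The state with `w` moved by `alpha_w * delta`; `theta` unchanged.
#' @export
update_value <- function(state, delta, config) {
  learner_state(w = state$w + config$alpha_w * delta, theta = state$theta)
}

#' Eligibility of an action under the Gaussian policy
#'
#' The gradient of the log policy density with respect to the policy mean,
#' `(a - theta) / sigma^2`. Its expectation over the policy is zero.
#'
#' @param action The sampled investment.
#' @param state A [learner_state].
#' @param config A [learning_config].
#' @return The eligibility.
#' @export
eligibility <- function(action, state, config) {
  if (config$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  (action - state$theta) / config$sigma^2
}

#' Actor (policy-gradient) update
#'
#' @param state A [learner_state].
#' @param delta TD error.
#' @param elig Eligibility of the sampled action.
#' @param config A [learning_config].
#' @return The state with `theta` moved by `alpha_theta * delta * elig`;
#'   `w` unchanged. The expected increment equals
#'   `alpha_theta * Cov(delta, elig)`.
#' @export
update_policy <- function(state, delta, elig, config) {
  learner_state(w = state$w,
                theta = state$theta + config$alpha_theta * delta * elig)
}

#' One synchronous round of group learning
#'
#' All g members sample an investment from their pre-round policies; each
#' receives the perceived reward computed with its perceived quality `p_i`;
#' each then applies the critic update followed by the actor update using its
#' own TD error and eligibility. Updates are synchronous: every action in the
#' round is drawn from the pre-round states.
#'
#' @param states List of g [learner_state] objects.
#' @param composition A [group_composition].
#' @param params A [payoff_params].
#' @param config A [learning_config].
#' @return A list with `states` (the updated learner states) and `record`, a
#'   one-row-per-individual data frame with the actions, perceived rewards,
#'   TD errors and post-update states.
#' @export
step_round <- function(states, composition, params, config) {
  g <- composition$g
  if (length(states) != g) {
    stop("need one learner state per group member", call. = FALSE)
  }
  theta <- vapply(states, `[[`, numeric(1), "theta")
  w <- vapply(states, `[[`, numeric(1), "w")
  actions <- stats::rnorm(g, mean = theta, sd = config$sigma)
  if (config$clamp_actions) actions <- pmin(actions, params$a_max)
  rewards <- payoff(actions, composition$p, params)
  deltas <- rewards - w
  zetas <- (actions - theta) / config$sigma^2
  w_new <- w + config$alpha_w * deltas
  theta_new <- theta + config$alpha_theta * deltas * zetas
  list(
    states = lapply(seq_len(g), function(i) {
      learner_state(w = w_new[i], theta = theta_new[i])
    }),
    record = data.frame(
      individual = seq_len(g), q = composition$q, p = composition$p,
      action = actions, reward = rewards, delta = deltas,
      w = w_new, theta = theta_new
    )
  )
}

#' Run the within-generation learning dynamics for one group
#'
#' Iterates [step_round()] for `config$T` rounds and records the full
#' trajectory. Rewards are computed from perceived qualities; the trajectory
#' also reports each individual's true-quality (fitness) payoff per round,
#' which differs from the perceived reward by exactly
#' `K12 * (q_i - p_i) * a_i`.
#'
#' The learning dynamics approach the one-shot Nash equilibrium of the stage
#' game with the perceived qualities as the quality vector (see
#' [nash_investments()]), so the terminal window of `theta` can be compared
#' directly to that prediction.
#'
#' @param composition A [group_composition].
#' @param params A [payoff_params].
#' @param config A [learning_config].
#' @return An object of class `pgg_trajectory`: list with `records` (a data
#'   frame with columns t, individual, q, p, action, reward, fitness_payoff,
#'   delta, w, theta), `composition` and `config`.
#' @examples
#' set.seed(1)
#' traj <- run_learning(group_composition(q = c(0, 1)), payoff_params(),
#'                      learning_config(T = 200))
#' tail(subset(traj$records, individual == 2)$theta, 3)
#' @export
run_learning <- function(composition, params, config) {
  g <- composition$g
  states <- replicate(g, learner_state(config$w_init, config$theta_init),
                      simplify = FALSE)
  recs <- vector("list", config$T)
  for (t in seq_len(config$T)) {
    out <- step_round(states, composition, params, config)
    states <- out$states
    rec <- out$record
    rec$t <- t
    recs[[t]] <- rec
  }
  records <- do.call(rbind, recs)
  records$fitness_payoff <- records$reward +
    params$K12 * (records$q - records$p) * records$action
  records <- records[, c("t", "individual", "q", "p", "action", "reward",
                         "fitness_payoff", "delta", "w", "theta")]
  rownames(records) <- NULL
  structure(list(records = records, composition = composition,
                 config = config, params = params),
            class = "pgg_trajectory")
}

#' @export
print.pgg_trajectory <- function(x, ...) {
  cat(sprintf("Learning trajectory: g = %d, T = %d rounds\n",
              x$composition$g, x$config$T))
  fin <- trajectory_summary(x)
  print(fin, row.names = FALSE)
  invisible(x)
}

#' Terminal-window summary of a learning trajectory
#'
#' Mean and SD of `theta` and `w` over the last `window` rounds for each
#' individual, the scale on which learning outcomes are compared with the
#' one-shot Nash predictions.
#'
#' @param trajectory A `pgg_trajectory` from [run_learning()].
#' @param window Number of final rounds to average over.
#' @return A data frame with one row per individual.
#' @export
trajectory_summary <- function(trajectory, window = 500L) {
  r <- trajectory$records
  window <- min(window, trajectory$config$T)
  r <- r[r$t > trajectory$config$T - window, ]
  out <- do.call(rbind, lapply(split(r, r$individual), function(d) {
    data.frame(individual = d$individual[1], q = d$q[1], p = d$p[1],
               theta_mean = mean(d$theta), theta_sd = stats::sd(d$theta),
               w_mean = mean(d$w), w_sd = stats::sd(d$w),
               delta_mean = mean(d$delta))
  }))
  rownames(out) <- NULL
  out
}

#' Couple the actor learning rate to the critic learning rate
#'
#' For the value estimate and the policy mean to traverse their working
#' ranges `delta_w` and `delta_theta` over comparable numbers of rounds, the
#' rates should satisfy `alpha_w * delta_theta ~ (alpha_theta / sigma) *
#' delta_w` (the eligibility has magnitude about `1/sigma`), giving
#' `alpha_theta = alpha_w * sigma * delta_theta / delta_w`. With both ranges
#' about 1, the reference critic rate 0.04 and SD 0.05 yield the reference
#' actor rate 0.002.
#'
#' @param alpha_w Critic learning rate (> 0).
#' @param sigma Policy SD (> 0).
#' @param delta_w Working range of the estimated value (> 0).
#' @param delta_theta Working range of the policy mean (> 0).
#' @return The coupled actor learning rate `alpha_theta`.
#' @examples
#' couple_rates(0.04, 0.05)  # 0.002
#' @export
couple_rates <- function(alpha_w, sigma, delta_w = 1, delta_theta = 1) {
  vals <- c(alpha_w, sigma, delta_w, delta_theta)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  alpha_w * sigma * delta_theta / delta_w
}
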