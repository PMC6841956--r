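# Reference parameterisation used across the tests: the quadratic stage game
# with B = (1, 4, -2), K = (1, 1, -1), two learners with sigma = 0.05,
# alpha_w = 0.04, alpha_theta = 0.002, started at (w, theta) = (1.0, 0.2).

fig_params <- function() {
  payoff_params(B0 = 1, B1 = 4, B2 = -2, K1 = 1, K11 = 1, K12 = -1)
}

fig_learning <- function(T = 2000L, ...) {
  learning_config(sigma = 0.05, alpha_w = 0.04, alpha_theta = 0.002, T = T,
                  w_init = 1.0, theta_init = 0.2, ...)
}

quality_set5 <- c(0, 0.25, 0.5, 0.75, 1)

# random payoff parameter draws respecting the sign constraints
random_params <- function() {
  payoff_params(
    B0 = runif(1, 0, 2), B1 = runif(1, 1, 5), B2 = -runif(1, 0.5, 3),
    K1 = runif(1, 0.5, 2), K11 = runif(1, 0.5, 2), K12 = -runif(1, 0.2, 1.5)
  )
}

# one long reference learning run, computed once per test session
fig1_reference_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(20240201)
      cache <<- run_learning(group_composition(q = c(0, 1)), fig_params(),
                             fig_learning(T = 3000L))
    }
    cache
  }
})
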