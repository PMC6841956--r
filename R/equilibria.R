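#' Closed-form coefficients of the one-shot Nash equilibrium
#'
#' For the quadratic stage game the unique Nash equilibrium is linear in the
#' quality vector: `a*_i = e0 + e1*x_i + e2*sum_{j!=i} x_j`, where `x` may be
#' the true or the perceived qualities. The coefficients follow from the
#' first-order conditions `(1/g) B'(abar*) = K1 + K11 a*_i + K12 x_i`:
#' summing over the group gives the equilibrium mean
#' `abar* = (B1 - g K1 - K12 sum x) / (g K11 - B2)`, and back-substitution
#' gives, with `D = g K11 - B2`,
#' \deqn{e_0 = (B_1 - g K_1)/D,\quad
#'       e_1 = -K_{12}\,(g^2 K_{11} - (g-1) B_2)/(g D K_{11}),\quad
#'       e_2 = -B_2 K_{12}/(g D K_{11}).}
#' Under the sign constraints `e1 > 0` and, for `g > 1`, `e2 < 0`: at
#' equilibrium higher-quality individuals invest more, and an individual's
#' investment decreases in each partner's quality. For `g = 1` there are no
#' partners and `e2` is reported as 0.
#'
#' @param params A [payoff_params].
#' @param g Group size (integer >= 1).
#' @return An object of class `nash_coefficients`: list with `e0`, `e1`,
#'   `e2` and `g`.
#' @examples
#' nash_coefficients(payoff_params(), g = 2)  # e = (0.5, 0.75, -0.25)
#' @export
nash_coefficients <- function(params, g) {
  stopifnot(inherits(params, "payoff_params"))
  g <- as.integer(g)
  if (is.na(g) || g < 1L) stop("g must be an integer >= 1", call. = FALSE)
  D <- g * params$K11 - params$B2
  if (D <= 0) stop("degenerate denominator g*K11 - B2 <= 0", call. = FALSE)
  e0 <- (params$B1 - g * params$K1) / D
  e1 <- -params$K12 * (g^2 * params$K11 - (g - 1) * params$B2) /
    (g * D * params$K11)
  e2 <- if (g == 1L) 0 else -params$B2 * params$K12 / (g * D * params$K11)
  structure(list(e0 = e0, e1 = e1, e2 = e2, g = g),
            class = "nash_coefficients")
}

#' @export
print.nash_coefficients <- function(x, ...) {
  cat(sprintf("Nash coefficients (g = %d): a*_i = %g + %g*x_i",
              x$g, x$e0, x$e1))
  if (x$g > 1L) cat(sprintf(" + %g*sum_{j!=i} x_j", x$e2))
  cat("\n")
  invisible(x)
}

#' Nash equilibrium investments for a quality vector
#'
#' Applies the linear closed form to a vector of qualities (true or
#' perceived) and fills in the equilibrium group mean and the expected
#' stage-game payoffs at the equilibrium profile.
#'
#' @param coeffs A [nash_coefficients] object.
#' @param qualities Numeric vector of length `g` of qualities.
#' @return An object of class `nash_solution`: list with `a_star`,
#'   `a_bar_star` and `expected_payoffs` (payoffs evaluated at the same
#'   quality vector that defined the equilibrium).
#' @examples
#' pp <- payoff_params()
#' nash_investments(nash_coefficients(pp, 2), c(0, 1))  # a* = (0.25, 1.25)
#' @export
nash_investments <- function(coeffs, qualities) {
  stopifnot(inherits(coeffs, "nash_coefficients"))
  x <- as.numeric(qualities)
  if (length(x) != coeffs$g) {
    stop("quality vector length must equal the coefficients' group size",
         call. = FALSE)
  }
  a <- coeffs$e0 + coeffs$e1 * x + coeffs$e2 * (sum(x) - x)
  structure(list(a_star = a, a_bar_star = mean(a), qualities = x),
            class = "nash_solution")
}

#' @export
print.nash_solution <- function(x, ...) {
  cat("One-shot Nash equilibrium\n")
  cat("  a*:   ", paste(format(x$a_star), collapse = ", "), "\n")
  cat("  abar*:", format(x$a_bar_star), "\n")
  invisible(x)
}

#' Expected payoffs at a Nash solution
#'
#' @param solution A `nash_solution`.
#' @param params The [payoff_params] that generated it.
#' @param qualities Qualities at which to score the payoffs; defaults to the
#'   qualities that defined the equilibrium. Passing true qualities while the
#'   equilibrium was computed from perceived qualities gives the fitness
#'   payoffs at the learning outcome.
#' @return Numeric vector of payoffs.
#' @export
nash_payoffs <- function(solution, params, qualities = solution$qualities) {
  payoff(solution$a_star, qualities, params)
}

#' Nash equilibrium by damped best-response iteration
#'
#' Independent numerical route to the equilibrium, used to validate the
#' closed form. Each player's best response to the others' investments has a
#' one-dimensional closed form from exact quadratic maximisation:
#' `BR_i = (B1/g + B2*S_i/g^2 - K1 - K12*x_i) / (K11 - B2/g^2)` with `S_i`
#' the partners' total investment; strict concavity (`K11 - B2/g^2 > 0`)
#' makes damped simultaneous iteration converge to the unique fixed point.
#'
#' @param params A [payoff_params].
#' @param qualities Quality vector (true or perceived).
#' @param tol Convergence tolerance on the max absolute change per sweep.
#' @param damping Damping weight on the new best response, in (0, 1].
#' @param start Optional starting profile (defaults to zeros).
#' @param max_iter Iteration cap.
#' @return A `nash_solution`, as from [nash_investments()].
#' @examples
#' pp <- payoff_params()
#' nash_best_response(pp, c(0, 1))$a_star
#' @export
nash_best_response <- function(params, qualities, tol = 1e-10, damping = 0.5,
                               start = NULL, max_iter = 1e5) {
  stopifnot(inherits(params, "payoff_params"))
  x <- as.numeric(qualities)
  g <- length(x)
  if (g < 1L) stop("need at least one player", call. = FALSE)
  a <- if (is.null(start)) numeric(g) else as.numeric(start)
  if (length(a) != g) stop("start profile has wrong length", call. = FALSE)
  denom <- params$K11 - params$B2 / g^2
  for (iter in seq_len(max_iter)) {
    s <- sum(a) - a
    br <- (params$B1 / g + params$B2 * s / g^2 - params$K1 -
             params$K12 * x) / denom
    a_new <- (1 - damping) * a + damping * br
    if (max(abs(a_new - a)) < tol) {
      a <- a_new
      return(structure(list(a_star = a, a_bar_star = mean(a), qualities = x),
                       class = "nash_solution"))
    }
    a <- a_new
  }
  stop("best-response iteration failed to converge", call. = FALSE)
}

#' Selection gradient of fitness with respect to perceived quality
#'
#' Derivative of individual `i`'s fitness payoff, evaluated at the one-shot
#' Nash equilibrium for the perceived qualities, with respect to its own
#' perceived quality `p_i`:
#' \deqn{dW_i/dp_i = [K_a(a^*_i, p_i) - K_a(a^*_i, q_i)]\,e_1
#'   + \tfrac{1}{g} B'(\bar a^*(p)) \sum_{j \ne i} e_2,}
#' where `K_a` is the marginal cost and the equilibrium sensitivities are the
#' Nash coefficients (`da*_i/dp_i = e1`, `da*_j/dp_i = e2`). For the
#' quadratic cost the bracket equals `K12 * (p_i - q_i)`. At `p = q` the
#' bracket vanishes while the partner term is negative for `g > 1`, so zero
#' bias is not an evolutionary equilibrium: fitness increases as an
#' individual lowers its perceived quality below its true quality.
#'
#' @param params A [payoff_params].
#' @param g Group size.
#' @param q True qualities (length g).
#' @param p Perceived qualities (length g).
#' @param i Player index.
#' @return The scalar selection gradient.
#' @examples
#' pp <- payoff_params()
#' selection_gradient(pp, 2, q = c(1, 1), p = c(1, 1), i = 1)  # negative
#' @export
selection_gradient <- function(params, g, q, p, i) {
  g <- as.integer(g)
  if (length(q) != g || length(p) != g) {
    stop("q and p must have length g", call. = FALSE)
  }
  if (i < 1 || i > g) stop("player index out of range", call. = FALSE)
  co <- nash_coefficients(params, g)
  sol <- nash_investments(co, p)
  bracket <- params$K12 * (p[i] - q[i])
  bprime <- params$B1 + params$B2 * sol$a_bar_star
  bracket * co$e1 + (1 / g) * bprime * (g - 1) * co$e2
}

#' Evolutionarily stable bias line
#'
#' Solves `selection_gradient = 0` simultaneously for all group members. For
#' the quadratic stage game the solution forces a common bias `d` for every
#' member (the partner term depends on the perceived qualities only through
#' the equilibrium mean), satisfying the scalar linear fixed point
#' `K12 e1 d + ((g-1) e2 / g) B'(abar*(qbar + d)) = 0`, whose solution is
#' linear in the group-mean true quality: `d* = beta0 + beta1 * qbar`. For
#' `g = 1` both coefficients are zero — a solitary individual evolves no
#' bias. For `g > 1` under the default parameters the line is negative over
#' the whole quality range and its magnitude shrinks toward zero as `g`
#' grows.
#'
#' @param params A [payoff_params].
#' @param g Group size.
#' @return An object of class `bias_coefficients`: list with `beta0`,
#'   `beta1` and `g`.
#' @examples
#' ess_bias_line(payoff_params(), g = 2)  # (beta0, beta1) = (-0.6, 0.2)
#' @export
ess_bias_line <- function(params, g) {
  stopifnot(inherits(params, "payoff_params"))
  g <- as.integer(g)
  if (is.na(g) || g < 1L) stop("g must be an integer >= 1", call. = FALSE)
  if (g == 1L) {
    return(structure(list(beta0 = 0, beta1 = 0, g = g),
                     class = "bias_coefficients"))
  }
  co <- nash_coefficients(params, g)
  D <- g * params$K11 - params$B2
  # B'(abar*(qbar + d)) = g * ((B1 K11 - B2 K1) - B2 K12 (qbar + d)) / D
  A <- params$B1 * params$K11 - params$B2 * params$K1
  C <- params$K12 * co$e1 - (g - 1) * co$e2 * params$B2 * params$K12 / D
  if (abs(C) < .Machine$double.eps) {
    stop("degenerate bias-line solve", call. = FALSE)
  }
  beta0 <- -(g - 1) * co$e2 * A / (D * C)
  beta1 <- (g - 1) * co$e2 * params$B2 * params$K12 / (D * C)
  structure(list(beta0 = beta0, beta1 = beta1, g = g),
            class = "bias_coefficients")
}

#' @export
print.bias_coefficients <- function(x, ...) {
  cat(sprintf("ESS bias line (g = %d): d* = %g + %g * qbar\n",
              x$g, x$beta0, x$beta1))
  invisible(x)
}

#' Numeric check of the stable bias by root finding
#'
#' Finds the common bias `d` at which the selection gradient vanishes for a
#' group with all true qualities equal to components of `q`, by
#' one-dimensional root finding on [selection_gradient()]. Used as an
#' independent verification of [ess_bias_line()].
#'
#' @param params A [payoff_params].
#' @param q True-quality vector (length g).
#' @param interval Search interval for the bias.
#' @return The root `d*`.
#' @export
ess_bias_numeric <- function(params, q, interval = c(-2, 1)) {
  g <- length(q)
  if (g == 1L) return(0)
  f <- function(d) {
    selection_gradient(params, g, q = q, p = q + d, i = 1L)
  }
  stats::uniroot(f, interval = interval, tol = 1e-12)$root
}

#' Population-average predicted bias
#'
#' Expected stable bias `E[beta0 + beta1 * qbar]` over group compositions
#' whose qualities are drawn iid from a finite quality distribution. Because
#' the bias line is linear in the group mean, this equals
#' `beta0 + beta1 * E[q]`.
#'
#' @param params A [payoff_params].
#' @param g Group size.
#' @param quality_values Finite set of quality values.
#' @param weights Probability weights (default uniform); must sum to 1.
#' @return The predicted population-mean bias.
#' @examples
#' predicted_mean_bias(payoff_params(), 2,
#'                     quality_values = c(0, 0.25, 0.5, 0.75, 1))  # -0.5
#' @export
predicted_mean_bias <- function(params, g, quality_values,
                                weights = NULL) {
  if (length(quality_values) < 1L) {
    stop("quality set must be non-empty", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(quality_values), length(quality_values))
  }
  if (length(weights) != length(quality_values)) {
    stop("weights must match the quality set", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("weights must sum to 1", call. = FALSE)
  }
  line <- ess_bias_line(params, g)
  line$beta0 + line$beta1 * sum(quality_values * weights)
}
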