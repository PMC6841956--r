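#' Payoff parameters of the public goods stage game
#'
#' The stage game has a shared benefit that is a concave quadratic function of
#' the group-mean investment, and a private cost that is a convex quadratic
#' function of an individual's own investment, reduced for individuals of
#' higher quality through a negative investment-by-quality interaction.
#'
#' The benefit is \eqn{B(\bar a) = B_0 + B_1 \bar a + \tfrac12 B_2 \bar a^2}
#' and the cost is
#' \eqn{K(a, q) = K_1 a + \tfrac12 K_{11} a^2 + K_{12} a q}.
#' Sign constraints \eqn{B_1 > 0}, \eqn{B_2 < 0}, \eqn{K_1 > 0},
#' \eqn{K_{11} > 0}, \eqn{K_{12} < 0} make the benefit concave with an
#' interior maximum at \eqn{a_{max} = -B_1/B_2} and the cost convex,
#' increasing more steeply for lower-quality individuals.
#'
#' @param B0 Benefit intercept (reward units).
#' @param B1 Linear benefit coefficient; must be positive.
#' @param B2 Quadratic benefit coefficient; must be negative.
#' @param K1 Linear cost coefficient; must be positive.
#' @param K11 Quadratic cost coefficient; must be positive.
#' @param K12 Cost-quality interaction coefficient; must be negative.
#'
#' @return An object of class `payoff_params`: a validated list with the six
#'   coefficients and the derived maximum-benefit action `a_max`.
#' @examples
#' pp <- payoff_params(B0 = 1, B1 = 4, B2 = -2, K1 = 1, K11 = 1, K12 = -1)
#' benefit(0.75, pp)
#' cost(0.25, q = 0, pp)
#' @export
payoff_params <- function(B0 = 1, B1 = 4, B2 = -2, K1 = 1, K11 = 1, K12 = -1) {
  vals <- c(B0 = B0, B1 = B1, B2 = B2, K1 = K1, K11 = K11, K12 = K12)
  if (!all(is.finite(vals))) {
    stop("all payoff coefficients must be finite numbers", call. = FALSE)
  }
  bad <- character(0)
  if (B1 <= 0) bad <- c(bad, "B1 > 0")
  if (B2 >= 0) bad <- c(bad, "B2 < 0")
  if (K1 <= 0) bad <- c(bad, "K1 > 0")
  if (K11 <= 0) bad <- c(bad, "K11 > 0")
  if (K12 >= 0) bad <- c(bad, "K12 < 0")
  if (length(bad)) {
    stop("payoff parameter sign constraint(s) violated: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(B0 = B0, B1 = B1, B2 = B2, K1 = K1, K11 = K11, K12 = K12,
         a_max = -B1 / B2),
    class = "payoff_params"
  )
}

#' @export
print.payoff_params <- function(x, ...) {
  cat("Public goods payoff parameters\n")
  cat(sprintf("  benefit: B(abar) = %g + %g*abar + (1/2)*%g*abar^2  (a_max = %g)\n",
              x$B0, x$B1, x$B2, x$a_max))
  cat(sprintf("  cost:    K(a, q) = %g*a + (1/2)*%g*a^2 + %g*a*q\n",
              x$K1, x$K11, x$K12))
  invisible(x)
}

#' Group composition: size, true qualities and perceived qualities
#'
#' An interacting group is described by its size `g`, the members' true
#' qualities `q` (non-genetic states in `[0, 1]` that lower the marginal cost
#' of investing) and their perceived qualities `p`. Perceived qualities are
#' the quality values the reward system behaves as if the individual had;
#' they must satisfy `p <= 1` but may be negative, so the cognitive bias
#' `d = p - q` can take either sign.
#'
#' @param q Numeric vector of true qualities, each in `[0, 1]`.
#' @param p Numeric vector of perceived qualities, each `<= 1`; defaults to
#'   `q` (no bias).
#'
#' @return An object of class `group_composition` with fields `g`, `q`, `p`.
#' @examples
#' group_composition(q = c(0, 1))
#' group_composition(q = c(1, 1), p = c(0.6, 0.6))  # bias d = -0.4
#' @export
group_composition <- function(q, p = q) {
  q <- as.numeric(q)
  p <- as.numeric(p)
  if (length(q) < 1L) stop("group must have at least one member", call. = FALSE)
  if (length(p) != length(q)) {
    stop("q and p must have equal length", call. = FALSE)
  }
  if (!all(is.finite(q)) || !all(is.finite(p))) {
    stop("qualities must be finite", call. = FALSE)
  }
  if (any(q < 0) || any(q > 1)) {
    stop("true qualities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p > 1)) {
    stop("perceived qualities must satisfy p <= 1", call. = FALSE)
  }
  structure(list(g = length(q), q = q, p = p), class = "group_composition")
}

#' @export
print.group_composition <- function(x, ...) {
  cat(sprintf("Group of size g = %d\n", x$g))
  cat("  q:", paste(format(x$q), collapse = ", "), "\n")
  cat("  p:", paste(format(x$p), collapse = ", "), "\n")
  invisible(x)
}

#' Group mean investment
#'
#' @param actions Numeric vector of the g investments in a round.
#' @return The arithmetic mean of the investments.
#' @examples
#' group_mean(c(0.25, 1.25))
#' @export
group_mean <- function(actions) {
  if (length(actions) < 1L) {
    stop("action profile must contain at least one investment", call. = FALSE)
  }
  if (!all(is.finite(actions))) stop("actions must be finite", call. = FALSE)
  sum(actions) / length(actions)
}

#' Shared benefit of the group-mean investment
#'
#' @param a_bar Group-mean investment (scalar or vector).
#' @param params A [payoff_params] object.
#' @return `B0 + B1*a_bar + 0.5*B2*a_bar^2`, vectorised over `a_bar`.
#' @examples
#' pp <- payoff_params()
#' benefit(0.75, pp)  # 3.4375 under the default coefficients
#' @export
benefit <- function(a_bar, params) {
  stopifnot(inherits(params, "payoff_params"))
  params$B0 + params$B1 * a_bar + 0.5 * params$B2 * a_bar^2
}

#' Private cost of an individual's investment
#'
#' Convex and increasing in the investment `a` (for `a >= 0`, `q <= 1` under
#' the default sign constraints) and, for `a > 0`, strictly decreasing in the
#' quality `q` because the interaction coefficient is negative.
#'
#' @param a Investment (scalar or vector).
#' @param q Quality entering the cost; a true quality for fitness payoffs or
#'   a perceived quality for the rewards that drive learning. Recycled
#'   against `a`.
#' @param params A [payoff_params] object.
#' @return `K1*a + 0.5*K11*a^2 + K12*a*q`.
#' @examples
#' pp <- payoff_params()
#' cost(0.25, q = 0, pp)  # 0.28125
#' cost(1.25, q = 1, pp) < cost(1.25, q = 0, pp)
#' @export
cost <- function(a, q, params) {
  stopifnot(inherits(params, "payoff_params"))
  params$K1 * a + 0.5 * params$K11 * a^2 + params$K12 * a * q
}

#' Stage-game payoff
#'
#' Payoff to each player: the shared benefit of the group-mean investment
#' minus the private cost of the player's own investment at its quality.
#' Passing true qualities gives Darwinian (fitness) payoffs; passing
#' perceived qualities gives the perceived rewards that drive learning. The
#' two differ by exactly `K12 * (q - p) * a` for each player.
#'
#' @param actions Numeric vector of the g investments.
#' @param qualities Numeric vector of the g qualities (true or perceived).
#' @param params A [payoff_params] object.
#' @param i Optional 1-based player index; if supplied, only that player's
#'   payoff is returned.
#' @return Numeric vector of g payoffs, or a scalar when `i` is given.
#' @examples
#' pp <- payoff_params()
#' payoff(c(0.25, 1.25), c(0, 1), pp)        # c(3.15625, 2.65625)
#' payoff(c(0.25, 1.25), c(0, 1), pp, i = 1)
#' @export
payoff <- function(actions, qualities, params, i = NULL) {
  if (length(qualities) != length(actions)) {
    stop("actions and qualities must have equal length", call. = FALSE)
  }
  w <- benefit(group_mean(actions), params) - cost(actions, qualities, params)
  if (is.null(i)) return(w)
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > length(actions)) {
    stop("player index out of range", call. = FALSE)
  }
  w[[i]]
}
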