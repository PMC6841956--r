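---
title: "Learning, one-shot equilibria, and the evolution of cognitive bias in public goods games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning, one-shot equilibria, and the evolution of cognitive bias in public goods games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggbias)
```

## The model

A group of $g$ individuals plays a repeated public goods game. In round $t$
each member invests $a_{it}$; everyone receives a benefit of the group mean
investment $\bar a_t$ and pays a private cost of its own investment:

$$B(\bar a) = B_0 + B_1 \bar a + \tfrac12 B_2 \bar a^2, \qquad
  K(a, q) = K_1 a + \tfrac12 K_{11} a^2 + K_{12}\, a\, q,$$

with $B_1 > 0 > B_2$ (concave benefit, maximal at $a_{max} = -B_1/B_2$),
$K_1, K_{11} > 0 > K_{12}$ (convex cost, cheaper at the margin for
higher-quality individuals). The payoff to player $i$ is
$W_i = B(\bar a) - K(a_i, q_i)$, where the quality $q_i \in [0,1]$ is a
non-genetic individual state drawn at the start of a generation and fixed
for life. The package default is the reference parameterisation
$(B_0, B_1, B_2, K_1, K_{11}, K_{12}) = (1, 4, -2, 1, 1, -1)$, under which
all quantities below have simple closed forms.

Individuals know nothing about the game or their own quality; they only
experience rewards. Each runs a one-state actor-critic:

* investments are sampled from a Gaussian policy,
  $a \sim \mathcal N(\theta_{it}, \sigma^2)$;
* the critic keeps an estimated value $w_{it}$ and forms the TD error
  $\delta_{it} = R_{i,t+1} - w_{it}$;
* updates are $w \leftarrow w + \alpha_w \delta$ and
  $\theta \leftarrow \theta + \alpha_\theta \delta \zeta$ with eligibility
  $\zeta = (a - \theta)/\sigma^2$, the gradient of the log policy density.

Each round is an independent episode: no discounting, no eligibility traces
across rounds. The expected policy increment equals
$\alpha_\theta \mathrm{Cov}(\delta, \zeta)$, so the policy climbs the local
reward gradient. Within-round updates are synchronous — every action in a
round is sampled from the pre-round states — which matches simultaneous
investment; the order of the value and policy updates within a round is
irrelevant because both use the same $\delta$, and we fix value-then-policy.

### Learning parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `sigma` | exploration SD of the policy | action | 0.05 |
| `alpha_w` | critic learning rate | — | 0.04 |
| `alpha_theta` | actor learning rate | — | 0.002 |
| `T` | rounds per interaction | rounds | 2000 (1500 in evolutionary runs) |
| `w_init`, `theta_init` | initial learner state | reward, action | 1.0, 0.2 |

`sigma` is held constant: exploration never anneals. The two rates are
coupled: for $w$ and $\theta$ to traverse working ranges $\Delta w$ and
$\Delta\theta$ over comparable numbers of rounds one needs
$\alpha_w \Delta\theta \sim (\alpha_\theta/\sigma) \Delta w$, i.e.
`couple_rates(alpha_w, sigma)` $= \alpha_w \sigma \Delta\theta/\Delta w$;
with both ranges about 1 the defaults satisfy this
(`couple_rates(0.04, 0.05) = 0.002`).

Actions are *not* clamped by default. Gaussian exploration can produce
negative investments, and the same quadratic formulas score them; an
optional `clamp_actions` flag caps sampled actions at $a_{max}$, but under
the default parameters equilibrium investments sit well inside the range
and the clamp never binds in practice.

## The one-shot equilibrium and where learning goes

Learning in this game is myopic: it responds to the immediate reward
gradient and cannot discover that a partner's policy will drift in response
to one's own investment level over tens of rounds. Its attractor is the
one-shot Nash equilibrium of the stage game with the qualities the rewards
are computed from. Strict concavity makes that equilibrium unique and, for
the quadratic game, linear in the quality vector $x$:

$$a^*_i = e_0 + e_1 x_i + e_2 \textstyle\sum_{j \ne i} x_j,$$

with, writing $D = g K_{11} - B_2$,

$$e_0 = \frac{B_1 - g K_1}{D}, \qquad
  e_1 = -\frac{K_{12}\,(g^2 K_{11} - (g-1) B_2)}{g D K_{11}}, \qquad
  e_2 = -\frac{B_2 K_{12}}{g D K_{11}}.$$

These follow from the first-order conditions
$\frac1g B'(\bar a^*) = \partial K/\partial a_i$: summing them over the
group isolates $\bar a^*$, and back-substitution gives each $a^*_i$. Under
the sign constraints $e_1 > 0$ and $e_2 < 0$ (for $g > 1$): higher-quality
members invest more, and each partner's quality depresses one's own
equilibrium investment — partners *compensate*. Because the derivation
involves a linear solve that is easy to get wrong silently, the package
carries an independent route to the same object: damped simultaneous
best-response iteration (`nash_best_response`), with each best response an
exact quadratic maximisation. The two routes agree to $10^{-8}$ on
randomised parameter draws in the test suite, and two distant starting
profiles reach the same fixed point, checking uniqueness empirically.

```{r}
pp <- payoff_params()
nash_investments(nash_coefficients(pp, 2), c(0, 1))
```

## Perceived quality and the stable bias line

An individual may behave as if its quality were $p_i \le 1$ rather than
$q_i$ — it learns from rewards with the cost scored at $p_i$, while
selection scores its payoff at $q_i$. Learning then delivers the Nash
equilibrium for the *perceived* qualities, and the fitness consequence of a
marginal change in $p_i$ is

$$\frac{dW_i}{dp_i} =
  \underbrace{K_{12} (p_i - q_i)\, e_1}_{\text{own-cost mismatch}}
  + \underbrace{\tfrac1g B'(\bar a^*(p)) (g-1) e_2}_{\text{partner response}}.$$

At $p = q$ the first term vanishes and the second is negative whenever
$g > 1$: lowering one's perceived quality pays, because partners compensate
for the resulting shortfall. Solving the gradient for all members at once
(the quadratic structure forces a common bias) gives a stable bias linear
in the group-mean quality, $d^* = \beta_0 + \beta_1 \bar q$, computed by
`ess_bias_line` and verified in the tests by numeric root-finding on the
gradient. For the reference parameters and $g = 2$,
$(\beta_0, \beta_1) = (-0.6, 0.2)$, so a group of two top-quality
individuals should evolve $d^* = -0.4$, and averaging over groups whose
qualities are iid uniform on $\{0, 0.25, 0.5, 0.75, 1\}$ gives a predicted
population-mean bias of $-0.5$ (`predicted_mean_bias`). For $g = 1$ the
line is identically zero — no partners, no bias — and its magnitude shrinks
toward zero as $g$ grows, since a single member's shortfall is diluted
across many compensators.

## The individual-based simulation

`run_evolution` iterates, per generation:

1. **qualities** — each newborn draws $q$ iid from a finite set with given
   weights; its perceived quality is $p = \min(q + d, 1)$ where $d$ is its
   genetic bias;
2. **groups** — a uniformly random partition into groups of $g$;
3. **learning and fitness** — each group runs the actor-critic dynamics for
   $T$ rounds with rewards at perceived qualities; Darwinian fitness is the
   individual's *average true-quality payoff over all $T$ rounds*;
4. **reproduction** — $N$ offspring, each drawing two parents independently
   with probability proportional to fitness; hermaphroditic diploids with
   one additive locus ($d = $ allele$_1$ + allele$_2$), each transmitted
   allele mutating with probability `mu` by a Normal(0, `mut_sd`) increment.

Design choices where the biology is genuinely open: selfing is permitted
(parents are independent draws); the founding population is monomorphic at
$d = 0$; fitness is floored at $10^{-6}$ before proportional selection as a
guard against non-positive payoffs (never triggered under the default
parameters); mutational increments attach to the transmitted allele. The
population-scale learning loop is compiled (Rcpp); it draws in a fixed
(group, member, round) order from R's RNG, so a single-group run of the
compiled kernel is bit-identical to the pure-R `run_learning` on the same
seed — the test suite pins this, which means the fast path and the
definitional path cannot drift apart.

What the generator emulates: a closed population under
mutation-selection-drift balance with the life cycle above. What it does
not: overlapping generations, sexes, linkage, environmental inheritance of
quality, or any strategic sophistication in learning beyond the one-state
actor-critic. Passing tests therefore speak to the internal consistency of
model, theory and simulation — not to how real organisms learn.

## Numerical choices

* Best-response iteration: damping 0.5, tolerance $10^{-10}$, cap $10^5$
  sweeps; the game's strict concavity ($K_{11} - B_2/g^2 > 0$ always)
  keeps the damped map contractive.
* Degenerate inputs are rejected at construction time (sign constraints on
  the payoff coefficients, $gK_{11} - B_2 > 0$, $N$ divisible by $g$,
  probability weights summing to 1), so downstream code never sees them.
* Tables are written with the C `%.17g` format: doubles round-trip exactly
  and equal seeds give byte-identical output files.
* All randomness flows through R's global RNG; replicate runs use integer
  sub-seeds derived once from a master seed (`seed_streams`).

## Problem sizes and a known limitation

The analytic results are exact and instantaneous. The simulation checks in
the test suite run at reduced scale, chosen as the sizes a desk machine
handles comfortably: learning checks use $g = 2$, $T = 3000$; evolutionary
checks use populations of 600–2400 rather than 24 000, $T = 1500$ rounds
per generation, and 250–3000 generations.

One limitation matters when comparing desk-scale evolved biases with the
analytic line, and it is a property of the model, not of the code. Fitness
is the average payoff over *all* $T$ rounds, including the approach from
the naive initial state $(w, \theta) = (1.0, 0.2)$. The policy relaxes
toward the equilibrium on a time scale
$\tau \approx 1/(\alpha_\theta (K_{11} - B_2/g^2)) \approx 333$ rounds, so
at $T = 1500$ a substantial fraction of lifetime payoff accrues during the
climb — a phase in which investing *more* is individually profitable
(early on, $B'(\bar a)/g$ far exceeds the marginal cost). This transient
component of fitness pushes selection on the bias toward zero and shifts
the zero of the effective selection gradient: direct Monte-Carlo
measurement of invasion fitness at $T = 1500$ places the effective stable
bias for $g = 2$, $q \equiv 1$ near $-0.1$ rather than the asymptotic
$-0.4$, with the shortfall shrinking roughly like $1/T$ (an evolution run
at $T = 6000$ reaches about $-0.3$). With the five-point quality
distribution the simulated population-mean bias at $T = 1500$ settles
between about $-0.13$ and $-0.25$ across seeds, reproducing the sign and
mechanism of the predicted $-0.50$ at a third to a half of its magnitude. Quantitative convergence to the
analytic line requires $T \gg \tau$ (of order $10^4$ rounds per
generation), which is beyond desk scale; the acceptance script reports the
desk-scale value as computed. A second, related effect: when all true
qualities equal 1, any positive bias is invisible (perceived quality is
capped at 1), so at weak effective selection the trait can drift into this
neutral region; mixed-quality populations do not have it.

## Session info

```{r}
sessionInfo()
```
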