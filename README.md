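# pggbias

Actor-critic learning and the evolution of cognitive bias in public goods
games.

`pggbias` models groups of individuals that repeatedly invest into a joint
project, learn how much to invest through model-free reinforcement learning,
and — over evolutionary time — evolve a heritable *cognitive bias* in how
they perceive their own cost of investing. It is aimed at behavioural
ecologists and evolutionary game theorists studying how bounded rationality
of learning shapes the evolution of preferences.

## The model

**Stage game.** A group of `g` individuals each invests `a_i` per round.
Everyone receives a shared benefit of the group mean investment and pays a
private cost:

    B(ā) = B0 + B1·ā + ½·B2·ā²            (B1 > 0, B2 < 0)
    K(a, q) = K1·a + ½·K11·a² + K12·a·q   (K1, K11 > 0, K12 < 0)
    W_i = B(ā) − K(a_i, q_i)

Quality `q_i ∈ [0, 1]` is a non-genetic state that lowers the marginal cost
of investing.

**Learning.** Each individual runs a one-state actor-critic: investments are
drawn from Normal(θ, σ²); the temporal-difference error δ = R − w updates
the value estimate (w ← w + α_w·δ) and, weighted by the eligibility
ζ = (a − θ)/σ², the policy mean (θ ← θ + α_θ·δ·ζ). Over rounds the group
converges to the one-shot Nash equilibrium of the stage game — with the
qualities the *rewards* are computed from, which need not be the true ones.

**Nash equilibrium (closed form).** For the quadratic game the unique
equilibrium is linear in the quality vector, `a*_i = e0 + e1·x_i +
e2·Σ_{j≠i} x_j`, with `e1 > 0` and `e2 < 0`: higher-quality members invest
more, and each partner's quality lowers one's own equilibrium investment.

**Evolution of bias.** An individual may carry a heritable bias `d`, so that
it learns from rewards scored at the perceived quality `p = min(q + d, 1)`
while natural selection scores its true-quality payoff. Because learning
stops at the one-shot equilibrium and ignores that partners compensate for
a shortfall, the selection gradient on `p` at `p = q` is negative whenever
`g > 1`: a negative bias (overestimated cost of investing) invades. The
evolutionarily stable bias is linear in the group-mean quality,
`d* = β0 + β1·q̄`, and vanishes for solitary individuals. An
individual-based simulation (diploid, one additive locus,
fitness-proportional mating, mutation) lets the bias evolve and be compared
with this prediction.

## Worked example

```r
library(pggbias)
pp <- payoff_params(B0 = 1, B1 = 4, B2 = -2, K1 = 1, K11 = 1, K12 = -1)

nash_coefficients(pp, g = 2)
#> Nash coefficients (g = 2): a*_i = 0.5 + 0.75*x_i + -0.25*sum_{j!=i} x_j

nash_investments(nash_coefficients(pp, 2), c(0, 1))
#> One-shot Nash equilibrium
#>   a*:    0.25, 1.25
#>   abar*: 0.75

ess_bias_line(pp, g = 2)
#> ESS bias line (g = 2): d* = -0.6 + 0.2 * qbar

predicted_mean_bias(pp, 2, quality_values = c(0, 0.25, 0.5, 0.75, 1))
#> [1] -0.5

set.seed(1)
traj <- run_learning(group_composition(q = c(0, 1)), pp,
                     learning_config(T = 3000))
trajectory_summary(traj)
#>   individual q p theta_mean   theta_sd   w_mean       w_sd   delta_mean
#> 1          1 0 0  0.2618251 0.01079780 3.170928 0.01391548 0.0013721339
#> 2          2 1 1  1.2632663 0.01078888 2.663771 0.01513102 0.0004850495
```

The two learners settle at the equilibrium investments 0.25 and 1.25
derived for their qualities, and the low-quality individual's estimated
value approaches its equilibrium payoff 3.15625 — more than its
higher-quality partner earns (2.65625), because the partner learns to
compensate for its low investment. That asymmetry is exactly what selection
on perceived quality exploits.

A desk-scale evolutionary run:

```r
set.seed(1)
cfg <- evo_config(N = 600, g = 2, quality_values = c(0, 0.25, 0.5, 0.75, 1),
                  mu = 0.05, mut_sd = 0.04, G = 250,
                  learning = learning_config(T = 1500))
ev <- run_evolution(cfg, pp)
mean_bias(ev, window = 50)
#> [1] -0.126017
```

The population-mean bias drifts negative, in the direction of the analytic
line; see the methods vignette for how far desk-scale runs can be expected
to travel toward the prediction and why.

A thin command-line front end is installed with the package
(`inst/scripts/pgg`) with subcommands `nash`, `ess`, `learn` and `evolve`
driven by YAML configuration files (see `inst/extdata/` for examples).

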