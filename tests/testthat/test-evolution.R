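test_that("evolution configuration validates its invariants", {
  expect_error(evo_config(N = 10, g = 3, quality_values = 1), "multiple of g")
  expect_error(evo_config(N = 10, g = 2, quality_values = 1, mu = 1.5),
               "mu")
  expect_error(evo_config(N = 10, g = 2, quality_values = c(0, 2)),
               "\\[0, 1\\]")
  cfg <- evo_config(N = 10, g = 2, quality_values = c(0, 1))
  expect_equal(cfg$quality_weights, c(0.5, 0.5))
})

test_that("quality assignment samples the configured distribution and clamps p", {
  cfg <- evo_config(N = 24000, g = 2, quality_values = c(0, 1),
                    learning = learning_config(T = 10L))
  pop <- list(allele1 = rep(0, 24000), allele2 = rep(0, 24000))
  set.seed(1)
  pop <- assign_qualities(pop, cfg)
  freq1 <- mean(pop$q == 1)
  expect_lt(abs(freq1 - 0.5), 3 * sqrt(0.25 / 24000))
  expect_equal(pop$p, pop$q)  # d = 0

  # point-mass quality set, positive bias clamped at 1
  cfg1 <- evo_config(N = 100, g = 2, quality_values = 1,
                     learning = learning_config(T = 10L))
  pop1 <- list(allele1 = rep(0.25, 100), allele2 = rep(0.25, 100))
  pop1 <- assign_qualities(pop1, cfg1)
  expect_true(all(pop1$q == 1))
  expect_equal(pop1$d, rep(0.5, 100))
  expect_true(all(pop1$p == 1))
})

test_that("group formation is a uniformly random partition", {
  set.seed(2)
  ord <- form_groups(4L, 2L)
  expect_setequal(ord, 1:4)
  expect_error(form_groups(5L, 2L), "multiple of g")
  expect_equal(form_groups(3L, 1L) |> sort(), 1:3)
  # probability that individuals 1 and 2 share a group is (g-1)/(N-1)
  set.seed(3)
  N <- 6L; g <- 2L
  hits <- replicate(4000, {
    o <- form_groups(N, g)
    grp <- (match(1:2, o) - 1L) %/% g
    grp[1] == grp[2]
  })
  p_hat <- mean(hits)
  p_exp <- (g - 1) / (N - 1)
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 4000))
})

test_that("fitness is the mean true-quality payoff and favours low quality", {
  pp <- fig_params()
  cfg <- evo_config(N = 2, g = 2, quality_values = c(0, 1),
                    quality_weights = c(0.5, 0.5),
                    learning = fig_learning(T = 3000L))
  pop <- list(allele1 = c(0, 0), allele2 = c(0, 0))
  set.seed(10)
  pop <- assign_qualities(pop, cfg)
  pop$q <- c(0, 1); pop$p <- c(0, 1); pop$d <- c(0, 0)
  pop <- run_generation(pop, cfg, pp)
  # at the learning outcome the q = 0 member earns more than its partner
  # (equilibrium payoffs 3.15625 > 2.65625)
  expect_gt(pop$fitness[1], pop$fitness[2])
  expect_equal(pop$fitness[1], 3.15625, tolerance = 0.15)
  expect_equal(pop$fitness[2], 2.65625, tolerance = 0.15)
})

test_that("a solitary unbiased learner approaches its private optimum", {
  pp <- fig_params()
  cfg <- evo_config(N = 1, g = 1, quality_values = 1,
                    learning = fig_learning(T = 4000L))
  pop <- list(allele1 = 0, allele2 = 0)
  set.seed(8)
  pop <- assign_qualities(pop, cfg)
  pop <- run_generation(pop, cfg, pp)
  # optimum W(4/3) = 11/3, approached from below with O(sigma^2)
  # exploration loss and the early-learning transient
  expect_lt(pop$fitness[1], 11 / 3)
  expect_equal(pop$fitness[1], 11 / 3, tolerance = 0.05)
})

test_that("reproduction is neutral without mutation or variation", {
  cfg <- evo_config(N = 6, g = 2, quality_values = 1, mu = 0,
                    learning = learning_config(T = 5L))
  pop <- list(allele1 = rep(0.3, 6), allele2 = rep(0.3, 6),
              fitness = rep(2, 6))
  set.seed(4)
  off <- reproduce(pop, cfg)
  expect_equal(off$allele1 + off$allele2, rep(0.6, 6))

  # mu = 1 with zero-variance increments leaves alleles unchanged
  cfg2 <- evo_config(N = 6, g = 2, quality_values = 1, mu = 1, mut_sd = 0,
                     learning = learning_config(T = 5L))
  off2 <- reproduce(pop, cfg2)
  expect_equal(off2$allele1 + off2$allele2, rep(0.6, 6))
})

test_that("parentage shares are fitness-proportional", {
  # two clonal lineages at fitness 2 : 1 -> expected parentage 2/3 vs 1/3
  N <- 3000L
  cfg <- evo_config(N = N, g = 2, quality_values = 1, mu = 0,
                    learning = learning_config(T = 5L))
  pop <- list(allele1 = rep(c(1, 0), each = N / 2),
              allele2 = rep(c(1, 0), each = N / 2),
              fitness = rep(c(2, 1), each = N / 2))
  set.seed(21)
  off <- reproduce(pop, cfg)
  share <- mean(c(off$allele1, off$allele2))  # fraction of alleles from lineage 1
  expect_lt(abs(share - 2 / 3), 3 * sqrt((2 / 9) / (2 * N)))
})

test_that("without variation or mutation the mean bias stays exactly zero", {
  pp <- fig_params()
  cfg <- evo_config(N = 20, g = 2, quality_values = c(0, 1), mu = 0,
                    mut_sd = 0.04, G = 5L,
                    learning = learning_config(T = 30L))
  set.seed(13)
  ev <- run_evolution(cfg, pp)
  expect_equal(ev$summaries$mean_d, rep(0, 5))
  expect_equal(ev$summaries$sd_d, rep(0, 5))
  expect_equal(nrow(ev$final_population), 20L)
})

test_that("neutral allelic variation drifts: centred mean, growing spread", {
  # equal fitness, no mutation: allele frequencies follow pure drift
  cfg <- evo_config(N = 60, g = 2, quality_values = 1, mu = 0,
                    learning = learning_config(T = 5L))
  final_means <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    pop <- list(allele1 = rnorm(60, 0, 0.1), allele2 = rnorm(60, 0, 0.1))
    for (gen in 1:30) {
      pop$fitness <- rep(1, 60)
      pop <- reproduce(pop, cfg)
    }
    mean(pop$allele1 + pop$allele2)
  }, numeric(1))
  expect_lt(abs(mean(final_means)), 0.05)   # centred across replicates
  expect_gt(sd(final_means), 0.02)          # drift spreads replicate means
})

test_that("population size and diploid structure persist across generations", {
  pp <- fig_params()
  cfg <- evo_config(N = 24, g = 3, quality_values = c(0, 0.5, 1), mu = 0.05,
                    mut_sd = 0.04, G = 4L, learning = learning_config(T = 20L))
  set.seed(99)
  ev <- run_evolution(cfg, pp)
  expect_equal(nrow(ev$summaries), 4L)
  expect_equal(nrow(ev$final_population), 24L)
  expect_true(all(ev$final_population$p <= 1))
  expect_true(all(is.finite(ev$final_population$fitness)))
  expect_true(all(ev$summaries$sd_d >= 0))
})

test_that("final-generation bias resolves by group composition", {
  pp <- fig_params()
  cfg <- evo_config(N = 40, g = 2, quality_values = c(0, 1), mu = 0.05,
                    mut_sd = 0.04, G = 3L, learning = learning_config(T = 20L))
  set.seed(55)
  ev <- run_evolution(cfg, pp)
  bc <- bias_by_composition(ev)
  expect_true(all(bc$q_bar %in% c(0, 0.5, 1)))
  expect_equal(sum(bc$n), 40L)
  line <- ess_bias_line(pp, 2)
  expect_equal(bc$predicted, line$beta0 + line$beta1 * bc$q_bar)
  # every group id labels exactly g members
  expect_true(all(table(ev$final_population$group) == 2))
})

test_that("a negative bias emerges under selection for g = 2", {
  # reduced population and horizon: the direction of the evolutionary
  # response, not its equilibrium value, is the property under test; the
  # elevated mutation rate speeds the build-up of selectable variation
  pp <- fig_params()
  finals <- vapply(1:3, function(s) {
    cfg <- evo_config(N = 600, g = 2, quality_values = quality_set5,
                      mu = 0.05, mut_sd = 0.04, G = 250L,
                      learning = fig_learning(T = 1500L))
    set.seed(4000 + s)
    ev <- run_evolution(cfg, pp)
    mean(tail(ev$summaries$mean_d, 50))
  }, numeric(1))
  expect_true(all(finals < 0))
  expect_lt(mean(finals), -0.04)
})
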