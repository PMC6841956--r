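#' Configuration of the evolutionary simulation
#'
#' Discrete, non-overlapping generations of hermaphroditic diploids. A single
#' locus with two real-valued alleles additively determines the cognitive
#' bias trait `d = allele1 + allele2`; an individual with true quality `q`
#' perceives quality `p = min(q + d, 1)` and learns from rewards scored at
#' `p` while its Darwinian fitness is scored at `q`.
#'
#' Each generation: (i) newborns are sorted into random groups of size `g`
#' and assigned true qualities iid from a finite quality distribution;
#' (ii) each group runs the actor-critic learning dynamics for `T` rounds
#' with perceived qualities driving rewards; (iii) each individual's fitness
#' is its average true-quality payoff over the rounds; (iv) the next
#' generation is formed by fitness-proportional mating: each offspring draws
#' two parents independently (selfing possible), inherits one allele from
#' each, and each transmitted allele mutates with probability `mu` by a
#' Normal(0, `mut_sd`) increment.
#'
#' @param N Population size; must be a positive multiple of `g`.
#' @param g Group size.
#' @param quality_values Finite set of true-quality values, each in `[0, 1]`.
#' @param quality_weights Sampling weights (default uniform).
#' @param mu Per-allele mutation probability per generation, in `[0, 1]`.
#' @param mut_sd SD of the normal mutant increments (>= 0).
#' @param G Number of generations.
#' @param learning A [learning_config] governing the within-generation
#'   interaction (its `T` is the number of rounds).
#' @param d_init Initial (monomorphic) bias trait value; split equally
#'   between the two alleles.
#' @param fitness_floor Fitness values are clamped below at this positive
#'   constant before proportional selection, guarding against non-positive
#'   payoffs (with the default parameters payoffs are positive in practice).
#'
#' @return An object of class `evo_config`.
#' @export
evo_config <- function(N, g, quality_values, quality_weights = NULL,
                       mu = 0.001, mut_sd = 0.04, G = 1000L,
                       learning = learning_config(T = 1500L),
                       d_init = 0, fitness_floor = 1e-6) {
  N <- as.integer(N); g <- as.integer(g); G <- as.integer(G)
  if (is.na(N) || N < 1L) stop("N must be a positive integer", call. = FALSE)
  if (is.na(g) || g < 1L) stop("g must be a positive integer", call. = FALSE)
  if (N %% g != 0L) stop("N must be a multiple of g", call. = FALSE)
  if (is.na(G) || G < 1L) stop("G must be a positive integer", call. = FALSE)
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  if (mut_sd < 0) stop("mut_sd must be >= 0", call. = FALSE)
  quality_values <- as.numeric(quality_values)
  if (length(quality_values) < 1L || any(quality_values < 0) ||
      any(quality_values > 1)) {
    stop("quality values must be a non-empty set within [0, 1]", call. = FALSE)
  }
  if (is.null(quality_weights)) {
    quality_weights <- rep(1 / length(quality_values), length(quality_values))
  }
  if (length(quality_weights) != length(quality_values) ||
      any(quality_weights < 0) || abs(sum(quality_weights) - 1) > 1e-12) {
    stop("quality weights must be a probability vector over the quality set",
         call. = FALSE)
  }
  stopifnot(inherits(learning, "learning_config"))
  if (fitness_floor <= 0) stop("fitness_floor must be > 0", call. = FALSE)
  structure(
    list(N = N, g = g, quality_values = quality_values,
         quality_weights = quality_weights, mu = mu, mut_sd = mut_sd, G = G,
         learning = learning, d_init = d_init, fitness_floor = fitness_floor),
    class = "evo_config"
  )
}

#' @export
print.evo_config <- function(x, ...) {
  cat("Evolutionary simulation configuration\n")
  cat(sprintf("  N = %d, g = %d, G = %d generations, T = %d rounds\n",
              x$N, x$g, x$G, x$learning$T))
  cat(sprintf("  mutation: mu = %g per allele, increment SD = %g\n",
              x$mu, x$mut_sd))
  cat("  quality set:", paste(format(x$quality_values), collapse = ", "), "\n")
  invisible(x)
}

new_population <- function(config) {
  half <- config$d_init / 2
  list(allele1 = rep(half, config$N), allele2 = rep(half, config$N))
}

#' Assign random true qualities and derived perceived qualities
#'
#' Draws each individual's true quality iid from the configured finite
#' distribution and sets its perceived quality to `min(q + d, 1)`, where `d`
#' is the genetically determined bias.
#'
#' @param population A population list with allele vectors (as built
#'   internally by [run_evolution()]).
#' @param config An [evo_config].
#' @return The population with fields `q`, `d` and `p` filled in.
#' @export
assign_qualities <- function(population, config) {
  n <- length(population$allele1)
  population$q <- sample(config$quality_values, n, replace = TRUE,
                         prob = config$quality_weights)
  population$d <- population$allele1 + population$allele2
  population$p <- pmin(population$q + population$d, 1)
  population
}

#' Randomly partition the population into groups
#'
#' @param N Population size.
#' @param g Group size; must divide `N`.
#' @return An integer vector: a uniformly random permutation of `1:N` in
#'   which consecutive blocks of `g` entries form the groups.
#' @export
form_groups <- function(N, g) {
  if (N %% g != 0L) stop("N must be a multiple of g", call. = FALSE)
  sample.int(N)
}

#' Run one generation's group interactions
#'
#' Sorts the (already quality-assigned) population into random groups, runs
#' the actor-critic learning dynamics for `T` rounds in every group with
#' perceived qualities driving the rewards, and assigns each individual a
#' Darwinian fitness equal to its mean true-quality payoff over the rounds.
#'
#' @param population A population with `q`, `d`, `p` assigned.
#' @param config An [evo_config].
#' @param params A [payoff_params].
#' @return The population with `fitness` (and the grouping permutation
#'   `group_order`) filled in.
#' @export
run_generation <- function(population, config, params) {
  n <- length(population$allele1)
  ord <- form_groups(n, config$g)
  lc <- config$learning
  res <- learn_kernel(
    w0 = rep(lc$w_init, n), theta0 = rep(lc$theta_init, n),
    p = population$p[ord], q = population$q[ord],
    g = config$g, T = lc$T,
    B0 = params$B0, B1 = params$B1, B2 = params$B2,
    K1 = params$K1, K11 = params$K11, K12 = params$K12,
    sigma = lc$sigma, alpha_w = lc$alpha_w, alpha_theta = lc$alpha_theta,
    clamp = lc$clamp_actions, a_max = params$a_max, record = FALSE
  )
  population$fitness <- numeric(n)
  population$fitness[ord] <- res$fitness
  population$theta_final <- numeric(n)
  population$theta_final[ord] <- res$theta
  population$group_order <- ord
  population
}

#' Form the next generation by fitness-proportional mating
#'
#' Each of the `N` offspring draws two parents independently with
#' probability proportional to fitness (floored below at the configured
#' positive constant); each parent transmits one of its two alleles with
#' equal probability; each transmitted allele mutates with probability `mu`
#' by adding a Normal(0, `mut_sd`) increment.
#'
#' @param population A population with `fitness` computed.
#' @param config An [evo_config].
#' @return A fresh population list (alleles only).
#' @export
reproduce <- function(population, config) {
  n <- length(population$allele1)
  wts <- pmax(population$fitness, config$fitness_floor)
  if (!any(wts > 0)) stop("degenerate selection: no positive fitness",
                          call. = FALSE)
  parents <- sample.int(n, 2L * n, replace = TRUE, prob = wts)
  pick2 <- stats::runif(2L * n) < 0.5
  transmitted <- ifelse(pick2, population$allele2[parents],
                        population$allele1[parents])
  if (config$mu > 0 && config$mut_sd > 0) {
    hit <- stats::runif(2L * n) < config$mu
    nhit <- sum(hit)
    if (nhit > 0) {
      transmitted[hit] <- transmitted[hit] +
        stats::rnorm(nhit, 0, config$mut_sd)
    }
  } else if (config$mu > 0) {
    # mut_sd = 0: increments are degenerate at zero; consume no RNG draws
  }
  list(allele1 = transmitted[seq_len(n)],
       allele2 = transmitted[n + seq_len(n)])
}

#' Run the evolutionary simulation
#'
#' Iterates quality assignment, group formation, within-generation learning
#' and fitness-proportional reproduction for `G` generations, starting from
#' a population monomorphic at the configured initial bias. Randomness comes
#' from R's global RNG; call `set.seed()` beforehand for reproducibility.
#'
#' @param config An [evo_config].
#' @param params A [payoff_params].
#' @param progress_every If positive, a progress line is written to stderr
#'   every that many generations.
#' @return An object of class `pgg_evolution`: list with `summaries` (a data
#'   frame with one row per generation: mean/SD of the bias `d` and the
#'   perceived quality `p`, and mean fitness) and `final_population` (a data
#'   frame with the last generation's individual id, group id, q, d, p and
#'   fitness).
#' @examples
#' set.seed(42)
#' ev <- run_evolution(
#'   evo_config(N = 40, g = 2, quality_values = 1, mu = 0.05, mut_sd = 0.04,
#'              G = 5L, learning = learning_config(T = 50L)),
#'   payoff_params()
#' )
#' ev$summaries
#' @export
run_evolution <- function(config, params, progress_every = 0L) {
  stopifnot(inherits(config, "evo_config"), inherits(params, "payoff_params"))
  pop <- new_population(config)
  sm <- matrix(NA_real_, nrow = config$G, ncol = 6,
               dimnames = list(NULL, c("mean_d", "sd_d", "mean_p", "sd_p",
                                       "mean_fitness", "sd_fitness")))
  for (gen in seq_len(config$G)) {
    pop <- assign_qualities(pop, config)
    pop <- run_generation(pop, config, params)
    sm[gen, ] <- c(mean(pop$d), stats::sd(pop$d), mean(pop$p),
                   stats::sd(pop$p), mean(pop$fitness),
                   stats::sd(pop$fitness))
    if (progress_every > 0L && gen %% progress_every == 0L) {
      message(sprintf("generation %d / %d: mean d = %.4f",
                      gen, config$G, sm[gen, "mean_d"]))
    }
    if (gen < config$G) {
      offspring <- reproduce(pop, config)
      pop$allele1 <- offspring$allele1
      pop$allele2 <- offspring$allele2
    }
  }
  grp <- integer(config$N)
  grp[pop$group_order] <- rep(seq_len(config$N %/% config$g), each = config$g)
  final <- data.frame(
    id = seq_len(config$N), group = grp, q = pop$q, d = pop$d, p = pop$p,
    fitness = pop$fitness
  )
  structure(
    list(summaries = data.frame(generation = seq_len(config$G), sm),
         final_population = final, config = config, params = params),
    class = "pgg_evolution"
  )
}

#' @export
print.pgg_evolution <- function(x, ...) {
  cat(sprintf("Evolutionary simulation: N = %d, g = %d, %d generations\n",
              x$config$N, x$config$g, x$config$G))
  last <- x$summaries[nrow(x$summaries), ]
  cat(sprintf("  final generation: mean d = %.4f (SD %.4f), mean fitness = %.4f\n",
              last$mean_d, last$sd_d, last$mean_fitness))
  invisible(x)
}

#' Composition-resolved bias in the final generation
#'
#' Groups the final generation by group-mean true quality and reports the
#' mean evolved bias per composition next to the analytic stable-bias line,
#' the comparison behind composition-resolved plots of evolved vs predicted
#' bias.
#'
#' @param evolution A `pgg_evolution` from [run_evolution()].
#' @return A data frame with columns `q_bar`, `mean_d`, `n`, `predicted`
#'   (the bias line evaluated at `q_bar`), one row per observed group-mean
#'   quality.
#' @export
bias_by_composition <- function(evolution) {
  fp <- evolution$final_population
  qbar <- stats::ave(fp$q, fp$group)
  line <- ess_bias_line(evolution$params, evolution$config$g)
  out <- do.call(rbind, lapply(split(fp$d, qbar), function(d) {
    data.frame(mean_d = mean(d), n = length(d))
  }))
  out$q_bar <- as.numeric(rownames(out))
  out$predicted <- line$beta0 + line$beta1 * out$q_bar
  rownames(out) <- NULL
  out[order(out$q_bar), c("q_bar", "mean_d", "n", "predicted")]
}

#' Time-averaged mean bias over the final generations
#'
#' @param evolution A `pgg_evolution` from [run_evolution()].
#' @param window Number of final generations to average over.
#' @return Mean of the per-generation population-mean bias over the window.
#' @export
mean_bias <- function(evolution, window = 200L) {
  s <- evolution$summaries
  window <- min(window, nrow(s))
  mean(s$mean_d[s$generation > nrow(s) - window])
}
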