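#' Scenario presets
#'
#' Named parameter sets for the reference scenarios studied with this model.
#' Only values that define a scenario are carried by the preset (payoff
#' coefficients, learning rates, group size, quality distribution, mutation
#' regime); run-length settings (`T`, `G`, `N`) have package defaults that
#' are recorded as such in the provenance block, so scenario-defining values
#' and package defaults are never conflated.
#'
#' Available presets:
#' * `"fig1"` — two learners, qualities (0, 1), the reference payoff and
#'   learning parameters.
#' * `"fig2"` — populations of learning groups, qualities iid on \{0, 1\},
#'   full-scale N = 24000.
#' * `"fig3a"` — evolution of bias with all true qualities 1, g = 2,
#'   mu = 0.05, mutant-increment SD 0.04.
#' * `"fig3b"` — evolution of bias with qualities iid uniform on
#'   \{0, 0.25, 0.5, 0.75, 1\}, g = 2, mu = 0.001, SD 0.04.
#' * `"fig4-g2"`, `"fig4-g3"`, `"fig4-g5"` — as `"fig3b"` at group sizes
#'   2, 3, 5.
#'
#' @param name Preset name.
#' @return A named list of configuration values, as [load_config()] returns.
#' @examples
#' scenario_preset("fig1")$payoff$B1
#' @export
scenario_preset <- function(name) {
  base_payoff <- list(B0 = 1, B1 = 4, B2 = -2, K1 = 1, K11 = 1, K12 = -1)
  base_learning <- list(sigma = 0.05, alpha_w = 0.04, alpha_theta = 0.002,
                        w_init = 1.0, theta_init = 0.2)
  fig3b_evo <- function(g) {
    list(g = g, quality_values = c(0, 0.25, 0.5, 0.75, 1),
         mu = 0.001, mut_sd = 0.04)
  }
  presets <- list(
    fig1 = list(payoff = base_payoff, learning = base_learning,
                group = list(g = 2, q = c(0, 1))),
    fig2 = list(payoff = base_payoff, learning = base_learning,
                evo = list(g = 2, quality_values = c(0, 1), N = 24000)),
    fig3a = list(payoff = base_payoff, learning = base_learning,
                 evo = list(g = 2, quality_values = 1,
                            mu = 0.05, mut_sd = 0.04)),
    fig3b = list(payoff = base_payoff, learning = base_learning,
                 evo = fig3b_evo(2)),
    `fig4-g2` = list(payoff = base_payoff, learning = base_learning,
                     evo = fig3b_evo(2)),
    `fig4-g3` = list(payoff = base_payoff, learning = base_learning,
                     evo = fig3b_evo(3)),
    `fig4-g5` = list(payoff = base_payoff, learning = base_learning,
                     evo = fig3b_evo(5))
  )
  if (!name %in% names(presets)) {
    stop("unknown scenario preset: ", name, "; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

known_config_keys <- list(
  top = c("payoff", "learning", "evo", "group", "scenario", "seed",
          "output_dir"),
  payoff = c("B0", "B1", "B2", "K1", "K11", "K12"),
  learning = c("sigma", "alpha_w", "alpha_theta", "T", "w_init",
               "theta_init", "clamp_actions"),
  evo = c("N", "g", "quality_values", "quality_weights", "mu", "mut_sd",
          "G", "d_init", "fitness_floor"),
  group = c("g", "q", "p")
)

check_keys <- function(x, section) {
  allowed <- known_config_keys[[section]]
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s config: %s",
                 section, paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file with optional sections `payoff`,
#' `learning`, `evo` and `group`, plus top-level `scenario`, `seed` and
#' `output_dir`. If `scenario` names a [scenario_preset()], the preset
#' supplies defaults which explicit file values override. Unknown keys are
#' rejected; the payoff section is validated through [payoff_params()] so
#' sign-constraint violations are reported by name.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration: list of class `run_config` with
#'   elements `payoff` ([payoff_params]), `learning` ([learning_config]),
#'   and, when present, `evo` ([evo_config]) and `group`
#'   ([group_composition]), plus `seed` and `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # YAML 1.1 would read a bare `N:` key as the boolean no; keep one-letter
  # keys literal and accept only spelled-out true/false as logicals
  keep_word <- function(x) {
    if (x %in% c("true", "True", "TRUE")) TRUE
    else if (x %in% c("false", "False", "FALSE")) FALSE
    else x
  }
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = keep_word,
                                               "bool#no" = keep_word))
  if (!is.list(raw)) stop("config file must parse to a mapping", call. = FALSE)
  check_keys(raw, "top")
  merged <- raw
  if (!is.null(raw$scenario)) {
    preset <- scenario_preset(raw$scenario)
    merged <- utils::modifyList(preset, raw)
  }
  resolve_config(merged)
}

#' Build a validated run configuration from a list
#'
#' Programmatic counterpart of [load_config()]: takes a nested list in the
#' same layout (e.g. a [scenario_preset()]) and returns validated objects.
#'
#' @param x Nested configuration list.
#' @return A `run_config`, as from [load_config()].
#' @export
resolve_config <- function(x) {
  for (sec in intersect(names(x), c("payoff", "learning", "evo", "group"))) {
    check_keys(x[[sec]], sec)
  }
  pay <- do.call(payoff_params, x$payoff %||% list())
  lrn <- do.call(learning_config, x$learning %||% list())
  out <- list(payoff = pay, learning = lrn,
              seed = x$seed, output_dir = x$output_dir,
              scenario = x$scenario)
  if (!is.null(x$group)) {
    out$group <- group_composition(q = x$group$q,
                                   p = x$group$p %||% x$group$q)
  }
  if (!is.null(x$evo)) {
    ev <- x$evo
    ev$learning <- lrn
    out$evo <- do.call(evo_config, ev)
  }
  structure(out, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table of results as TSV
#'
#' Tab-separated, header line first, deterministic row order (rows written
#' as given), doubles rendered with the C `%.17g` format so values
#' round-trip exactly and equal seeds yield byte-identical files.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  cols <- lapply(records, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(paste(names(records), collapse = "\t"),
             if (nrow(records)) do.call(paste, c(cols, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Draws `n` distinct integer seeds from R's RNG initialised at the master
#' seed, for running replicate simulations whose streams are reproducible
#' and (statistically) independent. The global RNG state is left at the
#' state following the draw.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds (>= 1).
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
seed_streams <- function(master_seed, n) {
  if (n < 1) stop("need at least one stream", call. = FALSE)
  set.seed(as.integer(master_seed))
  sample.int(2147483645L, n)
}

#' Write a provenance block for a run
#'
#' Records the fully resolved configuration, the seed, and the package
#' version as JSON next to the run outputs, with scenario-defining values
#' and package defaults listed separately.
#'
#' @param config A `run_config` (or plain nested list).
#' @param seed The seed used.
#' @param path Output path for the JSON file.
#' @param defaults Optional named list of values that came from package
#'   defaults rather than the scenario definition.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, seed, path, defaults = NULL) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  block <- list(
    package = "pggbias",
    version = as.character(utils::packageVersion("pggbias")),
    seed = seed,
    config = strip(config)
  )
  if (!is.null(defaults)) block$artifact_defaults <- defaults
  jsonlite::write_json(block, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the learning scenario and write its outputs
#'
#' Convenience wrapper used by the command-line interface: runs
#' [run_learning()] under the given seed and writes `trajectory.tsv` (one
#' row per round and individual), `summary.tsv` (terminal-window means/SDs
#' next to the one-shot Nash predictions for the perceived qualities) and
#' `provenance.json` into `out_dir`.
#'
#' @param config A `run_config` with a `group` section.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the trajectory object.
#' @export
write_learning_run <- function(config, seed, out_dir) {
  if (is.null(config$group)) stop("config has no group section", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  traj <- run_learning(config$group, config$payoff, config$learning)
  smry <- trajectory_summary(traj)
  nash <- nash_investments(
    nash_coefficients(config$payoff, config$group$g), config$group$p
  )
  smry$theta_nash <- nash$a_star
  smry$w_nash <- nash_payoffs(nash, config$payoff)
  write_table(traj$records, file.path(out_dir, "trajectory.tsv"))
  write_table(smry, file.path(out_dir, "summary.tsv"))
  write_provenance(config, seed, file.path(out_dir, "provenance.json"))
  invisible(traj)
}

#' Run the evolutionary scenario and write its outputs
#'
#' Runs [run_evolution()] under the given seed and writes `summaries.tsv`
#' (one row per generation), `final_population.tsv` (individual id, q, d, p,
#' fitness) and `provenance.json` into `out_dir`.
#'
#' @param config A `run_config` with an `evo` section.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the evolution object.
#' @export
write_evolution_run <- function(config, seed, out_dir) {
  if (is.null(config$evo)) stop("config has no evo section", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  ev <- run_evolution(config$evo, config$payoff)
  write_table(ev$summaries, file.path(out_dir, "summaries.tsv"))
  write_table(ev$final_population, file.path(out_dir, "final_population.tsv"))
  write_provenance(config, seed, file.path(out_dir, "provenance.json"),
                   defaults = list(G = config$evo$G, T = config$learning$T,
                                   N = config$evo$N))
  invisible(ev)
}
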