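# Whole-run configuration and the simulation driver.

#' Simulation configuration
#'
#' Bundles every knob of one forward-time run. Defaults correspond to the
#' all-low corner of the high/low design space (see [default_level_map()]).
#'
#' @param gene_count genes per host genome (500 or 5000 in the standard
#'   design; the `NP_BP` parameter).
#' @param gene_length bp per gene.
#' @param te_length bp per TE copy.
#' @param intergenic_length initial non-genic, non-TE bp (default 10% of the
#'   genic bp).
#' @param initial_te_count TE copies seeded per founder host (the experiments
#'   start from one).
#' @param te_progeny new copies per transposition event.
#' @param te_excision_rate per-copy per-generation transposition probability.
#' @param te_death_rate per-copy per-generation death probability.
#' @param insertion_bias genic per-bp weight in `[0, 1]`
#'   (see [sample_insertion_site()]).
#' @param corrected_mutation_rate expected background mutation events per
#'   host per generation.
#' @param bp beneficial probability of a genic insertion.
#' @param mutation_effect magnitude of one deleterious/beneficial hit
#'   (0.1 high, 0.01 low).
#' @param p_lethal,p_deleterious fixed lethal and deleterious probabilities.
#' @param magnitude_mode `"uniform"` (magnitude scaled by U(0,1)) or
#'   `"fixed"`.
#' @param carrying_capacity expected survivors per generation, `C`.
#' @param g_max generation budget; a run reaching it with live hosts and at
#'   least one active TE is classified `PERSIST`.
#' @param seed optional integer seed applied at the start of the run.
#' @param retain_dead_bp keep the DNA of dead TE copies as non-genic
#'   sequence (default `TRUE`).
#' @param step_parents if `TRUE` (default) parents as well as offspring
#'   undergo mutation and TE dynamics each generation.
#' @param keep_trajectory record the per-generation summary table.
#' @return a `sim_config` list.
#' @export
sim_config <- function(gene_count = 500, gene_length = 1000, te_length = 1000,
                       intergenic_length = NULL, initial_te_count = 1,
                       te_progeny = 1, te_excision_rate = 0.005,
                       te_death_rate = 0.005, insertion_bias = 0.1,
                       corrected_mutation_rate = 0.01, bp = 0.20,
                       mutation_effect = 0.01, p_lethal = 0.30,
                       p_deleterious = 0.20, magnitude_mode = "uniform",
                       carrying_capacity = 100, g_max = 1000, seed = NULL,
                       retain_dead_bp = TRUE, step_parents = TRUE,
                       keep_trajectory = TRUE) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  # fail fast on impossible settings
  te_rates(cfg$te_excision_rate, cfg$te_death_rate, cfg$te_progeny)
  make_effect_model(cfg$bp, cfg$mutation_effect, cfg$p_lethal, cfg$p_deleterious)
  if (cfg$carrying_capacity < 0 ||
      cfg$carrying_capacity != floor(cfg$carrying_capacity))
    stop("`carrying_capacity` must be a non-negative integer")
  if (cfg$g_max < 0) stop("`g_max` must be non-negative")
  if (cfg$insertion_bias < 0 || cfg$insertion_bias > 1)
    stop("`insertion_bias` must lie in [0, 1]")
  cfg$magnitude_mode <- match.arg(cfg$magnitude_mode, c("uniform", "fixed"))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat)) cat("  ", nm, ": ", format(flat[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Run one forward-time simulation
#'
#' Founds a population of `carrying_capacity` hosts, each with likelihood 1
#' and `initial_te_count` TE copies, then iterates generations until one of
#' three terminal states: all TE copies inactive or lost (`TE_EXTINCT`), all
#' hosts dead (`HOST_EXTINCT`), or the generation budget reached with both
#' still present (`PERSIST`).
#'
#' @param config a `sim_config`.
#' @return a `te_outcome`: list with `outcome`, `terminal_generation`,
#'   `peak_te_count`, `trajectory` (data frame of generation, n_hosts,
#'   n_active_tes, mean_L, n_disrupted_genes), `seed` and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  hosts <- vector("list", config$carrying_capacity)
  for (i in seq_len(config$carrying_capacity)) {
    g <- new_genome(config$gene_count, config$gene_length, config$te_length,
                    config$initial_te_count, config$intergenic_length)
    hosts[[i]] <- new_host(i, g)
  }
  population <- structure(
    list(hosts = hosts, carrying_capacity = config$carrying_capacity,
         generation = 0, next_host_id = config$carrying_capacity + 1),
    class = "te_population")

  traj <- matrix(NA_real_, nrow = config$g_max + 1, ncol = 5)
  colnames(traj) <- c("generation", "n_hosts", "n_active_tes", "mean_L",
                      "n_disrupted_genes")
  row <- .pop_summary(population$hosts, 0)
  traj[1, ] <- row
  peak <- row[["n_active_tes"]]
  outcome <- NULL

  if (length(population$hosts) == 0) {
    outcome <- "HOST_EXTINCT"
  } else if (row[["n_active_tes"]] == 0) {
    outcome <- "TE_EXTINCT"
  }

  gen <- 0
  while (is.null(outcome) && gen < config$g_max) {
    population <- run_generation(population, config)
    gen <- gen + 1
    row <- .pop_summary(population$hosts, gen)
    traj[gen + 1, ] <- row
    peak <- max(peak, row[["n_active_tes"]])
    if (row[["n_hosts"]] == 0) outcome <- "HOST_EXTINCT"
    else if (row[["n_active_tes"]] == 0) outcome <- "TE_EXTINCT"
  }
  if (is.null(outcome)) outcome <- "PERSIST"

  structure(
    list(outcome = outcome, terminal_generation = gen, peak_te_count = peak,
         trajectory = if (config$keep_trajectory)
           as.data.frame(traj[seq_len(gen + 1), , drop = FALSE]) else NULL,
         seed = config$seed, config = config),
    class = "te_outcome")
}

#' @export
print.te_outcome <- function(x, ...) {
  cat("<te_outcome> ", x$outcome, " at generation ", x$terminal_generation,
      " (peak ", x$peak_te_count, " active TEs)\n", sep = "")
  invisible(x)
}

#' Write a run trajectory as TSV
#'
#' @param outcome a `te_outcome` with a recorded trajectory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(outcome, path) {
  if (is.null(outcome$trajectory)) stop("run was executed without a trajectory")
  utils::write.table(outcome$trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize an outcome record as JSON
#'
#' One JSON object per run: outcome class, terminal generation, peak copy
#' number and seed (the trajectory is omitted).
#'
#' @param outcome a `te_outcome`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
outcome_to_json <- function(outcome, path = NULL) {
  obj <- list(outcome = outcome$outcome,
              terminal_generation = outcome$terminal_generation,
              peak_te_count = outcome$peak_te_count,
              seed = outcome$seed)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds named fields matching the arguments of [sim_config()];
#' unknown fields are an error.
#'
#' @param path YAML or JSON file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}
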