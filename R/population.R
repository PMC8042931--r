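# Host-level generational loop.
#
# Each generation the live population is doubled by replication (every host
# leaves one offspring that inherits its survival likelihood and a copy of
# its genome), every candidate undergoes background mutation and TE
# dynamics, lethally hit candidates are removed, and the pool is thinned by
# carrying-capacity selection: candidate i survives independently with
# probability min(1, L_i / sum(L) * C). With likelihoods near 1 and a pool of
# 2C candidates this is ~1/2 per head and the expected number of survivors
# is exactly C; a host carrying a fresh beneficial hit of full magnitude Me
# survives with (1 + Me)/2.

#' Create a host
#'
#' @param host_id unique integer id.
#' @param genome a `te_genome`.
#' @param likelihood inherited survival likelihood; initialized to 1 at the
#'   start of an experiment.
#' @return a `te_host`.
#' @export
new_host <- function(host_id, genome, likelihood = 1) {
  if (likelihood < 0) stop("`likelihood` must be non-negative")
  structure(list(host_id = host_id, likelihood = likelihood,
                 genome = genome, alive = TRUE),
            class = "te_host")
}

#' Carrying-capacity survival probability
#'
#' Probability that a candidate with likelihood `L_i` survives selection in a
#' pool with total likelihood `sum_L` under carrying capacity `C`:
#' `min(1, L_i / sum_L * C)`. Any one-time mutation-effect adjustment is
#' already folded into `L_i`. Summed over the pool (before clamping) this
#' equals `C`, so the carrying capacity is conserved in expectation.
#'
#' @param L_i candidate likelihood(s); vectorized.
#' @param sum_L total likelihood of the candidate pool (> 0).
#' @param C carrying capacity (>= 1).
#' @return survival probability in `[0, 1]` per candidate.
#' @export
survival_probability <- function(L_i, sum_L, C) {
  if (any(L_i < 0)) stop("likelihoods must be non-negative")
  if (C < 1) stop("`C` must be >= 1")
  if (sum_L <= 0)
    stop("population extinct: total survival likelihood is zero",
         call. = FALSE)
  pmin(1, L_i / sum_L * C)
}

#' Double a population by replication
#'
#' Every live host leaves one offspring inheriting its survival likelihood
#' and a copy of its genome (mutations in the copy never touch the parent).
#' Parents stay in the pool and compete with their offspring at selection.
#'
#' @param hosts list of live `te_host` objects.
#' @param next_host_id first id to assign to offspring.
#' @return list with `hosts` (pool of size `2 * length(hosts)`) and
#'   `next_host_id`.
#' @export
replicate_hosts <- function(hosts, next_host_id = NULL) {
  if (length(hosts) == 0) stop("cannot replicate an empty population")
  if (is.null(next_host_id))
    next_host_id <- max(vapply(hosts, `[[`, numeric(1), "host_id")) + 1
  offspring <- vector("list", length(hosts))
  for (i in seq_along(hosts)) {
    h <- hosts[[i]]
    offspring[[i]] <- new_host(next_host_id, h$genome, h$likelihood)
    next_host_id <- next_host_id + 1
  }
  list(hosts = c(hosts, offspring), next_host_id = next_host_id)
}

#' Carrying-capacity selection
#'
#' Each candidate survives independently with
#' `survival_probability(L_i, sum(L), C)` (Bernoulli thinning; the expected
#' survivor count is `min(C, pool size)` for homogeneous likelihoods).
#'
#' @param hosts candidate pool (list of `te_host`).
#' @param C carrying capacity; `C = 0` leaves no survivors.
#' @return list of surviving hosts.
#' @export
selection_step <- function(hosts, C) {
  if (length(hosts) == 0) stop("candidate pool is empty")
  if (C < 1) return(list())
  L <- vapply(hosts, `[[`, numeric(1), "likelihood")
  p <- survival_probability(L, sum(L), C)
  hosts[stats::runif(length(hosts)) < p]
}

#' Background host mutation
#'
#' Draws a Poisson number of mutation events with mean
#' `corrected_mutation_rate`; each event hits a uniformly random gene and is
#' classified and applied exactly like a genic TE insertion (one-time
#' likelihood change, or death if lethal). Point mutations do not alter the
#' chromosome layout.
#'
#' @param host a live `te_host`.
#' @param corrected_mutation_rate expected events per host per generation.
#' @param effect_model a `te_effect_model`.
#' @param magnitude_mode `"uniform"` or `"fixed"`.
#' @return the updated host (possibly flagged dead).
#' @export
background_mutation_step <- function(host, corrected_mutation_rate,
                                     effect_model,
                                     magnitude_mode = "uniform") {
  if (!host$alive) stop("`host` must be alive")
  if (corrected_mutation_rate < 0) stop("mutation rate must be non-negative")
  n <- stats::rpois(1, corrected_mutation_rate)
  for (i in seq_len(n)) {
    eff <- draw_effect(effect_model)
    res <- apply_insertion_effect(host$likelihood, eff,
                                  effect_model$mutation_effect, magnitude_mode)
    host$likelihood <- res$likelihood
    if (res$lethal) host$alive <- FALSE
  }
  host
}

# one summary row of population state
.pop_summary <- function(hosts, generation) {
  n_tes <- 0; sum_L <- 0; n_disr <- 0
  for (h in hosts) {
    n_tes <- n_tes + sum(h$genome$te_active)
    sum_L <- sum_L + h$likelihood
    n_disr <- n_disr + length(h$genome$disrupted_genes)
  }
  c(generation = generation, n_hosts = length(hosts), n_active_tes = n_tes,
    mean_L = if (length(hosts)) sum_L / length(hosts) else NA_real_,
    n_disrupted_genes = n_disr)
}

#' Advance a population by one generation
#'
#' Order of events: replicate (pool doubles) -> background mutation ->
#' TE death/transposition/effects per candidate -> remove lethally hit
#' candidates -> carrying-capacity selection. The generation counter
#' increments by one.
#'
#' @param population a `te_population` (see [run_simulation()]).
#' @param config a `sim_config`.
#' @return the updated population; if every candidate dies the population is
#'   returned with zero hosts.
#' @export
run_generation <- function(population, config) {
  hosts <- population$hosts
  if (length(hosts) == 0) stop("population has no live hosts")

  rep_out <- replicate_hosts(hosts, population$next_host_id)
  pool <- rep_out$hosts
  population$next_host_id <- rep_out$next_host_id

  rates <- te_rates(config$te_excision_rate, config$te_death_rate,
                    config$te_progeny)
  model <- make_effect_model(config$bp, config$mutation_effect,
                             config$p_lethal, config$p_deleterious)
  step_idx <- if (config$step_parents) seq_along(pool)
              else seq(length(hosts) + 1, length(pool))
  for (i in step_idx) {
    h <- pool[[i]]
    if (config$corrected_mutation_rate > 0) {
      h <- background_mutation_step(h, config$corrected_mutation_rate, model,
                                    config$magnitude_mode)
      if (!h$alive) { pool[[i]] <- h; next }
    }
    h <- transpose_step(h, rates, model, config$insertion_bias,
                        config$magnitude_mode, config$retain_dead_bp)
    pool[[i]] <- h
  }
  pool <- pool[vapply(pool, `[[`, logical(1), "alive")]

  population$hosts <- if (length(pool))
    selection_step(pool, config$carrying_capacity) else list()
  population$generation <- population$generation + 1
  population
}
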