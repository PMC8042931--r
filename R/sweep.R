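# High/low condition codes and the beneficial-rate sweep harness.
#
# Eight model parameters are varied between a High and a Low level and a
# condition is named by an 8-letter code over {H, L}, positions in order:
# TE_progeny, TE_excision_rate, TE_death_rate, Insertion_bias,
# Corrected_mutation_rate, NP_BP (gene count), Mutation_effect,
# Carrying_capacity. The replication experiment takes 11 such conditions
# known to allow persistence, crosses them with 6 beneficial-probability
# levels and 3 replicates (198 runs), and counts how many runs end in
# persistence.

.CONDITION_PARAMS <- c("TE_progeny", "TE_excision_rate", "TE_death_rate",
                       "Insertion_bias", "Corrected_mutation_rate", "NP_BP",
                       "Mutation_effect", "Carrying_capacity")

#' The 11 study condition codes
#'
#' The conditions under which long-term persistence had previously been
#' observed. The final code (`LLLLLLHL`) is reconstructed from the tabulated
#' row list rather than named in prose, and is flagged as such.
#'
#' @return character vector of 11 8-letter H/L codes; the
#'   `"reconstructed"` attribute marks the final code.
#' @export
te_world_conditions <- function() {
  codes <- c("HLLLHLLL", "LLHHLHHH", "LLHLLHHH", "LLLHLHHH", "LLHHLHHL",
             "LLLHLHHL", "LLLHLHLL", "LLHHLLHH", "LLLHLLHH", "LLLHLLHL",
             "LLLLLLHL")
  attr(codes, "reconstructed") <- "LLLLLLHL"
  codes
}

#' Default numeric levels for the H/L parameters
#'
#' The gene-count and mutation-effect pairs are fixed by the study design
#' (500/5000 genes; effect magnitudes 0.01/0.1). The remaining numeric
#' levels are this package's defaults — plausible per-generation rates for
#' an active TE family — and are fully configurable.
#'
#' @return named list; each element is `c(H = , L = )`.
#' @export
default_level_map <- function() {
  list(
    TE_progeny = c(H = 2, L = 1),
    TE_excision_rate = c(H = 0.05, L = 0.005),
    TE_death_rate = c(H = 0.05, L = 0.005),
    Insertion_bias = c(H = 1.0, L = 0.1),
    Corrected_mutation_rate = c(H = 0.1, L = 0.01),
    NP_BP = c(H = 5000, L = 500),
    Mutation_effect = c(H = 0.1, L = 0.01),
    Carrying_capacity = c(H = 1000, L = 100)
  )
}

.check_level_map <- function(level_map) {
  missing <- setdiff(.CONDITION_PARAMS, names(level_map))
  if (length(missing))
    stop("level map is missing: ", paste(missing, collapse = ", "))
  for (p in .CONDITION_PARAMS) {
    lv <- level_map[[p]]
    if (!all(c("H", "L") %in% names(lv)))
      stop("level map entry for ", p, " needs both H and L values")
  }
  invisible(level_map)
}

#' Decode a condition code into numeric parameters
#'
#' @param code 8-letter string over `{H, L}` (see [te_world_conditions()]
#'   for letter order).
#' @param level_map named list mapping each parameter to its `H` and `L`
#'   values.
#' @return named list of 8 numeric parameter values.
#' @export
decode_condition <- function(code, level_map = default_level_map()) {
  if (length(code) != 1 || is.na(code) || nchar(code) != 8)
    stop("condition code must be a single 8-character string")
  letters8 <- strsplit(code, "")[[1]]
  if (!all(letters8 %in% c("H", "L")))
    stop("condition code must use only H and L: ", code)
  .check_level_map(level_map)
  vals <- mapply(function(p, l) unname(level_map[[p]][[l]]),
                 .CONDITION_PARAMS, letters8, SIMPLIFY = FALSE)
  names(vals) <- .CONDITION_PARAMS
  vals
}

# multiplicative-congruential hash so per-run seeds are stable under plan
# edits: adding conditions or levels never shifts other runs' streams
.derive_seed <- function(base_seed, cond_idx, bp_idx, rep_idx) {
  h <- base_seed %% 2147483647
  for (v in c(cond_idx, bp_idx, rep_idx)) {
    h <- (h * 69069 + v * 30269 + 10007) %% 2147483647
  }
  h
}

#' Define a sweep over conditions and beneficial-probability levels
#'
#' @param conditions character vector of H/L condition codes (default: the
#'   11 study conditions).
#' @param bp_levels beneficial probabilities to sweep (default
#'   0.20, 0.15, 0.10, 0.05, 0.01, 0).
#' @param replicates seeded replicates per (condition, bp) cell (default 3).
#' @param base_seed integer; per-run seeds are derived from it.
#' @param level_map numeric H/L levels, see [default_level_map()].
#' @param g_max generation budget per run.
#' @param gene_length,te_length,magnitude_mode,step_parents,retain_dead_bp,
#'   p_lethal,p_deleterious passed through to [sim_config()].
#' @return a `te_sweep_plan`.
#' @export
sweep_plan <- function(conditions = te_world_conditions(),
                       bp_levels = c(0.20, 0.15, 0.10, 0.05, 0.01, 0),
                       replicates = 3, base_seed = 1,
                       level_map = default_level_map(), g_max = 1000,
                       gene_length = 1000, te_length = 1000,
                       magnitude_mode = "uniform", step_parents = TRUE,
                       retain_dead_bp = TRUE, p_lethal = 0.30,
                       p_deleterious = 0.20) {
  .check_level_map(level_map)
  for (cc in conditions) decode_condition(cc, level_map)
  if (replicates < 1 || replicates != floor(replicates))
    stop("`replicates` must be a positive integer")
  if (any(bp_levels < 0 | bp_levels > 1 - p_lethal - p_deleterious))
    stop("bp levels must leave a non-negative neutral probability")
  structure(as.list(environment()), class = "te_sweep_plan")
}

#' @export
print.te_sweep_plan <- function(x, ...) {
  cat("<te_sweep_plan> ", length(x$conditions), " conditions x ",
      length(x$bp_levels), " bp levels x ", x$replicates, " replicates = ",
      length(x$conditions) * length(x$bp_levels) * x$replicates,
      " runs (g_max ", x$g_max, ", base seed ", x$base_seed, ")\n", sep = "")
  invisible(x)
}

#' Resolve a sweep plan into per-run configurations
#'
#' Expands the (condition, bp, replicate) grid, decodes each condition
#' through the plan's level map, and derives one seed per run as a
#' deterministic hash of the base seed and the run's grid indices.
#'
#' @param plan a `te_sweep_plan`.
#' @return data frame with one row per run: `condition`, `bp`, `replicate`,
#'   `seed` and the 8 decoded numeric parameters.
#' @export
plan_runs <- function(plan) {
  stopifnot(inherits(plan, "te_sweep_plan"))
  grid <- expand.grid(replicate = seq_len(plan$replicates),
                      bp = plan$bp_levels,
                      condition = plan$conditions,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("condition", "bp", "replicate")]
  ci <- match(grid$condition, plan$conditions)
  bi <- match(grid$bp, plan$bp_levels)
  grid$seed <- mapply(.derive_seed, plan$base_seed, ci, bi, grid$replicate)
  dec <- lapply(plan$conditions, decode_condition, level_map = plan$level_map)
  for (p in .CONDITION_PARAMS)
    grid[[p]] <- vapply(dec, `[[`, numeric(1), p)[ci]
  rownames(grid) <- NULL
  grid
}

# sim_config for one resolved run row
.run_config <- function(plan, row) {
  sim_config(
    gene_count = row$NP_BP,
    gene_length = plan$gene_length,
    te_length = plan$te_length,
    initial_te_count = 1,
    te_progeny = row$TE_progeny,
    te_excision_rate = row$TE_excision_rate,
    te_death_rate = row$TE_death_rate,
    insertion_bias = row$Insertion_bias,
    corrected_mutation_rate = row$Corrected_mutation_rate,
    bp = row$bp,
    mutation_effect = row$Mutation_effect,
    p_lethal = plan$p_lethal,
    p_deleterious = plan$p_deleterious,
    magnitude_mode = plan$magnitude_mode,
    carrying_capacity = row$Carrying_capacity,
    g_max = plan$g_max,
    seed = row$seed,
    retain_dead_bp = plan$retain_dead_bp,
    step_parents = plan$step_parents,
    keep_trajectory = FALSE
  )
}

#' Execute every run of a sweep plan
#'
#' Runs are independent with pre-assigned seeds, so results are identical
#' for any worker count. A failing run is recorded with outcome `"ERROR"`
#' and the sweep continues.
#'
#' @param plan a `te_sweep_plan`.
#' @param workers parallel workers (forked via [parallel::mclapply()];
#'   1 = serial).
#' @return a `te_sweep_result`: list with `plan`, `runs` (one row per run
#'   with outcome, terminal generation and peak copy number) and the
#'   aggregate `persistence` tables.
#' @export
run_sweep <- function(plan, workers = 1) {
  stopifnot(inherits(plan, "te_sweep_plan"))
  if (workers < 1) stop("`workers` must be >= 1")
  runs <- plan_runs(plan)
  one <- function(i) {
    row <- runs[i, ]
    tryCatch({
      out <- run_simulation(.run_config(plan, row))
      c(outcome = out$outcome,
        terminal_generation = out$terminal_generation,
        peak_te_count = out$peak_te_count)
    }, error = function(e) c(outcome = "ERROR",
                             terminal_generation = NA, peak_te_count = NA))
  }
  res <- if (workers > 1) {
    parallel::mclapply(seq_len(nrow(runs)), one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(runs)), one)
  }
  runs$outcome <- vapply(res, `[[`, character(1), "outcome")
  runs$terminal_generation <- as.numeric(vapply(res, `[[`, character(1),
                                                "terminal_generation"))
  runs$peak_te_count <- as.numeric(vapply(res, `[[`, character(1),
                                          "peak_te_count"))
  structure(list(plan = plan, runs = runs,
                 persistence = persistence_table(runs)),
            class = "te_sweep_result")
}

#' Persistence counts by bp level and by condition
#'
#' @param result a `te_sweep_result`, or the `runs` data frame of one.
#' @return list with `by_bp` and `by_condition` data frames (`n_runs`,
#'   `n_persist`) and the scalar `total_persist`.
#' @export
persistence_table <- function(result) {
  runs <- if (inherits(result, "te_sweep_result")) result$runs else result
  stopifnot(is.data.frame(runs), all(c("condition", "bp", "outcome") %in%
                                       names(runs)))
  agg <- function(key) {
    n_runs <- tapply(runs$outcome, runs[[key]], length)
    n_persist <- tapply(runs$outcome == "PERSIST", runs[[key]], sum)
    out <- data.frame(key = names(n_runs), n_runs = as.vector(n_runs),
                      n_persist = as.vector(n_persist))
    names(out)[1] <- key
    out
  }
  by_bp <- agg("bp")
  by_bp$bp <- as.numeric(by_bp$bp)
  by_bp <- by_bp[order(-by_bp$bp), ]
  rownames(by_bp) <- NULL
  list(by_bp = by_bp, by_condition = agg("condition"),
       total_persist = sum(runs$outcome == "PERSIST"))
}

#' @export
print.te_sweep_result <- function(x, ...) {
  cat("<te_sweep_result> ", nrow(x$runs), " runs, ",
      x$persistence$total_persist, " persisted\n", sep = "")
  print(x$persistence$by_bp, ...)
  invisible(x)
}

#' Read a sweep plan from YAML or JSON
#'
#' Fields mirror the arguments of [sweep_plan()]; a `level_map` block gives
#' the numeric H/L values (`param: {H: , L: }`).
#'
#' @param path YAML or JSON file.
#' @return a `te_sweep_plan`.
#' @export
read_sweep_plan <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sweep_plan))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown plan fields: ", paste(bad, collapse = ", "))
  if (!is.null(vals$level_map))
    vals$level_map <- lapply(vals$level_map, unlist)
  do.call(sweep_plan, vals)
}
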