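# Desk-scale replication plan.
#
# The full 11 x 6 x 3 sweep at carrying capacities of 100-1000 hosts and a
# long persistence horizon is a cluster-scale computation. For routine
# verification the package ships a miniature plan that preserves the model
# and the H/L design but shrinks the carrying capacity and horizon, raises
# the replicate count, and restricts the grid to the two extreme beneficial
# probabilities. Its condition set is chosen to span the three dynamical
# regimes: a persistence-prone study condition (HLLLHLLL: replicative
# progeny with slow turnover), a TE-loss-prone study condition (LLHHLHHH:
# copy death far outpacing transposition) and one high-activity stress code
# (HHLLLLHH: fast replicative transposition with a high mutation effect,
# where at a high beneficial probability TE-laden hosts accumulate enough
# fitness advantage to shelter a copy-number explosion that then overwhelms
# the population with lethal insertions).

#' Numeric levels for desk-scale runs
#'
#' Identical to [default_level_map()] except that the carrying capacity is
#' shrunk to 50 (L) / 100 (H) hosts so a run completes in seconds.
#'
#' @return named list of `c(H = , L = )` levels.
#' @export
miniature_level_map <- function() {
  lm <- default_level_map()
  lm$Carrying_capacity <- c(H = 100, L = 50)
  lm
}

#' Desk-scale sweep plan
#'
#' Three regime-spanning conditions x beneficial probabilities {0.20, 0} x
#' `replicates` seeded replicates, with a 200-generation persistence horizon
#' under [miniature_level_map()]. Under this plan all three outcome classes
#' (TE extinction, host extinction, persistence) appear, including
#' persistence at a beneficial probability of zero.
#'
#' @param base_seed integer seed the per-run seeds derive from.
#' @param replicates replicates per cell (default 10).
#' @param g_max persistence horizon (default 200 generations).
#' @return a `te_sweep_plan`.
#' @export
miniature_sweep_plan <- function(base_seed = 20260921, replicates = 10,
                                 g_max = 200) {
  sweep_plan(
    conditions = c("HLLLHLLL", "LLHHLHHH", "HHLLLLHH"),
    bp_levels = c(0.20, 0),
    replicates = replicates,
    base_seed = base_seed,
    level_map = miniature_level_map(),
    g_max = g_max
  )
}
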