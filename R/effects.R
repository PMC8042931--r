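# Insertion-effect model and the per-generation TE lifecycle.
#
# A TE landing inside a gene draws one of four fitness-effect classes:
# lethal, mildly deleterious, neutral, or beneficial. Lethal and deleterious
# probabilities are fixed (0.30 and 0.20 by default); the beneficial
# probability BP is the swept experimental variable and the neutral class
# absorbs the remainder. Deleterious/beneficial hits scale the host's
# survival likelihood once, by a magnitude governed by the mutation-effect
# parameter; the change is inherited but never re-applied in descendants.

.EFFECT_LEVELS <- c("LETHAL", "DELETERIOUS", "NEUTRAL", "BENEFICIAL")

#' Build an insertion-effect model
#'
#' @param bp probability that a genic insertion is beneficial (the swept
#'   variable; the study uses 0.20, 0.15, 0.10, 0.05, 0.01 and 0).
#' @param mutation_effect magnitude of a single deleterious/beneficial hit on
#'   the host survival likelihood (0.1 = "high", 0.01 = "low").
#' @param p_lethal probability a genic insertion is lethal (fixed at 0.30).
#' @param p_deleterious probability a genic insertion is mildly deleterious
#'   (fixed at 0.20).
#' @return a `te_effect_model` with the neutral probability derived so the
#'   four classes total exactly 1.
#' @export
make_effect_model <- function(bp = 0.20, mutation_effect = 0.1,
                              p_lethal = 0.30, p_deleterious = 0.20) {
  probs <- c(bp = bp, mutation_effect = mutation_effect,
             p_lethal = p_lethal, p_deleterious = p_deleterious)
  if (any(is.na(probs)) || any(probs < 0))
    stop("effect-model parameters must be non-negative")
  if (bp > 1 || p_lethal > 1 || p_deleterious > 1)
    stop("probabilities must lie in [0, 1]")
  p_neutral <- 1 - p_lethal - p_deleterious - bp
  if (p_neutral < 0)
    stop("bp = ", bp, " leaves a negative neutral probability under fixed ",
         "lethal/deleterious rates ", p_lethal, "/", p_deleterious)
  structure(
    list(p_lethal = p_lethal, p_deleterious = p_deleterious,
         p_neutral = p_neutral, p_beneficial = bp,
         mutation_effect = mutation_effect),
    class = "te_effect_model"
  )
}

#' @export
print.te_effect_model <- function(x, ...) {
  cat("<te_effect_model> lethal ", x$p_lethal, ", deleterious ",
      x$p_deleterious, ", neutral ", x$p_neutral, ", beneficial ",
      x$p_beneficial, "; mutation effect ", x$mutation_effect, "\n", sep = "")
  invisible(x)
}

#' Draw insertion-effect classes
#'
#' @param model a `te_effect_model`.
#' @param n number of independent categorical draws.
#' @return character vector over `"LETHAL"`, `"DELETERIOUS"`, `"NEUTRAL"`,
#'   `"BENEFICIAL"`.
#' @export
draw_effect <- function(model, n = 1) {
  stopifnot(inherits(model, "te_effect_model"))
  p <- c(model$p_lethal, model$p_deleterious, model$p_neutral, model$p_beneficial)
  .EFFECT_LEVELS[sample.int(4L, n, replace = TRUE, prob = p)]
}

#' Apply one insertion effect to a host likelihood
#'
#' The effect is applied exactly once, at the generation of the insertion:
#' a beneficial hit multiplies the likelihood by `1 + delta`, a deleterious
#' hit by `1 - delta`, a neutral hit leaves it unchanged, and a lethal hit
#' flags the host as dead. In `"uniform"` magnitude mode `delta =
#' mutation_effect * U(0,1)` (the advantage varies uniformly between zero and
#' the full magnitude); `"fixed"` mode applies the full magnitude and
#' reproduces the closed-form one-generation survival values exactly.
#'
#' @param likelihood current host survival likelihood `L >= 0`.
#' @param effect one of the four effect-class strings.
#' @param mutation_effect magnitude parameter.
#' @param magnitude_mode `"uniform"` or `"fixed"`.
#' @return list with `likelihood` (updated) and `lethal` (logical).
#' @export
apply_insertion_effect <- function(likelihood, effect, mutation_effect,
                                   magnitude_mode = c("uniform", "fixed")) {
  if (is.na(likelihood) || likelihood < 0)
    stop("`likelihood` must be non-negative")
  magnitude_mode <- match.arg(magnitude_mode)
  effect <- match.arg(effect, .EFFECT_LEVELS)
  delta <- if (magnitude_mode == "uniform")
    mutation_effect * stats::runif(1) else mutation_effect
  switch(effect,
    NEUTRAL = list(likelihood = likelihood, lethal = FALSE),
    BENEFICIAL = list(likelihood = likelihood * (1 + delta), lethal = FALSE),
    DELETERIOUS = list(likelihood = likelihood * (1 - delta), lethal = FALSE),
    LETHAL = list(likelihood = likelihood, lethal = TRUE)
  )
}

#' TE lifecycle rates
#'
#' @param excision_rate per-copy per-generation probability of transposing.
#' @param death_rate per-copy per-generation probability of dying.
#' @param progeny number of new copies produced per transposition event.
#'   Transposition is replicative: the transposing copy remains in place and
#'   `progeny` daughters insert elsewhere, which is how copy number can climb
#'   into the thousands from a single founder.
#' @return a `te_rates` object.
#' @export
te_rates <- function(excision_rate, death_rate, progeny) {
  if (excision_rate < 0 || excision_rate > 1 || death_rate < 0 || death_rate > 1)
    stop("rates must lie in [0, 1]")
  if (progeny < 1 || progeny != floor(progeny))
    stop("`progeny` must be a positive integer")
  structure(list(excision_rate = excision_rate, death_rate = death_rate,
                 progeny = progeny), class = "te_rates")
}

#' One generation of TE dynamics within one host
#'
#' Processes every copy that is active at the start of the step, in fixed
#' order: (1) each copy dies with `death_rate` — death is exclusive, a dying
#' copy does not transpose; (2) each surviving copy transposes with
#' `excision_rate`, placing `progeny` new copies at sites drawn under the
#' insertion bias; (3) each new copy landing inside a gene draws an effect
#' class and applies it to the host likelihood. Landings in intergenic DNA or
#' inside other TEs never affect fitness. A lethal hit marks the host dead
#' but the step runs to completion so the event log is deterministic.
#'
#' @param host a `te_host`.
#' @param rates a `te_rates`.
#' @param effect_model a `te_effect_model`.
#' @param insertion_bias genic per-bp weight in `[0, 1]`.
#' @param magnitude_mode `"uniform"` or `"fixed"` effect magnitude.
#' @param retain_dead_bp if `TRUE` (default) a dying copy is inactivated but
#'   its DNA persists as non-genic sequence; if `FALSE` its bp are excised.
#' @param log if `TRUE`, attach a data frame of events as
#'   `attr(host, "te_events")`.
#' @return the updated host.
#' @export
transpose_step <- function(host, rates, effect_model, insertion_bias,
                           magnitude_mode = "uniform", retain_dead_bp = TRUE,
                           log = FALSE) {
  if (!host$alive) stop("`host` must be alive")
  g <- host$genome
  act <- g$te_id[g$te_active]
  if (length(act) == 0) return(host)

  dies <- stats::runif(length(act)) < rates$death_rate
  events <- if (log) list() else NULL
  for (id in act[dies]) {
    g <- if (retain_dead_bp) .deactivate_te(g, id) else remove_te(g, id)
    if (log) events[[length(events) + 1]] <-
      data.frame(te_id = id, event = "death", site = NA_character_,
                 effect = NA_character_, delta_L = 0)
  }

  survivors <- act[!dies]
  if (length(survivors)) {
    transposes <- stats::runif(length(survivors)) < rates$excision_rate
    for (id in survivors[transposes]) {
      for (k in seq_len(rates$progeny)) {
        pos <- sample_insertion_site(g, insertion_bias)
        ins <- .insert_te_at(g, pos)
        g <- ins$genome
        if (ins$site$kind == "GENIC") {
          eff <- draw_effect(effect_model)
          before <- host$likelihood
          res <- apply_insertion_effect(host$likelihood, eff,
                                        effect_model$mutation_effect,
                                        magnitude_mode)
          host$likelihood <- res$likelihood
          if (res$lethal) host$alive <- FALSE
          if (log) events[[length(events) + 1]] <-
            data.frame(te_id = ins$te_id, event = "insertion", site = "GENIC",
                       effect = eff, delta_L = res$likelihood - before)
        } else if (log) {
          events[[length(events) + 1]] <-
            data.frame(te_id = ins$te_id, event = "insertion",
                       site = ins$site$kind, effect = NA_character_,
                       delta_L = 0)
        }
      }
    }
  }
  host$genome <- g
  if (log) attr(host, "te_events") <-
    if (length(events)) do.call(rbind, events) else
      data.frame(te_id = numeric(0), event = character(0),
                 site = character(0), effect = character(0),
                 delta_L = numeric(0))
  host
}
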