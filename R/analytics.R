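# Analytic machinery for the fate of a beneficial lineage.
#
# A host that has just received a beneficial insertion survives one round of
# carrying-capacity selection with probability ~ (1 + Me)/2 (likelihoods near
# 1, candidate pool ~ 2C), against 1/2 for the null host. Because each
# survivor is replicated into two candidates that survive independently, the
# count of carriers is a Galton-Watson branching process with per-individual
# offspring distribution Binomial(2, p) — a "cascade" of binomial draws, one
# generation after another.

#' One-generation survival of a fresh beneficial carrier
#'
#' Closed form `(1 + Me)/2`: the carrier's likelihood `1 + Me` against a
#' pool total of `2C` with carrying capacity `C`. Gives 0.55 at the high
#' mutation effect (0.1) and 0.505 at the low one (0.01); the null host gets
#' 1/2. Note this applies the full effect magnitude; when the realized
#' advantage is scaled by a U(0,1) draw its expectation is `(1 + Me/2)/2`.
#'
#' @param mutation_effect magnitude `Me` in `[0, 1]`.
#' @return survival probability.
#' @export
one_generation_survival <- function(mutation_effect) {
  if (any(mutation_effect < 0 | mutation_effect > 1))
    stop("`mutation_effect` must lie in [0, 1]")
  (1 + mutation_effect) / 2
}

#' Exact lineage-size distribution of the cascaded binomial process
#'
#' Starting from one carrier, each individual alive at generation `t` is
#' replicated into 2 candidates, each surviving independently with
#' probability `p`; the next-generation count given `n` carriers is
#' Binomial(2n, p). The distribution is propagated exactly by iterated
#' convolution. Sizes above `size_cap` are lumped into the top bin so the
#' mass still sums to 1 (relevant only for supercritical `p` and horizons
#' near the cap).
#'
#' @param p per-candidate survival probability in `[0, 1]`.
#' @param generations horizon `T >= 0`; capped at 20 (use
#'   [monte_carlo_lineage()] beyond that).
#' @param size_cap largest lineage size tracked exactly.
#' @return data frame with columns `size` and `prob` (trailing zero-mass
#'   sizes trimmed).
#' @export
lineage_size_distribution <- function(p, generations, size_cap = 1024) {
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (generations < 0 || generations != floor(generations))
    stop("`generations` must be a non-negative integer")
  if (generations > 20)
    stop("exact convolution is capped at 20 generations; ",
         "use monte_carlo_lineage() for longer horizons")
  pmf <- c(0, 1) # mass at sizes 0, 1
  for (t in seq_len(generations)) {
    support <- which(pmf > 0) - 1L
    top <- min(2 * max(support), size_cap)
    new <- numeric(top + 1)
    for (n in support) {
      if (n == 0) { new[1] <- new[1] + pmf[1]; next }
      m <- min(2 * n, size_cap)
      q <- stats::dbinom(0:m, 2 * n, p)
      if (2 * n > size_cap)
        q[m + 1] <- q[m + 1] + stats::pbinom(size_cap, 2 * n, p,
                                             lower.tail = FALSE)
      new[1:(m + 1)] <- new[1:(m + 1)] + pmf[n + 1] * q
    }
    pmf <- new
  }
  last <- max(which(pmf > 0), 1)
  data.frame(size = 0:(last - 1), prob = pmf[seq_len(last)])
}

#' Ultimate extinction probability of a beneficial lineage
#'
#' The extinction probability of the Binomial(2, p) branching process is the
#' smallest non-negative root of the fixed-point equation
#' `q = (1 - p + p q)^2`. The equation is quadratic with roots 1 and
#' `((1 - p)/p)^2`, so the smallest fixed point in `[0, 1]` is
#' `min(1, ((1 - p)/p)^2)`: certain extinction at or below the critical
#' survival probability 1/2 (mean offspring `2p <= 1`), and a positive
#' escape probability above it.
#'
#' @param p per-candidate survival probability in `[0, 1]`; vectorized.
#' @return extinction probability in `[0, 1]`.
#' @export
extinction_probability <- function(p) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  q <- ifelse(p <= 0.5, 1, ((1 - p) / p)^2)
  # p = 0: no candidate ever survives
  q[p == 0] <- 1
  q
}

#' Monte-Carlo lineage survival
#'
#' Simulates `n_reps` independent cascaded-binomial lineages from one
#' founder for `generations` generations and reports the fraction still
#' alive — the stochastic cross-check for [lineage_size_distribution()] and
#' [extinction_probability()].
#'
#' @param p per-candidate survival probability.
#' @param generations horizon.
#' @param n_reps number of simulated lineages.
#' @param seed optional seed.
#' @param size_cap lineages at or above this size are counted as surviving
#'   and no longer simulated (their extinction probability is negligible for
#'   supercritical `p`; for subcritical `p` the cap is effectively never
#'   hit).
#' @return empirical survival fraction.
#' @export
monte_carlo_lineage <- function(p, generations, n_reps, seed = NULL,
                                size_cap = 1e6) {
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- rep(1, n_reps)
  escaped <- rep(FALSE, n_reps)
  for (t in seq_len(generations)) {
    act <- which(n > 0 & !escaped)
    if (length(act) == 0) break
    n[act] <- stats::rbinom(length(act), 2 * n[act], p)
    escaped[n >= size_cap] <- TRUE
  }
  mean(n > 0 | escaped)
}
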