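test_that("survival probability reproduces the closed forms and clamps", {
  # fresh beneficial carrier at full magnitude in a pool of 2C likelihood-1 hosts
  for (C in c(10, 100, 1000)) {
    expect_equal(survival_probability(1 + 0.1, 2 * C, C), 0.55)
    expect_equal(survival_probability(1 + 0.01, 2 * C, C), 0.505)
    expect_equal(survival_probability(1, 2 * C, C), 0.5) # null host
  }
  expect_equal(survival_probability(5, 5, 1), 1) # sole candidate, single slot
  expect_equal(survival_probability(1, 1, 5), 1) # clamp
  # monotone in the beneficiary's effect magnitude
  p <- survival_probability(1 + seq(0, 0.5, by = 0.1), 200, 100)
  expect_true(all(diff(p) >= 0))
  expect_error(survival_probability(1, 0, 10), "extinct")
  expect_error(survival_probability(-1, 10, 10), "non-negative")
})

test_that("replication doubles the pool and isolates offspring genomes", {
  set.seed(81)
  hosts <- lapply(1:10, function(i) new_host(i, tiny_genome(1)))
  out <- replicate_hosts(hosts)
  expect_length(out$hosts, 20)
  expect_equal(vapply(out$hosts, `[[`, numeric(1), "host_id"), c(1:10, 11:20))

  rich <- new_host(1, tiny_genome(1), likelihood = 1.2)
  kid <- replicate_hosts(list(rich))$hosts[[2]]
  expect_equal(kid$likelihood, 1.2)

  # mutating the offspring genome leaves the parent untouched
  pool <- replicate_hosts(list(rich))$hosts
  pool[[2]]$genome <- insert_te(pool[[2]]$genome, 0)
  expect_length(pool[[1]]$genome$disrupted_genes, 0)
  expect_error(replicate_hosts(list()), "empty")
})

test_that("selection conserves the carrying capacity in expectation", {
  C <- 100
  hosts <- lapply(seq_len(2 * C), function(i) new_host(i, tiny_genome(0)))
  set.seed(91)
  survivors <- replicate(200, length(selection_step(hosts, C)))
  sigma_mean <- sqrt(2 * C * 0.5 * 0.5 / 200)
  expect_lt(abs(mean(survivors) - C), 4 * sigma_mean)

  expect_length(selection_step(hosts, 0), 0)
  # a lone candidate under ample capacity always survives (clamped at 1)
  lone <- list(new_host(1, tiny_genome(0)))
  expect_length(selection_step(lone, 5), 1)
})

test_that("background mutation is Poisson-driven and inert at rate zero", {
  m <- make_effect_model(0.20, 0.1)
  host <- new_host(1, tiny_genome(1))
  expect_identical(background_mutation_step(host, 0, m), host)

  # with certain lethality per event, P(dead) = P(N >= 1) = 1 - exp(-rate)
  m_lethal <- make_effect_model(bp = 0, p_lethal = 1, p_deleterious = 0)
  set.seed(101)
  n <- 5000
  dead <- replicate(n, !background_mutation_step(host, 1, m_lethal)$alive)
  p <- 1 - exp(-1)
  expect_lt(abs(mean(dead) - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("null dynamics hold the population near capacity with constant TEs", {
  cfg <- sim_config(gene_count = 5, gene_length = 10, te_length = 5,
                    initial_te_count = 2, te_excision_rate = 0,
                    te_death_rate = 0, corrected_mutation_rate = 0,
                    carrying_capacity = 50, g_max = 30, seed = 111)
  out <- run_simulation(cfg)
  expect_identical(out$outcome, "PERSIST")
  tr <- out$trajectory
  expect_true(all(tr$n_active_tes == 2 * tr$n_hosts))
  expect_true(all(tr$mean_L == 1)) # no insertions, no mutations: L never moves
  expect_true(all(abs(tr$n_hosts[-1] - 50) < 30))
  expect_true(all(diff(tr$generation) == 1))
})

test_that("terminal states classify as TE extinction, host extinction or persistence", {
  # pure-death TE process
  base <- list(gene_count = 5, gene_length = 10, te_length = 5,
               corrected_mutation_rate = 0, carrying_capacity = 20)
  cfg <- do.call(sim_config, c(base, list(te_excision_rate = 0,
                                          te_death_rate = 0.5, g_max = 200,
                                          seed = 121)))
  out <- run_simulation(cfg)
  expect_identical(out$outcome, "TE_EXTINCT")
  expect_lt(out$terminal_generation, 200)
  expect_equal(out$peak_te_count, 20)

  # vacuous budget: both present at generation 0
  cfg0 <- do.call(sim_config, c(base, list(g_max = 0, seed = 122)))
  expect_identical(run_simulation(cfg0)$outcome, "PERSIST")

  # aggressive genic transposition with no beneficial class kills small hosts
  set.seed(123)
  crash <- vapply(1:20, function(s) {
    cfg <- sim_config(gene_count = 50, gene_length = 100, te_length = 100,
                      te_excision_rate = 1, te_progeny = 2,
                      insertion_bias = 1, bp = 0, mutation_effect = 0.01,
                      corrected_mutation_rate = 0, carrying_capacity = 10,
                      g_max = 50, seed = 1000 + s, keep_trajectory = FALSE)
    run_simulation(cfg)$outcome
  }, character(1))
  expect_gt(mean(crash == "HOST_EXTINCT"), 0.5)
})

test_that("runs are deterministic under a fixed seed", {
  cfg <- sim_config(gene_count = 5, gene_length = 10, te_length = 5,
                    te_excision_rate = 0.2, te_death_rate = 0.1,
                    te_progeny = 2, insertion_bias = 0.5, bp = 0.2,
                    corrected_mutation_rate = 0.05, carrying_capacity = 20,
                    g_max = 40, seed = 131)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$outcome, b$outcome)
})

test_that("with only beneficial effects the mean likelihood trends upward", {
  cfg <- sim_config(gene_count = 5, gene_length = 10, te_length = 5,
                    initial_te_count = 2, te_excision_rate = 0.2,
                    te_progeny = 1, te_death_rate = 0.1, insertion_bias = 1,
                    bp = 0.5, p_lethal = 0, p_deleterious = 0,
                    mutation_effect = 0.1, corrected_mutation_rate = 0,
                    carrying_capacity = 30, g_max = 20, seed = 141)
  out <- run_simulation(cfg)
  tr <- out$trajectory
  expect_true(all(tr$mean_L >= 1)) # likelihoods only ever multiply up
  expect_gt(tr$mean_L[nrow(tr)], tr$mean_L[1])
})

test_that("trajectory TSV and outcome JSON are written faithfully", {
  cfg <- sim_config(gene_count = 5, gene_length = 10, te_length = 5,
                    carrying_capacity = 10, g_max = 5, seed = 151)
  out <- run_simulation(cfg)
  tsv <- tempfile(fileext = ".tsv")
  write_trajectory(out, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back, out$trajectory)
  js <- jsonlite::fromJSON(outcome_to_json(out))
  expect_identical(js$outcome, out$outcome)
  expect_equal(js$peak_te_count, out$peak_te_count)
})
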