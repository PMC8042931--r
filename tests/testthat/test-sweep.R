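# small level map so sweep smoke tests run in seconds
tiny_level_map <- function(C_low = 10) {
  list(
    TE_progeny = c(H = 2, L = 1),
    TE_excision_rate = c(H = 0.2, L = 0.02),
    TE_death_rate = c(H = 0.2, L = 0.02),
    Insertion_bias = c(H = 1, L = 0.1),
    Corrected_mutation_rate = c(H = 0.05, L = 0),
    NP_BP = c(H = 10, L = 5),
    Mutation_effect = c(H = 0.1, L = 0.01),
    Carrying_capacity = c(H = 20, L = C_low)
  )
}

test_that("condition codes decode through the level map", {
  lm <- default_level_map()
  vals <- decode_condition("HLLLHLLL", lm)
  expect_equal(vals$TE_progeny, lm$TE_progeny[["H"]])
  expect_equal(vals$Corrected_mutation_rate, lm$Corrected_mutation_rate[["H"]])
  for (p in c("TE_excision_rate", "TE_death_rate", "Insertion_bias", "NP_BP",
              "Mutation_effect", "Carrying_capacity"))
    expect_equal(vals[[p]], lm[[p]][["L"]])

  all_low <- decode_condition("LLLLLLLL", lm)
  expect_equal(unname(unlist(all_low)),
               unname(vapply(lm, `[[`, numeric(1), "L")))

  expect_error(decode_condition("HLLLHLXL", lm), "only H and L")
  expect_error(decode_condition("HLL", lm), "8-character")
  expect_error(decode_condition("HLLLHLLL", lm[-1]), "missing")
})

test_that("the default plan resolves to the full 11 x 6 x 3 design", {
  plan <- sweep_plan()
  runs <- plan_runs(plan)
  expect_equal(nrow(runs), 198)
  expect_equal(as.vector(table(runs$bp)), rep(33L, 6))
  expect_equal(as.vector(table(runs$condition)), rep(18L, 11))
  expect_length(te_world_conditions(), 11)
  expect_identical(attr(te_world_conditions(), "reconstructed"), "LLLLLLHL")
})

test_that("per-run seeds are derived, distinct and stable under plan edits", {
  p5 <- sweep_plan(conditions = "LLLLLLLL", bp_levels = 0.1, replicates = 5,
                   base_seed = 7)
  r5 <- plan_runs(p5)
  expect_equal(nrow(r5), 5)
  expect_length(unique(r5$seed), 5)
  expect_identical(plan_runs(p5), r5) # reproducible resolution
  expect_true(all(r5$seed >= 0 & r5$seed < 2^31))

  # appending a condition must not shift existing runs' seeds
  a <- plan_runs(sweep_plan(conditions = c("HLLLHLLL", "LLHHLHHH"),
                            base_seed = 3))
  b <- plan_runs(sweep_plan(conditions = c("HLLLHLLL", "LLHHLHHH", "LLLLLLHL"),
                            base_seed = 3))
  shared <- b$condition %in% c("HLLLHLLL", "LLHHLHHH")
  expect_identical(b$seed[shared], a$seed)
})

test_that("persistence tables aggregate and partition exactly", {
  runs <- data.frame(
    condition = rep(c("A", "B"), each = 4),
    bp = rep(c(0, 0.2), 4),
    outcome = c("PERSIST", "TE_EXTINCT", "PERSIST", "HOST_EXTINCT",
                "TE_EXTINCT", "TE_EXTINCT", "PERSIST", "PERSIST")
  )
  pt <- persistence_table(runs)
  expect_equal(pt$total_persist, 4)
  expect_equal(pt$by_bp$n_persist[pt$by_bp$bp == 0], 3)
  expect_equal(sum(pt$by_bp$n_persist), pt$total_persist)
  expect_equal(sum(pt$by_condition$n_persist), pt$total_persist)
  expect_equal(sum(pt$by_bp$n_runs), nrow(runs))

  none <- runs; none$outcome <- "TE_EXTINCT"
  expect_equal(persistence_table(none)$total_persist, 0)
})

test_that("run_sweep executes miniature plans deterministically", {
  plan <- sweep_plan(conditions = c("LLHHLLLL", "LLLLLLLL"),
                     bp_levels = c(0.2, 0), replicates = 2, base_seed = 5,
                     level_map = tiny_level_map(), g_max = 15,
                     gene_length = 10, te_length = 5)
  res <- run_sweep(plan)
  expect_s3_class(res, "te_sweep_result")
  expect_equal(nrow(res$runs), 8)
  expect_true(all(res$runs$outcome %in%
                    c("TE_EXTINCT", "HOST_EXTINCT", "PERSIST")))
  expect_equal(res$persistence$total_persist,
               sum(res$runs$outcome == "PERSIST"))

  res2 <- run_sweep(plan)
  expect_identical(res$runs, res2$runs) # pre-assigned seeds
  res4 <- run_sweep(plan, workers = 2)
  expect_identical(res$runs, res4$runs) # worker count cannot matter

  # a degenerate capacity only affects its own runs
  plan0 <- sweep_plan(conditions = c("LLLLLLLH", "LLLLLLLL"),
                      bp_levels = 0.2, replicates = 1, base_seed = 5,
                      level_map = tiny_level_map(C_low = 0), g_max = 5,
                      gene_length = 10, te_length = 5)
  res0 <- run_sweep(plan0)
  expect_identical(res0$runs$outcome[res0$runs$condition == "LLLLLLLL"],
                   "HOST_EXTINCT")
  expect_false(res0$runs$outcome[res0$runs$condition == "LLLLLLLH"] ==
                 "HOST_EXTINCT")
})

test_that("reports mirror the aggregates on disk", {
  plan <- sweep_plan(conditions = c("LLHHLLLL", "LLLLLLLL"),
                     bp_levels = c(0.2, 0), replicates = 2, base_seed = 5,
                     level_map = tiny_level_map(), g_max = 15,
                     gene_length = 10, te_length = 5)
  res <- run_sweep(plan)
  dir <- file.path(tempdir(), "teworld-report")
  paths <- render_report(res, dir)
  expect_true(file.exists(file.path(dir, "runs.tsv")))
  expect_true(file.exists(file.path(dir, "aggregates.tsv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_length(grep("^panel_", basename(paths)), 2) # one per condition

  runs_back <- utils::read.delim(file.path(dir, "runs.tsv"))
  expect_equal(nrow(runs_back), nrow(res$runs))
  agg <- utils::read.delim(file.path(dir, "aggregates.tsv"))
  bp_rows <- agg[agg$group == "bp", ]
  expect_equal(sort(bp_rows$n_persist),
               sort(res$persistence$by_bp$n_persist))
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(js$total_persist, res$persistence$total_persist)
  unlink(dir, recursive = TRUE)
})

test_that("plans and configs round-trip through YAML", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "conditions: [HLLLHLLL, LLHHLHHH]",
    "bp_levels: [0.2, 0.0]",
    "replicates: 2",
    "base_seed: 9",
    "g_max: 50"
  ), yml)
  plan <- read_sweep_plan(yml)
  expect_equal(nrow(plan_runs(plan)), 8)
  expect_equal(plan$base_seed, 9)

  cfg_yml <- tempfile(fileext = ".yaml")
  writeLines(c("gene_count: 500", "bp: 0.05", "carrying_capacity: 40",
               "seed: 3"), cfg_yml)
  cfg <- read_sim_config(cfg_yml)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$bp, 0.05)
  writeLines("nonsense: 1", cfg_yml)
  expect_error(read_sim_config(cfg_yml), "unknown config fields")
})
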