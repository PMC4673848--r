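popn <- yeast_cycle_population()

test_that("initialized populations have the prescribed parameter and age
           statistics", {
  spec <- single_gene_network(noise_cv = 0.10)
  set.seed(51)
  cells <- init_population(5000, spec, popn)
  r1 <- vapply(cells, function(c) c$params$r1, numeric(1))
  se <- popn$sds["r1"] / sqrt(5000)
  expect_lt(abs(mean(r1) - popn$means["r1"]), 3 * se)
  ages <- vapply(cells, function(c) -c$birth_time, numeric(1))
  # ages are exponential(120) folded into one cycle; compare against the
  # folded-exponential mean for each cell's own cycle length
  totals <- vapply(cells, function(c) c$cycle$total, numeric(1))
  folded_mean <- mean(120 - totals * exp(-totals / 120) /
                        (1 - exp(-totals / 120)))
  expect_lt(abs(mean(ages) - folded_mean), 3 * 120 / sqrt(5000))
  # noise factors are centred on one
  nf <- vapply(cells, function(c) c$noise["transcription"], numeric(1))
  expect_lt(abs(mean(nf) - 1), 3 * 0.1 / sqrt(5000))
  # CV = 0 collapses all noise factors to exactly one
  spec0 <- single_gene_network(noise_cv = 0)
  cells0 <- init_population(10, spec0, popn)
  expect_true(all(vapply(cells0, function(c) all(c$noise == 1), logical(1))))
})

test_that("population growth matches branching-process expectations at
           reduced scale", {
  p <- protocol_spec(100, 660, 100, 0)
  finals <- vapply(1:3, function(s) {
    res <- run_protocol(p, NULL, popn, seed = s, chemistry = FALSE)
    res$n_after_phase1
  }, numeric(1))
  # 100 cells, 11 h at ~120-min effective doubling: ~100 * 2^5.5
  expected <- 100 * 2^5.5
  expect_lt(abs(mean(finals) - expected) / expected, 0.15)
})

test_that("zero-duration protocols and sampling behave exactly", {
  p0 <- protocol_spec(50, 0, 50, 0)
  res <- run_protocol(p0, NULL, popn, seed = 2, chemistry = FALSE)
  expect_equal(nrow(res$snapshot), 50)
  expect_equal(res$snapshot$generation, rep(0L, 50))
  expect_equal(nrow(res$divisions), 0)
  # sampling returns exactly the requested number of cells
  p1 <- protocol_spec(80, 300, 37, 0)
  res1 <- run_protocol(p1, NULL, popn, seed = 3, chemistry = FALSE)
  expect_gte(res1$n_after_phase1, 80)
  expect_equal(length(res1$sampled_ids), 37)
  # requesting more cells than exist is an error
  p2 <- protocol_spec(10, 0, 50, 0)
  expect_error(run_protocol(p2, NULL, popn, seed = 4, chemistry = FALSE),
               "exceeds population size")
})

test_that("identical seeds give bit-identical runs, different seeds differ", {
  spec <- gal_network()
  p <- protocol_22h(0.05, n_initial = 15, n_sample = 15, t_phase = 150,
                    snapshot_interval = 10)
  r1 <- run_protocol(p, spec, popn, seed = 11)
  r2 <- run_protocol(p, spec, popn, seed = 11)
  expect_identical(r1$snapshot, r2$snapshot)
  expect_identical(r1$divisions, r2$divisions)
  expect_identical(r1$traces, r2$traces)
  r3 <- run_protocol(p, spec, popn, seed = 12)
  expect_false(identical(r1$snapshot, r3$snapshot))
})

test_that("volume and molecule conservation hold at every division", {
  spec <- gal_network()
  p <- protocol_22h(0.1, n_initial = 25, n_sample = 25, t_phase = 330)
  res <- run_protocol(p, spec, popn, seed = 13)
  div <- res$divisions
  expect_gt(nrow(div), 100)
  expect_equal(div$V_mother + div$V_daughter, div$V_total, tolerance = 1e-12)
  expect_equal(div$mol_mother + div$mol_daughter, div$mol_pre)
  expect_true(all(div$V_mother > 0 & div$V_daughter > 0))
})

test_that("lineage tracing returns a consistent subtree", {
  spec <- single_gene_network()
  p <- protocol_spec(5, 500, 5, 0, snapshot_interval = 20)
  res <- run_protocol(p, spec, popn, seed = 14)
  root <- res$snapshot$cell_id[1]
  roots <- 1:5
  for (r in roots) {
    tl <- trace_lineage(res, r, Vref = spec$Vref)
    # node count = 1 + number of divisions inside the subtree
    expect_equal(length(tl$cell_ids), 1 + nrow(tl$edges))
    # every daughter is born after (or when) its mother's birth
    if (nrow(tl$edges)) {
      born <- tl$edges$time
      expect_true(all(born >= 0))
    }
  }
  # all cells in the run are covered by the founder subtrees
  all_ids <- sort(unique(unlist(lapply(roots, function(r)
    trace_lineage(res, r)$cell_ids))))
  expect_equal(all_ids,
               sort(unique(c(res$divisions$mother_id,
                             res$divisions$daughter_id,
                             res$snapshot$cell_id))))
  expect_error(trace_lineage(res, 99999L), "unknown cell id")
})

test_that("long-run generation composition is geometric", {
  # grow from a small founder population for >= 6 mean generations
  p <- protocol_spec(30, 840, 30, 0)
  res <- run_protocol(p, NULL, popn, seed = 15, chemistry = FALSE)
  cells <- res$cells
  # census the phase-1 population (before sampling): rerun phase 1 only
  set.seed(16)
  cells <- init_population(30, NULL, popn, chemistry = FALSE)
  out <- lineageSSA:::simulate_population(cells, 840, NULL, popn,
                                          chemistry = FALSE,
                                          master_seed = 16)
  snap <- population_snapshot(out$cells)
  expect_gt(nrow(snap), 1500)
  cen <- generation_census(snap)
  f0 <- cen$fraction[cen$generation == 0]
  f1 <- cen$fraction[cen$generation == 1]
  expect_lt(abs(f0 - 0.5), 0.04)
  expect_lt(abs(f1 - 0.25), 0.04)
})
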