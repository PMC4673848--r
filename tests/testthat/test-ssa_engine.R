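test_that("propensities follow the volume-scaled rate list", {
  spec <- single_gene_network(r_act_max = 0.1, f_active = 0.5, rm_obs = 2,
                              b_obs = 0.1, r_p = 0.5, d_m = 0.1, d_p = 0.01)
  # empty cell: only activation and basal transcription can fire
  st <- fixed_volume_cell(spec, pr_on = 0L, pr_off = 1L)
  a <- compute_propensities(st, spec, dV = 0)
  nonzero <- names(a)[a > 0]
  expect_setequal(nonzero, c("g.activation", "g.basal_tx"))
  # at V = Vref the scaling factor is exactly one
  st2 <- fixed_volume_cell(spec, pr_on = 1L, pr_off = 1L, mrna = 5, prot = 50)
  a2 <- compute_propensities(st2, spec, dV = 0)
  d <- derive_rates(spec$genes$g)
  expect_equal(unname(a2["g.full_tx"]), d$rm_true)
  expect_equal(unname(a2["g.mrna_decay"]), 0.1 * 5)
  expect_equal(unname(a2["g.translation"]), 0.5 * 5)
  expect_equal(unname(a2["g.prot_decay"]), 0.01 * 50)
  # doubling V halves every Vref/V-scaled channel, promoter switching fixed
  st3 <- st2; st3$V <- 2 * spec$Vref
  a3 <- compute_propensities(st3, spec, dV = 0)
  scaled <- c("g.basal_tx", "g.full_tx", "g.mrna_decay", "g.translation",
              "g.prot_decay")
  expect_equal(unname(a3[scaled]), unname(a2[scaled]) / 2)
  expect_equal(a3["g.activation"], a2["g.activation"])
  expect_equal(a3["g.inactivation"], a2["g.inactivation"])
})

test_that("promoter replication doubles copies preserving their state", {
  spec <- single_gene_network()
  st <- fixed_volume_cell(spec, pr_on = 1L, pr_off = 0L)
  st$replicated <- FALSE
  r <- replicate_promoters(st)
  expect_identical(r$pr_on, 2L)
  expect_identical(r$pr_off, 0L)
  st2 <- fixed_volume_cell(spec, pr_on = 0L, pr_off = 1L)
  st2$replicated <- FALSE
  r2 <- replicate_promoters(st2)
  expect_identical(r2$pr_on, 0L)
  expect_identical(r2$pr_off, 2L)
  expect_identical(r2$pr_on + r2$pr_off, 2L * (st2$pr_on + st2$pr_off))
  expect_error(replicate_promoters(r2), "already replicated")
})

test_that("binomial partitioning conserves every species exactly", {
  spec <- single_gene_network()
  set.seed(31)
  for (i in 1:300) {
    mrna <- rpois(1, 20); prot <- rpois(1, 500)
    st <- fixed_volume_cell(spec, pr_on = sample(0:2, 1),
                            pr_off = 2L - sample(0:2, 1), mrna = mrna,
                            prot = prot, V = 90)
    st$pr_off <- 2L - st$pr_on   # replicated complement of 2
    part <- partition_at_division(st, V_mother = 60, V_daughter = 30)
    expect_equal(part$mother$mrna + part$daughter$mrna, mrna)
    expect_equal(part$mother$prot + part$daughter$prot, prot)
    expect_equal(part$mother$pr_on + part$daughter$pr_on, st$pr_on)
    expect_equal(part$mother$pr_off + part$daughter$pr_off, st$pr_off)
    expect_equal(part$daughter$pr_on + part$daughter$pr_off, 1L)
  }
  # zero counts split into zeros
  st0 <- fixed_volume_cell(spec, pr_on = 2L, pr_off = 0L, V = 90)
  p0 <- partition_at_division(st0, 45, 45)
  expect_equal(p0$daughter$mrna, 0L)
  expect_error(partition_at_division(st0, 50, 45), "pre-division volume")
})

test_that("partition fractions follow binomial moments", {
  spec <- single_gene_network()
  st <- fixed_volume_cell(spec, pr_on = 2L, pr_off = 0L, mrna = 0,
                          prot = 1e4, V = 100)
  set.seed(32)
  means <- replicate(100, {
    partition_at_division(st, 50, 50)$daughter$prot
  })
  se <- sqrt(1e4 * 0.25)   # sd of one binomial draw
  expect_lt(abs(mean(means) - 5000), 3 * se / sqrt(100))
})

test_that("stationary moments match the telegraph/birth-death closed forms", {
  spec <- single_gene_network(r_act_max = 0.1, f_active = 0.6, rm_obs = 1,
                              b_obs = 0, r_p = 0.2, d_m = 0.1, d_p = 0.02)
  g <- spec$genes$g
  st <- fixed_volume_cell(spec, pr_on = 1L, pr_off = 0L)
  set.seed(42)
  out <- simulate_cell(st, spec, t_end = 6e4, dV = 0, snapshot_interval = 5)
  tr <- out$trace
  m <- trace_mean_se(tr, "mrna0", burn_in = 5e3)
  p <- trace_mean_se(tr, "prot0", burn_in = 5e3)
  on <- trace_mean_se(tr, "pr_on0", burn_in = 5e3)
  # with b = 0 the observed-rate bookkeeping gives mean mRNA = rm_obs / d_m
  expect_lt(abs(m$mean - 10), 3 * m$se)
  expect_lt(abs(p$mean - 100), 3 * p$se)
  expect_lt(abs(on$mean - g$f_active), 3 * on$se)
})

test_that("volume trajectory tracks the deterministic growth curve", {
  popn <- yeast_cycle_population()
  spec <- single_gene_network()
  set.seed(43)
  devs <- replicate(60, {
    params <- draw_cell_params(popn)
    cyc <- realize_cycle(params, params$Vi)
    st <- cell_state(1L, NA_integer_, 0, 0L, 0, params$Vi, params, cyc, 0,
                     pr_on = 1L, pr_off = 0L, mrna = 0, prot = 0,
                     noise = stats::setNames(rep(1, 5),
                                             lineageSSA:::NOISE_CATEGORIES),
                     replicated = FALSE)
    out <- simulate_cell(st, spec, t_end = Inf)
    v_det <- volume_at_age(cyc, params, cyc$t_division)
    (out$state$V - v_det) / v_det
  })
  expect_lt(sqrt(mean(devs^2)), 0.02)   # < 2% RMS at the default quantum
})

test_that("rates respond to volume: the mRNA level tracks its stationary
           value while the cell grows", {
  # constant F, growing volume, no division: because synthesis and decay
  # carry the same Vref/V factor, the stationary copy number stays at
  # rm/d_m at every volume, so the time-averaged concentration must track
  # the volume-dependent prediction (rm/d_m) * Vref / V(t)
  spec <- single_gene_network(r_act_max = 1, f_active = 1, rm_obs = 5,
                              b_obs = 0, r_p = 0, d_m = 0.2, d_p = 0.01)
  params <- cell_cycle_params(40, 0.02, 0.02, 0.02, 1e9, 1, 1, 0, 40)
  cyc <- list(T1 = 1e9, T2 = 1, T3 = 1, Vs = 40, V0 = 40, t_start = 1e9,
              t_s_entry = Inf, t_division = Inf, total = Inf)
  st <- cell_state(1L, NA_integer_, 0, 0L, 0, 40, params, cyc, 0,
                   pr_on = 1L, pr_off = 0L, mrna = 25, prot = 0,
                   noise = stats::setNames(rep(1, 5),
                                           lineageSSA:::NOISE_CATEGORIES),
                   replicated = TRUE)
  set.seed(44)
  out <- simulate_cell(st, spec, t_end = 4e3, snapshot_interval = 2)
  tr <- out$trace
  expect_gt(out$state$V, 2 * 40)   # volume more than doubled
  conc <- tr[, "mrna0"] * spec$Vref / tr[, "V"]
  pred <- (5 / 0.2) * spec$Vref / tr[, "V"]
  expect_lt(abs(mean(conc) - mean(pred)) / mean(pred), 0.05)
})
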