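test_that("observed-to-mechanistic rate transform matches hand solutions", {
  # always-on promoter: nothing to correct
  g <- gene_spec("g", 0.1, f_active = 1, rm_obs = 2, b_obs = 0.1,
                 r_p = 1, d_m = 0.1, d_p = 0.01)
  d <- derive_rates(g)
  expect_equal(d$r_off, 0)
  expect_equal(d$rm_true, 2)
  expect_equal(d$b_true, 0.1)
  # no leak
  g2 <- gene_spec("g", 0.1, 0.5, rm_obs = 2, b_obs = 0, 1, 0.1, 0.01)
  d2 <- derive_rates(g2)
  expect_equal(d2$rm_true, 4)
  expect_equal(d2$b_true, 0)
  # hand-solved case: f = 0.5, rm_obs = 2, b_obs = 0.1
  g3 <- gene_spec("g", 0.1, 0.5, rm_obs = 2, b_obs = 0.1, 1, 0.1, 0.01)
  d3 <- derive_rates(g3)
  expect_equal(d3$rm_true, 3.8)
  expect_equal(d3$b_true, 0.2 / 3.8)
})

test_that("rate transform round-trips to machine precision", {
  set.seed(21)
  for (i in 1:200) {
    f <- runif(1, 0.05, 1)
    rm_obs <- runif(1, 0.01, 10)
    b_obs <- runif(1, 0, 1)
    r_act <- runif(1, 1e-3, 1)
    g <- gene_spec("g", r_act, f, rm_obs, b_obs, 1, 0.1, 0.01)
    d <- derive_rates(g)
    back <- lineageSSA:::observe_rates(d$r_off, d$rm_true, d$b_true, r_act)
    expect_equal(back$f_active, f, tolerance = 1e-12)
    expect_equal(back$rm_obs, rm_obs, tolerance = 1e-12)
    expect_equal(back$b_obs, b_obs, tolerance = 1e-12)
  }
})

test_that("GAL functional form obeys limits, closed form, and monotonicity", {
  ff <- functional_form(S3 = 1, S1 = 1, S80 = 4500, beta = 2)
  # no repressor
  expect_equal(gal_functional_form(1, 1, 0, 0.1, ff), 1)
  # overwhelming repressor
  expect_lt(gal_functional_form(1, 1, 1e12, 0.1, ff), 1e-10)
  # direct evaluation of the closed form: S80 = 4500, inner sum = 899
  ff2 <- functional_form(S3 = 899, S1 = 1, S80 = 4500, beta = 2)
  F <- gal_functional_form(conc_gal3p = 1, conc_gal1p = 0, conc_gal80p = 1,
                           galactose = 1, ff2)
  expect_equal(F, 1 / 26)
  # monotonicity by finite differences on a grid
  ff3 <- functional_form(S3 = 100, S1 = 10, S80 = 4500, beta = 3)
  grid <- expand.grid(g3 = c(0.1, 1, 10), g1 = c(0.1, 1, 10),
                      g80 = c(0.1, 1, 10))
  h <- 1e-6
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      F0 <- gal_functional_form(g3, g1, g80, 0.1, ff3)
      expect_gte(gal_functional_form(g3 + h, g1, g80, 0.1, ff3), F0)
      expect_gte(gal_functional_form(g3, g1 + h, g80, 0.1, ff3), F0)
      expect_lte(gal_functional_form(g3, g1, g80 + h, 0.1, ff3), F0)
      expect_true(F0 >= 0 && F0 <= 1)
    })
  }
})

test_that("F is invariant under joint rescaling of S3, S1, S80 when the
           activator term dominates", {
  ff <- functional_form(S3 = 1e4, S1 = 1e3, S80 = 4500, beta = 2.5)
  ff10 <- functional_form(S3 = 1e5, S1 = 1e4, S80 = 45000, beta = 2.5)
  for (gal in c(0.02, 0.1, 0.5)) {
    F1 <- gal_functional_form(50, 200, 80, gal, ff)
    F2 <- gal_functional_form(50, 200, 80, gal, ff10)
    expect_equal(F1, F2, tolerance = 1e-3)
  }
})

test_that("promoter activation rate scales r_act_max by F", {
  g <- gene_spec("g", r_act_max = 0.2, f_active = 0.5, 1, 0, 1, 0.1, 0.01)
  expect_equal(promoter_activation_rate(g, 0), 0)
  expect_equal(promoter_activation_rate(g, 1), 0.2)
  expect_equal(promoter_activation_rate(g, 1 / 26), 0.2 / 26)
  expect_error(promoter_activation_rate(g, 1.5), "0, 1")
})

test_that("basal steady state matches the closed form without feedback", {
  spec <- single_gene_network(r_act_max = 0.1, f_active = 0.4, rm_obs = 2,
                              b_obs = 0.1, r_p = 0.5, d_m = 0.1, d_p = 0.01)
  ss <- basal_steady_state(spec)
  # constant F = 1: phi = f_active and observed-rate bookkeeping gives
  # mean mRNA = rm_obs / d_m exactly
  expect_equal(ss$phi, 0.4)
  expect_equal(ss$mrna, 2 / 0.1, tolerance = 1e-9)
  expect_equal(ss$protein, 0.5 * 20 / 0.01, tolerance = 1e-9)
})

test_that("basal fixed point is independent of the starting point", {
  spec <- gal_network()
  ss1 <- basal_steady_state(spec, galactose = 0)
  start <- stats::setNames(rep(500, length(spec$genes)), names(spec$genes))
  ss2 <- basal_steady_state(spec, galactose = 0, start = start)
  expect_equal(ss1$protein, ss2$protein, tolerance = 1e-4)
  # zero leak and zero promoter activity: the all-zero state is the fixed
  # point
  genes0 <- lapply(names(spec$genes), function(g)
    gene_spec(g, r_act_max = 0, f_active = 0.5, rm_obs = 1, b_obs = 0,
              r_p = 1, d_m = 0.1, d_p = 0.01))
  spec0 <- network_spec(genes0, ff = spec$ff, Vref = 60,
                        regulators = spec$regulators)
  ss0 <- basal_steady_state(spec0, galactose = 0)
  expect_equal(ss0$protein, rep(0, 4))
  expect_equal(ss0$mrna, rep(0, 4))
})

test_that("tied parameters are enforced in the network spec", {
  spec <- gal_network()
  expect_equal(spec$genes$reporter$r_act_max, spec$genes$GAL1$r_act_max)
  expect_equal(spec$genes$reporter$f_active, spec$genes$GAL1$f_active)
  expect_error(
    network_spec(list(gene_spec("a", 0.1, 0.5, 1, 0, 1, 0.1, 0.01)),
                 tied = list(c("a", "nonexistent", "r_act_max"))),
    "unknown gene")
})
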