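test_that("start volume follows the linear size rule", {
  expect_equal(volume_at_start(r1 = 5, k = 0, b = 30), 30)
  expect_equal(volume_at_start(r1 = 1, k = 10, b = 20), 30)
  expect_equal(volume_at_start(r1 = 0.6, k = 25, b = 12), 27.0)
  expect_error(volume_at_start(r1 = 1, k = -50, b = 10), "inconsistent")
})

test_that("T1 combines the size-threshold time with the floor", {
  # threshold already met: the floor binds (max combiner)
  expect_equal(t1_duration(V0 = 30, Vs = 30, r1 = 1, T1min = 10), 10)
  # pure size control
  expect_equal(t1_duration(V0 = 20, Vs = 30, r1 = 0.5, T1min = 0), 20)
  # the two combiners differ exactly as the two readings of the rule
  expect_equal(t1_duration(20, 30, 1, 30, combiner = "max"), 30)
  expect_equal(t1_duration(20, 30, 1, 30, combiner = "min"), 10)
  expect_error(t1_duration(20, 30, r1 = 0, T1min = 10), "never reached")
})

test_that("growth is piecewise linear and emits boundary events in order", {
  p <- cell_cycle_params(Vi = 25, r1 = 0.5, r2 = 1, r2m = 0.4,
                         T1min = 20, T2 = 10, T3 = 50, k = 0, b = 35)
  cyc <- realize_cycle(p, V0 = 25)
  pos <- list(block = "T1", clock = 0, cycle = cyc)
  # dt = 0 changes nothing
  g0 <- grow(pos, p, 0)
  expect_equal(g0$volume, 25)
  expect_length(g0$events, 0)
  # linear growth within T1
  g1 <- grow(pos, p, 10)
  expect_equal(g1$volume, 30)
  expect_equal(g1$position$block, "T1")
  # crossing into T2 and T3 emits both events with exact crossing times
  g2 <- grow(pos, p, cyc$t_s_entry + 1)
  types <- vapply(g2$events, `[[`, "", "type")
  expect_equal(types, c("START_REACHED", "S_ENTRY"))
  expect_equal(g2$events[[1]]$time, cyc$t_start)
  expect_equal(g2$events[[2]]$time, cyc$t_s_entry)
  # stepping past the end of T3 emits DIVISION carrying leftover time
  near_end <- list(block = "T3", clock = cyc$t_division - 0.5, cycle = cyc)
  g3 <- grow(near_end, p, 2)
  types <- vapply(g3$events, `[[`, "", "type")
  expect_true("DIVISION" %in% types)
  div <- g3$events[[which(types == "DIVISION")]]
  expect_equal(div$remaining, 1.5)
})

test_that("division splits the bud volume and conserves total volume", {
  p <- cell_cycle_params(Vi = 25, r1 = 0.5, r2 = 0.4, r2m = 0.15,
                         T1min = 20, T2 = 10, T3 = 80, k = 0, b = 35)
  v <- divide_volume(60, p)
  expect_equal(unname(v["daughter"]), (0.4 - 0.15) * 80)
  expect_equal(unname(v["mother"]), 40)
  expect_equal(sum(v), 60)
  # degenerate: no bud growth
  p2 <- cell_cycle_params(25, 0.5, 0.4, 0.4, 20, 10, 80, 0, 35)
  expect_error(divide_volume(60, p2), "r2 must exceed r2m")
  # conservation holds for random valid inputs
  set.seed(1)
  for (i in 1:50) {
    Vt <- runif(1, 50, 150)
    v <- divide_volume(Vt, p)
    expect_identical(sum(v), Vt)
  }
})

test_that("volume is continuous and non-decreasing within a cycle", {
  p <- cell_cycle_params(25, 0.4, 0.8, 0.3, 30, 10, 60, 30, 20)
  cyc <- realize_cycle(p, 25)
  ages <- seq(0, cyc$total, length.out = 200)
  v <- volume_at_age(cyc, p, ages)
  expect_true(all(diff(v) >= 0))
  expect_lt(max(abs(diff(v))), 1)   # no jumps on a fine grid
})

test_that("parameter inheritance mixes parent and fresh draws", {
  popn <- yeast_cycle_population()
  parent <- draw_cell_params(popn)
  # c = 1: daughter is a clone
  popn1 <- popn; popn1$c_inherit <- 1
  set.seed(7)
  d <- inherit_params(parent, popn1)
  expect_equal(d$r1, parent$r1)
  expect_equal(d$T3, parent$T3)
  # c = 0: fresh draws centred on the population mean
  popn0 <- popn; popn0$c_inherit <- 0
  set.seed(8)
  draws <- replicate(1e4, inherit_params(parent, popn0)$r1)
  se <- popn$sds["r1"] / sqrt(1e4)
  expect_lt(abs(mean(draws) - popn$means["r1"]), 3 * se)
  # c = 0.25 (default): E[daughter] = mu + 0.25 * (parent - mu)
  mu <- popn$means["T2"]; sigma <- popn$sds["T2"]
  parent25 <- parent; parent25$T2 <- unname(mu + sigma)
  set.seed(9)
  draws25 <- replicate(1e4, inherit_params(parent25, popn)$T2)
  expected <- unname(mu + 0.25 * sigma)
  se25 <- 0.75 * unname(sigma) / sqrt(1e4)
  expect_lt(abs(mean(draws25) - expected), 3 * se25)
})

test_that("fresh draws are truncated at zero and respect r2m < r2", {
  popn <- cell_cycle_population(
    means = c(Vi = 1, r1 = 0.01, r2 = 0.2, r2m = 0.18,
              T1min = 1, T2 = 1, T3 = 1),
    sds = c(Vi = 2, r1 = 0.05, r2 = 0.05, r2m = 0.05,
            T1min = 2, T2 = 2, T3 = 2),
    k = 1, b = 1)
  set.seed(11)
  for (i in 1:200) {
    p <- draw_cell_params(popn)
    expect_true(all(unlist(p[c("Vi", "r1", "T1min", "T2", "T3")]) >= 0))
    expect_lt(p$r2m, p$r2)
  }
})
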