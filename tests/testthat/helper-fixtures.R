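# shared in-code fixtures for the suite

# a single gene with no feedback (constant F = 1 via ff = NULL)
single_gene_network <- function(r_act_max = 0.1, f_active = 0.6,
                                rm_obs = 1, b_obs = 0, r_p = 0.2,
                                d_m = 0.1, d_p = 0.02, Vref = 60,
                                noise_cv = 0) {
  network_spec(list(gene_spec("g", r_act_max, f_active, rm_obs, b_obs,
                              r_p, d_m, d_p)),
               ff = NULL, Vref = Vref, noise_cv = noise_cv)
}

# a non-dividing, non-growing cell at V = Vref (chemostat-like conditions)
fixed_volume_cell <- function(spec, pr_on = 1L, pr_off = 0L,
                              mrna = 0, prot = 0, V = spec$Vref) {
  n <- length(spec$genes)
  params <- cell_cycle_params(V, 0, 0, 0, 1e9, 1, 1, 0, V)
  cyc <- list(T1 = 1e9, T2 = 1, T3 = 1, Vs = V, V0 = V, t_start = 1e9,
              t_s_entry = Inf, t_division = Inf, total = Inf)
  cell_state(1L, NA_integer_, 0, 0L, 0, V, params, cyc, 0,
             pr_on = rep(as.integer(pr_on), n),
             pr_off = rep(as.integer(pr_off), n),
             mrna = rep(as.numeric(mrna), n),
             prot = rep(as.numeric(prot), n),
             noise = stats::setNames(rep(1, 5),
                                     c("switching", "transcription",
                                       "translation", "mrna_decay",
                                       "protein_decay")),
             replicated = TRUE)
}

# time-average of a trace column with burn-in, plus a batch-means SE
trace_mean_se <- function(trace, col, burn_in = 0, n_batches = 20) {
  x <- trace[trace[, "time"] > burn_in, col]
  batches <- split(x, cut(seq_along(x), n_batches))
  bm <- vapply(batches, mean, numeric(1))
  list(mean = mean(x), se = stats::sd(bm) / sqrt(n_batches))
}

# exact continuous-time telegraph series sampled on a snapshot grid
simulate_telegraph_series <- function(n_cells, t_total_h, k_on, k_off,
                                      snap_h, f0 = NULL) {
  fss <- k_on / (k_on + k_off)
  if (is.null(f0)) f0 <- fss
  out <- vector("list", n_cells)
  grid <- seq(0, t_total_h, by = snap_h)
  for (i in seq_len(n_cells)) {
    state <- stats::runif(1) < f0
    t <- 0
    times <- numeric(0); states <- logical(0)
    s <- state
    while (t <= t_total_h) {
      rate <- if (s) k_off else k_on
      dwell <- stats::rexp(1, rate)
      times <- c(times, t); states <- c(states, s)
      t <- t + dwell
      s <- !s
    }
    idx <- findInterval(grid, times)
    out[[i]] <- data.frame(cell_id = i, time = grid * 60,
                           state = states[idx])
  }
  do.call(rbind, out)
}
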