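# deterministic per-cell seed derived from (master seed, cell id), so the
# simulation of a cell does not depend on execution order
cell_seed <- function(master, id) {
  s <- ((as.double(master) %% 2147483647) * 48271 +
          as.double(id) * 1299709 + 12345) %% 2147483629
  as.integer(s) + 1L
}

#' Protocol specification
#'
#' A two-phase induction protocol: `n_initial` cells are simulated for
#' `t_pre` minutes at inducer level `gal_pre`, a uniform sample of
#' `n_sample` cells is drawn without replacement, and the sample is
#' simulated for a further `t_post` minutes at `gal_post`.
#'
#' @param n_initial initial population size.
#' @param t_pre,t_post phase durations, min.
#' @param n_sample cells kept at the subsampling step.
#' @param gal_pre,gal_post galactose level (% w/v) in each phase.
#' @param snapshot_interval per-cell trace interval, min (0 disables).
#' @param id protocol label.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_initial, t_pre, n_sample, t_post,
                          gal_pre = 0, gal_post = gal_pre,
                          snapshot_interval = 0, id = "custom") {
  if (t_pre < 0 || t_post < 0) stop("durations must be >= 0")
  if (n_initial < 1 || n_sample < 1) stop("population sizes must be >= 1")
  structure(list(id = id, n_initial = n_initial, t_pre = t_pre,
                 n_sample = n_sample, t_post = t_post, gal_pre = gal_pre,
                 gal_post = gal_post,
                 snapshot_interval = snapshot_interval),
            class = "protocol_spec")
}

#' The 22-h induction protocol
#'
#' Inducer present from t = 0: 1000 cells for 11 h, a sample of 2000 from
#' the grown population, then a further 11 h.
#'
#' @param galactose inducer level, % w/v.
#' @param n_initial,n_sample,t_phase scaled-down overrides.
#' @param snapshot_interval trace interval, min.
#' @export
protocol_22h <- function(galactose, n_initial = 1000, n_sample = 2000,
                         t_phase = 660, snapshot_interval = 0) {
  protocol_spec(n_initial, t_phase, n_sample, t_phase,
                gal_pre = galactose, gal_post = galactose,
                snapshot_interval = snapshot_interval, id = "22h")
}

#' The 5-h induction protocol
#'
#' 20,000 cells grown 5 h in basal conditions, a sample of 20,000 taken,
#' the inducer introduced, and the sample simulated a further 5 h.
#'
#' @inheritParams protocol_22h
#' @export
protocol_5h <- function(galactose, n_initial = 20000, n_sample = 20000,
                        t_phase = 300, snapshot_interval = 0) {
  protocol_spec(n_initial, t_phase, n_sample, t_phase,
                gal_pre = 0, gal_post = galactose,
                snapshot_interval = snapshot_interval, id = "5h")
}

# basal molecular initialization for one cell: nominal mean-field steady
# state scaled by the cell's process-noise ratios (feedback via F is
# negligible at basal activity), counts rounded, promoter states Bernoulli
init_molecular_state <- function(ss, spec, noise) {
  n <- length(spec$genes)
  m_scale <- noise["transcription"] / noise["mrna_decay"]
  p_scale <- m_scale * noise["translation"] / noise["protein_decay"]
  mrna <- round(ss$mrna * m_scale)
  prot <- round(ss$protein * p_scale)
  nprom <- vapply(spec$genes, function(g) g$n_promoter, integer(1))
  pr_on <- vapply(seq_len(n), function(i)
    sum(stats::rbinom(nprom[i], 1L, ss$phi[i])), integer(1))
  list(pr_on = as.integer(pr_on), pr_off = as.integer(nprom - pr_on),
       mrna = as.numeric(mrna), prot = as.numeric(prot))
}

#' Initialize a population of cells
#'
#' Each cell draws its own cycle parameters from the population
#' distributions and five per-process extrinsic-noise factors
#' (Normal(1, CV), shared across genes). Its age at t = 0 is sampled from
#' an exponential distribution with mean equal to the strain's average
#' doubling time and mapped onto its own cycle (age modulo realized cycle
#' length); volume follows the deterministic growth curve from a fresh
#' birth-volume draw. The molecular state is set from the basal mean-field
#' steady state.
#'
#' @param n number of cells.
#' @param spec a `network_spec` (may be `NULL` when `chemistry = FALSE`).
#' @param popn a `cycle_population`.
#' @param doubling_time mean of the age distribution, min (default 120).
#' @param galactose inducer level for the basal steady state (default 0).
#' @param chemistry initialize molecular state? (`FALSE` for growth-only
#'   demography runs).
#' @param first_id id assigned to the first cell.
#' @return list of `cell_state` objects.
#' @export
init_population <- function(n, spec, popn, doubling_time = 120,
                            galactose = 0, chemistry = TRUE, first_id = 1L) {
  ss <- if (chemistry) basal_steady_state(spec, galactose) else NULL
  cv <- if (chemistry) spec$noise_cv else 0
  lapply(seq_len(n), function(i) {
    params <- draw_cell_params(popn)
    cyc <- realize_cycle(params, params$Vi, popn$t1_combiner)
    age <- stats::rexp(1, 1 / doubling_time) %% cyc$total
    noise <- draw_noise_factors(cv)
    mol <- if (chemistry) init_molecular_state(ss, spec, noise)
           else list(pr_on = integer(0), pr_off = integer(0),
                     mrna = numeric(0), prot = numeric(0))
    replicated <- age >= cyc$t_s_entry
    if (replicated && chemistry) {
      mol$pr_on <- 2L * mol$pr_on
      mol$pr_off <- 2L * mol$pr_off
    }
    cell_state(id = first_id + i - 1L, parent = NA_integer_, birth_time = -age,
               generation = 0L, t = 0, V = volume_at_age(cyc, params, age),
               params = params, cycle = cyc, cycle_start = -age,
               pr_on = mol$pr_on, pr_off = mol$pr_off,
               mrna = mol$mrna, prot = mol$prot,
               noise = noise, replicated = replicated)
  })
}

# advance one cell deterministically (growth only) to min(t_end, division)
advance_growth_only <- function(cell, t_end) {
  t_div <- cell$cycle_start + cell$cycle$t_division
  t_stop <- min(t_end, t_div)
  cell$V <- volume_at_age(cell$cycle, cell$params, t_stop - cell$cycle_start)
  cell$t <- t_stop
  list(state = cell, reason = if (t_div <= t_end) "division" else "t_end",
       trace = NULL)
}

# simulate a set of cells from their current time to t_end, handling
# divisions; returns final cells + division log + traces
simulate_population <- function(cells, t_end, spec, popn, galactose = 0,
                                chemistry = TRUE, dV = 0.04,
                                snapshot_interval = 0, master_seed = 1L,
                                next_id = NULL,
                                noise_inheritance = c("fresh", "inherit"),
                                scale_decay = TRUE) {
  noise_inheritance <- match.arg(noise_inheritance)
  if (is.null(next_id))
    next_id <- max(vapply(cells, function(c) c$id, integer(1))) + 1L
  stack <- cells
  sp <- length(stack)
  final <- vector("list", length(cells) * 4L)
  nf <- 0L
  div <- list(); nd <- 0L
  traces <- list(); nt <- 0L

  push <- function(cell) { sp <<- sp + 1L; stack[[sp]] <<- cell }

  while (sp > 0L) {
    cell <- stack[[sp]]; sp <- sp - 1L
    set.seed(cell_seed(master_seed, cell$id))
    repeat {
      step <- if (chemistry)
        simulate_cell(cell, spec, t_end, galactose, dV, snapshot_interval,
                      scale_decay = scale_decay)
      else advance_growth_only(cell, t_end)
      cell <- step$state
      if (chemistry && snapshot_interval > 0 && nrow(step$trace) > 0) {
        nt <- nt + 1L
        traces[[nt]] <- cbind(cell_id = cell$id, step$trace)
      }
      if (step$reason != "division") {
        nf <- nf + 1L
        if (nf > length(final)) final <- c(final, vector("list", length(final)))
        final[[nf]] <- cell
        break
      }
      # ---- division ----
      vols <- divide_volume(cell$V, cell$params, cell$cycle$T3)
      if (chemistry) {
        part <- partition_at_division(cell, vols["mother"], vols["daughter"])
      } else {
        part <- list(mother = list(pr_on = integer(0), pr_off = integer(0),
                                   mrna = numeric(0), prot = numeric(0)),
                     daughter = list(pr_on = integer(0), pr_off = integer(0),
                                     mrna = numeric(0), prot = numeric(0)))
      }
      d_id <- next_id; next_id <- next_id + 1L
      nd <- nd + 1L
      div[[nd]] <- c(time = cell$t, mother_id = cell$id, daughter_id = d_id,
                     V_total = cell$V, V_mother = unname(vols["mother"]),
                     V_daughter = unname(vols["daughter"]),
                     mol_pre = sum(round(cell$mrna)) + sum(round(cell$prot)),
                     mol_mother = sum(part$mother$mrna) + sum(part$mother$prot),
                     mol_daughter = sum(part$daughter$mrna) +
                       sum(part$daughter$prot))
      d_params <- inherit_params(cell$params, popn)
      d_cycle <- realize_cycle(d_params, vols["daughter"], popn$t1_combiner)
      d_noise <- if (!chemistry) cell$noise
                 else if (noise_inheritance == "fresh")
                   draw_noise_factors(spec$noise_cv)
                 else cell$noise
      daughter <- cell_state(
        id = d_id, parent = cell$id, birth_time = cell$t, generation = 0L,
        t = cell$t, V = unname(vols["daughter"]), params = d_params,
        cycle = d_cycle, cycle_start = cell$t,
        pr_on = part$daughter$pr_on, pr_off = part$daughter$pr_off,
        mrna = as.numeric(part$daughter$mrna),
        prot = as.numeric(part$daughter$prot),
        noise = d_noise, replicated = FALSE)
      push(daughter)
      # mother re-enters T1 immediately with her own parameters
      cell$generation <- cell$generation + 1L
      cell$V <- unname(vols["mother"])
      cell$cycle <- realize_cycle(cell$params, cell$V, popn$t1_combiner)
      cell$cycle_start <- cell$t
      cell$pr_on <- part$mother$pr_on
      cell$pr_off <- part$mother$pr_off
      cell$mrna <- as.numeric(part$mother$mrna)
      cell$prot <- as.numeric(part$mother$prot)
      cell$replicated <- FALSE
    }
  }

  div_df <- if (nd > 0) as.data.frame(do.call(rbind, div[seq_len(nd)]))
            else data.frame(time = numeric(0), mother_id = numeric(0),
                            daughter_id = numeric(0), V_total = numeric(0),
                            V_mother = numeric(0), V_daughter = numeric(0),
                            mol_pre = numeric(0), mol_mother = numeric(0),
                            mol_daughter = numeric(0))
  tr_df <- if (nt > 0) as.data.frame(do.call(rbind, traces[seq_len(nt)]))
           else NULL
  list(cells = final[seq_len(nf)], divisions = div_df, traces = tr_df,
       next_id = next_id)
}

# cycle block of a cell at its current time
cycle_block <- function(cell) {
  a <- cell$t - cell$cycle_start
  if (a < cell$cycle$t_start) "T1"
  else if (a < cell$cycle$t_s_entry) "T2" else "T3"
}

#' Population snapshot
#'
#' One row per live cell: identity, lineage, volume, cycle block and the
#' per-gene mRNA and protein counts.
#'
#' @param cells list of `cell_state` objects.
#' @param spec a `network_spec` or `NULL` (growth-only cells).
#' @return a data.frame ordered by `cell_id`.
#' @export
population_snapshot <- function(cells, spec = NULL) {
  base <- data.frame(
    cell_id = vapply(cells, function(c) c$id, integer(1)),
    parent_id = vapply(cells, function(c) as.integer(c$parent), integer(1)),
    birth_time = vapply(cells, function(c) c$birth_time, numeric(1)),
    generation = vapply(cells, function(c) c$generation, integer(1)),
    time = vapply(cells, function(c) c$t, numeric(1)),
    volume = vapply(cells, function(c) c$V, numeric(1)),
    block = vapply(cells, cycle_block, character(1)))
  if (!is.null(spec) && length(cells) && length(cells[[1]]$mrna)) {
    gn <- names(spec$genes)
    for (i in seq_along(gn)) {
      base[[paste0("mrna_", gn[i])]] <-
        vapply(cells, function(c) c$mrna[i], numeric(1))
      base[[paste0("prot_", gn[i])]] <-
        vapply(cells, function(c) c$prot[i], numeric(1))
    }
  }
  base[order(base$cell_id), , drop = FALSE]
}

#' Run a two-phase induction protocol
#'
#' Initializes the population, simulates the pre phase, samples uniformly
#' without replacement, simulates the post phase, and returns the final
#' snapshot plus the full lineage log.
#'
#' @param protocol a `protocol_spec`.
#' @param spec a `network_spec` (ignored when `chemistry = FALSE`).
#' @param popn a `cycle_population`.
#' @param seed master seed; every random stream derives from it.
#' @param chemistry simulate the gene network (`FALSE`: growth/division
#'   demography only).
#' @param dV volume quantum, fL.
#' @param doubling_time mean initial-age, min.
#' @param init_galactose inducer level used for the initial steady state
#'   (0 = basal/OFF history; an induced level emulates cells pre-grown in
#'   galactose, the ON-history initial condition of switching-rate
#'   experiments).
#' @param noise_inheritance `"fresh"` (default): daughters draw new
#'   extrinsic-noise factors at birth; `"inherit"`: they keep the
#'   mother's.
#' @param scale_decay include the `Vref/V` factor on first-order decay
#'   channels (see [compute_propensities()]).
#' @return an object of class `protocol_result`: list with `snapshot`
#'   (final population data.frame), `cells`, `divisions`, `traces`,
#'   `n_after_phase1` (population size before sampling), `sampled_ids`,
#'   and the `protocol` echo.
#' @export
run_protocol <- function(protocol, spec, popn, seed = 1L, chemistry = TRUE,
                         dV = 0.04, doubling_time = 120,
                         init_galactose = 0,
                         noise_inheritance = c("fresh", "inherit"),
                         scale_decay = TRUE) {
  noise_inheritance <- match.arg(noise_inheritance)
  set.seed(seed)
  cells <- init_population(protocol$n_initial, spec, popn,
                           doubling_time = doubling_time,
                           galactose = init_galactose,
                           chemistry = chemistry)
  ph1 <- simulate_population(cells, protocol$t_pre, spec, popn,
                             galactose = protocol$gal_pre,
                             chemistry = chemistry, dV = dV,
                             snapshot_interval = protocol$snapshot_interval,
                             master_seed = seed,
                             noise_inheritance = noise_inheritance,
                             scale_decay = scale_decay)
  n1 <- length(ph1$cells)
  if (n1 == 0) stop("population went extinct")
  if (protocol$n_sample > n1)
    stop("sample size (", protocol$n_sample,
         ") exceeds population size (", n1, ") at the sampling step")
  set.seed(cell_seed(seed, 0L))  # dedicated stream for the sampling draw
  keep <- sort(sample.int(n1, protocol$n_sample))
  sampled <- ph1$cells[keep]
  ph2 <- simulate_population(sampled, protocol$t_pre + protocol$t_post,
                             spec, popn, galactose = protocol$gal_post,
                             chemistry = chemistry, dV = dV,
                             snapshot_interval = protocol$snapshot_interval,
                             master_seed = seed + 1L,
                             next_id = ph1$next_id,
                             noise_inheritance = noise_inheritance,
                             scale_decay = scale_decay)
  divisions <- rbind(ph1$divisions, ph2$divisions)
  traces <- if (is.null(ph1$traces)) ph2$traces
            else rbind(ph1$traces, ph2$traces)
  if (!is.null(traces)) {
    traces <- traces[order(traces$cell_id, traces$time), ]
    traces <- traces[!duplicated(traces[, c("cell_id", "time")]), ]
    rownames(traces) <- NULL
  }
  structure(list(snapshot = population_snapshot(ph2$cells,
                                                if (chemistry) spec),
                 cells = ph2$cells, divisions = divisions, traces = traces,
                 n_after_phase1 = n1,
                 sampled_ids = vapply(sampled, function(c) c$id, integer(1)),
                 protocol = protocol, seed = seed, chemistry = chemistry),
            class = "protocol_result")
}

#' Trace the lineage subtree of a cell
#'
#' All descendants of a root cell, with the division edges and (when
#' tracing was enabled) each cell's time series of volume and reporter
#' content; reporter concentration is `count * Vref / V`.
#'
#' @param result a `protocol_result`.
#' @param root_id id of the root cell.
#' @param Vref reference volume for the concentration column, fL.
#' @return list with `cell_ids`, `edges` (division records inside the
#'   subtree) and `traces` (with a `conc0` column when available).
#' @export
trace_lineage <- function(result, root_id, Vref = 60) {
  div <- result$divisions
  known <- unique(c(div$mother_id, div$daughter_id,
                    vapply(result$cells, function(c) c$id, integer(1))))
  if (!(root_id %in% known)) stop("unknown cell id: ", root_id)
  members <- root_id
  frontier <- root_id
  while (length(frontier)) {
    kids <- div$daughter_id[div$mother_id %in% frontier &
                              !(div$daughter_id %in% members)]
    members <- c(members, kids)
    frontier <- kids
  }
  edges <- div[div$mother_id %in% members & div$daughter_id %in% members, ]
  traces <- NULL
  if (!is.null(result$traces)) {
    traces <- result$traces[result$traces$cell_id %in% members, ]
    traces$conc0 <- traces$prot0 * Vref / traces$V
  }
  list(cell_ids = sort(members), edges = edges, traces = traces)
}

#' Generation census of a population
#'
#' Fractions of cells by replicative generation. In exponential growth the
#' composition is geometric: about one half of the cells have never
#' divided, a quarter have divided once, and so on.
#'
#' @param snapshot a population snapshot data.frame.
#' @return data.frame with `generation`, `n`, `fraction`.
#' @export
generation_census <- function(snapshot) {
  tab <- table(snapshot$generation)
  data.frame(generation = as.integer(names(tab)), n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(snapshot))
}
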