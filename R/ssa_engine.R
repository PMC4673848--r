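#' @useDynLib lineageSSA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# process-category noise factors: one Normal(1, cv) multiplier per category,
# shared across genes within a cell (extrinsic/global noise)
NOISE_CATEGORIES <- c("switching", "transcription", "translation",
                      "mrna_decay", "protein_decay")

draw_noise_factors <- function(cv) {
  if (cv <= 0) return(stats::setNames(rep(1, 5), NOISE_CATEGORIES))
  stats::setNames(rnorm_trunc0(5, rep(1, 5), rep(cv, 5)), NOISE_CATEGORIES)
}

#' Construct a cell state
#'
#' The full per-cell state carried through a simulation: identity and
#' lineage fields, volume and cycle position, per-gene promoter copies in
#' ON/OFF state, mRNA and protein counts, the cell's own cycle parameters
#' and extrinsic-noise factors.
#'
#' @param id,parent integer cell ids (`parent = NA` for founders).
#' @param birth_time birth time, min.
#' @param generation replicative generation (0 = never divided).
#' @param t current simulation time, min.
#' @param V current volume, fL.
#' @param params `cell_cycle_params` for this cell.
#' @param cycle realized cycle from [realize_cycle()].
#' @param cycle_start absolute time of the current cycle's start, min.
#' @param pr_on,pr_off integer vectors of promoter copies per gene.
#' @param mrna,prot numeric count vectors per gene.
#' @param noise named numeric vector of the five process noise factors.
#' @param replicated has the promoter complement been doubled this cycle?
#' @return a list of class `cell_state`.
#' @export
cell_state <- function(id, parent, birth_time, generation, t, V, params,
                       cycle, cycle_start, pr_on, pr_off, mrna, prot,
                       noise, replicated = FALSE) {
  stopifnot(V > 0, all(pr_on >= 0), all(pr_off >= 0),
            all(mrna >= 0), all(prot >= 0))
  structure(list(id = id, parent = parent, birth_time = birth_time,
                 generation = generation, t = t, V = V, params = params,
                 cycle = cycle, cycle_start = cycle_start,
                 pr_on = pr_on, pr_off = pr_off, mrna = mrna, prot = prot,
                 noise = noise, replicated = replicated),
            class = "cell_state")
}

# 7 x n matrix of mechanistic rates for the kernel
rate_matrix <- function(spec) {
  dr <- lapply(spec$genes, derive_rates)
  m <- vapply(names(spec$genes), function(g) {
    gs <- spec$genes[[g]]; d <- dr[[g]]
    c(gs$r_act_max, d$r_off, d$rm_true, d$b_true, gs$r_p, gs$d_m, gs$d_p)
  }, numeric(7))
  rownames(m) <- c("r_act", "r_off", "rm_true", "b_true", "r_p", "d_m", "d_p")
  m
}

ff_kernel_args <- function(spec, galactose) {
  if (is.null(spec$ff))
    return(list(type = 0L, par = numeric(6), idx = rep(-1L, 3)))
  gene_idx <- function(slot) {
    g <- spec$regulators[[slot]]
    if (is.null(g) || is.na(g)) -1L else match(g, names(spec$genes)) - 1L
  }
  list(type = 1L,
       par = c(spec$ff$S3, spec$ff$S1, spec$ff$S80, spec$ff$alpha,
               spec$ff$beta, inducer_g(spec$ff, galactose)),
       idx = c(gene_idx("gal3"), gene_idx("gal1"), gene_idx("gal80")))
}

#' Reaction propensities of a cell
#'
#' Reference (R-level) computation of the propensity of every reaction
#' channel: per gene — promoter activation `r_act*F*PR_OFF`, inactivation
#' `r_off*PR_ON`, basal transcription `rm_true*b_true*PR_OFF*(Vref/V)`,
#' full transcription `rm_true*PR_ON*(Vref/V)`, mRNA decay
#' `d_m*R*(Vref/V)`, translation `r_p*R*(Vref/V)`, protein decay
#' `d_p*P*(Vref/V)` — each multiplied by the cell's noise factor for its
#' process category; plus the volume channel at (growth rate)/dV.
#'
#' @param state a `cell_state`.
#' @param spec a `network_spec`.
#' @param galactose inducer level, % w/v.
#' @param dV volume quantum, fL (default 0.04, chosen so the realized volume at division stays within 2% RMS of the deterministic trajectory).
#' @param scale_decay include the `Vref/V` factor on the first-order decay
#'   channels as the model's rate list specifies; `FALSE` gives the
#'   conventional volume-independent first-order decay.
#' @return named numeric vector of propensities (1/min), genes blocked as
#'   `<gene>.<channel>` plus a final `volume` entry.
#' @export
compute_propensities <- function(state, spec, galactose = 0, dV = 0.04,
                                 scale_decay = TRUE) {
  rm_ <- rate_matrix(spec)
  s <- spec$Vref / state$V
  F <- network_activity(spec, as.list(stats::setNames(state$prot,
                                                      names(spec$genes))),
                        state$V, galactose)
  ns <- state$noise
  out <- c()
  for (i in seq_along(spec$genes)) {
    g <- names(spec$genes)[i]
    r <- rm_[, i]
    sd_ <- if (scale_decay) s else 1
    a <- c(activation   = ns["switching"] * r["r_act"] * F * state$pr_off[i],
           inactivation = ns["switching"] * r["r_off"] * state$pr_on[i],
           basal_tx     = ns["transcription"] * r["rm_true"] * r["b_true"] *
                            state$pr_off[i] * s,
           full_tx      = ns["transcription"] * r["rm_true"] * state$pr_on[i] * s,
           mrna_decay   = ns["mrna_decay"] * r["d_m"] * state$mrna[i] * sd_,
           translation  = ns["translation"] * r["r_p"] * state$mrna[i] * s,
           prot_decay   = ns["protein_decay"] * r["d_p"] * state$prot[i] * sd_)
    names(a) <- paste(g, c("activation", "inactivation", "basal_tx", "full_tx",
                           "mrna_decay", "translation", "prot_decay"), sep = ".")
    out <- c(out, a)
  }
  in_g1 <- state$t - state$cycle_start < state$cycle$t_s_entry
  rg <- if (in_g1) state$params$r1 else state$params$r2
  c(out, volume = if (dV > 0) rg / dV else 0)
}

#' Replicate promoters at S entry
#'
#' Doubles every gene's promoter complement, each copy keeping its current
#' state: an active promoter replicates into two active promoters, an
#' inactive one into two inactive promoters.
#'
#' @param state a `cell_state` entering S phase.
#' @return the updated `cell_state`.
#' @export
replicate_promoters <- function(state) {
  if (state$replicated) stop("promoters already replicated this cycle")
  state$pr_on <- 2L * state$pr_on
  state$pr_off <- 2L * state$pr_off
  state$replicated <- TRUE
  state
}

#' Binomial partitioning at division
#'
#' Splits a dividing cell's molecular content between mother and daughter.
#' Each mRNA and protein species is partitioned independently, the daughter
#' receiving `Binomial(count, V_daughter / V_total)`. The replicated
#' promoter copies are re-assorted so each cell gets the pre-replication
#' complement per gene, each copy preserving its ON/OFF state (daughter ON
#' copies drawn hypergeometrically from the ON/OFF pool).
#'
#' @param state the dividing `cell_state` (at the end of T3).
#' @param V_mother,V_daughter the two volumes from [divide_volume()];
#'   must sum to `state$V`.
#' @return list with `mother` and `daughter` partial states (`pr_on`,
#'   `pr_off`, `mrna`, `prot`).
#' @export
partition_at_division <- function(state, V_mother, V_daughter) {
  if (abs(V_mother + V_daughter - state$V) > 1e-6 * state$V)
    stop("V_mother + V_daughter must equal the pre-division volume")
  p <- V_daughter / state$V
  d_mrna <- stats::rbinom(length(state$mrna), round(state$mrna), p)
  d_prot <- stats::rbinom(length(state$prot), round(state$prot), p)
  n_each <- (state$pr_on + state$pr_off) %/% 2L
  d_on <- mapply(function(on, off, k) stats::rhyper(1, on, off, k),
                 state$pr_on, state$pr_off, n_each)
  list(mother = list(pr_on = state$pr_on - as.integer(d_on),
                     pr_off = state$pr_off - (n_each - as.integer(d_on)),
                     mrna = round(state$mrna) - d_mrna,
                     prot = round(state$prot) - d_prot),
       daughter = list(pr_on = as.integer(d_on),
                       pr_off = n_each - as.integer(d_on),
                       mrna = d_mrna, prot = d_prot))
}

#' Simulate one cell until its next division or a stop time
#'
#' Runs the exact SSA for a single cell from its current time until
#' `min(t_end, scheduled division)`; promoter replication at S entry is
#' handled inside. Division itself (volume split, molecule partitioning,
#' parameter inheritance) is the caller's job — see [run_protocol()].
#'
#' @param state a `cell_state`.
#' @param spec a `network_spec`.
#' @param t_end absolute stop time, min.
#' @param galactose inducer level, % w/v.
#' @param dV volume quantum, fL.
#' @param snapshot_interval record (time, volume, reporter mRNA/protein,
#'   reporter ON-promoters) at this interval; 0 disables tracing.
#' @param scale_decay see [compute_propensities()].
#' @return list with the updated `state`, `reason` (`"division"` or
#'   `"t_end"`), and `trace` (matrix, possibly 0-row).
#' @export
simulate_cell <- function(state, spec, t_end, galactose = 0, dV = 0.04,
                          snapshot_interval = 0, scale_decay = TRUE) {
  ff <- ff_kernel_args(spec, galactose)
  res <- ssa_cell_kernel(
    as.integer(state$pr_on), as.integer(state$pr_off),
    as.numeric(state$mrna), as.numeric(state$prot),
    state$V, state$t, t_end,
    state$cycle_start + state$cycle$t_s_entry,
    state$cycle_start + state$cycle$t_division,
    state$replicated,
    state$params$r1, state$params$r2, dV,
    rate_matrix(spec), unname(state$noise), spec$Vref,
    ff$type, ff$par, ff$idx, snapshot_interval, scale_decay)
  state$pr_on <- res$pr_on; state$pr_off <- res$pr_off
  state$mrna <- res$mrna; state$prot <- res$prot
  state$V <- res$V; state$t <- res$t; state$replicated <- res$replicated
  list(state = state, reason = res$reason, trace = res$trace,
       n_events = res$n_events)
}
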