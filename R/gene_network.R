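#' Gene specification for a two-state-promoter gene
#'
#' Each gene in the network (and the reporter) is described by seven
#' observable parameters: the maximum promoter activation rate `r_act_max`,
#' the fully-induced active fraction `f_active` (long-run fraction of time
#' the promoter spends ON when fully induced), the observed mRNA synthesis
#' rate `rm_obs`, the observed basal expression fraction `b_obs`, the
#' translation rate `r_p`, and the mRNA/protein degradation rates `d_m`,
#' `d_p`. The mechanistic ON-state rates are recovered with
#' [derive_rates()].
#'
#' @param name gene name.
#' @param r_act_max maximum promoter activation rate, 1/min.
#' @param f_active fully-induced ON fraction, in (0, 1].
#' @param rm_obs observed mRNA synthesis rate, mRNA/min per promoter.
#' @param b_obs observed basal expression fraction, in \[0, 1\].
#' @param r_p translation rate, protein/(mRNA min).
#' @param d_m mRNA degradation rate, 1/min.
#' @param d_p protein degradation rate, 1/min.
#' @param n_promoter promoter copy number before replication (default 1).
#' @return an object of class `gene_spec`.
#' @export
gene_spec <- function(name, r_act_max, f_active, rm_obs, b_obs,
                      r_p, d_m, d_p, n_promoter = 1L) {
  if (f_active <= 0 || f_active > 1) stop("f_active must lie in (0, 1]")
  if (b_obs < 0 || b_obs > 1) stop("b_obs must lie in [0, 1]")
  rates <- c(r_act_max, rm_obs, r_p, d_m, d_p)
  if (any(rates < 0) || any(!is.finite(rates))) stop("rates must be finite and >= 0")
  if (n_promoter < 1) stop("n_promoter must be >= 1")
  structure(list(name = name, r_act_max = r_act_max, f_active = f_active,
                 rm_obs = rm_obs, b_obs = b_obs, r_p = r_p, d_m = d_m,
                 d_p = d_p, n_promoter = as.integer(n_promoter)),
            class = "gene_spec")
}

#' Mechanistic rates from observed parameters
#'
#' Converts the observed parameterization to the mechanistic two-state
#' rates. The ON fraction fixes the inactivation rate,
#' `r_off = r_act_max * (1 - f) / f`. The observed synthesis rate averages
#' ON- and OFF-state transcription, `rm_obs = rm_true*f + b_true*rm_true*(1-f)`,
#' and the observed basal fraction satisfies `b_obs * rm_obs = b_true * rm_true`;
#' solving jointly gives
#' `rm_true = rm_obs * (1 - b_obs*(1 - f)) / f` and
#' `b_true = b_obs * rm_obs / rm_true`.
#'
#' @param spec a `gene_spec`.
#' @return list with `r_off`, `rm_true`, `b_true`.
#' @export
derive_rates <- function(spec) {
  f <- spec$f_active
  if (f <= 0) stop("f_active must be > 0")
  r_off <- spec$r_act_max * (1 - f) / f
  rm_true <- spec$rm_obs * (1 - spec$b_obs * (1 - f)) / f
  b_true <- if (rm_true > 0) spec$b_obs * spec$rm_obs / rm_true else 0
  if (b_true > 1 + 1e-12)
    stop("derived b_true > 1: observed parameters are inconsistent")
  list(r_off = r_off, rm_true = rm_true, b_true = min(b_true, 1))
}

# forward map: mechanistic -> observed (used in round-trip tests)
observe_rates <- function(r_off, rm_true, b_true, r_act_max) {
  f <- r_act_max / (r_act_max + r_off)
  rm_obs <- rm_true * f + b_true * rm_true * (1 - f)
  list(f_active = f, rm_obs = rm_obs,
       b_obs = if (rm_obs > 0) b_true * rm_true / rm_obs else 0)
}

#' Functional-form parameters of the GAL network
#'
#' Scale parameters for the action of Gal3p, Gal1p and Gal80p in the
#' network-activity function, the inner exponent `alpha` (fixed at 1), the
#' outer Hill exponent `beta`, and the inducer coupling `g_model` mapping
#' galactose concentration (% w/v) to the multiplier `g` (linear by
#' default; `"saturating"` uses `g = gal / (K + gal)`).
#'
#' @param S3,S1,S80 positive scale parameters (S80 conventionally fixed at
#'   4500; only S3 and S1 are fitted).
#' @param alpha inner exponent (default 1).
#' @param beta outer Hill exponent, > 0.
#' @param g_model `"linear"` or `"saturating"`.
#' @param K half-saturation constant for the saturating coupling (% w/v).
#' @return an object of class `functional_form`.
#' @export
functional_form <- function(S3 = 2e4, S1 = 1e3, S80 = 4500, alpha = 1,
                            beta = 3, g_model = c("linear", "saturating"),
                            K = 0.05) {
  if (any(c(S3, S1, S80) <= 0)) stop("scale parameters must be > 0")
  if (beta <= 0) stop("beta must be > 0")
  structure(list(S3 = S3, S1 = S1, S80 = S80, alpha = alpha, beta = beta,
                 g_model = match.arg(g_model), K = K),
            class = "functional_form")
}

#' Inducer coupling g
#'
#' @param ff a `functional_form`.
#' @param galactose galactose concentration, % w/v.
#' @return the multiplier `g` (dimensionless).
#' @export
inducer_g <- function(ff, galactose) {
  if (any(galactose < 0)) stop("galactose must be >= 0")
  switch(ff$g_model,
         linear = galactose,
         saturating = galactose / (ff$K + galactose))
}

#' GAL-network activity F
#'
#' The dimensionless activity of the GAL network, in \[0, 1\]:
#' \deqn{F = 1 / (1 + (S80 [Gal80p] / (1 + (S3 g [Gal3p] + S1 g [Gal1p])^\alpha))^\beta)}
#' Monotone increasing in the activator concentrations (Gal3p, Gal1p),
#' monotone decreasing in the repressor (Gal80p). Concentrations are
#' counts normalized to the reference volume (count * Vref / V).
#'
#' @param conc_gal3p,conc_gal1p,conc_gal80p concentrations (>= 0).
#' @param galactose galactose concentration, % w/v.
#' @param ff a `functional_form`.
#' @return F in \[0, 1\].
#' @export
gal_functional_form <- function(conc_gal3p, conc_gal1p, conc_gal80p,
                                galactose, ff) {
  if (any(c(conc_gal3p, conc_gal1p, conc_gal80p) < 0))
    stop("concentrations must be >= 0")
  g <- inducer_g(ff, galactose)
  act <- ff$S3 * g * conc_gal3p + ff$S1 * g * conc_gal1p
  ratio <- (ff$S80 * conc_gal80p) / (1 + act^ff$alpha)
  1 / (1 + ratio^ff$beta)
}

#' Promoter activation rate
#'
#' `r_ON = r_act_max * F`: the promoter's activation rate scaled by the
#' current network activity.
#'
#' @param gene a `gene_spec`.
#' @param F network activity in \[0, 1\].
#' @return activation rate, 1/min.
#' @export
promoter_activation_rate <- function(gene, F) {
  if (any(F < 0 | F > 1)) stop("F must lie in [0, 1]")
  gene$r_act_max * F
}

#' Network specification
#'
#' Ordered list of genes — the reporter `G0` first, then the network genes
#' `G1..GN` — together with the functional form, the reference volume, the
#' per-process extrinsic-noise CV, and a parameter-tying map. `regulators`
#' names which genes' proteins enter the GAL functional form (set any to
#' `NA` for a gene-free slot, contributing zero concentration).
#'
#' @param genes list of `gene_spec` objects; the first is the reporter.
#' @param ff a `functional_form`, or `NULL` for a constant `F = 1`
#'   (useful for single-gene studies).
#' @param Vref reference volume, fL.
#' @param noise_cv per-process extrinsic-noise coefficient of variation
#'   (default 0.10): each cell draws one Normal(1, CV) factor per process
#'   category, applied to all genes.
#' @param regulators named character vector with entries `gal3`, `gal1`,
#'   `gal80` naming genes in `genes`.
#' @param tied list of `c(gene_a, gene_b, parameter)` triples: parameter of
#'   `gene_a` is copied from `gene_b` whenever parameters are set (used to
#'   share the promoter parameters of the reporter and GAL1).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(genes, ff = NULL, Vref = 60, noise_cv = 0.10,
                         regulators = NULL, tied = list()) {
  if (!length(genes)) stop("at least one gene (the reporter) is required")
  if (Vref <= 0) stop("Vref must be > 0")
  names(genes) <- vapply(genes, function(g) g$name, "")
  if (!is.null(regulators)) {
    known <- stats::na.omit(unlist(regulators))
    if (!all(known %in% names(genes)))
      stop("unknown regulator gene(s): ",
           paste(setdiff(known, names(genes)), collapse = ", "))
  }
  for (tie in tied) {
    if (!all(tie[1:2] %in% names(genes)))
      stop("tied_parameters references unknown gene: ",
           paste(setdiff(tie[1:2], names(genes)), collapse = ", "))
    genes[[tie[1]]][[tie[3]]] <- genes[[tie[2]]][[tie[3]]]
  }
  structure(list(genes = genes, ff = ff, Vref = Vref, noise_cv = noise_cv,
                 regulators = regulators, tied = tied),
            class = "network_spec")
}

#' Default GAL-network instantiation
#'
#' The canonical galactose network of *S. cerevisiae*: a YFP reporter under
#' the GAL1 promoter plus GAL1, GAL3 and GAL80. Fixed per-gene rates
#' (synthesis, decay, translation, basal fractions) are literature-anchored
#' defaults chosen to give basal mRNA counts of order 1 and induced protein
#' counts of order 1e3; the promoter parameters (`r_act_max`, `f_active`)
#' and the functional-form scales are the quantities normally subject to
#' fitting. The reporter shares the GAL1 promoter, so its `r_act_max` and
#' `f_active` are tied to GAL1's.
#'
#' @param ff a `functional_form` (default [functional_form()]).
#' @param Vref reference volume, fL.
#' @param noise_cv per-process extrinsic-noise CV.
#' @return a `network_spec`.
#' @export
gal_network <- function(ff = functional_form(), Vref = 60, noise_cv = 0.10) {
  genes <- list(
    gene_spec("reporter", r_act_max = 0.10, f_active = 0.5,
              rm_obs = 1.0, b_obs = 0.02, r_p = 0.5, d_m = 0.05, d_p = 0.005),
    gene_spec("GAL1", r_act_max = 0.10, f_active = 0.5,
              rm_obs = 1.0, b_obs = 0.02, r_p = 0.5, d_m = 0.05, d_p = 0.005),
    gene_spec("GAL3", r_act_max = 0.08, f_active = 0.5,
              rm_obs = 0.5, b_obs = 0.05, r_p = 0.5, d_m = 0.05, d_p = 0.005),
    gene_spec("GAL80", r_act_max = 0.05, f_active = 0.5,
              rm_obs = 0.15, b_obs = 0.30, r_p = 0.5, d_m = 0.05, d_p = 0.005))
  network_spec(genes, ff = ff, Vref = Vref, noise_cv = noise_cv,
               regulators = c(gal3 = "GAL3", gal1 = "GAL1", gal80 = "GAL80"),
               tied = list(c("reporter", "GAL1", "r_act_max"),
                           c("reporter", "GAL1", "f_active")))
}

# network activity from protein counts (concentration = count * Vref / V)
network_activity <- function(spec, proteins, V, galactose) {
  if (is.null(spec$ff)) return(1)
  conc <- function(slot) {
    g <- spec$regulators[[slot]]
    if (is.null(g) || is.na(g)) 0 else proteins[[g]] * spec$Vref / V
  }
  gal_functional_form(conc("gal3"), conc("gal1"), conc("gal80"),
                      galactose, spec$ff)
}

#' Basal steady state of a network
#'
#' Deterministic mean-field fixed point at `V = Vref`, used to initialize
#' cells. Iterates: compute `F` from current protein concentrations, the
#' ON-state occupancy `phi = r_act*F / (r_act*F + r_off)`, the mean mRNA
#' `rm_true * (phi + b_true*(1-phi)) * n_promoter / d_m`, and the mean
#' protein `r_p * mRNA / d_p`, until protein levels change by less than
#' `tol` (relative).
#'
#' @param spec a `network_spec`.
#' @param galactose inducer level (default 0: basal conditions).
#' @param start optional named numeric vector of starting protein levels.
#' @param tol relative convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 1e4).
#' @return data.frame with one row per gene: `gene`, `phi` (ON-state
#'   probability), `mrna`, `protein` (means, not yet rounded).
#' @export
basal_steady_state <- function(spec, galactose = 0, start = NULL,
                               tol = 1e-6, max_iter = 1e4) {
  genes <- spec$genes
  dr <- lapply(genes, derive_rates)
  prot <- if (is.null(start)) stats::setNames(rep(0, length(genes)), names(genes))
          else start[names(genes)]
  phi <- mrna <- stats::setNames(rep(0, length(genes)), names(genes))
  for (it in seq_len(max_iter)) {
    F <- network_activity(spec, as.list(prot), spec$Vref, galactose)
    new_prot <- prot
    for (g in names(genes)) {
      gs <- genes[[g]]; d <- dr[[g]]
      ract <- gs$r_act_max * F
      phi[g] <- if (ract + d$r_off > 0) ract / (ract + d$r_off) else 0
      mrna[g] <- if (gs$d_m > 0)
        d$rm_true * (phi[g] + d$b_true * (1 - phi[g])) * gs$n_promoter / gs$d_m
        else 0
      new_prot[g] <- if (gs$d_p > 0) gs$r_p * mrna[g] / gs$d_p else 0
    }
    if (max(abs(new_prot - prot) / pmax(abs(prot), 1e-12)) < tol ||
        max(abs(new_prot - prot)) < tol) {
      return(data.frame(gene = names(genes), phi = unname(phi),
                        mrna = unname(mrna), protein = unname(new_prot),
                        stringsAsFactors = FALSE))
    }
    # damped update: keeps the iteration from cycling when the feedback
    # through F is strong
    prot <- 0.5 * prot + 0.5 * new_prot
  }
  stop("basal_steady_state did not converge in ", max_iter, " iterations")
}
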