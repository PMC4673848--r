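#' Classify cells as ON or OFF
#'
#' A cell is ON iff its reporter content (molecule count or fluorescence)
#' is at or above the threshold.
#'
#' @param x reporter values.
#' @param threshold classification threshold, > 0.
#' @return logical vector (`TRUE` = ON).
#' @export
classify_on <- function(x, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  x >= threshold
}

#' Automatic ON threshold from a bimodal distribution
#'
#' Fits a two-component Gaussian mixture to `log10(x + 1)` and returns the
#' midpoint (in log space) between the component means, back-transformed.
#' Falls back to the median when the mixture is degenerate.
#'
#' @param x reporter counts or fluorescence of a (bimodal) population.
#' @return a threshold on the original scale.
#' @export
antimode_threshold <- function(x) {
  lx <- log10(x + 1)
  fit <- tryCatch(
    mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || length(unique(round(fit$parameters$mean, 6))) < 2)
    return(stats::median(x) + 1)
  10^mean(fit$parameters$mean) - 1
}

#' Fraction of ON cells
#'
#' @param x reporter values of a population snapshot.
#' @param threshold classification threshold.
#' @return list with `fraction`, `se` (binomial standard error), `n`.
#' @export
fraction_on <- function(x, threshold) {
  if (!length(x)) stop("empty population")
  f <- mean(classify_on(x, threshold))
  list(fraction = f, se = sqrt(f * (1 - f) / length(x)), n = length(x))
}

#' Phenotypic switching rates from dense per-cell series
#'
#' Counts classification flips between consecutive snapshots of each cell
#' and divides by the total time spent in the originating state:
#' `k_off_to_on = (#OFF->ON flips) / (time exposed OFF)` and conversely,
#' pooled over cells. Lineage-aware by construction: each cell contributes
#' the interval between its own consecutive snapshots only, so exposure
#' ends at division and daughters contribute their own series.
#'
#' @param series data.frame with columns `cell_id`, `time` (min) and
#'   either logical `state` (TRUE = ON) or a reporter column `value`
#'   classified via `threshold`.
#' @param threshold used when `series` has a `value` column.
#' @return an object of class `switching_rates`: list with `k_off_to_on`
#'   and `k_on_to_off` (1/h), transition counts and exposures (h). A rate
#'   with zero exposure is `NA`.
#' @export
switching_rates_from_series <- function(series, threshold = NULL) {
  if (!("state" %in% names(series))) {
    if (is.null(threshold)) stop("threshold required to classify `value`")
    series$state <- classify_on(series$value, threshold)
  }
  series <- series[order(series$cell_id, series$time), ]
  id <- series$cell_id
  same_cell <- id[-1] == id[-length(id)]
  if (!is.null(series$time)) {
    dt <- diff(series$time)[same_cell]
    if (any(dt <= 0)) stop("times must be strictly increasing within a cell")
  }
  s0 <- series$state[-nrow(series)][same_cell]
  s1 <- series$state[-1][same_cell]
  exp_off <- sum(dt[!s0]) / 60
  exp_on <- sum(dt[s0]) / 60
  n_off_on <- sum(!s0 & s1)
  n_on_off <- sum(s0 & !s1)
  structure(list(
    k_off_to_on = if (exp_off > 0) n_off_on / exp_off else NA_real_,
    k_on_to_off = if (exp_on > 0) n_on_off / exp_on else NA_real_,
    n_off_to_on = n_off_on, n_on_to_off = n_on_off,
    exposure_off_h = exp_off, exposure_on_h = exp_on),
    class = "switching_rates")
}

#' Two-state back-calculation of switching rates from endpoint fractions
#'
#' The experimental-style estimate: two cultures with different initial ON
#' fractions (an OFF history and an ON history) are observed only at the
#' start and the end of an induction period of length `T`. Assuming a
#' homogeneous two-state process, the ON fraction relaxes as
#' `f(t) = f_ss + (f0 - f_ss) exp(-(k_on + k_off) t)` with
#' `f_ss = k_on / (k_on + k_off)`; the two (f0, fT) pairs give two
#' equations for the two rates. The exact published extraction procedure
#' for this design is not reproduced here; this is the standard closed-form
#' two-state solution, documented as a stand-in.
#'
#' @param f0_off,fT_off initial and final ON fraction of the OFF-history
#'   culture.
#' @param f0_on,fT_on same for the ON-history culture.
#' @param T induction period, hours.
#' @param rate_cap cap applied when the system has fully equilibrated
#'   (relaxation complete; the rate sum is unidentifiable and reported at
#'   the cap), default 1e3/h.
#' @return a `switching_rates` object with `k_off_to_on` (= k_on) and
#'   `k_on_to_off` (= k_off), 1/h.
#' @export
two_state_backcalc <- function(f0_off, fT_off, f0_on, fT_on, T,
                               rate_cap = 1e3) {
  fr <- c(f0_off, fT_off, f0_on, fT_on)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (T <= 0) stop("T must be > 0")
  if (f0_off == f0_on) stop("the two histories must start at different fractions")
  rho <- (fT_on - fT_off) / (f0_on - f0_off)   # = exp(-(k_on+k_off) T)
  if (rho < 0)
    stop("endpoint fractions are inconsistent with a two-state model")
  if (rho >= 1) {           # no net relaxation between the two histories
    k <- list(k_on = 0, k_off = 0)
  } else if (rho == 0 || -log(rho) / T >= rate_cap) {
    ksum <- rate_cap
    fss <- fT_off          # relaxation complete: endpoints sit at f_ss
    k <- list(k_on = fss * ksum, k_off = (1 - fss) * ksum)
  } else {
    ksum <- -log(rho) / T
    fss <- (fT_off - f0_off * rho) / (1 - rho)
    if (fss < -1e-9 || fss > 1 + 1e-9)
      stop("implied steady-state fraction outside [0, 1]; ",
           "data inconsistent with a two-state model")
    fss <- min(max(fss, 0), 1)
    k <- list(k_on = fss * ksum, k_off = (1 - fss) * ksum)
  }
  structure(list(k_off_to_on = k$k_on, k_on_to_off = k$k_off,
                 n_off_to_on = NA, n_on_to_off = NA,
                 exposure_off_h = NA, exposure_on_h = NA),
            class = "switching_rates")
}

#' Forward-simulate the two-state ON-fraction ODE
#'
#' Closed-form relaxation of the ON fraction under constant rates; useful
#' as an oracle for [two_state_backcalc()].
#'
#' @param f0 initial ON fraction.
#' @param k_on,k_off rates, 1/h.
#' @param t time, hours (vectorized).
#' @return ON fraction at `t`.
#' @export
two_state_fraction <- function(f0, k_on, k_off, t) {
  fss <- k_on / (k_on + k_off)
  fss + (f0 - fss) * exp(-(k_on + k_off) * t)
}

#' Compare endpoint and dense switching-rate estimators on simulated data
#'
#' Replicates the switching-rate experiment *in silico*: for each
#' replicate, an OFF-history population (basal initial state) and an
#' ON-history population (pre-induced initial state) are simulated in the
#' same galactose medium. The OFF-to-ON rate is then estimated two ways —
#' densely, from every cell's classified time series
#' ([switching_rates_from_series()]), and from the endpoint ON fractions
#' of the two histories via the homogeneous two-state closed form
#' ([two_state_backcalc()]). Because induction makes the true rates
#' time-varying, the endpoint method is expected to underestimate.
#'
#' @param n_rep number of replicates.
#' @param n_cells initial cells per history.
#' @param galactose induction level, % w/v.
#' @param T_h observation period, hours.
#' @param threshold ON threshold on the reporter count.
#' @param spec,popn model objects.
#' @param seed base seed.
#' @param snapshot_interval dense-observation interval, min.
#' @return data.frame per replicate: `k_on_dense`, `k_on_endpoint`,
#'   `k_off_dense`, `k_off_endpoint`, and `endpoint_le_dense` (logical,
#'   OFF-to-ON comparison; `NA` when the endpoint solve fails).
#' @export
compare_switching_estimators <- function(n_rep = 10, n_cells = 10,
                                         galactose = 0.05, T_h = 8,
                                         threshold = 200,
                                         spec = gal_network(),
                                         popn = yeast_cycle_population(),
                                         seed = 1L,
                                         snapshot_interval = 15) {
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    p <- protocol_spec(n_cells, 0, n_cells, T_h * 60,
                       gal_pre = galactose, gal_post = galactose,
                       snapshot_interval = snapshot_interval)
    off <- run_protocol(p, spec, popn, seed = seed + r,
                        init_galactose = 0)
    on <- run_protocol(p, spec, popn, seed = seed + r + 49999L,
                       init_galactose = 0.1)
    ser_off <- phenotype_series(off, threshold)
    ser_on <- phenotype_series(on, threshold)
    ser_on$cell_id <- ser_on$cell_id + max(ser_off$cell_id) + 1L
    dense <- switching_rates_from_series(rbind(ser_off, ser_on))
    t0 <- min(ser_off$time)
    f0_off <- mean(ser_off$state[ser_off$time == t0])
    f0_on <- mean(ser_on$state[ser_on$time == t0])
    fT_off <- mean(classify_on(off$snapshot$prot_reporter, threshold))
    fT_on <- mean(classify_on(on$snapshot$prot_reporter, threshold))
    bc <- tryCatch(two_state_backcalc(f0_off, fT_off, f0_on, fT_on, T_h),
                   error = function(e) NULL)
    out[[r]] <- data.frame(
      k_on_dense = dense$k_off_to_on,
      k_on_endpoint = if (is.null(bc)) NA_real_ else bc$k_off_to_on,
      k_off_dense = dense$k_on_to_off,
      k_off_endpoint = if (is.null(bc)) NA_real_ else bc$k_on_to_off,
      endpoint_le_dense = if (is.null(bc) || is.na(dense$k_off_to_on))
        NA else bc$k_off_to_on <= dense$k_off_to_on)
  }
  do.call(rbind, out)
}

#' Build a phenotype series from protocol traces
#'
#' Converts the per-cell traces of a [run_protocol()] result into the
#' series format of [switching_rates_from_series()], classifying on the
#' reporter protein count.
#'
#' @param result a `protocol_result` run with a positive
#'   `snapshot_interval`.
#' @param threshold ON threshold on the reporter count.
#' @return data.frame with `cell_id`, `time`, `value`, `state`.
#' @export
phenotype_series <- function(result, threshold) {
  tr <- result$traces
  if (is.null(tr)) stop("protocol was run without tracing")
  data.frame(cell_id = tr$cell_id, time = tr$time, value = tr$prot0,
             state = classify_on(tr$prot0, threshold))
}
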