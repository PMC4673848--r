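#' Per-cell cell-cycle parameter set
#'
#' Bundle of growth and division parameters for one asymmetrically dividing
#' budding-yeast cell. The cycle is split into two growth stages (G1 and
#' S/G2/M) and three time blocks: `T1` from birth until *start*, `T2` from
#' *start* until S-phase entry, and `T3` spanning S/G2/M. Volume grows
#' linearly at rate `r1` during T1 and T2 and at `r2` during T3; of the
#' S/G2/M growth only `r2m` goes to the mother compartment, the remainder
#' `r2 - r2m` builds the bud and sets the daughter's birth volume.
#'
#' @param Vi initial (birth) volume, fL.
#' @param r1 G1 volume growth rate, fL/min.
#' @param r2 overall S/G2/M growth rate, fL/min.
#' @param r2m mother-compartment S/G2/M growth rate, fL/min (`r2m <= r2`).
#' @param T1min minimum length of the T1 block, min.
#' @param T2 duration from *start* to S entry, min.
#' @param T3 duration of S/G2/M, min.
#' @param k slope relating `r1` to the start volume `Vs = k*r1 + b`, min.
#' @param b intercept of the start-volume rule, fL.
#' @param c_inherit parameter-inheritance coefficient in \[0, 1\]: a daughter's
#'   parameter is `c_inherit * parent + (1 - c_inherit) * fresh draw`.
#' @return an object of class `cell_cycle_params` (a named list).
#' @seealso [cell_cycle_population()], [volume_at_start()], [t1_duration()]
#' @export
cell_cycle_params <- function(Vi, r1, r2, r2m, T1min, T2, T3, k, b,
                              c_inherit = 0.25) {
  p <- list(Vi = Vi, r1 = r1, r2 = r2, r2m = r2m, T1min = T1min,
            T2 = T2, T3 = T3, k = k, b = b, c_inherit = c_inherit)
  p <- lapply(p, function(x) unname(x)[1])
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("cell-cycle parameters must be finite")
  if (any(vals[c("Vi", "r1", "r2", "r2m", "T1min", "T2", "T3")] < 0))
    stop("rates and durations must be >= 0")
  if (c_inherit < 0 || c_inherit > 1) stop("c_inherit must lie in [0, 1]")
  if (r2m > r2) stop("r2m must not exceed r2 (bud growth r2 - r2m >= 0)")
  structure(p, class = "cell_cycle_params")
}

#' Population-level cell-cycle parameter distributions
#'
#' Means and standard deviations of the per-cell parameters `Vi, r1, r2,
#' r2m, T1min, T2, T3` (each normally distributed, truncated at zero on
#' sampling) plus the fixed scalars `k`, `b` and the inheritance coefficient.
#'
#' @param means named numeric vector with entries
#'   `Vi, r1, r2, r2m, T1min, T2, T3`.
#' @param sds named numeric vector over the same names; defaults to 10% of
#'   each mean.
#' @param k,b start-volume rule `Vs = k*r1 + b` (min, fL).
#' @param c_inherit inheritance coefficient in \[0, 1\].
#' @param t1_combiner `"max"` (default; T1min acts as a lower bound on T1) or
#'   `"min"` (take the smaller of T1min and the size-threshold time).
#' @return an object of class `cycle_population` (a named list).
#' @export
cell_cycle_population <- function(means, sds = 0.10 * means, k, b,
                                  c_inherit = 0.25, t1_combiner = "max") {
  nm <- c("Vi", "r1", "r2", "r2m", "T1min", "T2", "T3")
  means <- means[nm]; sds <- sds[nm]
  if (anyNA(means) || anyNA(sds))
    stop("means and sds must be named over: ", paste(nm, collapse = ", "))
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  t1_combiner <- match.arg(t1_combiner, c("max", "min"))
  structure(list(means = means, sds = sds, k = k, b = b,
                 c_inherit = c_inherit, t1_combiner = t1_combiner),
            class = "cycle_population")
}

#' Default budding-yeast cell-cycle population
#'
#' Ships the package's calibrated defaults for a haploid BY-background
#' strain: parameter means chosen so that an exponentially growing
#' population doubles every ~120 min (daughters need ~125 min from birth to
#' their first division because they are born below the start size; mothers
#' re-enter T1 above the start size and cycle in ~118 min). Standard
#' deviations are 10% of the means.
#'
#' @param c_inherit inheritance coefficient (default 0.25).
#' @param t1_combiner see [cell_cycle_population()].
#' @return a `cycle_population` object.
#' @export
yeast_cycle_population <- function(c_inherit = 0.25, t1_combiner = "max") {
  means <- c(Vi = 26, r1 = 0.30, r2 = 0.61, r2m = 0.27,
             T1min = 36, T2 = 10, T3 = 72)
  cell_cycle_population(means, k = 38, b = 26.1,
                        c_inherit = c_inherit, t1_combiner = t1_combiner)
}

#' Volume at start
#'
#' The critical size licensing passage through *start*: `Vs = k*r1 + b`,
#' linear in the G1 growth rate.
#'
#' @param r1 G1 growth rate, fL/min.
#' @param k,b slope (min) and intercept (fL) of the size rule.
#' @return start volume Vs in fL.
#' @export
volume_at_start <- function(r1, k, b) {
  if (any(r1 < 0)) stop("r1 must be >= 0")
  Vs <- k * r1 + b
  if (any(Vs < 0)) stop("negative start volume: k, b, r1 are inconsistent")
  Vs
}

#' Realized T1 duration
#'
#' Time from birth until *start*, combining the size-threshold time
#' `(Vs - V0)/r1` (zero when the cell is already above `Vs`) with the block
#' floor `T1min`. With `combiner = "max"` (default) `T1min` acts as a lower
#' bound on T1; `combiner = "min"` takes the minimum of the two terms
#' instead.
#'
#' @param V0 volume at cycle start, fL.
#' @param Vs start volume, fL.
#' @param r1 G1 growth rate, fL/min.
#' @param T1min minimum T1, min.
#' @param combiner `"max"` (floor semantics) or `"min"` (take the
#'   smaller of the two terms instead).
#' @return T1 in minutes.
#' @export
t1_duration <- function(V0, Vs, r1, T1min, combiner = c("max", "min")) {
  combiner <- match.arg(combiner)
  if (r1 <= 0) {
    if (any(V0 < Vs)) stop("r1 = 0 and V0 < Vs: start is never reached")
    t_size <- 0
  } else {
    t_size <- pmax(0, (Vs - V0) / r1)
  }
  if (combiner == "max") pmax(T1min, t_size) else pmin(T1min, t_size)
}

#' Realize one cell cycle
#'
#' Draws no randomness: given a cell's parameters and its volume at cycle
#' start, returns the realized block durations and scheduled (relative)
#' event times for this cycle.
#'
#' @param params a `cell_cycle_params` object.
#' @param V0 volume at cycle start, fL.
#' @param combiner T1 combiner, see [t1_duration()].
#' @return list with `T1`, `T2`, `T3`, `Vs`, `total` (cycle length, min),
#'   `t_start` (T1 end), `t_s_entry` (T1+T2), `t_division` (T1+T2+T3),
#'   all relative to cycle start, plus `V0`.
#' @export
realize_cycle <- function(params, V0, combiner = "max") {
  V0 <- unname(V0)
  Vs <- params$k * params$r1 + params$b
  if (Vs < 0) stop("negative start volume: k, b, r1 are inconsistent")
  t_size <- if (params$r1 > 0) max(0, (Vs - V0) / params$r1) else {
    if (V0 < Vs) stop("r1 = 0 and V0 < Vs: start is never reached") else 0
  }
  T1 <- if (combiner == "min") min(params$T1min, t_size)
        else max(params$T1min, t_size)
  list(T1 = T1, T2 = params$T2, T3 = params$T3, Vs = Vs, V0 = V0,
       t_start = T1, t_s_entry = T1 + params$T2,
       t_division = T1 + params$T2 + params$T3,
       total = T1 + params$T2 + params$T3)
}

#' Deterministic volume along a cycle
#'
#' Piecewise-linear volume at age `a` (minutes since cycle start): rate `r1`
#' through T1 and T2, rate `r2` through T3.
#'
#' @param cycle a realized cycle from [realize_cycle()].
#' @param params the cell's `cell_cycle_params`.
#' @param a age within the cycle, min (vectorized).
#' @return volume in fL.
#' @export
volume_at_age <- function(cycle, params, a) {
  if (any(a < 0) || any(a > cycle$total + 1e-9))
    stop("age outside the current cycle")
  g1 <- pmin(a, cycle$t_s_entry)
  g2 <- pmax(0, a - cycle$t_s_entry)
  cycle$V0 + params$r1 * g1 + params$r2 * g2
}

#' Grow a cell deterministically through its cycle
#'
#' Advances a cycle position by `dt` minutes, emitting block-boundary events
#' with their exact crossing times so a caller can process them in order.
#' Division ends the advance: any remaining time is reported back via the
#' `remaining` field of the `DIVISION` event.
#'
#' @param position list with `block` (`"T1"`, `"T2"` or `"T3"`), `clock`
#'   (time elapsed within the cycle, min), and the realized `cycle`
#'   (from [realize_cycle()]).
#' @param params the cell's `cell_cycle_params`.
#' @param dt time to advance, min.
#' @return list with `volume`, updated `position`, and `events` — a list of
#'   `list(type, time)` entries (`time` relative to the advance start);
#'   the `DIVISION` event also carries `remaining`.
#' @export
grow <- function(position, params, dt) {
  if (dt < 0) stop("dt must be >= 0")
  cyc <- position$cycle
  t0 <- position$clock
  t1 <- min(t0 + dt, cyc$t_division)
  events <- list()
  add <- function(type, at, ...)
    events[[length(events) + 1L]] <<- c(list(type = type, time = at - t0), list(...))
  if (t0 < cyc$t_start && t1 >= cyc$t_start) add("START_REACHED", cyc$t_start)
  if (t0 < cyc$t_s_entry && t1 >= cyc$t_s_entry) add("S_ENTRY", cyc$t_s_entry)
  if (t0 + dt >= cyc$t_division)
    add("DIVISION", cyc$t_division, remaining = t0 + dt - cyc$t_division)
  block <- if (t1 < cyc$t_start) "T1" else if (t1 < cyc$t_s_entry) "T2" else "T3"
  list(volume = volume_at_age(cyc, params, t1),
       position = list(block = block, clock = t1, cycle = cyc),
       events = events)
}

#' Division geometry
#'
#' Splits the pre-division volume of a cell at the end of T3. The daughter
#' receives the bud, i.e. the S/G2/M growth not attributed to the mother
#' compartment: `V_daughter = (r2 - r2m) * T3`; the mother keeps the rest.
#' Volume is conserved exactly.
#'
#' @param V_total volume at division, fL.
#' @param params the cell's `cell_cycle_params`.
#' @param T3 realized T3 for this cycle (defaults to `params$T3`).
#' @return named numeric vector `c(mother = ..., daughter = ...)`.
#' @export
divide_volume <- function(V_total, params, T3 = params$T3) {
  Vd <- (params$r2 - params$r2m) * T3
  if (Vd <= 0) stop("daughter volume <= 0: r2 must exceed r2m")
  if (Vd >= V_total) stop("daughter volume >= total volume at division")
  c(mother = V_total - Vd, daughter = Vd)
}

# one truncated-normal draw per element: redraw anything negative
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Draw a fresh per-cell parameter set from the population
#'
#' Samples each distributed parameter from its (zero-truncated) normal
#' distribution; the pair (r2, r2m) is redrawn jointly until `r2m < r2` so
#' the bud growth rate stays positive.
#'
#' @param popn a `cycle_population`.
#' @return a `cell_cycle_params` object.
#' @export
draw_cell_params <- function(popn) {
  m <- popn$means; s <- popn$sds
  v <- rnorm_trunc0(length(m), m, s)
  names(v) <- names(m)
  while (v["r2m"] >= v["r2"]) {
    v[c("r2", "r2m")] <- rnorm_trunc0(2, m[c("r2", "r2m")], s[c("r2", "r2m")])
  }
  cell_cycle_params(v["Vi"], v["r1"], v["r2"], v["r2m"], v["T1min"],
                    v["T2"], v["T3"], popn$k, popn$b, popn$c_inherit)
}

#' Parameter inheritance at division
#'
#' A daughter's distributed parameters are a convex mixture of her parent's
#' values and a fresh population draw: `p_daughter = c*p_parent +
#' (1-c)*p_fresh` with `c = c_inherit`. The scalars `k`, `b` and
#' `c_inherit` are copied unchanged.
#'
#' @param parent the parent's `cell_cycle_params`.
#' @param popn the `cycle_population` supplying fresh draws.
#' @return the daughter's `cell_cycle_params`.
#' @export
inherit_params <- function(parent, popn) {
  fresh <- draw_cell_params(popn)
  cc <- popn$c_inherit
  # convex mixture of two valid parameter sets is valid (incl. r2m < r2),
  # so skip re-validation in this hot path
  structure(list(
    Vi = cc * parent$Vi + (1 - cc) * fresh$Vi,
    r1 = cc * parent$r1 + (1 - cc) * fresh$r1,
    r2 = cc * parent$r2 + (1 - cc) * fresh$r2,
    r2m = cc * parent$r2m + (1 - cc) * fresh$r2m,
    T1min = cc * parent$T1min + (1 - cc) * fresh$T1min,
    T2 = cc * parent$T2 + (1 - cc) * fresh$T2,
    T3 = cc * parent$T3 + (1 - cc) * fresh$T3,
    k = popn$k, b = popn$b, c_inherit = cc), class = "cell_cycle_params")
}
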