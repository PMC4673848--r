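---
title: "lineageSSA: model, numerical choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lineageSSA: model, numerical choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineageSSA)
```

## What the package models

`lineageSSA` simulates gene-network activity in single budding-yeast cells
whose volume, cell-cycle stage, and gene dosage change in real time. Two
coupled modules do the work:

1. **A cell growth and division module.** The cycle is split into two
   growth stages (G1 and S/G2/M) and three time blocks. `T1` runs from
   birth to *start*, the size-licensed G1 commitment point; `T2` from
   *start* to S entry; `T3` spans S/G2/M. Volume grows linearly at rate
   `r1` through T1 and T2 and at `r2` through T3. The start size is linear
   in the G1 growth rate, `Vs = k*r1 + b`, so `T1` combines the
   size-threshold time `(Vs - V0)/r1` with a floor `T1min`. Division is
   asymmetric: the daughter receives the bud, whose volume is the S/G2/M
   growth not attributed to the mother compartment, `(r2 - r2m) * T3`.
   Each cell carries its own parameter vector; daughters inherit a
   fraction `c_inherit` of the mother's values mixed with a fresh
   population draw, `p_d = c*p_m + (1-c)*p_fresh`, with `c = 0.25` by
   default.

2. **A stochastic gene-network module.** Every gene (a fluorescent
   reporter `G0` plus network genes `G1..GN`) is a two-state (telegraph)
   promoter with seven reaction channels: activation (`r_act*F`),
   inactivation, basal and full transcription, mRNA decay, translation,
   and protein decay. Concentration-dependent channels carry a `Vref/V`
   factor so that rate constants are expressed at a reference volume. The
   promoter activation rate is modulated by a network-activity function
   `F` in [0, 1] of the regulator concentrations and the inducer. Volume
   growth itself is a stochastic reaction: the volume channel fires at
   (growth rate)/dV and adds a fixed quantum dV. At S entry every
   promoter copy replicates in its current state (active to two active,
   inactive to two inactive); at division mRNA and protein are split
   binomially with p = V_daughter/V_total, and the replicated promoter
   copies are re-assorted one complement to each cell, each copy keeping
   its state.

The simulation is an exact (modified Gillespie) SSA: scheduled cell-cycle
events are interleaved with the chemistry by the next-event-time rule — a
sampled reaction landing past the next scheduled boundary is rejected, the
boundary is processed, and propensities are recomputed. Between divisions
every cell is independent, which the population driver exploits: each
cell's random stream is seeded deterministically from (master seed,
cell id), so results are reproducible regardless of execution order.

## The GAL-network instantiation

The shipped `gal_network()` models the canonical galactose network:
Gal80p represses the master activator; Gal3p (strongly) and Gal1p
(weakly) sequester Gal80p in the presence of galactose, forming dual
positive feedback loops through the GAL1 and GAL3 promoters. The
activity function is

$$F = \frac{1}{1 + \left(\frac{S_{80}\,[\mathrm{Gal80p}]}
 {1 + (S_3\,g\,[\mathrm{Gal3p}] + S_1\,g\,[\mathrm{Gal1p}])^{\alpha}}\right)^{\beta}}$$

with `alpha = 1` and `S80` fixed at 4500: when the activator term is much
larger than one, jointly rescaling `S3`, `S1`, `S80` leaves `F` unchanged,
so only the ratios are identifiable and one scale may be pinned. The
inducer coupling `g` is linear in the galactose concentration (% w/v) by
default, with a saturating alternative (`g = gal/(K+gal)`) available; the
shape of `g` is not derivable from the main-text model, so it is a
configuration choice rather than a claim, and the fitted scales absorb
its units.

Observed, experiment-facing parameters are used throughout: the ON
fraction `f = r_act/(r_act + r_off)` replaces the inactivation rate, the
observed synthesis rate `rm_obs = rm*f + b*rm*(1-f)` replaces the ON-state
rate, and `b_obs*rm_obs = b*rm` replaces the OFF/ON ratio. `derive_rates()`
inverts these relations exactly; a property test checks the round trip to
machine precision. Per-gene fixed rates (synthesis, decay, translation,
basal fractions) are editable literature-anchored defaults chosen to give
basal mRNA counts of order 1 and induced reporter counts of order 10^3;
they are deliberately ordinary numbers, because a fitted conversion
factor between reporter counts and fluorescence absorbs their scale.

## Parameter choices and units

Units are minutes, femtoliters, and per-minute rates everywhere;
concentrations are counts normalized to the reference volume
(`count * Vref / V`), so at `V = Vref` concentration equals count.

The cell-cycle defaults are calibrated, once, to the strain's stated
120-min average doubling time. With the shipped means (`T1min = 36`,
`T2 = 10`, `T3 = 72` min; `r1 = 0.30`, `r2 = 0.61`, `r2m = 0.27` fL/min;
`k = 38` min, `b = 26.1` fL) a daughter is born at
`(r2 - r2m)*T3 ≈ 24.5` fL, below its start size of ~37.5 fL, and needs
~125 min for its first cycle; a mother re-enters T1 above the start size
and cycles in ~118 min. The Euler–Lotka balance
`exp(-λ*118) + exp(-λ*125) = 1` gives a population growth rate
corresponding to an effective doubling time of ~121 min, which reproduces
the reference demography: 1000 cells grow to ~42,000 in 11 h, a 2000-cell
sample to ~84,000 in a further 11 h, and the steady generation census is
~51% newborn and ~24% one-generation-old cells. Per-cell parameters are
drawn from normal distributions with SD = 10% of the mean, truncated at
zero (redrawn when negative, and the `(r2, r2m)` pair redrawn jointly
until `r2m < r2`); extrinsic noise multiplies each of the five process
categories (promoter switching, transcription, translation, mRNA decay,
protein decay) by one Normal(1, 0.10) factor per cell, shared across
genes.

Two ways of combining `T1min` with the size-threshold time are in
circulation for rules of this family: taking their *minimum*, or treating
`T1min` as a *lower bound* (the maximum). The package defaults to the
lower-bound semantics (`t1_combiner = "max"`) — under the minimum reading
the size threshold could never lengthen G1 beyond `T1min`, defeating size
control — and keeps `t1_combiner = "min"` available for the alternative
formula.

Other numerical choices:

- **Volume quantum** `dV = 0.04` fL. The volume channel is Poissonian, so
  the realized volume at division has standard deviation
  `sqrt(growth * dV)`; 0.04 fL keeps that below 2% RMS of the division
  volume while adding only ~10 events/min per cell. The deterministic
  trajectory is recovered as `dV -> 0`.
- **Basal initialization.** Cells start at the deterministic mean-field
  fixed point of their network (damped iteration, relative tolerance
  1e-6, error after 1e4 iterations), counts rounded, promoter states
  drawn Bernoulli from the ON-state occupancy, then scaled by the cell's
  own noise factors. Initial ages are Exponential(120 min) folded into
  each cell's own cycle; the volume follows the deterministic growth
  curve from a fresh birth-volume draw. Cells initialized past S entry
  start with the replicated promoter complement.
- **Division bookkeeping.** The daughter volume uses the cell's realized
  `T3`; molecule conservation at division is exact by construction and
  property-tested over >1000 simulated divisions.
- **First-order decay scaling.** The model's rate list applies `Vref/V`
  to mRNA and protein decay as well; this is the default, with
  `scale_decay = FALSE` giving the conventional volume-independent decay.

## Fluorescence likelihood and fitting

Simulated reporter counts are compared with flow-cytometry data through a
fitted linear conversion: `F_i = c*R_i + B_i` with
`B_i ~ Normal(61, 17)`, the background of an uninduced population.
`log10` fluorescence is histogrammed into the 20 bins
`[0,0.2), ..., [3.8,4)`, area-normalized, and the per-cell pdf is floored
at 1e-4 (also outside the binned range), which bounds the per-cell
log-likelihood between `log(1e-4)` and `log(5)`. Non-positive totals —
possible because the background is Normal — are clamped to 1 fluorescence
unit before the log transform, mimicking an instrument floor; values
above 10^4 are clamped into the top bin. `c` is optimized in log space by
Nelder–Mead; each of `n_restarts` repeats draws one fixed background set,
and the score is the mean of the maximized log-likelihoods (8 repeats by
default at desk scale; the full-scale schedule uses 32 and then 120).
Within a repeat the conversion factor is shared across all conditions
(the per-condition log-likelihoods add).

Network fitting frees nine parameters — `r_act` and `f` for the three
promoter groups (the reporter shares the GAL1 promoter and is tied to
it), plus `S3`, `S1`, `beta` — and maximizes the simulation likelihood by
Nelder–Mead from sweep-selected starting points, `N_R` simulation repeats
per evaluation (each repeat simulates every galactose-by-protocol
condition). Stage budgets are expressed in evaluations, not wall-clock
time, for hardware independence. By default each objective evaluation
reuses the same per-repeat seeds (common random numbers), which makes the
objective deterministic and is what lets small-`N_R` fits converge;
`common_random_numbers = FALSE` gives fresh seeds per evaluation.
Points whose simulated reporter distribution is bimodal (two-component
Gaussian mixture on log counts beating one component by 10 BIC units) are
flagged during the sweep, as seeding metadata only. Full nine-parameter
recovery is explicitly not a supported claim — the likelihood surface is
stochastic and multimodal — but one- and two-dimensional recovery slices
are testable, and the suite recovers a freed `S3` within 20% from
synthetic fixture data at reduced scale (100-cell populations, `N_R = 4`).

## Phenotype analysis

Cells are classified ON when the reporter count (or fluorescence) crosses
a threshold; the default automatic threshold is the midpoint, in log
space, between the two component means of a Gaussian mixture fitted to a
bimodal population. Switching rates are estimated two ways:

- **Dense (simulation-side):** transitions divided by exposure time in
  the originating state, pooled over all cells' classified time series;
  lineage-aware because every cell contributes only its own
  inter-snapshot intervals.
- **Endpoint (experiment-style):** ON fractions of two cultures with
  different histories (pre-grown with and without galactose) at the start
  and end of induction, inverted through the homogeneous two-state
  closed form `f(t) = f_ss + (f0 - f_ss)e^{-(k_on+k_off)t}`. The exact
  published extraction procedure for this design is not reproduced here;
  the standard closed form is used and labeled a stand-in, with a
  1e3/h cap when the histories have fully relaxed and the rate sum is
  unidentifiable.

Because induction makes the true rates time-varying, the endpoint method
is expected to read low; `compare_switching_estimators()` reproduces that
direction on simulated data, and the suite requires the endpoint
OFF-to-ON estimate to undercut the dense one in at least 90% of
replicates.

## What the synthetic-data generator does and does not emulate

`generate_fixtures()` writes flow-cytometry-shaped CSVs (one fluorescence
column per condition and duration, a manifest, and a ground-truth JSON)
by simulating the network at known parameters, resampling final reporter
counts to the requested cell number, and applying the known conversion
factor plus Normal(61, 17) background. Passing fitting tests on these
fixtures shows the machinery recovers parameters *when the model is the
data-generating process*. Real cytometry data additionally contain
autofluorescence structure, gating artifacts, instrument nonlinearity,
and biological effects outside the model (senescence, nutrient shifts,
non-two-state promoter behavior), so fixture recovery bounds, but does
not demonstrate, performance on real data.

## Problem sizes in the shipped tests

The suite runs every quantitative claim at a stated scale: the full
1000-to-84,000-cell demography once; a >10^4-cell generation census;
1.2x10^5 simulated minutes for single-gene stationarity; >10^3 audited
divisions; 20 replicates of 10^4 cells for conversion-factor recovery;
20 paired switching-rate replicates; and one 1-D likelihood fit at
100-cell scale with `N_R = 4`. Full-scale protocols (20,000-cell 5-h
runs, `N_R = 128`) are available through the same interfaces by
configuration.

## Known limitations

- Senescence, replicative aging, and cell death are out of scope; mother
  cells grow without bound, which is acceptable on the ~11-generation
  horizon the protocols cover.
- `F` plug-ins: the engine ships the GAL functional form and a constant
  form; arbitrary user-defined `F` functions would require extending the
  compiled kernel.
- The per-cell trace is recorded for the reporter gene; full-network
  traces can be reconstructed by re-running single cells.
- Population snapshots are taken at protocol boundaries; intermediate
  population composition is reconstructed from the per-cell traces rather
  than from synchronized global snapshots.
- Output formats are CSV/JSON only.
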