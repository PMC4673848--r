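#' Free-parameter table for network fitting
#'
#' The default fit frees the nine promoter/functional-form parameters:
#' `r_act_max` and `f_active` for the three promoter groups (the reporter
#' shares the GAL1 promoter and is tied to it), and `S3`, `S1`, `beta` of
#' the functional form. `S80` stays fixed (only the ratio of the scales
#' matters in the strongly induced regime). Positive scales are optimized
#' in log space, ON fractions on the logit scale.
#'
#' @return data.frame with columns `name`, `type` (`"gene"` or `"ff"`),
#'   `gene`, `field`, `lower`, `upper`, `transform`.
#' @export
default_free_params <- function() {
  data.frame(
    name = c("r_act_GAL1", "f_GAL1", "r_act_GAL3", "f_GAL3",
             "r_act_GAL80", "f_GAL80", "S3", "S1", "beta"),
    type = c(rep("gene", 6), rep("ff", 3)),
    gene = c("GAL1", "GAL1", "GAL3", "GAL3", "GAL80", "GAL80", NA, NA, NA),
    field = c("r_act_max", "f_active", "r_act_max", "f_active",
              "r_act_max", "f_active", "S3", "S1", "beta"),
    lower = c(1e-4, 0.01, 1e-4, 0.01, 1e-4, 0.01, 1e-3, 1e-3, 0.5),
    upper = c(10, 1, 10, 1, 10, 1, 1e6, 1e6, 8),
    transform = c("log", "logit", "log", "logit", "log", "logit",
                  "log", "log", "log"),
    stringsAsFactors = FALSE)
}

# write a named parameter vector into a network_spec, re-applying ties
apply_free_params <- function(spec, free, theta) {
  for (i in seq_len(nrow(free))) {
    v <- theta[[free$name[i]]]
    if (is.null(v) || is.na(v)) next
    if (free$type[i] == "gene") spec$genes[[free$gene[i]]][[free$field[i]]] <- v
    else spec$ff[[free$field[i]]] <- v
  }
  for (tie in spec$tied)
    spec$genes[[tie[1]]][[tie[3]]] <- spec$genes[[tie[2]]][[tie[3]]]
  spec
}

to_unconstrained <- function(free, theta) {
  vapply(seq_len(nrow(free)), function(i) {
    x <- theta[[free$name[i]]]
    if (free$transform[i] == "log") log(x) else stats::qlogis(x)
  }, numeric(1))
}

from_unconstrained <- function(free, z) {
  th <- lapply(seq_len(nrow(free)), function(i) {
    x <- if (free$transform[i] == "log") exp(z[i]) else stats::plogis(z[i])
    min(max(x, free$lower[i]), free$upper[i])
  })
  stats::setNames(th, free$name)
}

#' Fit configuration
#'
#' @param free free-parameter table (default [default_free_params()]); a
#'   subset of rows freezes the remaining parameters at the template's
#'   values.
#' @param conditions data.frame with columns `galactose` (% w/v) and
#'   `protocol` (`"22h"` or `"5h"`): one simulated reporter set per row.
#' @param protocols named list with elements `22h` and `5h`, each a
#'   `protocol_spec`; defaults are desk-scale versions of the full-scale
#'   protocols ([protocol_22h()], [protocol_5h()]).
#' @param N_R simulation repeats per objective evaluation (full scale: 32,
#'   then 128).
#' @param n_fluor_restarts background re-draws inside the fluorescence fit
#'   (full scale: 32, then 120).
#' @param seed master seed.
#' @param common_random_numbers reuse the same per-repeat seeds at every
#'   objective evaluation (variance reduction for the optimizer); `FALSE`
#'   draws fresh seeds per evaluation.
#' @param maxit Nelder-Mead iteration budget.
#' @param sweep_N_R reduced repeat count used during the grid sweep.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(free = default_free_params(),
                       conditions = data.frame(galactose = 0.05,
                                               protocol = c("22h", "5h")),
                       protocols = list(
                         "22h" = protocol_22h(NA, n_initial = 60,
                                              n_sample = 60, t_phase = 240),
                         "5h" = protocol_5h(NA, n_initial = 60,
                                            n_sample = 60, t_phase = 120)),
                       N_R = 4, n_fluor_restarts = 4, seed = 1L,
                       common_random_numbers = TRUE, maxit = 40,
                       sweep_N_R = 1) {
  if (N_R < 1) stop("N_R must be >= 1")
  structure(list(free = free, conditions = conditions, protocols = protocols,
                 N_R = N_R, n_fluor_restarts = n_fluor_restarts, seed = seed,
                 common_random_numbers = common_random_numbers,
                 maxit = maxit, sweep_N_R = sweep_N_R),
            class = "fit_config")
}

# one simulation repeat: reporter counts for every condition row
simulate_conditions <- function(spec, popn, config, seed) {
  lapply(seq_len(nrow(config$conditions)), function(i) {
    gal <- config$conditions$galactose[i]
    proto <- config$protocols[[config$conditions$protocol[i]]]
    proto$gal_post <- gal
    if (proto$id == "22h") proto$gal_pre <- gal
    res <- run_protocol(proto, spec, popn, seed = seed + i * 131L)
    res$snapshot[[paste0("prot_", names(spec$genes)[1])]]
  })
}

#' Score a parameter vector against experimental data
#'
#' Runs `N_R` simulation repeats — each repeat simulates every condition
#' (galactose level x protocol) — converts the reporter counts to a
#' histogram likelihood against the matching experimental sets via
#' [fit_conversion_factor()] (the conversion factor is shared across
#' conditions within a repeat), and returns the mean repeat score.
#'
#' @param theta named list/vector of free-parameter values.
#' @param config a `fit_config`.
#' @param data list of experimental fluorescence vectors, one per row of
#'   `config$conditions`.
#' @param template the `network_spec` holding the frozen parameters.
#' @param popn a `cycle_population`.
#' @param model a `fluorescence_model` (background parameters).
#' @param eval_seed overrides the per-evaluation seed base.
#' @return list with `score` (mean log-likelihood), `c_fluo`, per-repeat
#'   `scores`, and `R_sets` from the last repeat.
#' @export
evaluate_params <- function(theta, config, data, template, popn,
                            model = fluorescence_model(),
                            eval_seed = NULL) {
  spec <- apply_free_params(template, config$free, theta)
  if (is.null(eval_seed))
    eval_seed <- if (config$common_random_numbers) config$seed
                 else sample.int(2^30, 1)
  scores <- rep(NA_real_, config$N_R)
  c_best <- NA_real_
  R_last <- NULL
  for (r in seq_len(config$N_R)) {
    res <- tryCatch({
      R_sets <- simulate_conditions(spec, popn, config,
                                    seed = eval_seed + r * 7919L)
      fl <- fit_conversion_factor(R_sets, data, model,
                                  n_restarts = config$n_fluor_restarts)
      list(score = fl$score, c_fluo = fl$c_fluo, R_sets = R_sets)
    }, error = function(e) {
      warning("simulation repeat ", r, " discarded: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      scores[r] <- res$score
      c_best <- res$c_fluo
      R_last <- res$R_sets
    }
  }
  if (all(is.na(scores))) stop("all simulation repeats failed")
  list(score = mean(scores, na.rm = TRUE), c_fluo = c_best,
       scores = scores, R_sets = R_last)
}

#' Is a count distribution bimodal?
#'
#' A two-component Gaussian mixture on `log10(count + 1)` must beat the
#' one-component fit by `margin` BIC units. Used only to flag sweep
#' starting points, never for scoring.
#'
#' @param counts reporter counts.
#' @param margin BIC margin (default 10).
#' @return logical.
#' @export
is_bimodal <- function(counts, margin = 10) {
  lx <- log10(counts + 1)
  if (length(unique(round(lx, 8))) < 3) return(FALSE)
  b1 <- tryCatch(mclust::Mclust(lx, G = 1, verbose = FALSE)$bic,
                 error = function(e) NA)
  b2 <- tryCatch(mclust::Mclust(lx, G = 2, modelNames = "V",
                                verbose = FALSE)$bic,
                 error = function(e) NA)
  isTRUE(b2 - b1 > margin)
}

#' Sweep a parameter grid for starting points
#'
#' Evaluates the score over an explicit grid (at the reduced `sweep_N_R`)
#' and returns the grid ranked by score, flagging points whose simulated
#' reporter distribution is bimodal.
#'
#' @param grid data.frame, one column per free parameter, one row per
#'   candidate.
#' @param config,data,template,popn,model as in [evaluate_params()].
#' @return the grid with `score` and `bimodal` columns, best first.
#' @export
sweep_params <- function(grid, config, data, template, popn,
                         model = fluorescence_model()) {
  if (!nrow(grid)) stop("empty sweep grid")
  cfg <- config
  cfg$N_R <- config$sweep_N_R
  out <- lapply(seq_len(nrow(grid)), function(i) {
    ev <- evaluate_params(as.list(grid[i, , drop = FALSE]), cfg, data,
                          template, popn, model,
                          eval_seed = config$seed)
    list(score = ev$score,
         bimodal = is_bimodal(ev$R_sets[[1]]))
  })
  grid$score <- vapply(out, `[[`, numeric(1), "score")
  grid$bimodal <- vapply(out, `[[`, logical(1), "bimodal")
  grid[order(-grid$score), , drop = FALSE]
}

#' Per-condition histogram overlays
#'
#' Simulated and experimental log10-fluorescence bin heights side by side,
#' one block per condition — the standard way to inspect a fit.
#'
#' @param R_sets simulated count vectors (one per condition).
#' @param E_sets experimental fluorescence vectors (same length).
#' @param c_fluo conversion factor used for the simulated side.
#' @param model a `fluorescence_model` (background parameters).
#' @param labels optional condition labels.
#' @return data.frame with `condition`, `bin_lo`, `bin_hi`, `sim_height`,
#'   `exp_height` (area-normalized heights over the 20 log10 bins).
#' @export
condition_overlays <- function(R_sets, E_sets, c_fluo,
                               model = fluorescence_model(),
                               labels = NULL) {
  if (!is.list(R_sets)) R_sets <- list(R_sets)
  if (!is.list(E_sets)) E_sets <- list(E_sets)
  if (is.null(labels)) labels <- seq_along(R_sets)
  out <- lapply(seq_along(R_sets), function(i) {
    B <- stats::rnorm(length(R_sets[[i]]), model$mu_b, model$sigma_b)
    sim <- histogram_pdf(pmax(c_fluo * R_sets[[i]] + B, 1))
    exp_ <- histogram_pdf(E_sets[[i]])
    data.frame(condition = labels[i],
               bin_lo = sim$breaks[-21], bin_hi = sim$breaks[-1],
               sim_height = sim$heights, exp_height = exp_$heights)
  })
  do.call(rbind, out)
}

#' Fit the network parameters
#'
#' Nelder-Mead maximization of the simulation likelihood starting from the
#' best sweep point (or the template's values when no grid is given).
#'
#' @param config a `fit_config`.
#' @param data experimental fluorescence sets (one per condition row).
#' @param template `network_spec` with the frozen parameter values.
#' @param popn a `cycle_population`.
#' @param grid optional sweep grid (see [sweep_params()]).
#' @param model a `fluorescence_model`.
#' @return an object of class `fit_result`: list with `par` (best free
#'   parameters), `score`, `c_fluo`, `trajectory` (per-evaluation scores),
#'   `sweep` (ranked grid or `NULL`), `spec` (network at the optimum).
#' @export
fit_network <- function(config, data, template, popn, grid = NULL,
                        model = fluorescence_model()) {
  free <- config$free
  start <- if (!is.null(grid)) {
    sw <- sweep_params(grid, config, data, template, popn, model)
    as.list(sw[1, free$name, drop = FALSE])
  } else {
    stats::setNames(lapply(seq_len(nrow(free)), function(i) {
      if (free$type[i] == "gene") template$genes[[free$gene[i]]][[free$field[i]]]
      else template$ff[[free$field[i]]]
    }), free$name)
  }
  traj <- list()
  obj <- function(z) {
    theta <- from_unconstrained(free, z)
    ev <- evaluate_params(theta, config, data, template, popn, model)
    traj[[length(traj) + 1L]] <<- c(unlist(theta), score = ev$score)
    -ev$score
  }
  opt <- suppressWarnings(
    stats::optim(to_unconstrained(free, start), obj, method = "Nelder-Mead",
                 control = list(maxit = config$maxit, reltol = 1e-4)))
  best <- from_unconstrained(free, opt$par)
  final <- evaluate_params(best, config, data, template, popn, model)
  structure(list(par = best, score = -opt$value, c_fluo = final$c_fluo,
                 trajectory = do.call(rbind, traj),
                 sweep = if (!is.null(grid)) sw else NULL,
                 spec = apply_free_params(template, free, best)),
            class = "fit_result")
}
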