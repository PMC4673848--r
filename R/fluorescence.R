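#' Fluorescence conversion model
#'
#' Linear reporter-count-to-fluorescence conversion plus measured
#' background: a cell with `R` reporter molecules fluoresces at
#' `c_fluo * R + B`, with `B ~ Normal(mu_b, sigma_b)` calibrated on an
#' uninduced population.
#'
#' @param c_fluo conversion factor (fluorescence units per molecule), > 0.
#' @param mu_b,sigma_b background mean and sd (defaults 61, 17).
#' @return an object of class `fluorescence_model`.
#' @export
fluorescence_model <- function(c_fluo = 1, mu_b = 61, sigma_b = 17) {
  if (c_fluo <= 0) stop("c_fluo must be > 0")
  if (sigma_b < 0) stop("sigma_b must be >= 0")
  structure(list(c_fluo = c_fluo, mu_b = mu_b, sigma_b = sigma_b,
                 breaks = seq(0, 4, by = 0.2)),
            class = "fluorescence_model")
}

#' Convert reporter counts to fluorescence
#'
#' `F_i = c_fluo * R_i + B_i` with a fresh background draw per cell.
#' Non-positive totals (possible since the background is Normal) are
#' clamped to 1 fluorescence unit (log10 = 0), mimicking the instrument
#' floor.
#'
#' @param R reporter counts (>= 0).
#' @param model a `fluorescence_model`.
#' @return fluorescence values, same length as `R`.
#' @export
to_fluorescence <- function(R, model) {
  if (any(R < 0)) stop("counts must be >= 0")
  B <- stats::rnorm(length(R), model$mu_b, model$sigma_b)
  pmax(model$c_fluo * R + B, 1)
}

#' Histogram pdf of log10 fluorescence
#'
#' Area-normalized histogram of `log10(F)` over the 20 bins
#' `[0, 0.2), [0.2, 0.4), ..., [3.8, 4)`; lookups return the height of the
#' query's bin, floored at 1e-4 (also for queries outside `[0, 4)`).
#' Values are clamped into the `[1, 1e4)` fluorescence domain before
#' binning.
#'
#' @param F fluorescence values (non-empty).
#' @param floor_value pdf floor (default 1e-4).
#' @return an object of class `histogram_pdf` with fields `heights`,
#'   `breaks`, `floor`; evaluate with [pdf_lookup()].
#' @export
histogram_pdf <- function(F, floor_value = 1e-4) {
  if (!length(F)) stop("F must be non-empty")
  breaks <- seq(0, 4, by = 0.2)
  lf <- pmin(pmax(log10(pmax(F, 1)), 0), 4 - 1e-9)
  h <- graphics::hist(lf, breaks = breaks, plot = FALSE, right = FALSE)
  heights <- h$counts / (length(lf) * 0.2)   # area integrates to 1
  structure(list(heights = heights, breaks = breaks, floor = floor_value),
            class = "histogram_pdf")
}

#' Evaluate a histogram pdf
#'
#' @param pdf a `histogram_pdf`.
#' @param g fluorescence values to score.
#' @return `max(floor, height of the bin containing log10(g))`, the floor
#'   for queries outside `[0, 4)`.
#' @export
pdf_lookup <- function(pdf, g) {
  lg <- log10(pmax(g, .Machine$double.xmin))
  bin <- findInterval(lg, pdf$breaks, rightmost.closed = FALSE)
  out <- rep(pdf$floor, length(g))
  ok <- lg >= 0 & lg < 4
  out[ok] <- pmax(pdf$floor, pdf$heights[bin[ok]])
  out
}

#' Histogram log-likelihood of experimental values
#'
#' Builds the simulated-fluorescence histogram pdf from counts `R` (one
#' fresh background set) and scores the experimental values `E`:
#' `sum(log(pdf(E_i)))`.
#'
#' @param R simulated reporter counts.
#' @param E experimental fluorescence values (non-empty).
#' @param c_fluo conversion factor.
#' @param model a `fluorescence_model` supplying the background; its
#'   `c_fluo` is overridden by the `c_fluo` argument.
#' @param B optional pre-drawn background values (length of `R`); when
#'   supplied no fresh draw is made (fixed-background likelihood).
#' @return the log-likelihood (a scalar).
#' @export
fluorescence_loglik <- function(R, E, c_fluo, model = fluorescence_model(),
                                B = NULL) {
  if (!length(E)) stop("E must be non-empty")
  if (is.null(B)) B <- stats::rnorm(length(R), model$mu_b, model$sigma_b)
  F <- pmax(c_fluo * R + B, 1)
  sum(log(pdf_lookup(histogram_pdf(F), E)))
}

#' Fit the reporter-to-fluorescence conversion factor
#'
#' Maximizes the combined log-likelihood over `c_fluo` with Nelder-Mead in
#' log space. The multi-condition likelihood is the sum of per-condition
#' log-likelihoods. The whole optimization is repeated `n_restarts` times
#' with independent background sets (one fixed set per repeat); the score
#' is the mean of the maximized log-likelihoods, and the reported
#' `c_fluo` is the best repeat's optimum.
#'
#' @param R_sets list of simulated count vectors, one per condition.
#' @param E_sets list of experimental fluorescence vectors, same length.
#' @param model a `fluorescence_model` (background parameters).
#' @param n_restarts independent repeats (default 8; the full-scale
#'   schedule uses 32 then 120).
#' @param c_init starting value for `c_fluo`.
#' @param reltol Nelder-Mead relative tolerance.
#' @return list with `c_fluo`, `score` (mean max log-likelihood),
#'   `logliks` (per repeat), `c_all` (per repeat optima).
#' @export
fit_conversion_factor <- function(R_sets, E_sets,
                                  model = fluorescence_model(),
                                  n_restarts = 8, c_init = 1,
                                  reltol = 1e-6) {
  if (!is.list(R_sets)) R_sets <- list(R_sets)
  if (!is.list(E_sets)) E_sets <- list(E_sets)
  if (length(R_sets) != length(E_sets) || !length(R_sets))
    stop("R_sets and E_sets must be non-empty lists of equal length")
  logliks <- numeric(n_restarts)
  c_all <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    B_sets <- lapply(R_sets, function(R)
      stats::rnorm(length(R), model$mu_b, model$sigma_b))
    neg <- function(logc) {
      -sum(mapply(function(R, E, B)
        fluorescence_loglik(R, E, exp(logc), model, B = B),
        R_sets, E_sets, B_sets))
    }
    opt <- suppressWarnings(stats::optim(log(c_init), neg,
                                         method = "Nelder-Mead",
                                         control = list(reltol = reltol)))
    if (!is.finite(opt$value))
      stop("conversion-factor optimization returned a non-finite score ",
           "(c = ", exp(opt$par), ")")
    logliks[r] <- -opt$value
    c_all[r] <- exp(opt$par)
  }
  best <- which.max(logliks)
  list(c_fluo = c_all[best], score = mean(logliks),
       logliks = logliks, c_all = c_all)
}
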