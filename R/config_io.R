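# ---- configuration schema ------------------------------------------------

config_defaults <- function() {
  popn <- yeast_cycle_population()
  list(
    seed = 1L,
    cell_cycle = list(
      mean = as.list(popn$means), sd = as.list(popn$sds),
      k = popn$k, b = popn$b, c_inherit = popn$c_inherit,
      t1_combiner = popn$t1_combiner),
    network = list(
      Vref = 60, noise_cv = 0.10,
      genes = lapply(gal_network()$genes, function(g)
        g[c("name", "r_act_max", "f_active", "rm_obs", "b_obs",
            "r_p", "d_m", "d_p", "n_promoter")]),
      functional_form = list(S3 = 2e4, S1 = 1e3, S80 = 4500, alpha = 1,
                             beta = 3, g_model = "linear", K = 0.05),
      tied_parameters = list(list("reporter", "GAL1", "r_act_max"),
                             list("reporter", "GAL1", "f_active")),
      regulators = list(gal3 = "GAL3", gal1 = "GAL1", gal80 = "GAL80")),
    protocol = list(id = "22h", galactose = 0.05, n_initial = 1000,
                    t_pre = 660, n_sample = 2000, t_post = 660,
                    snapshot_interval = 0, dV = 0.04, doubling_time = 120,
                    chemistry = TRUE),
    fit = list(N_R = 4, n_fluor_restarts = 8, maxit = 40,
               common_random_numbers = TRUE),
    output = list(dir = ".", traces = FALSE))
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!(k %in% names(defaults)) && !(path %in% c("network.genes",
                                                   "cell_cycle.mean",
                                                   "cell_cycle.sd")))
      stop("unknown configuration key: ",
           if (nzchar(path)) paste0(path, ".", k) else k)
    if (is.list(user[[k]]) && is.list(defaults[[k]]) &&
        !is.null(names(defaults[[k]])) &&
        !(k %in% c("genes", "tied_parameters")))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    if (nzchar(path)) paste0(path, ".", k) else k)
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, rejects unknown keys, fills
#' defaults, and checks cross-references (tied parameters must name
#' defined genes and fields).
#'
#' @param path configuration file.
#' @return an object of class `run_config` (a named list with sections
#'   `cell_cycle`, `network`, `protocol`, `fit`, `output`, and `seed`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
          else yaml::read_yaml(path)
  cfg <- merge_config(config_defaults(), user)
  cfg$network$tied_parameters <-
    lapply(cfg$network$tied_parameters, function(t) as.character(unlist(t)))
  gene_names <- vapply(cfg$network$genes, function(g) g$name, "")
  for (tie in cfg$network$tied_parameters) {
    tie <- unlist(tie)
    missing <- setdiff(tie[1:2], gene_names)
    if (length(missing))
      stop("tied_parameters references undefined gene: ",
           paste(missing, collapse = ", "))
    if (!(tie[3] %in% c("r_act_max", "f_active", "rm_obs", "b_obs",
                        "r_p", "d_m", "d_p")))
      stop("tied_parameters references unknown field: ", tie[3])
  }
  regs <- stats::na.omit(unlist(cfg$network$regulators))
  if (length(setdiff(regs, gene_names)))
    stop("regulators reference undefined gene: ",
         paste(setdiff(regs, gene_names), collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Write a configuration to YAML
#'
#' @param cfg a `run_config`.
#' @param path destination file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param cfg a `run_config`.
#' @return list with `popn` (`cycle_population`), `spec` (`network_spec`)
#'   and `protocol` (`protocol_spec`).
#' @export
config_to_objects <- function(cfg) {
  cc <- cfg$cell_cycle
  popn <- cell_cycle_population(unlist(cc$mean), unlist(cc$sd),
                                k = cc$k, b = cc$b,
                                c_inherit = cc$c_inherit,
                                t1_combiner = cc$t1_combiner)
  nw <- cfg$network
  genes <- lapply(nw$genes, function(g)
    gene_spec(g$name, g$r_act_max, g$f_active, g$rm_obs, g$b_obs,
              g$r_p, g$d_m, g$d_p, g$n_promoter))
  ffc <- nw$functional_form
  ff <- functional_form(ffc$S3, ffc$S1, ffc$S80, ffc$alpha, ffc$beta,
                        ffc$g_model, ffc$K)
  spec <- network_spec(genes, ff, Vref = nw$Vref, noise_cv = nw$noise_cv,
                       regulators = unlist(nw$regulators),
                       tied = lapply(nw$tied_parameters, unlist))
  pc <- cfg$protocol
  proto <- switch(pc$id,
    "22h" = protocol_22h(pc$galactose, pc$n_initial, pc$n_sample, pc$t_pre,
                         pc$snapshot_interval),
    "5h" = protocol_5h(pc$galactose, pc$n_initial, pc$n_sample, pc$t_pre,
                       pc$snapshot_interval),
    protocol_spec(pc$n_initial, pc$t_pre, pc$n_sample, pc$t_post,
                  gal_pre = pc$galactose, gal_post = pc$galactose,
                  snapshot_interval = pc$snapshot_interval))
  list(popn = popn, spec = spec, protocol = proto)
}

# ---- output writers ------------------------------------------------------

#' Write a population snapshot to CSV
#'
#' One row per cell, ordered by `cell_id`; comma-separated, UTF-8, '.'
#' decimal, header row mandatory.
#'
#' @param snapshot a snapshot data.frame.
#' @param path destination file.
#' @export
write_snapshot <- function(snapshot, path) {
  if (!nrow(snapshot)) stop("empty snapshot")
  utils::write.csv(snapshot[order(snapshot$cell_id), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write the lineage log (divisions and traces) to CSV
#'
#' @param result a `protocol_result`.
#' @param dir destination directory (created if missing).
#' @return paths of the written files.
#' @export
write_lineage <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dpath <- file.path(dir, "divisions.csv")
  utils::write.csv(result$divisions, dpath, row.names = FALSE)
  paths <- dpath
  tpath <- file.path(dir, "traces.csv")
  tr <- result$traces
  if (is.null(tr))
    tr <- data.frame(cell_id = integer(0), time = numeric(0),
                     V = numeric(0), mrna0 = numeric(0), prot0 = numeric(0),
                     pr_on0 = numeric(0))
  utils::write.csv(tr[order(tr$cell_id, tr$time), ], tpath, row.names = FALSE)
  c(paths, tpath)
}

#' Write run metadata
#'
#' @param cfg the `run_config` used (or any list).
#' @param seed master seed.
#' @param dir destination directory.
#' @export
write_metadata <- function(cfg, seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = "lineageSSA",
               version = as.character(utils::packageVersion("lineageSSA")),
               seed = seed, config = unclass(cfg),
               r_version = R.version.string)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "metadata.json"))
}

# ---- synthetic fixtures --------------------------------------------------

#' Generate synthetic experimental fixtures
#'
#' Simulates populations at known ground-truth parameters, converts the
#' final reporter counts to fluorescence with a known conversion factor
#' plus Normal background, and writes per-condition CSVs (one `fluorescence`
#' column, one file per condition/duration), a `manifest.csv` mapping
#' (galactose, hours) to files, and a `truth.json` with the ground truth —
#' the same shape as exported flow-cytometry data, for offline testing of
#' the fitting machinery.
#'
#' @param dir output directory.
#' @param conditions data.frame with columns `galactose` and `protocol`
#'   (`"22h"` or `"5h"`).
#' @param spec ground-truth `network_spec`.
#' @param popn `cycle_population`.
#' @param protocols named list of `protocol_spec`s (desk-scale defaults).
#' @param cells_per_condition rows per output CSV (final counts are
#'   resampled with replacement up to this size; >= 100).
#' @param c_fluo_true ground-truth conversion factor.
#' @param mu_b,sigma_b background parameters.
#' @param seed master seed.
#' @return invisibly, the manifest data.frame.
#' @export
generate_fixtures <- function(dir, conditions, spec = gal_network(),
                              popn = yeast_cycle_population(),
                              protocols = list(
                                "22h" = protocol_22h(NA, n_initial = 60,
                                                     n_sample = 60,
                                                     t_phase = 240),
                                "5h" = protocol_5h(NA, n_initial = 60,
                                                   n_sample = 60,
                                                   t_phase = 120)),
                              cells_per_condition = 2000,
                              c_fluo_true = 0.5, mu_b = 61, sigma_b = 17,
                              seed = 1L) {
  if (cells_per_condition < 100) stop("cells_per_condition must be >= 100")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- fluorescence_model(c_fluo_true, mu_b, sigma_b)
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    gal <- conditions$galactose[i]
    pid <- conditions$protocol[i]
    proto <- protocols[[pid]]
    proto$gal_post <- gal
    if (proto$id == "22h") proto$gal_pre <- gal
    res <- run_protocol(proto, spec, popn, seed = seed + i * 977L)
    counts <- res$snapshot[[paste0("prot_", names(spec$genes)[1])]]
    set.seed(seed + i * 977L + 1L)
    R <- sample(counts, cells_per_condition, replace = TRUE)
    fl <- to_fluorescence(R, model)
    hours <- if (pid == "22h") 22 else 5
    fname <- sprintf("fluor_gal%s_%dh.csv", format(gal), hours)
    utils::write.csv(data.frame(fluorescence = fl), file.path(dir, fname),
                     row.names = FALSE)
    rows[[i]] <- data.frame(galactose = gal, hours = hours,
                            protocol = pid, file = fname)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  truth <- list(c_fluo = c_fluo_true, mu_b = mu_b, sigma_b = sigma_b,
                seed = seed,
                free_params = list(
                  r_act_GAL1 = spec$genes$GAL1$r_act_max,
                  f_GAL1 = spec$genes$GAL1$f_active,
                  r_act_GAL3 = spec$genes$GAL3$r_act_max,
                  f_GAL3 = spec$genes$GAL3$f_active,
                  r_act_GAL80 = spec$genes$GAL80$r_act_max,
                  f_GAL80 = spec$genes$GAL80$f_active,
                  S3 = spec$ff$S3, S1 = spec$ff$S1, beta = spec$ff$beta))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read fixture (or experimental) fluorescence sets
#'
#' @param dir directory containing `manifest.csv` and the per-condition
#'   CSVs.
#' @return list with `manifest` and `E_sets` (one numeric vector per
#'   manifest row).
#' @export
read_fluorescence_data <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  E_sets <- lapply(manifest$file, function(f)
    utils::read.csv(file.path(dir, f))$fluorescence)
  list(manifest = manifest, E_sets = E_sets)
}
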