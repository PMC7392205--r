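## Reproducible experiment protocols: one canonical protocol per headline
## analysis, a config object, output manifests and test fixtures.

.th_experiments <- c("fig2", "fig3", "fig4", "fig5", "fig6", "s2fig",
                     "sensitivity")

#' Experiment configuration
#'
#' @param experiment one of `"fig2"` (in-vitro balance distributions and the
#'   secretion bifurcation), `"fig3"` (in-vitro mean dynamics), `"fig4"`
#'   (quorum bifurcation and scale decomposition), `"fig5"` (APC sparking
#'   and reversal windows), `"fig6"` (discernment volatility grids),
#'   `"s2fig"` (tunable transients and long-run convergence), or
#'   `"sensitivity"` (regime robustness and effect sizes).
#' @param out_dir output directory (created if missing).
#' @param seed master seed; required for the stochastic experiments.
#' @param param_file optional parameter JSON ([read_parameters()]); the
#'   calibrated default set is used when `NULL`.
#' @param overrides named list of parameter overrides applied on top.
#' @param scale `"desk"` (reduced Monte-Carlo breadth) or `"paper"`
#'   (full path/schedule counts).  Breadth is the only difference: time
#'   steps, horizons and densities are identical.
#' @return an object of class `th_config`.
#' @export
experiment_config <- function(experiment, out_dir, seed = NULL,
                              param_file = NULL, overrides = list(),
                              scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  if (!experiment %in% .th_experiments) {
    stop("unknown experiment '", experiment, "'; choose one of: ",
         paste(.th_experiments, collapse = ", "))
  }
  stochastic <- experiment %in% c("fig2", "fig3", "fig6", "sensitivity")
  if (stochastic && is.null(seed)) {
    stop("experiment '", experiment, "' is stochastic; a seed is required")
  }
  structure(list(experiment = experiment, out_dir = out_dir,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 param_file = param_file, overrides = overrides,
                 scale = scale),
            class = "th_config")
}

config_parameters <- function(config) {
  par <- if (is.null(config$param_file)) {
    model_parameters()
  } else {
    if (!file.exists(config$param_file)) {
      stop("parameter file not found: ", config$param_file)
    }
    read_parameters(config$param_file)
  }
  if (length(config$overrides) > 0L) {
    p <- unclass(par)
    for (f in names(config$overrides)) {
      if (!f %in% .th_param_fields) stop("unknown override key '", f, "'")
      p[[f]] <- config$overrides[[f]]
    }
    par <- validate_parameters(p)
  }
  par
}

write_hist_csv <- function(dist, path) {
  nb <- length(dist$counts)
  utils::write.csv(
    data.frame(bin_left = dist$breaks[-(nb + 1L)],
               bin_right = dist$breaks[-1L], count = dist$counts),
    path, row.names = FALSE)
  path
}

#' Run a canonical experiment protocol
#'
#' Executes the protocol selected by the config at its canonical densities
#' and horizons, writes CSV outputs under the config's output directory, and
#' returns (and writes) a manifest listing every output file with an MD5
#' content hash.  The mapping from `(config, seed)` to outputs is
#' deterministic.
#'
#' @param config an [experiment_config()].
#' @return invisibly, the manifest (list with `experiment`, `seed`,
#'   `scale`, `files` with their hashes); also written as `manifest.json`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "th_config"))
  par <- config_parameters(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  desk <- config$scale == "desk"
  files <- character(0)
  seed <- config$seed

  if (config$experiment == "fig2") {
    n_paths <- if (desk) 100 else 1000
    for (cond in c("on", "off")) {
      ens <- run_ensemble(n_paths, system_state(1, 1, 0, 0), par, 2e6,
                          secretion_scale = if (cond == "on") 1 else 0,
                          t_max = 168, master_seed = seed + (cond == "off"))
      dist <- balance_distribution(ens, 168)
      files <- c(files, write_hist_csv(
        dist, out(sprintf("fig2_theta_secretion_%s_hist.csv", cond))))
    }
    scan <- secretion_bifurcation_scan(par, 2e6)
    utils::write.csv(scan$summary, out("fig2_secretion_bifurcation.csv"),
                     row.names = FALSE)
    files <- c(files, out("fig2_secretion_bifurcation.csv"))
  } else if (config$experiment == "fig3") {
    n_paths <- if (desk) 100 else 1000
    ens <- run_ensemble(n_paths, system_state(1, 1, 0, 0), par, 2e6,
                        t_max = 168, master_seed = seed)
    utils::write.csv(ensemble_summary(ens), out("fig3_sde_summary.csv"),
                     row.names = FALSE)
    ode <- integrate_ode(system_state(1, 1, 0, 0), par, 2e6, t_max = 168)
    write_trajectory(ode, out("fig3_ode_trajectory.csv"))
    files <- c(files, out("fig3_sde_summary.csv"),
               out("fig3_ode_trajectory.csv"),
               out("fig3_ode_trajectory.csv.json"))
  } else if (config$experiment == "fig4") {
    rows <- list()
    for (rho in c(1e6, 2e6, 1e7, 1e8, 1e9)) {
      eq <- find_equilibria(par, rho)
      rows[[length(rows) + 1L]] <- cbind(rho = rho, as.data.frame(eq))
    }
    utils::write.csv(do.call(rbind, rows), out("fig4_equilibria.csv"),
                     row.names = FALSE)
    qd <- quorum_density(par)
    dec <- lapply(c(low = 2e6, high = 1e9), function(rho) {
      ctx <- apply_density(par, rho)
      st <- mixed_equilibrium(par, ctx)
      scale_decomposition(par, ctx, st)
    })
    utils::write.csv(
      data.frame(quantity = c("quorum_density_cells_per_ml",
                              "production_removal_ratio",
                              "cy_tf_ratio",
                              "within_effect_low", "cross_effect_low",
                              "within_effect_high", "cross_effect_high"),
                 value = c(qd$rho_crit, qd$production_removal_ratio,
                           qd$cy_tf_ratio,
                           dec$low$within, dec$low$cross,
                           dec$high$within, dec$high$cross)),
      out("fig4_quorum.csv"), row.names = FALSE)
    files <- c(files, out("fig4_equilibria.csv"), out("fig4_quorum.csv"))
  } else if (config$experiment == "fig5") {
    biases <- c(0.6, 0.75, 0.9)
    counts <- c(10, 100)
    rows <- list()
    for (n_apc in counts) {
      for (b in biases) {
        rw <- reversal_window(
          par, 1e9,
          apc_constants(b * n_apc, (1 - b) * n_apc, par),
          apc_constants(0, 1000, par))
        rows[[length(rows) + 1L]] <- data.frame(
          n_apc = n_apc, bias = b, window_h = rw$window,
          baseline_label = rw$baseline_label)
      }
    }
    utils::write.csv(do.call(rbind, rows), out("fig5_windows.csv"),
                     row.names = FALSE)
    tr <- integrate_ode(system_state(1, 1, 0, 0), par, 1e9,
                        apc = apc_constants(6, 4, par), t_max = 500)
    write_trajectory(tr, out("fig5a_sparking_trajectory.csv"))
    files <- c(files, out("fig5_windows.csv"),
               out("fig5a_sparking_trajectory.csv"),
               out("fig5a_sparking_trajectory.csv.json"))
  } else if (config$experiment == "fig6") {
    n_tc <- if (desk) 20 else 200
    n_p <- if (desk) 20 else 100
    ## 1-D scan: equal volatility on all four components
    vols <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)
    grid1 <- do.call(rbind, lapply(vols, function(v) {
      performance_grid(par, n_tf_grid = v, n_cy_grid = v,
                       n_timecourses = n_tc, n_paths = n_p,
                       master_seed = seed)
    }))
    utils::write.csv(grid1, out("fig6e_volatility_scan.csv"),
                     row.names = FALSE)
    grid2 <- performance_grid(par, n_tf_grid = c(0.02, 0.1, 0.4),
                              n_cy_grid = c(0.02, 0.1, 0.4),
                              n_timecourses = n_tc, n_paths = n_p,
                              master_seed = seed)
    utils::write.csv(grid2, out("fig6f_volatility_grid.csv"),
                     row.names = FALSE)
    files <- c(files, out("fig6e_volatility_scan.csv"),
               out("fig6f_volatility_grid.csv"))
  } else if (config$experiment == "s2fig") {
    stim <- expand.grid(CY1 = c(0, 1, 4), CY2 = c(0, 1, 4))
    rows <- list()
    for (i in seq_len(nrow(stim))) {
      tr <- integrate_ode(system_state(1, 1, stim$CY1[i], stim$CY2[i]),
                          par, 2e6, t_max = 24 * 7 * 10, t_step = 24)
      idx <- c(which(tr$time == 168), length(tr$time))
      rows[[i]] <- data.frame(
        CY1_0 = stim$CY1[i], CY2_0 = stim$CY2[i],
        when = c("week1", "week10"),
        TF1 = tr$states[idx, 1], TF2 = tr$states[idx, 2],
        theta = balance_index(tr$states[idx, 1], tr$states[idx, 2]))
    }
    utils::write.csv(do.call(rbind, rows), out("s2fig_convergence.csv"),
                     row.names = FALSE)
    files <- c(files, out("s2fig_convergence.csv"))
  } else if (config$experiment == "sensitivity") {
    n <- if (desk) 100 else 500
    low <- regime_scan(par, 2e6, amps = seq(0.1, 0.9, by = 0.2), n = n,
                       seed = seed)
    high <- regime_scan(par, 1e9, amps = c(0.1, 0.3, 0.5), n = n,
                        seed = seed + 1L)
    utils::write.csv(rbind(cbind(point = "low", low$table),
                           cbind(point = "high", high$table)),
                     out("sensitivity_regimes.csv"), row.names = FALSE)
    eff <- effect_sizes(par, 2e6, n = if (desk) 200 else 1000,
                        seed = seed + 2L)
    utils::write.csv(eff$effects, out("sensitivity_effect_sizes.csv"),
                     row.names = FALSE)
    files <- c(files, out("sensitivity_regimes.csv"),
               out("sensitivity_effect_sizes.csv"))
  }

  manifest <- list(
    experiment = config$experiment, seed = seed, scale = config$scale,
    files = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write small bundled fixtures
#'
#' Writes, under `dir`: the default calibrated parameter file
#' (`params_default.json`), three APC schedules (constant, transient switch,
#' sustained switch), and a 10-path mini-ensemble CSV with its summary —
#' all seeded and reproducible.
#'
#' @param seed integer seed for the mini-ensemble.
#' @param dir output directory.
#' @return character vector of the files written, invisibly.
#' @export
make_fixtures <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  par <- model_parameters()
  files <- file.path(dir, c("params_default.json", "schedule_constant.csv",
                            "schedule_transient.csv",
                            "schedule_sustained.csv",
                            "mini_ensemble.csv", "mini_ensemble_summary.csv"))
  write_parameters(par, files[1])
  k <- par$kappa_apc
  write_schedule(apc_schedule(0, 6 * k, 4 * k), files[2])
  ## transient: complete Th2 excursion far shorter than any sensitivity
  write_schedule(apc_schedule(c(0, 100, 110), c(10 * k, 0, 10 * k),
                              c(0, 10 * k, 0)), files[3])
  ## sustained: complete switch held to the end of the horizon
  write_schedule(apc_schedule(c(0, 100), c(10 * k, 0), c(0, 10 * k)),
                 files[4])
  ens <- run_ensemble(10, system_state(1, 1, 0, 0), par, 2e6, t_max = 24,
                      master_seed = seed)
  write_ensemble(ens, files[5], summary_path = files[6])
  invisible(files)
}
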