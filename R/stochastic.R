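## Stochastic simulation: Euler-Maruyama paths, ensembles, and
## distributional summaries of the Th1/Th2 balance.

#' Simulate one stochastic sample path
#'
#' Euler-Maruyama discretization of the stochastic model in natural
#' coordinates: `x <- x + drift*dt + diffusion*sqrt(dt)*xi` with independent
#' standard normal `xi` per component per step, and clamping at zero (the
#' multiplicative noise amplitude vanishes at zero, so zero is the natural
#' boundary).  All randomness is drawn from R's RNG under `seed`, so an
#' identical seed yields an identical path.
#'
#' @inheritParams integrate_ode
#' @param dt Euler-Maruyama step (hours); the default 0.01 h resolves the
#'   fastest cytokine turnover at in-vivo density.
#' @param seed integer seed for this path.
#' @param record_every record the state every this many steps.
#' @return a `th_trajectory` (see [integrate_ode()]) with the seed recorded
#'   in its metadata.
#' @examples
#' par <- model_parameters()
#' tr <- simulate_sde(system_state(1, 1, 0, 0), par, rho = 2e6,
#'                    t_max = 24, seed = 1)
#' @export
simulate_sde <- function(initial, par, rho, apc = apc_instruction(),
                         secretion_scale = 1, t_max, dt = 0.01, seed,
                         record_every = max(1L, round(1 / dt))) {
  check_state(initial)
  stopifnot(inherits(par, "th_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  ctx <- apply_density(par, rho)
  sched <- as_schedule(apc)
  n_steps <- round(t_max / dt)
  if (abs(n_steps * dt - t_max) > 1e-9 * t_max) {
    n_steps <- ceiling(t_max / dt)
  }
  record_every <- as.integer(record_every)
  if (n_steps %% record_every != 0L) {
    stop("t_max / dt must be a multiple of record_every")
  }
  nvol <- c(par$n_TF1, par$n_TF2, par$n_CY1, par$n_CY2)
  noisy <- any(nvol > 0)
  set.seed(as.integer(seed))
  noise <- if (noisy) {
    matrix(stats::rnorm(n_steps * 4L), n_steps, 4L)
  } else {
    matrix(numeric(0), 0, 4)
  }
  res <- em_path_cpp(unname(initial), as_param_vector(par),
                     ctx$a1, ctx$a2, ctx$dCY1, ctx$dCY2,
                     schedule_matrix(sched), secretion_scale,
                     dt, n_steps, record_every, noise, nvol)
  if (isTRUE(res$exploded)) {
    stop(sprintf(
      "Euler-Maruyama step diverged at t = %.4g h; use a smaller dt",
      res$step * dt))
  }
  time <- seq(0, by = dt * record_every, length.out = nrow(res$states))
  tr <- new_trajectory(time, res$states, rho, secretion_scale, sched,
                       seed = as.integer(seed))
  tr
}

#' Simulate an ensemble of stochastic sample paths
#'
#' Runs `n_paths` independent Euler-Maruyama paths on a common time grid.
#' Per-path seeds are drawn reproducibly from `master_seed`, so the whole
#' ensemble is a deterministic function of its arguments.
#'
#' @inheritParams simulate_sde
#' @param n_paths number of sample paths (>= 1).
#' @param master_seed integer master seed.
#' @return a `th_ensemble`: list with `time`, `states`
#'   (array `time x component x path`), `seeds`, `master_seed` and run
#'   metadata.
#' @export
run_ensemble <- function(n_paths, initial, par, rho,
                         apc = apc_instruction(), secretion_scale = 1,
                         t_max, dt = 0.01, master_seed,
                         record_every = max(1L, round(1 / dt))) {
  if (n_paths < 1) stop("n_paths must be >= 1")
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_paths)
  paths <- vector("list", n_paths)
  for (i in seq_len(n_paths)) {
    paths[[i]] <- simulate_sde(initial, par, rho, apc, secretion_scale,
                               t_max, dt, seed = seeds[i],
                               record_every = record_every)
  }
  time <- paths[[1]]$time
  states <- array(NA_real_,
                  dim = c(length(time), 4L, n_paths),
                  dimnames = list(NULL, .th_state_names, NULL))
  for (i in seq_len(n_paths)) states[, , i] <- paths[[i]]$states
  structure(list(time = time, states = states, seeds = seeds,
                 master_seed = as.integer(master_seed), rho = rho,
                 secretion_scale = secretion_scale,
                 schedule = paths[[1]]$schedule,
                 noise = c(n_TF1 = par$n_TF1, n_TF2 = par$n_TF2,
                           n_CY1 = par$n_CY1, n_CY2 = par$n_CY2)),
            class = "th_ensemble")
}

#' @export
print.th_ensemble <- function(x, ...) {
  cat(sprintf(
    "Th ensemble: %d paths x %d time points over %.4g h at rho = %.3g cells/mL (master seed %d)\n",
    dim(x$states)[3], length(x$time), max(x$time), x$rho, x$master_seed))
  invisible(x)
}

#' Distribution of the Th1/Th2 balance across an ensemble
#'
#' Computes the balance index `theta = TF1/(TF1+TF2)` of every path at an
#' evaluation time, histograms it on `n_bins` equal bins over \[0, 1\], and
#' labels the shape with a fixed rule: *U-shaped* when the two outer bins
#' each hold more than twice the mean inner-bin mass and the two middle bins
#' each hold at most half of it; *uniform* when the max/min bin-mass ratio
#' is below 3; *unimodal-central* when neither holds and the fullest bin is
#' central; otherwise *other*.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param t_eval evaluation time; must lie on the ensemble grid.
#' @param n_bins number of histogram bins (default 10, the bin count the
#'   shape rule is stated for).
#' @return list with `t_eval`, `theta` (per path), `breaks`, `counts`,
#'   `shape`.
#' @export
balance_distribution <- function(ensemble, t_eval, n_bins = 10) {
  stopifnot(inherits(ensemble, "th_ensemble"))
  idx <- which(abs(ensemble$time - t_eval) < 1e-9 * max(1, t_eval))
  if (length(idx) != 1L) {
    stop("t_eval = ", t_eval, " h is not on the ensemble time grid")
  }
  theta <- balance_index(ensemble$states[idx, 1, ],
                         ensemble$states[idx, 2, ])
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(theta, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  inner <- counts[2:(n_bins - 1L)]
  mid <- counts[c(n_bins %/% 2, n_bins %/% 2 + 1L)]
  inner_mean <- mean(inner)
  shape <- if (counts[1] > 2 * inner_mean && counts[n_bins] > 2 * inner_mean &&
               all(mid <= inner_mean / 2)) {
    "U-shaped"
  } else if (min(counts) > 0 && max(counts) / min(counts) < 3) {
    "uniform"
  } else if (which.max(counts) %in% seq(n_bins %/% 2 - 1L,
                                        n_bins %/% 2 + 2L)) {
    "unimodal-central"
  } else {
    "other"
  }
  list(t_eval = t_eval, theta = theta, breaks = breaks, counts = counts,
       shape = shape)
}

#' Per-time summary statistics of an ensemble
#'
#' @param ensemble a [run_ensemble()] result.
#' @return data frame with, per time point and state variable, the mean,
#'   median and interquartile bounds (columns `<var>_mean`, `<var>_median`,
#'   `<var>_q25`, `<var>_q75`).
#' @export
ensemble_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "th_ensemble"))
  if (dim(ensemble$states)[3] < 1L) stop("empty ensemble")
  out <- data.frame(time_h = ensemble$time)
  for (k in 1:4) {
    v <- .th_state_names[k]
    m <- ensemble$states[, k, , drop = FALSE]
    dim(m) <- c(length(ensemble$time), dim(ensemble$states)[3])
    out[[paste0(v, "_mean")]] <- rowMeans(m)
    qs <- apply(m, 1, stats::quantile, probs = c(0.25, 0.5, 0.75),
                names = FALSE)
    out[[paste0(v, "_median")]] <- qs[2, ]
    out[[paste0(v, "_q25")]] <- qs[1, ]
    out[[paste0(v, "_q75")]] <- qs[3, ]
  }
  out
}

#' Write an ensemble to CSV
#'
#' Long format: `path_id, time_h, TF1, TF2, CY1, CY2`, plus (optionally) a
#' per-time summary CSV.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param path output CSV path.
#' @param summary_path optional path for the [ensemble_summary()] CSV.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, summary_path = NULL) {
  stopifnot(inherits(ensemble, "th_ensemble"))
  n_path <- dim(ensemble$states)[3]
  n_time <- length(ensemble$time)
  long <- data.frame(
    path_id = rep(seq_len(n_path), each = n_time),
    time_h = rep(ensemble$time, n_path),
    TF1 = as.vector(ensemble$states[, 1, ]),
    TF2 = as.vector(ensemble$states[, 2, ]),
    CY1 = as.vector(ensemble$states[, 3, ]),
    CY2 = as.vector(ensemble$states[, 4, ]))
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    utils::write.csv(ensemble_summary(ensemble), summary_path,
                     row.names = FALSE)
  }
  invisible(path)
}
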