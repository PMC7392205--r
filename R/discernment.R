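## Time-varying APC instruction, the optimal-response construction, tracking
## performance, and the volatility-grid discernment experiments.

#' Piecewise-constant APC instruction schedule
#'
#' @param t_start strictly increasing segment start times (hours); the first
#'   must be 0.  Each segment extends to the next start time (the last to the
#'   end of whatever horizon the schedule is used with).
#' @param APC1,APC2 non-negative per-segment instruction constants
#'   (concentration units).
#' @return an object of class `th_schedule`.
#' @seealso [apc_at()], [schedule_bias()], [random_apc_timecourse()]
#' @export
apc_schedule <- function(t_start, APC1, APC2) {
  if (length(t_start) != length(APC1) || length(t_start) != length(APC2)) {
    stop("t_start, APC1 and APC2 must have equal length")
  }
  if (t_start[1] != 0) stop("the first segment must start at t = 0")
  if (length(t_start) > 1L && any(diff(t_start) <= 0)) {
    stop("segment start times must be strictly increasing")
  }
  if (any(APC1 < 0) || any(APC2 < 0)) {
    stop("APC constants must be non-negative")
  }
  structure(list(t_start = as.numeric(t_start), APC1 = as.numeric(APC1),
                 APC2 = as.numeric(APC2)),
            class = "th_schedule")
}

#' @export
print.th_schedule <- function(x, ...) {
  cat(sprintf("APC schedule with %d segment(s):\n", length(x$t_start)))
  print(data.frame(t_start_h = x$t_start, APC1 = x$APC1, APC2 = x$APC2))
  invisible(x)
}

#' Evaluate a schedule at a time point
#'
#' @param sched a [apc_schedule()].
#' @param t time (hours).
#' @return numeric `(APC1, APC2)` active at `t`.
#' @export
apc_at <- function(sched, t) {
  stopifnot(inherits(sched, "th_schedule"))
  i <- findInterval(t, sched$t_start, rightmost.closed = FALSE)
  i <- max(i, 1L)
  c(APC1 = sched$APC1[i], APC2 = sched$APC2[i])
}

#' Instruction bias fraction of a schedule
#'
#' The bias `beta(t) = APC1 / (APC1 + APC2)` (0.5 where both are zero).
#'
#' @inheritParams apc_at
#' @return bias fraction in \[0, 1\] at `t`.
#' @export
schedule_bias <- function(sched, t) {
  v <- apc_at(sched, t)
  if (sum(v) == 0) 0.5 else unname(v[1] / sum(v))
}

## truncate a schedule to [0, horizon)
schedule_window <- function(sched, horizon) {
  keep <- sched$t_start < horizon
  apc_schedule(sched$t_start[keep], sched$APC1[keep], sched$APC2[keep])
}

#' Write / read an APC schedule as CSV
#'
#' Columns `t_start_h, apc1, apc2`.
#'
#' @param sched a [apc_schedule()].
#' @param path CSV path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `th_schedule`.
#' @export
write_schedule <- function(sched, path) {
  stopifnot(inherits(sched, "th_schedule"))
  utils::write.csv(data.frame(t_start_h = sched$t_start, apc1 = sched$APC1,
                              apc2 = sched$APC2),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  apc_schedule(df$t_start_h, df$apc1, df$apc2)
}

#' Randomly generate an APC instruction time-course
#'
#' Draws a piecewise-constant schedule of the kind used in the discernment
#' experiments: 1-6 segments whose durations are log-uniform on
#' \[10, 250\] h (the last segment extended to the horizon), each with a
#' Th1-bias fraction drawn from `bias_values` at a fixed total instruction
#' strength.  Such collections contain sporadic (shorter than a sensitivity
#' duration) and sustained complete switches as well as incomplete ones.
#'
#' @param seed integer seed.
#' @param horizon schedule horizon (hours).
#' @param total total APC instruction strength `APC1 + APC2`
#'   (concentration units).
#' @param n_segments range (length-2) of segment counts to draw from.
#' @param duration_range log-uniform segment-duration range (hours).
#' @param bias_values candidate Th1-bias fractions per segment.
#' @return a `th_schedule`.
#' @export
random_apc_timecourse <- function(seed, horizon = 500, total = 1,
                                  n_segments = c(1, 6),
                                  duration_range = c(10, 250),
                                  bias_values = c(0, 0.25, 0.4, 0.6,
                                                  0.75, 1)) {
  if (horizon <= 0) stop("horizon must be positive")
  if (any(duration_range <= 0)) stop("durations must be positive")
  set.seed(as.integer(seed))
  k <- sample(seq(n_segments[1], n_segments[2]), 1L)
  dur <- exp(stats::runif(k, log(duration_range[1]), log(duration_range[2])))
  starts <- c(0, cumsum(dur[-k]))
  keep <- starts < horizon
  starts <- starts[keep]
  bias <- sample(bias_values, length(starts), replace = TRUE)
  apc_schedule(starts, total * bias, total * (1 - bias))
}

#' Theoretically optimal response to an instruction time-course
#'
#' The target effector label starts on the side of the initial majority
#' bias and switches only when the schedule holds a *complete* (100%)
#' opposite bias *continuously* for at least the sensitivity duration `tau`;
#' the switch takes effect at the moment the criterion is met.  Sporadic
#' (shorter than `tau`) or incomplete excursions leave the target unchanged.
#'
#' @param sched a [apc_schedule()].
#' @param tau sensitivity duration (hours): how long a complete change must
#'   last to count as sustained.
#' @param horizon horizon over which the target is defined (hours).
#' @return an object of class `th_optimal`: list with `t_start` (label
#'   change times), `label` (per interval, `"Th1"`/`"Th2"`), and `tau`.
#' @export
optimal_response <- function(sched, tau, horizon = 500) {
  stopifnot(inherits(sched, "th_schedule"))
  if (tau <= 0) stop("tau must be positive")
  if (all(sched$APC1 + sched$APC2 == 0)) {
    stop("schedule has zero total APC instruction everywhere; no target defined")
  }
  n <- length(sched$t_start)
  t_end <- c(sched$t_start[-1], max(horizon, sched$t_start[n] + tau))
  bias <- ifelse(sched$APC1 + sched$APC2 > 0,
                 sched$APC1 / (sched$APC1 + sched$APC2), 0.5)
  ## initial side: first segment with a strict majority
  first_major <- which(bias != 0.5)[1]
  if (is.na(first_major)) stop("schedule never holds a majority bias")
  label <- if (bias[first_major] > 0.5) "Th1" else "Th2"
  out_t <- 0
  out_lab <- label
  run_start <- NA_real_   # start of the current complete-opposite run
  for (i in seq_len(n)) {
    opp <- (label == "Th1" && bias[i] == 0) ||
           (label == "Th2" && bias[i] == 1)
    if (opp) {
      if (is.na(run_start)) run_start <- sched$t_start[i]
      if (t_end[i] - run_start >= tau) {
        label <- if (label == "Th1") "Th2" else "Th1"
        out_t <- c(out_t, run_start + tau)
        out_lab <- c(out_lab, label)
        run_start <- NA_real_
        ## the remainder of this run cannot re-switch (same side as target)
      }
    } else {
      run_start <- NA_real_
    }
  }
  structure(list(t_start = out_t, label = out_lab, tau = tau,
                 horizon = horizon),
            class = "th_optimal")
}

optimal_label_at <- function(opt, t) {
  i <- pmax(findInterval(t, opt$t_start), 1L)
  opt$label[i]
}

#' Tracking performance of an ensemble against the optimal response
#'
#' Per path, the score is the fraction of evaluation times at which the
#' path's attractor label (from the balance index, see
#' [classify_attractor()]) agrees with the optimal target label; times at
#' which the path is mixed count as disagreement with any target.  The
#' pooled score is the mean over paths.  Higher is better; scores lie in
#' \[0, 1\].
#'
#' @param ensemble a [run_ensemble()] result simulated under the same
#'   schedule and horizon as `optimal`.
#' @param optimal an [optimal_response()] object.
#' @param t_min scoring starts at this time (hours); the default skips the
#'   initial sparking transient before any commitment exists.
#' @return list with `per_path` scores and the `pooled` mean score.
#' @export
tracking_performance <- function(ensemble, optimal, t_min = 0) {
  stopifnot(inherits(ensemble, "th_ensemble"),
            inherits(optimal, "th_optimal"))
  n_paths <- dim(ensemble$states)[3]
  if (n_paths < 1L) stop("empty ensemble")
  use <- ensemble$time >= t_min
  tt <- ensemble$time[use]
  target <- optimal_label_at(optimal, tt)
  per_path <- numeric(n_paths)
  for (i in seq_len(n_paths)) {
    lab <- classify_attractor(ensemble$states[use, 1, i],
                              ensemble$states[use, 2, i])
    per_path[i] <- mean(lab == target)
  }
  list(per_path = per_path, pooled = mean(per_path))
}

#' Discernment performance over a volatility grid
#'
#' For every `(n_TF, n_CY)` volatility pair the mean tracking performance is
#' measured over `n_timecourses` random instruction schedules times
#' `n_paths` stochastic paths at in-vivo density, for each sensitivity
#' duration in `tau`.  Relative performance divides each cell mean by the
#' best cell mean for that sensitivity, so exactly one cell scores 1.
#'
#' @param par a [model_parameters()] object (its noise fields are
#'   overridden cell by cell).
#' @param n_tf_grid,n_cy_grid volatility grids for transcription factors and
#'   cytokines; cells are the cross product.
#' @param tau sensitivity durations (hours).
#' @param n_timecourses,n_paths Monte-Carlo breadth.
#' @param master_seed integer master seed; schedules and paths derive from
#'   it reproducibly.
#' @param rho cell density (default in-vivo).
#' @param horizon schedule/simulation horizon (hours).
#' @param total total APC instruction strength of the generated schedules;
#'   the default is the late-infection APC frequency of the reversal
#'   scenario (1000 APCs), the regime in which instruction competes with an
#'   established quorum and discernment is actually at stake.
#' @param dt Euler-Maruyama step (hours).
#' @param t_min scoring start (hours), passed to [tracking_performance()].
#' @return data frame with one row per `(n_tf, n_cy, tau_h)`:
#'   `mean_performance`, `relative_performance`, plus the run sizes and
#'   master seed.
#' @export
performance_grid <- function(par, n_tf_grid, n_cy_grid, tau = c(24, 48, 96),
                             n_timecourses = 20, n_paths = 20,
                             master_seed, rho = 1e9, horizon = 500,
                             total = 1000 * par$kappa_apc, dt = 0.01,
                             t_min = 48) {
  if (length(n_tf_grid) < 1L || length(n_cy_grid) < 1L) {
    stop("volatility grids must be non-empty")
  }
  if (n_timecourses < 1 || n_paths < 1) stop("counts must be >= 1")
  set.seed(as.integer(master_seed))
  sched_seeds <- sample.int(.Machine$integer.max - 1L, n_timecourses)
  ens_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L,
               n_timecourses * length(n_tf_grid) * length(n_cy_grid)),
    nrow = n_timecourses)
  scheds <- lapply(sched_seeds, random_apc_timecourse, horizon = horizon,
                   total = total)
  opts <- lapply(tau, function(tv) {
    lapply(scheds, function(s) optimal_response(s, tv, horizon = horizon))
  })
  cells <- expand.grid(n_tf = n_tf_grid, n_cy = n_cy_grid)
  res <- vector("list", nrow(cells) * length(tau))
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    par_c <- par
    par_c$n_TF1 <- par_c$n_TF2 <- cells$n_tf[ci]
    par_c$n_CY1 <- par_c$n_CY2 <- cells$n_cy[ci]
    par_c <- validate_parameters(unclass(par_c))
    perf <- matrix(NA_real_, n_timecourses, length(tau))
    for (si in seq_len(n_timecourses)) {
      ens <- run_ensemble(n_paths, system_state(1, 1, 0, 0), par_c, rho,
                          apc = scheds[[si]], t_max = horizon, dt = dt,
                          master_seed = ens_seeds[si, ci])
      for (ti in seq_along(tau)) {
        perf[si, ti] <- tracking_performance(ens, opts[[ti]][[si]],
                                             t_min = t_min)$pooled
      }
    }
    for (ti in seq_along(tau)) {
      row <- row + 1L
      res[[row]] <- data.frame(
        n_tf = cells$n_tf[ci], n_cy = cells$n_cy[ci], tau_h = tau[ti],
        mean_performance = mean(perf[, ti]),
        n_timecourses = n_timecourses, n_paths = n_paths,
        master_seed = as.integer(master_seed))
    }
  }
  out <- do.call(rbind, res)
  out$relative_performance <- NA_real_
  for (tv in tau) {
    sel <- out$tau_h == tv
    out$relative_performance[sel] <-
      out$mean_performance[sel] / max(out$mean_performance[sel])
  }
  out
}
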