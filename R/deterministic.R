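## Deterministic analysis: ODE integration, equilibrium location, linear
## stability, bifurcation scans, quorum density and reversal-window timing.

as_schedule <- function(apc) {
  if (inherits(apc, "th_schedule")) return(apc)
  if (inherits(apc, "th_apc")) {
    return(apc_schedule(0, apc$APC1, apc$APC2))
  }
  stop("'apc' must be an apc_instruction() or an apc_schedule()")
}

schedule_matrix <- function(sched) {
  cbind(t_start = sched$t_start, apc1 = sched$APC1, apc2 = sched$APC2)
}

#' Integrate the deterministic model
#'
#' Integrates the four ODEs with a stiff-capable solver
#' ([deSolve::ode()], `lsoda`) under a fixed cell density, a constant or
#' piecewise-constant APC schedule, and a secretion scale.  Piecewise
#' schedules are integrated segment by segment so instruction switches are
#' exact.  Solutions are reported on a uniform grid and clamped of the
#' solver's tiny negative excursions.
#'
#' @param initial non-negative initial state, see [system_state()].
#' @param par a [model_parameters()] object.
#' @param rho cell density (cells/mL).
#' @param apc an [apc_instruction()] (constant) or [apc_schedule()]
#'   (piecewise-constant) instruction.
#' @param secretion_scale fraction in \[0, 1\] multiplying maximal secretion.
#' @param t_max time horizon (hours).
#' @param t_step reporting step (hours).
#' @param rtol,atol solver tolerances.
#' @return A `th_trajectory`: list with `time` (hours), `states`
#'   (matrix, columns `TF1, TF2, CY1, CY2`), and metadata
#'   (`rho`, `secretion_scale`, `schedule`, `seed = NA`).
#' @examples
#' par <- model_parameters()
#' tr <- integrate_ode(system_state(1, 1, 0, 0), par, rho = 2e6, t_max = 24)
#' tail(as.data.frame(tr), 2)
#' @export
integrate_ode <- function(initial, par, rho, apc = apc_instruction(),
                          secretion_scale = 1, t_max, t_step = 1,
                          rtol = 1e-8, atol = 1e-10) {
  check_state(initial)
  stopifnot(inherits(par, "th_params"))
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be positive")
  ctx <- apply_density(par, rho)
  sched <- as_schedule(apc)
  if (max(sched$t_start) > t_max) {
    sched <- schedule_window(sched, t_max)
  }
  times <- seq(0, t_max, by = t_step)
  if (times[length(times)] < t_max) times <- c(times, t_max)
  bounds <- unique(c(0, sched$t_start[sched$t_start > 0 &
                                        sched$t_start < t_max], t_max))
  bounds <- sort(bounds)
  rhs_fun <- function(t, y, parms) {
    list(th_rhs(y, ctx, par, parms[1], parms[2], secretion_scale))
  }
  out_t <- numeric(0)
  out_s <- NULL
  y <- initial
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    seg_apc <- apc_at(sched, t0)
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    sol <- deSolve::ode(y = y, times = seg_times, func = rhs_fun,
                        parms = seg_apc, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf(
        "ODE solver failed between t = %.3g h and t = %.3g h; last valid time %.6g h",
        t0, t1, max(sol[, 1])))
    }
    y <- pmax(sol[nrow(sol), 2:5], 0)
    keep <- sol[, 1] %in% times
    out_t <- c(out_t, sol[keep, 1])
    out_s <- rbind(out_s, pmax(sol[keep, 2:5, drop = FALSE], 0))
  }
  dup <- duplicated(out_t)   # segment joins are recorded by both segments
  new_trajectory(out_t[!dup], out_s[!dup, , drop = FALSE], rho,
                 secretion_scale, sched, seed = NA_integer_)
}

new_trajectory <- function(time, states, rho, secretion_scale, sched, seed) {
  colnames(states) <- .th_state_names
  structure(list(time = as.numeric(time), states = states, rho = rho,
                 secretion_scale = secretion_scale, schedule = sched,
                 seed = seed),
            class = "th_trajectory")
}

#' @export
print.th_trajectory <- function(x, ...) {
  n <- length(x$time)
  fin <- x$states[n, ]
  cat(sprintf("Th trajectory: %d points over %.4g h at rho = %.3g cells/mL\n",
              n, x$time[n], x$rho))
  cat(sprintf("  final state: TF1 = %.4g, TF2 = %.4g, CY1 = %.4g, CY2 = %.4g (theta = %.3f)\n",
              fin[1], fin[2], fin[3], fin[4], balance_index(fin[1], fin[2])))
  invisible(x)
}

#' @export
as.data.frame.th_trajectory <- function(x, ...) {
  data.frame(time_h = x$time, x$states)
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' @param traj a `th_trajectory`.
#' @param path CSV output path; metadata is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "th_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(rho = traj$rho, secretion_scale = traj$secretion_scale,
               seed = traj$seed,
               schedule = list(t_start = traj$schedule$t_start,
                               APC1 = traj$schedule$APC1,
                               APC2 = traj$schedule$APC2))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

## -------------------------------------------------------------------------
## Equilibrium location

## Run the compiled damped-Newton iteration (central-difference Jacobian,
## non-negative orthant projection) from a matrix of starts; convergence is
## measured on the normalized residual max|f| / (1 + max|x|).
newton_roots <- function(starts, par, ctx, apc, secretion_scale,
                         tol = 1e-11, max_iter = 80) {
  newton_roots_cpp(starts, as_param_vector(par),
                   ctx$a1, ctx$a2, ctx$dCY1, ctx$dCY2,
                   apc$APC1, apc$APC2, secretion_scale, tol, max_iter)
}

## Quasi-steady cytokine levels given fixed TFs (fixed-point iteration of the
## cytokine equations); used only to seed root-search starts.
qss_cytokines <- function(TF1, TF2, par, ctx, apc, secretion_scale) {
  cy <- c(0, 0)
  for (i in 1:40) {
    c1 <- cy[1] + apc$APC1; c2 <- cy[2] + apc$APC2
    cy_new <- c(
      secretion_scale * ctx$a1 * hill_act(TF1, par$A1, par$ha) *
        hill_inh(TF2, par$R2, par$hr) * hill_inh(c2, par$U2, par$hu) /
        ctx$dCY1,
      secretion_scale * ctx$a2 * hill_act(TF2, par$A2, par$ha) *
        hill_inh(TF1, par$R1, par$hr) * hill_inh(c1, par$U1, par$hu) /
        ctx$dCY2)
    if (max(abs(cy_new - cy)) < 1e-10 * (1 + max(cy_new))) break
    cy <- 0.5 * cy + 0.5 * cy_new
  }
  pmax(cy, 0)
}

default_starts <- function(par, ctx, apc, secretion_scale, n_tf = 5) {
  thr <- c(par$P1, par$P2, par$X1, par$X2, par$A1, par$A2, par$R1, par$R2)
  lo <- 1e-2 * min(thr); hi <- 1e2 * max(thr)
  tf_grid <- exp(seq(log(lo), log(hi), length.out = n_tf))
  grid <- expand.grid(tf1 = tf_grid, tf2 = tf_grid)
  starts <- matrix(0, nrow(grid), 4)
  for (i in seq_len(nrow(grid))) {
    starts[i, ] <- c(grid$tf1[i], grid$tf2[i],
                     qss_cytokines(grid$tf1[i], grid$tf2[i], par, ctx, apc,
                                   secretion_scale))
  }
  starts
}

#' Locate all equilibria of the deterministic model
#'
#' Multi-start Newton root search over a log-spaced grid of transcription
#' factor values spanning 1e-2 to 1e2 times the Hill thresholds, with
#' cytokines seeded at their quasi-steady levels (and at zero).  Verified
#' roots (normalized drift below `tol`) are deduplicated at relative
#' tolerance `dedup_tol` and classified by the eigenvalues of the local
#' Jacobian: stable means every eigenvalue has negative real part.
#'
#' @inheritParams integrate_ode
#' @param tol acceptance tolerance on the normalized drift residual.
#' @param dedup_tol relative deduplication tolerance.
#' @param n_tf number of transcription-factor grid values per axis.
#' @return A `th_equilibria` object: data frame-like with one row per
#'   equilibrium (`TF1..CY2`, `lambda_max`, `stable`, `theta`, `label`) plus
#'   the inputs as attributes.
#' @examples
#' par <- model_parameters()
#' eq <- find_equilibria(par, rho = 2e6, secretion_scale = 0)
#' eq
#' @export
find_equilibria <- function(par, rho, apc = apc_instruction(),
                            secretion_scale = 1, tol = 1e-8,
                            dedup_tol = 1e-6, n_tf = 5) {
  stopifnot(inherits(par, "th_params"), inherits(apc, "th_apc"))
  ctx <- apply_density(par, rho)
  starts <- default_starts(par, ctx, apc, secretion_scale, n_tf = n_tf)
  sol <- newton_roots(starts, par, ctx, apc, secretion_scale)
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    if (!sol$converged[i] || sol$residual[i] >= tol) next
    x <- sol$roots[i, ]
    is_dup <- any(vapply(roots, function(r) {
      all(abs(r - x) <= dedup_tol * (1 + pmax(abs(r), abs(x))))
    }, logical(1)))
    if (!is_dup) roots[[length(roots) + 1L]] <- x
  }
  if (length(roots) == 0L) {
    warning("no equilibria found; check parameters and start grid")
  }
  build_equilibria(roots, par, ctx, apc, secretion_scale, tol)
}

build_equilibria <- function(roots, par, ctx, apc, secretion_scale, tol) {
  n <- length(roots)
  states <- if (n > 0) do.call(rbind, roots) else
    matrix(numeric(0), 0, 4)
  colnames(states) <- .th_state_names
  lam <- numeric(n); eigs <- vector("list", n)
  for (i in seq_len(n)) {
    J <- model_jacobian(pmax(states[i, ], 0), ctx, par, apc,
                        secretion_scale)
    ev <- eigen(J, only.values = TRUE)$values
    eigs[[i]] <- ev
    lam[i] <- max(Re(ev))
  }
  theta <- if (n > 0) unname(balance_index(states[, 1], states[, 2])) else
    numeric(0)
  structure(list(states = states, lambda_max = lam, stable = lam < 0,
                 eigenvalues = eigs, theta = theta,
                 label = classify_attractor(theta = theta),
                 rho = ctx$rho, secretion_scale = secretion_scale,
                 apc = apc, tol = tol),
            class = "th_equilibria")
}

#' @export
as.data.frame.th_equilibria <- function(x, ...) {
  data.frame(x$states, lambda_max = x$lambda_max, stable = x$stable,
             theta = x$theta, label = x$label)
}

#' @export
print.th_equilibria <- function(x, ...) {
  cat(sprintf(
    "Equilibria at rho = %.3g cells/mL, secretion_scale = %.3g, APC = (%.3g, %.3g)\n",
    x$rho, x$secretion_scale, x$apc$APC1, x$apc$APC2))
  print(format(as.data.frame(x), digits = 4))
  invisible(x)
}

#' @export
length.th_equilibria <- function(x) nrow(x$states)

#' Write an equilibrium set to CSV
#'
#' Columns: the four state components, the leading eigenvalue real part and
#' the stability flag.
#'
#' @param eq a `th_equilibria` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_equilibria <- function(eq, path) {
  stopifnot(inherits(eq, "th_equilibria"))
  utils::write.csv(as.data.frame(eq), path, row.names = FALSE)
  invisible(path)
}

## Track the mixed-branch equilibrium by Newton polishing from a guess (by
## default the symmetric quasi-steady construction).  Returns NULL when the
## iteration leaves the mixed branch or fails.
mixed_equilibrium <- function(par, ctx, apc = apc_instruction(),
                              secretion_scale = 1, guess = NULL) {
  if (is.null(guess)) {
    tf0 <- (par$b + par$s1 + par$s2 + par$p1 / 2) / par$dTF1
    cand <- t(vapply(c(0.25, 0.5, 1) * tf0, function(tf) {
      c(tf, tf, qss_cytokines(tf, tf, par, ctx, apc, secretion_scale))
    }, numeric(4)))
  } else {
    cand <- matrix(guess, nrow = 1)
  }
  sol <- newton_roots(cand, par, ctx, apc, secretion_scale)
  for (i in seq_len(nrow(cand))) {
    if (sol$converged[i] && sol$residual[i] < 1e-8) {
      x <- sol$roots[i, ]
      th <- balance_index(x[1], x[2])
      if (!is.null(guess) || (th > 0.2 && th < 0.8)) return(x)
    }
  }
  NULL
}

## -------------------------------------------------------------------------
## Bifurcation scans

#' Bifurcation scan over the permitted secretion scale
#'
#' Reproduces the cytokine-blocking analysis: at fixed density the
#' equilibrium structure is scanned as the permitted fraction of cytokine
#' secretion is reduced from 1 to 0 (antibody blocking in the wet-lab
#' analogue).  On the mixed branch the critical scale where stability is lost
#' is refined by bisection on the leading Jacobian eigenvalue.
#'
#' @inheritParams find_equilibria
#' @param scales decreasing or increasing grid of secretion scales in
#'   \[0, 1\].
#' @param refine_tol absolute bisection tolerance on the critical scale.
#' @return list with `summary` (one data-frame row per equilibrium per
#'   scale), `critical_scale`, and the bisection `bracket`.
#' @export
secretion_bifurcation_scan <- function(par, rho, scales = seq(1, 0, by = -0.1),
                                       apc = apc_instruction(),
                                       refine_tol = 1e-4) {
  stopifnot(all(scales >= 0 & scales <= 1))
  ctx <- apply_density(par, rho)
  scales <- sort(scales, decreasing = TRUE)
  rows <- list()
  for (s in scales) {
    eq <- find_equilibria(par, rho, apc = apc, secretion_scale = s)
    df <- as.data.frame(eq)
    if (nrow(df) > 0) df <- cbind(secretion_scale = s, df)
    rows[[length(rows) + 1L]] <- df
  }
  summary <- do.call(rbind, rows)
  lam_mixed <- function(s, guess) {
    st <- mixed_equilibrium(par, ctx, apc, s, guess = guess)
    if (is.null(st)) return(list(lam = NA_real_, state = NULL))
    J <- model_jacobian(st, ctx, par, apc, s)
    list(lam = max(Re(eigen(J, only.values = TRUE)$values)), state = st)
  }
  ## bracket the loss of mixed-branch stability along the grid
  critical <- NA_real_; bracket <- c(NA_real_, NA_real_)
  guess <- NULL; prev <- NULL
  for (s in scales) {
    cur <- lam_mixed(s, guess)
    if (!is.null(cur$state)) guess <- cur$state
    if (!is.null(prev) && is.finite(prev$lam) && is.finite(cur$lam) &&
        prev$lam < 0 && cur$lam > 0) {
      lo <- s; hi <- prev$s   # lam(hi) < 0 < lam(lo)
      g <- prev$state
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        lm <- lam_mixed(mid, g)
        if (!is.finite(lm$lam)) break
        g <- lm$state
        if (lm$lam > 0) lo <- mid else hi <- mid
      }
      critical <- (lo + hi) / 2
      bracket <- c(lo, hi)
      break
    }
    prev <- c(cur, list(s = s))
  }
  list(summary = summary, critical_scale = critical, bracket = bracket,
       rho = rho)
}

#' Quorum cell density
#'
#' Bisects on cell density for the point where the mixed-branch equilibrium
#' loses linear stability (leading Jacobian eigenvalue crosses zero): the
#' quorum density above which the Th group commits as a unit.  Also reports
#' the cytokine production:removal ratio and the cytokine:transcription
#' factor expression ratio at the mixed equilibrium at that density.
#'
#' @inheritParams find_equilibria
#' @param bracket length-2 density bracket (cells/mL); the mixed equilibrium
#'   must be stable at the low end and unstable at the high end.
#' @param rel_tol relative bisection tolerance on the density.
#' @return list with `rho_crit`, `production_removal_ratio`,
#'   `cy_tf_ratio`, the mixed `state` at the crossing, and the final
#'   `bracket`.
#' @export
quorum_density <- function(par, bracket = c(1e6, 1e9),
                           apc = apc_instruction(), secretion_scale = 1,
                           rel_tol = 1e-4) {
  lam_at <- function(rho, guess = NULL) {
    ctx <- apply_density(par, rho)
    st <- mixed_equilibrium(par, ctx, apc, secretion_scale, guess = guess)
    if (is.null(st)) stop("failed to track the mixed equilibrium at rho = ",
                          signif(rho, 4))
    J <- model_jacobian(st, ctx, par, apc, secretion_scale)
    list(lam = max(Re(eigen(J, only.values = TRUE)$values)), state = st)
  }
  lo <- min(bracket); hi <- max(bracket)
  at_lo <- lam_at(lo); at_hi <- lam_at(hi, guess = at_lo$state)
  if (at_lo$lam >= 0 || at_hi$lam <= 0) {
    stop(sprintf(
      "invalid bracket: mixed equilibrium must be stable at %.3g (lambda = %.3g) and unstable at %.3g (lambda = %.3g); widen the bracket",
      lo, at_lo$lam, hi, at_hi$lam))
  }
  guess <- at_lo$state
  while (hi / lo - 1 > rel_tol) {
    mid <- sqrt(lo * hi)
    at_mid <- lam_at(mid, guess = guess)
    guess <- at_mid$state
    if (at_mid$lam < 0) lo <- mid else hi <- mid
  }
  rho_crit <- sqrt(lo * hi)
  ctx <- apply_density(par, rho_crit)
  st <- mixed_equilibrium(par, ctx, apc, secretion_scale, guess = guess)
  cy_tf <- (st[3] + st[4]) / (st[1] + st[2])
  list(rho_crit = rho_crit, production_removal_ratio = ctx$ratio1,
       cy_tf_ratio = unname(cy_tf), state = st, bracket = c(lo, hi))
}

#' Within-scale versus cross-scale stability decomposition
#'
#' At a mixed-branch equilibrium the destabilizing direction is the
#' polarization mode (TF1 up / TF2 down and CY1 up / CY2 down); with
#' asymmetric parameters the analogous direction is the least-stable
#' eigenmode of the Jacobian.  Compressing the Jacobian onto that mode's
#' transcription-factor and cytokine components splits it into four signed
#' feedbacks: the
#' within-scale TF block (self-activation, TF cross-inhibition, decay), the
#' within-scale cytokine block (cytokine cross-inhibition, removal), and the
#' two cross-scale couplings (cytokines inducing TFs; TFs driving
#' secretion).  With both within-scale feedbacks stabilizing, the mixed
#' state is stable precisely while the product of within-scale feedbacks
#' exceeds the product of the cross-scale couplings; the verdict is
#' `"polarizing"` once the cross-scale total overtakes the within-scale net
#' effect (or the within-scale trace itself turns positive).
#'
#' @inheritParams find_equilibria
#' @param state the mixed-branch equilibrium to decompose (stable or not).
#' @param tol normalized drift tolerance for accepting `state` as an
#'   equilibrium.
#' @return list with `within` (net stabilizing effect, the product of the
#'   two within-scale mode feedbacks), `cross` (total destabilizing effect,
#'   the product of the two cross-scale couplings), `verdict`
#'   (`"mixed-stable"` or `"polarizing"`), the projected 2x2 matrix `M`, and
#'   `lambda_full` (leading eigenvalue of the full Jacobian).
#' @export
scale_decomposition <- function(par, ctx, state, apc = apc_instruction(),
                                secretion_scale = 1, tol = 1e-6) {
  stopifnot(inherits(ctx, "th_density"))
  f <- th_rhs(state, ctx, par, apc$APC1, apc$APC2, secretion_scale)
  if (max(abs(f)) / (1 + max(abs(state))) >= tol) {
    stop("supplied state is not an equilibrium (normalized drift = ",
         signif(max(abs(f)) / (1 + max(abs(state))), 3), ")")
  }
  J <- model_jacobian(state, ctx, par, apc, secretion_scale)
  es <- eigen(J)
  lambda_full <- max(Re(es$values))
  ## direction of the least-stable mode, split into its TF-scale and
  ## CY-scale components; for a symmetric parameter set at the mixed
  ## equilibrium this is exactly the polarization mode (1,-1 | 1,-1)
  v <- Re(es$vectors[, which.max(Re(es$values))])
  u_tf <- v[1:2]; u_cy <- v[3:4]
  pol <- c(1, -1) / sqrt(2)
  u_tf <- if (sqrt(sum(u_tf^2)) < 1e-10) pol else u_tf / sqrt(sum(u_tf^2))
  u_cy <- if (sqrt(sum(u_cy^2)) < 1e-10) pol else u_cy / sqrt(sum(u_cy^2))
  if (sum(u_tf * pol) < 0) u_tf <- -u_tf
  if (sum(u_cy * pol) < 0) u_cy <- -u_cy
  M <- matrix(c(u_tf %*% J[1:2, 1:2] %*% u_tf,
                u_tf %*% J[1:2, 3:4] %*% u_cy,
                u_cy %*% J[3:4, 1:2] %*% u_tf,
                u_cy %*% J[3:4, 3:4] %*% u_cy),
              2, 2, byrow = TRUE,
              dimnames = list(c("TF", "CY"), c("TF", "CY")))
  within <- M[1, 1] * M[2, 2]
  cross <- M[1, 2] * M[2, 1]
  verdict <- if (within >= cross && (M[1, 1] + M[2, 2]) < 0)
    "mixed-stable" else "polarizing"
  list(within = within, cross = cross, verdict = verdict, M = M,
       lambda_full = lambda_full)
}

## -------------------------------------------------------------------------
## APC reversal window

#' Reversal window of an instructed quorum
#'
#' An initially biased APC population sparks a committed quorum; at a switch
#' time the instruction flips to a (typically much stronger) fully opposed
#' APC population.  For each switch time the piecewise schedule is
#' integrated and the terminal attractor classified by balance index; the
#' reversal window is the largest switch time at which the late instruction
#' still reverses the commitment, refined by bisection between the last
#' reversing and first non-reversing grid points.
#'
#' @inheritParams integrate_ode
#' @param apc_initial the sparking instruction (biased to one type).
#' @param apc_switch the late instruction (fully biased to the other type).
#' @param switch_times increasing grid of candidate switch times (hours).
#' @param horizon classification horizon (hours after t = 0).
#' @param initial initial state.
#' @param refine_tol bisection tolerance on the window (hours).
#' @return list with `window` (hours; `Inf` when every scanned switch
#'   reverses, `NA` when none does), `baseline_label` (terminal attractor
#'   when never switched), and `table` (per switch time: terminal theta and
#'   label).
#' @export
reversal_window <- function(par, rho, apc_initial, apc_switch,
                            switch_times = seq(2, 100, by = 2),
                            horizon = 500, initial = system_state(1, 1, 0, 0),
                            refine_tol = 0.25) {
  stopifnot(inherits(apc_initial, "th_apc"), inherits(apc_switch, "th_apc"))
  target <- classify_attractor(apc_switch$APC1, apc_switch$APC2)
  if (target == "mixed") {
    stop("apc_switch must be fully biased to one effector type")
  }
  terminal <- function(switch_time) {
    sched <- if (is.finite(switch_time)) {
      apc_schedule(c(0, switch_time),
                   c(apc_initial$APC1, apc_switch$APC1),
                   c(apc_initial$APC2, apc_switch$APC2))
    } else {
      apc_schedule(0, apc_initial$APC1, apc_initial$APC2)
    }
    tr <- integrate_ode(initial, par, rho, apc = sched, t_max = horizon,
                        t_step = horizon / 100)
    fin <- tr$states[nrow(tr$states), ]
    th <- unname(balance_index(fin[1], fin[2]))
    lab <- classify_attractor(theta = th)
    if (lab == "mixed") {
      stop(sprintf(
        "terminal state unclassifiable at switch time %.4g h (balance index %.3f); extend the horizon",
        switch_time, th))
    }
    list(theta = th, label = lab)
  }
  base <- terminal(Inf)
  reverses <- logical(length(switch_times))
  thetas <- numeric(length(switch_times))
  labels <- character(length(switch_times))
  for (i in seq_along(switch_times)) {
    res <- terminal(switch_times[i])
    reverses[i] <- res$label == target
    thetas[i] <- res$theta
    labels[i] <- res$label
  }
  tab <- data.frame(switch_time_h = switch_times, theta_final = thetas,
                    label = labels, reversed = reverses)
  if (all(reverses)) {
    window <- Inf
  } else if (!reverses[1]) {
    window <- NA_real_
  } else {
    i_last <- max(which(reverses[seq_len(which.min(reverses))]))
    lo <- switch_times[i_last]            # still reverses
    hi <- switch_times[i_last + 1L]       # no longer reverses
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      if (terminal(mid)$label == target) lo <- mid else hi <- mid
    }
    window <- (lo + hi) / 2
  }
  list(window = window, baseline_label = base$label, table = tab)
}
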