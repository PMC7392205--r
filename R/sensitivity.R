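## Monte-Carlo parameter perturbation: per-parameter effect sizes near an
## operating point and regime-robustness sweeps.

## parameters subject to perturbation: all rates and thresholds.  Hill
## exponents are held fixed by default (multiplying them by 1 +/- 0.9 would
## change the model class), and the noise magnitudes, APC strength and the
## reference density do not enter the deterministic equilibrium structure.
.th_perturb_fields <- setdiff(.th_rate_fields,
                              c("kappa_apc", "rho_ref"))

#' Sample perturbed parameter sets
#'
#' Draws `n` parameter sets in which every rate and threshold is multiplied
#' by an independent uniform draw from `[1 - amp, 1 + amp]`.  Hill exponents
#' are excluded unless `perturb_hill = TRUE`.
#'
#' @param base a [model_parameters()] object.
#' @param amp variation amplitude as a fraction, in \[0, 0.9\].
#' @param n number of sets.
#' @param seed integer seed.
#' @param perturb_hill also perturb the Hill exponents (clamped at 1).
#' @return an object of class `th_param_sample`: list with `base`, `amp`,
#'   `multipliers` (an `n x p` matrix) and `sets` (list of `th_params`).
#' @export
sample_parameters <- function(base, amp, n, seed, perturb_hill = FALSE) {
  stopifnot(inherits(base, "th_params"))
  if (amp < 0 || amp >= 1) {
    stop("amp must lie in [0, 1); rates must stay positive")
  }
  if (amp > 0.9) stop("amp must not exceed 0.9")
  fields <- .th_perturb_fields
  if (perturb_hill) fields <- c(fields, .th_hill_fields)
  set.seed(as.integer(seed))
  mult <- matrix(stats::runif(n * length(fields), 1 - amp, 1 + amp),
                 nrow = n, dimnames = list(NULL, fields))
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    p <- unclass(base)
    for (f in fields) {
      p[[f]] <- unname(if (f %in% .th_hill_fields) {
        max(1, p[[f]] * mult[i, f])
      } else {
        p[[f]] * mult[i, f]
      })
    }
    sets[[i]] <- validate_parameters(p)
  }
  structure(list(base = base, amp = amp, multipliers = mult, sets = sets,
                 seed = as.integer(seed)),
            class = "th_param_sample")
}

#' Regime robustness under parameter variation
#'
#' The regime at an operating density is the number of stable equilibria.
#' For each variation amplitude, `n` perturbed parameter sets are drawn and
#' their regime compared with the base set's; the scan reports the fraction
#' matching per amplitude and the smallest amplitude at which any mismatch
#' occurs.  Perturbed sets on which the equilibrium search fails are flagged
#' and excluded from the fraction (with a count).
#'
#' @param base a [model_parameters()] object.
#' @param rho operating cell density (cells/mL).
#' @param amps vector of variation amplitudes.
#' @param n sets per amplitude.
#' @param seed integer seed (per-amplitude seeds derive from it).
#' @param secretion_scale passed to [find_equilibria()].
#' @return list with `base_regime`, `table` (per amp: `n`, `n_matching`,
#'   `n_failed`, `fraction_matching`) and `first_mismatch_amp`.
#' @export
regime_scan <- function(base, rho, amps = seq(0.1, 0.9, by = 0.1), n = 500,
                        seed, secretion_scale = 1) {
  base_eq <- find_equilibria(base, rho, secretion_scale = secretion_scale)
  base_regime <- sum(base_eq$stable)
  set.seed(as.integer(seed))
  amp_seeds <- sample.int(.Machine$integer.max - 1L, length(amps))
  rows <- vector("list", length(amps))
  for (ai in seq_along(amps)) {
    amp <- amps[ai]
    sample <- sample_parameters(base, amp, n, seed = amp_seeds[ai])
    match <- logical(n); failed <- logical(n)
    for (i in seq_len(n)) {
      regime <- tryCatch({
        eq <- suppressWarnings(
          find_equilibria(sample$sets[[i]], rho,
                          secretion_scale = secretion_scale))
        if (length(eq) == 0L) NA_integer_ else sum(eq$stable)
      }, error = function(e) NA_integer_)
      if (is.na(regime)) failed[i] <- TRUE
      else match[i] <- regime == base_regime
    }
    n_ok <- n - sum(failed)
    rows[[ai]] <- data.frame(
      amp = amp, n = n, n_matching = sum(match), n_failed = sum(failed),
      fraction_matching = if (n_ok > 0) sum(match) / n_ok else NA_real_)
  }
  tab <- do.call(rbind, rows)
  mism <- tab$amp[tab$fraction_matching < 1]
  list(base_regime = base_regime, table = tab,
       first_mismatch_amp = if (length(mism)) min(mism) else NA_real_)
}

#' Per-parameter net effect sizes on equilibrium position
#'
#' Monte-Carlo main-effects analysis near an operating point: `n` parameter
#' sets are drawn at amplitude `amp`, the tracked equilibrium (the mixed
#' branch at low density, or the polarized branch reached from the base
#' polarized state at high density) is relocated for each by Newton
#' polishing, and a main-effects linear model regresses each equilibrium
#' response (balance index `theta`, and total transcription factor level)
#' on the parameter multipliers.  A parameter's net effect is the predicted
#' change in the response across that parameter's sampled range with all
#' others held at base, expressed as a percentage of the base response.
#'
#' @inheritParams regime_scan
#' @param amp variation amplitude ("near" the operating point; default 0.1).
#' @param n number of sampled sets.
#' @param branch `"mixed"` or `"polarized"`: which equilibrium branch to
#'   track.
#' @return list with `effects` (data frame: parameter, response,
#'   `net_effect_percent`), `base_response`, `n_used`, and the fitted
#'   multiplier range.
#' @export
effect_sizes <- function(base, rho, amp = 0.1, n = 1000, seed,
                         branch = c("mixed", "polarized"),
                         secretion_scale = 1) {
  branch <- match.arg(branch)
  ctx <- apply_density(base, rho)
  apc0 <- apc_instruction()
  base_state <- if (branch == "mixed") {
    mixed_equilibrium(base, ctx, apc0, secretion_scale)
  } else {
    eq <- find_equilibria(base, rho, secretion_scale = secretion_scale)
    df <- as.data.frame(eq)
    cand <- df[df$stable & df$label == "Th1", , drop = FALSE]
    if (nrow(cand) == 0L) stop("no stable polarized (Th1) branch at rho = ",
                               signif(rho, 3))
    unlist(cand[1, 1:4])
  }
  if (is.null(base_state)) {
    stop("operating point has no tracked ", branch, " equilibrium")
  }
  sample <- sample_parameters(base, amp, n, seed = seed)
  p_names <- colnames(sample$multipliers)
  if (n < length(p_names) + 2L) {
    stop("n too small for a main-effects fit; need at least ",
         length(p_names) + 2L, " sets")
  }
  theta <- rep(NA_real_, n); tot_tf <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ctx_i <- apply_density(sample$sets[[i]], rho)
    st <- mixed_equilibrium(sample$sets[[i]], ctx_i, apc0, secretion_scale,
                            guess = base_state)
    if (is.null(st)) next
    theta[i] <- balance_index(st[1], st[2])
    tot_tf[i] <- st[1] + st[2]
  }
  ok <- is.finite(theta)
  X <- sample$multipliers[ok, , drop = FALSE]
  base_resp <- c(theta = balance_index(base_state[1], base_state[2]),
                 total_TF = unname(base_state[1] + base_state[2]))
  rows <- list()
  for (resp in names(base_resp)) {
    y <- if (resp == "theta") theta[ok] else tot_tf[ok]
    fit <- stats::lm.fit(cbind(1, X), y)
    coefs <- fit$coefficients[-1]
    rows[[resp]] <- data.frame(
      parameter = p_names, response = resp,
      net_effect_percent =
        100 * abs(coefs) * 2 * amp / abs(base_resp[[resp]]))
  }
  effects <- do.call(rbind, rows)
  rownames(effects) <- NULL
  list(effects = effects, base_response = base_resp, n_used = sum(ok),
       amp = amp)
}
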