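#' State vector helper
#'
#' The model state is a non-negative named numeric 4-vector
#' `(TF1, TF2, CY1, CY2)`: intracellular transcription factors in molecules
#' per cell, extracellular cytokines in concentration units.
#'
#' @param TF1,TF2,CY1,CY2 non-negative components.
#' @return named numeric vector of length 4.
#' @export
system_state <- function(TF1 = 0, TF2 = 0, CY1 = 0, CY2 = 0) {
  x <- c(TF1 = TF1, TF2 = TF2, CY1 = CY1, CY2 = CY2)
  check_state(x)
  x
}

.th_state_names <- c("TF1", "TF2", "CY1", "CY2")

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 4L) {
    stop("state must be a numeric 4-vector (TF1, TF2, CY1, CY2)")
  }
  if (any(!is.finite(state))) stop("state components must be finite")
  if (any(state < 0)) {
    stop("state components must be non-negative (got ",
         paste(signif(state, 4), collapse = ", "), ")")
  }
  invisible(state)
}

#' APC instruction constants
#'
#' Antigen-presenting cells (APCs) instruct Th differentiation by secreting
#' effector-driving cytokines directly onto Th cells.  This is modeled by
#' additive constants `APC1`/`APC2` (cytokine-concentration units) that
#' augment every appearance of `CY1`/`CY2` in the equations except the decay
#' terms.
#'
#' @param APC1,APC2 non-negative instruction constants.
#' @return an object of class `th_apc`.
#' @seealso [apc_constants()] to derive constants from APC counts.
#' @export
apc_instruction <- function(APC1 = 0, APC2 = 0) {
  if (!is.numeric(APC1) || !is.numeric(APC2) ||
      length(APC1) != 1L || length(APC2) != 1L ||
      !is.finite(APC1) || !is.finite(APC2) || APC1 < 0 || APC2 < 0) {
    stop("APC1 and APC2 must be single non-negative numbers")
  }
  structure(list(APC1 = APC1, APC2 = APC2), class = "th_apc")
}

#' Derive APC instruction constants from APC counts
#'
#' Each Type 1 (Th1-instructing) or Type 2 (Th2-instructing) APC contributes
#' `kappa_apc` concentration units of instruction, so
#' `APC_i = kappa_apc * n_type_i`.  The default `kappa_apc` is calibrated so
#' that 10 APCs at a 6:4 Th1 bias spark a Th1-committed quorum at in-vivo
#' density (see the methods vignette).
#'
#' @param n_type1,n_type2 non-negative APC counts.
#' @param par a [model_parameters()] object supplying `kappa_apc`.
#' @return a [apc_instruction()] object.
#' @export
apc_constants <- function(n_type1, n_type2, par) {
  stopifnot(inherits(par, "th_params"))
  if (!is.numeric(n_type1) || !is.numeric(n_type2) ||
      n_type1 < 0 || n_type2 < 0) {
    stop("APC counts must be non-negative")
  }
  apc_instruction(par$kappa_apc * n_type1, par$kappa_apc * n_type2)
}

#' Apply cell density to the cytokine kinetics
#'
#' Transcription factors are counted per cell and do not depend on cell
#' density, but cytokines are extracellular concentrations: as density
#' `rho` rises, secretion compacts into less extracellular volume and
#' consumption by cells intensifies.  Production scales linearly,
#' `a_i(rho) = a_i_base * rho / rho_ref`, while removal has a
#' density-scaled consumption part plus constant free decay,
#' `dCY_i(rho) = dCY_consume * rho / rho_ref + dCY_free`.  Because
#' `dCY_free > 0`, production scales more steeply than removal and the
#' production:removal ratio increases strictly with density — the lever of
#' quorum sensing.
#'
#' @param par a [model_parameters()] object.
#' @param rho cell density (cells/mL), strictly positive.
#' @return an object of class `th_density` with elements `rho`, `a1`, `a2`,
#'   `dCY1`, `dCY2` and the production:removal `ratio1`, `ratio2`.
#' @examples
#' par <- model_parameters()
#' apply_density(par, 2e6)
#' @export
apply_density <- function(par, rho) {
  stopifnot(inherits(par, "th_params"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("cell density 'rho' must be a single strictly positive number")
  }
  r <- rho / par$rho_ref
  a1 <- par$a1_base * r
  a2 <- par$a2_base * r
  d1 <- par$dCY_consume * r + par$dCY_free
  d2 <- d1
  structure(list(rho = rho, a1 = a1, a2 = a2, dCY1 = d1, dCY2 = d2,
                 ratio1 = a1 / d1, ratio2 = a2 / d2),
            class = "th_density")
}

#' @export
print.th_density <- function(x, ...) {
  cat(sprintf(
    "density context: rho = %.3g cells/mL | a = (%.4g, %.4g) /h | dCY = (%.4g, %.4g) /h | a/dCY = %.4g\n",
    x$rho, x$a1, x$a2, x$dCY1, x$dCY2, x$ratio1))
  invisible(x)
}

hill_act <- function(x, K, h) {
  xh <- x^h
  xh / (K^h + xh)
}

hill_inh <- function(x, K, h) {
  Kh <- K^h
  Kh / (Kh + x^h)
}

## Right-hand side of the four equations.  Cytokine appearances other than
## the decay terms are augmented by the APC constants; secretion_scale
## multiplies only the maximal secretion rates a1, a2 (cytokine blocking).
## Not exported; assumes arguments already validated and clamps transient
## small negatives from the integrator.
th_rhs <- function(state, ctx, par, apc1, apc2, secretion_scale) {
  x <- unname(pmax(state, 0))
  TF1 <- x[1]; TF2 <- x[2]; CY1 <- x[3]; CY2 <- x[4]
  c1 <- CY1 + apc1
  c2 <- CY2 + apc2
  dTF1 <- (par$b + par$p1 * hill_act(TF1, par$P1, par$hp)) *
            hill_inh(TF2, par$X2, par$hx) +
          par$s1 * hill_act(c1, par$S1, par$hs) *
            hill_inh(c2, par$Z2, par$hz) -
          par$dTF1 * TF1
  dTF2 <- (par$b + par$p2 * hill_act(TF2, par$P2, par$hp)) *
            hill_inh(TF1, par$X1, par$hx) +
          par$s2 * hill_act(c2, par$S2, par$hs) *
            hill_inh(c1, par$Z1, par$hz) -
          par$dTF2 * TF2
  dCY1 <- secretion_scale * ctx$a1 * hill_act(TF1, par$A1, par$ha) *
            hill_inh(TF2, par$R2, par$hr) *
            hill_inh(c2, par$U2, par$hu) -
          ctx$dCY1 * CY1
  dCY2 <- secretion_scale * ctx$a2 * hill_act(TF2, par$A2, par$ha) *
            hill_inh(TF1, par$R1, par$hr) *
            hill_inh(c1, par$U1, par$hu) -
          ctx$dCY2 * CY2
  c(TF1 = dTF1, TF2 = dTF2, CY1 = dCY1, CY2 = dCY2)
}

#' Deterministic drift of the four-variable model
#'
#' Evaluates the right-hand side of the model equations at a state.  The
#' transcription-factor equations combine basal plus self-activating
#' production gated by cross-inhibition from the opposing factor, and
#' cytokine-driven induction gated by cross-inhibition from the opposing
#' cytokine.  The cytokine equations combine secretion driven by the own-axis
#' factor, repressed by the opposing factor and the opposing cytokine, and
#' first-order removal.  APC constants augment every cytokine appearance
#' except removal.  The vector field is positivity-preserving: at a zero
#' component the corresponding rate is non-negative.
#'
#' @param state non-negative state 4-vector, see [system_state()].
#' @param ctx a [apply_density()] context.
#' @param par a [model_parameters()] object.
#' @param apc an [apc_instruction()] object (default: no APCs).
#' @param secretion_scale fraction in \[0, 1\] multiplying the maximal
#'   secretion rates only; 0 reproduces complete cytokine blocking.
#' @return named rate 4-vector (d/dt of each component).
#' @examples
#' par <- model_parameters()
#' ctx <- apply_density(par, 2e6)
#' drift(system_state(), ctx, par)   # (b, b, 0, 0)
#' @export
drift <- function(state, ctx, par, apc = apc_instruction(),
                  secretion_scale = 1) {
  check_state(state)
  stopifnot(inherits(ctx, "th_density"), inherits(par, "th_params"),
            inherits(apc, "th_apc"))
  if (!is.numeric(secretion_scale) || secretion_scale < 0 ||
      secretion_scale > 1) {
    stop("secretion_scale must lie in [0, 1]")
  }
  th_rhs(state, ctx, par, apc$APC1, apc$APC2, secretion_scale)
}

#' Diffusion amplitudes of the stochastic model
#'
#' The stochastic extension adds independent multiplicative Brownian terms
#' `n_X * X * dW_X` to each equation, modeling lognormal-type fluctuations in
#' molecular expression.  This returns the state-proportional amplitude
#' vector `(n_TF1*TF1, n_TF2*TF2, n_CY1*CY1, n_CY2*CY2)`; a component at
#' zero has zero noise (absorbing in the noise term).
#'
#' @inheritParams drift
#' @return named amplitude 4-vector.
#' @export
diffusion <- function(state, par) {
  check_state(state)
  stopifnot(inherits(par, "th_params"))
  c(TF1 = par$n_TF1 * state[[1]], TF2 = par$n_TF2 * state[[2]],
    CY1 = par$n_CY1 * state[[3]], CY2 = par$n_CY2 * state[[4]])
}

#' Jacobian of the drift field
#'
#' Central finite-difference Jacobian of [drift()] at a state, used for
#' linear stability classification of equilibria and for the within-scale /
#' cross-scale decomposition.
#'
#' @inheritParams drift
#' @param eps relative step for the finite differences.
#' @return a 4x4 matrix with rows/columns ordered `(TF1, TF2, CY1, CY2)`.
#' @export
model_jacobian <- function(state, ctx, par, apc = apc_instruction(),
                           secretion_scale = 1, eps = 1e-6) {
  check_state(state)
  J <- matrix(0, 4, 4, dimnames = list(.th_state_names, .th_state_names))
  for (j in 1:4) {
    h <- eps * max(abs(state[[j]]), 1)
    up <- state; up[j] <- state[[j]] + h
    dn <- state; dn[j] <- max(state[[j]] - h, 0)
    f_up <- th_rhs(up, ctx, par, apc$APC1, apc$APC2, secretion_scale)
    f_dn <- th_rhs(dn, ctx, par, apc$APC1, apc$APC2, secretion_scale)
    J[, j] <- (f_up - f_dn) / (up[[j]] - dn[[j]])
  }
  J
}

#' Balance index of a state
#'
#' The balance index `theta = TF1 / (TF1 + TF2)` operationalizes the balance
#' of T-bet versus GATA3 expression: 1 is fully Th1, 0 fully Th2, 0.5 an even
#' mixture.  The undecided state `TF1 = TF2 = 0` is assigned 0.5.
#'
#' @param TF1,TF2 non-negative expression levels (vectorized).
#' @return numeric vector of values in \[0, 1\].
#' @export
balance_index <- function(TF1, TF2) {
  tot <- TF1 + TF2
  ifelse(tot > 0, TF1 / tot, 0.5)
}

#' Classify a state as Th1, Th2 or mixed
#'
#' Applies the documented attractor-classification rule to the balance
#' index: `theta > 0.8` is Th1, `theta < 0.2` is Th2, anything else mixed.
#'
#' @param TF1,TF2 expression levels (vectorized), or `theta` directly.
#' @param theta optional balance index overriding `TF1`/`TF2`.
#' @return character vector of `"Th1"`, `"Th2"`, `"mixed"`.
#' @export
classify_attractor <- function(TF1, TF2, theta = NULL) {
  if (is.null(theta)) theta <- balance_index(TF1, TF2)
  ifelse(theta > 0.8, "Th1", ifelse(theta < 0.2, "Th2", "mixed"))
}
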