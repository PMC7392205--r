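#' Model parameters for the Th1/Th2 quorum-sensing model
#'
#' Constructs and validates the full parameter set of the four-variable
#' Th effector-choice model.  The state variables are the two master
#' transcription factors (`TF1` = T-bet, `TF2` = GATA3, molecules per cell)
#' and the two master cytokines (`CY1` = IFN-gamma, `CY2` = IL-4,
#' extracellular concentration).  Every interaction is a Hill function;
#' index 1 refers to the Th1 axis and index 2 to the Th2 axis.
#'
#' The default values form a *calibrated, symmetric stand-in* parameter set
#' (see the methods vignette for the calibration conditions): it is chosen so
#' that at in-vitro density (2e6 cells/mL) with full secretion the mixed
#' effector state is the unique stable equilibrium, with secretion blocked the
#' transcription-factor toggle is bistable and polarized, and at in-vivo
#' density (1e9 cells/mL) the mixed state is unstable with two stable
#' polarized states.
#'
#' @param b basal transcription-factor production rate
#'   (molecules cell^-1 h^-1).
#' @param p1,p2 maximal self-activation rates of TF1/TF2
#'   (molecules cell^-1 h^-1).
#' @param P1,P2 self-activation half-saturation levels (molecules cell^-1).
#' @param hp Hill exponent of TF self-activation.
#' @param X1,X2 half-inhibition thresholds for TF cross-inhibition
#'   (TF1 represses TF2 through X1 and vice versa; molecules cell^-1).
#' @param hx Hill exponent of TF cross-inhibition.
#' @param s1,s2 maximal cytokine-driven TF induction rates
#'   (molecules cell^-1 h^-1).
#' @param S1,S2 half-saturation of cytokine-driven induction (concentration).
#' @param hs Hill exponent of cytokine-driven induction.
#' @param Z1,Z2 half-inhibition thresholds for cytokine cross-inhibition of
#'   the opposing TF induction (concentration).
#' @param hz Hill exponent of that cross-inhibition.
#' @param a1_base,a2_base maximal cytokine secretion rates at the reference
#'   density `rho_ref` (concentration h^-1).
#' @param A1,A2 TF half-saturation for cytokine secretion
#'   (molecules cell^-1).
#' @param ha Hill exponent of secretion activation.
#' @param R1,R2 thresholds for TF repression of the opposing cytokine
#'   (molecules cell^-1).
#' @param hr Hill exponent of that repression.
#' @param U1,U2 thresholds for cytokine repression of the opposing cytokine
#'   (concentration).
#' @param hu Hill exponent of that repression.
#' @param dTF1,dTF2 TF decay rates (h^-1).
#' @param dCY_consume density-dependent cytokine removal coefficient at
#'   `rho_ref` (h^-1); scales linearly with cell density (consumption).
#' @param dCY_free density-independent free cytokine decay rate (h^-1).
#' @param n_TF1,n_TF2,n_CY1,n_CY2 dimensionless noise volatilities
#'   (per sqrt hour) of the multiplicative Brownian terms.
#' @param kappa_apc instruction strength contributed by a single APC
#'   (concentration units per APC); used by [apc_constants()].
#' @param rho_ref reference cell density (cells/mL) at which `a*_base` and
#'   `dCY_consume` are quoted.
#'
#' @return An object of class `th_params` (a validated named list).
#' @seealso [apply_density()], [drift()], [read_parameters()]
#' @examples
#' par <- model_parameters()
#' is_symmetric(par)
#' @export
model_parameters <- function(b = 2,
                             p1 = 10, p2 = 10, P1 = 50, P2 = 50, hp = 2,
                             X1 = 60, X2 = 60, hx = 2,
                             s1 = 7, s2 = 7, S1 = 0.5, S2 = 0.5, hs = 2,
                             Z1 = 10, Z2 = 10, hz = 2,
                             a1_base = 2, a2_base = 2, A1 = 5, A2 = 5,
                             ha = 2,
                             R1 = 100, R2 = 100, hr = 2,
                             U1 = 5, U2 = 5, hu = 2,
                             dTF1 = 0.1, dTF2 = 0.1,
                             dCY_consume = 0.008, dCY_free = 1,
                             n_TF1 = 0.1, n_TF2 = 0.1,
                             n_CY1 = 0.1, n_CY2 = 0.1,
                             kappa_apc = 0.0108,
                             rho_ref = 1e6) {
  par <- list(b = b, p1 = p1, p2 = p2, P1 = P1, P2 = P2, hp = hp,
              X1 = X1, X2 = X2, hx = hx,
              s1 = s1, s2 = s2, S1 = S1, S2 = S2, hs = hs,
              Z1 = Z1, Z2 = Z2, hz = hz,
              a1_base = a1_base, a2_base = a2_base, A1 = A1, A2 = A2,
              ha = ha, R1 = R1, R2 = R2, hr = hr,
              U1 = U1, U2 = U2, hu = hu,
              dTF1 = dTF1, dTF2 = dTF2,
              dCY_consume = dCY_consume, dCY_free = dCY_free,
              n_TF1 = n_TF1, n_TF2 = n_TF2, n_CY1 = n_CY1, n_CY2 = n_CY2,
              kappa_apc = kappa_apc, rho_ref = rho_ref)
  validate_parameters(par)
}

## field groups used by validation and by the sensitivity module
.th_rate_fields <- c("b", "p1", "p2", "P1", "P2", "X1", "X2",
                     "s1", "s2", "S1", "S2", "Z1", "Z2",
                     "a1_base", "a2_base", "A1", "A2", "R1", "R2",
                     "U1", "U2", "dTF1", "dTF2",
                     "dCY_consume", "dCY_free", "kappa_apc", "rho_ref")
.th_hill_fields <- c("hp", "hx", "hs", "hz", "ha", "hr", "hu")
.th_noise_fields <- c("n_TF1", "n_TF2", "n_CY1", "n_CY2")
.th_param_fields <- c(.th_rate_fields, .th_hill_fields, .th_noise_fields)

validate_parameters <- function(par) {
  missing <- setdiff(.th_param_fields, names(par))
  if (length(missing) > 0L) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  }
  for (f in .th_param_fields) {
    v <- par[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number")
    }
  }
  for (f in .th_rate_fields) {
    if (par[[f]] <= 0 && f != "kappa_apc") {
      stop("parameter '", f, "' must be strictly positive (got ",
           par[[f]], ")")
    }
  }
  if (par$kappa_apc < 0) stop("parameter 'kappa_apc' must be non-negative")
  for (f in .th_hill_fields) {
    if (par[[f]] < 1) {
      stop("Hill exponent '", f, "' must be >= 1 (got ", par[[f]], ")")
    }
  }
  for (f in .th_noise_fields) {
    if (par[[f]] < 0) {
      stop("noise magnitude '", f, "' must be >= 0 (got ", par[[f]], ")")
    }
  }
  par <- par[.th_param_fields]
  structure(par, class = "th_params")
}

#' Test whether a parameter set is index-symmetric
#'
#' A parameter set is symmetric when every Th1-axis value equals its Th2-axis
#' partner (`p1 == p2`, `X1 == X2`, ..., `n_CY1 == n_CY2`).  Under a symmetric
#' set the model commutes exactly with the swap
#' `(TF1, CY1) <-> (TF2, CY2)`.
#'
#' @param par a [model_parameters()] object.
#' @param tol relative comparison tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
is_symmetric <- function(par, tol = 1e-12) {
  stopifnot(inherits(par, "th_params"))
  pairs <- list(c("p1", "p2"), c("P1", "P2"), c("X1", "X2"),
                c("s1", "s2"), c("S1", "S2"), c("Z1", "Z2"),
                c("a1_base", "a2_base"), c("A1", "A2"), c("R1", "R2"),
                c("U1", "U2"), c("dTF1", "dTF2"),
                c("n_TF1", "n_TF2"), c("n_CY1", "n_CY2"))
  all(vapply(pairs, function(pr) {
    a <- par[[pr[1]]]; b <- par[[pr[2]]]
    abs(a - b) <= tol * max(abs(a), abs(b), 1)
  }, logical(1)))
}

#' @export
print.th_params <- function(x, ...) {
  cat("Th1/Th2 quorum-sensing model parameters\n")
  cat(sprintf("  symmetric: %s\n", is_symmetric(x)))
  cat(sprintf("  reference density: %.3g cells/mL\n", x$rho_ref))
  v <- unlist(x)
  for (i in seq(1, length(v), by = 6)) {
    j <- min(i + 5, length(v))
    cat("  ", paste(sprintf("%s=%.4g", names(v)[i:j], v[i:j]),
                    collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a parameter file
#'
#' Parameter files are flat JSON objects, one key per [model_parameters()]
#' field.  `read_parameters()` validates the result and reports the offending
#' key on failure.
#'
#' @param path file path.
#' @return `read_parameters()` returns a `th_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) raw <- as.list(raw)
  extra <- setdiff(names(raw), .th_param_fields)
  if (length(extra) > 0L) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  }
  validate_parameters(raw)
}

#' @rdname read_parameters
#' @param par a `th_params` object to serialize.
#' @export
write_parameters <- function(par, path) {
  stopifnot(inherits(par, "th_params"))
  jsonlite::write_json(unclass(par), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## fixed parameter ordering shared with the compiled stepper
as_param_vector <- function(par) {
  unlist(par[c("b", "p1", "p2", "P1", "P2", "hp", "X1", "X2", "hx",
               "s1", "s2", "S1", "S2", "hs", "Z1", "Z2", "hz",
               "A1", "A2", "ha", "R1", "R2", "hr", "U1", "U2", "hu",
               "dTF1", "dTF2")])
}
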