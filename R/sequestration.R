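# Activator/inhibitor sequestration circuit: the proofread activator branch A
# and an earlier inhibitor branch I are produced from the same receptor,
# bind each other nearly irreversibly, and with matched production gains the
# non-cognate contribution to A is removed, yielding ligand antagonism.

#' Activator/inhibitor sequestration circuit parameters
#'
#' @param kA_prod,kI_prod production rate constants of the proofread
#'   activator (A) branch and the inhibitor (I) branch (> 0).
#' @param Tc kinetic-proofreading delay of the A branch (>= 0).
#' @param rA,rI first-order degradation rates of A and I (> 0); the closed
#'   forms assume \code{rA == rI}, the general quadratic does not.
#' @param rAI sequestration (mutual binding/inactivation) rate constant
#'   (> 0).
#' @return An object of class \code{sequestration_circuit} with a
#'   \code{matched_gain} flag set when
#'   \eqn{k_A = k_I e^{r_{nc} T^c}} to within 1e-12 relative; the matched
#'   gain is what cancels the non-cognate drive from the A branch. The
#'   non-cognate unbinding rate is only known at production-rate time, so
#'   the flag is finalised by \code{\link{production_rates}}.
#' @export
sequestration_circuit <- function(kA_prod, kI_prod, Tc, rA, rI, rAI) {
  vals <- c(kA_prod = kA_prod, kI_prod = kI_prod, rA = rA, rI = rI,
            rAI = rAI)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all circuit rate constants must be positive")
  if (Tc < 0) stop("Tc must be >= 0")
  structure(list(kA_prod = kA_prod, kI_prod = kI_prod, Tc = Tc,
                 rA = rA, rI = rI, rAI = rAI),
            class = "sequestration_circuit")
}

#' Matched-gain activator production rate
#'
#' Returns the A-branch production rate \eqn{k_A = k_I e^{r_{nc} T^c}} that
#' exactly cancels the non-cognate ligand's contribution to the difference of
#' the two branch drives.
#'
#' @param kI_prod inhibitor-branch production rate.
#' @param r_nc non-cognate unbinding rate.
#' @param Tc proofreading delay of the A branch.
#' @return Matched \eqn{k_A}.
#' @export
matched_gain <- function(kI_prod, r_nc, Tc) kI_prod * exp(r_nc * Tc)

is_matched_gain <- function(circuit, r_nc) {
  target <- matched_gain(circuit$kI_prod, r_nc, circuit$Tc)
  abs(circuit$kA_prod - target) <= 1e-12 * target
}

#' Branch drive (production) rates of the sequestration circuit
#'
#' Mean production rates of the two branches given the ligand mixture:
#' \deqn{\beta_A = \frac{(k_c c_c/r_c) e^{-r_c T^c} +
#'   (k_{nc} c_{nc}/r_{nc}) e^{-r_{nc} T^c}}
#'   {1 + k_c c_c/r_c + k_{nc} c_{nc}/r_{nc}}\, k_A, \qquad
#'   \beta_I = \frac{k_c c_c/r_c + k_{nc} c_{nc}/r_{nc}}
#'   {1 + k_c c_c/r_c + k_{nc} c_{nc}/r_{nc}}\, k_I.}
#' With the matched gain \eqn{k_A = k_I e^{r_{nc} T^c}} the difference
#' \eqn{\beta_A - \beta_I} has the non-cognate-independent numerator
#' \eqn{(k_c c_c/r_c)(e^{(r_{nc}-r_c) T^c} - 1)\, k_I > 0} whenever the
#' cognate ligand is present.
#'
#' @param truth a \code{ligand_mixture} with the true concentrations.
#' @param circuit a \code{sequestration_circuit}.
#' @return List with \code{beta_A}, \code{beta_I} and the finalised
#'   \code{matched} flag.
#' @export
production_rates <- function(truth, circuit) {
  check_two_species(truth)
  stopifnot(inherits(circuit, "sequestration_circuit"))
  oc <- occupancy_parts(truth)
  Tc <- circuit$Tc
  numA <- oc$w[1L] * exp(-truth$r[1L] * Tc) +
          oc$w[2L] * exp(-truth$r[2L] * Tc)
  list(beta_A = unname(numA / oc$denom * circuit$kA_prod),
       beta_I = unname(sum(oc$w) / oc$denom * circuit$kI_prod),
       matched = is_matched_gain(circuit, truth$r[2L]))
}

#' Steady state of the sequestration circuit
#'
#' Solves the stationary conditions of the coupled rate equations
#' \deqn{\dot A = \beta_A - r_A A - r_{AI} A I, \qquad
#'       \dot I = \beta_I - r_I I - r_{AI} A I.}
#' Eliminating \eqn{I = \beta_I / (r_I + r_{AI} A)} gives the quadratic
#' \deqn{A^2 + \left(\frac{r_I}{r_{AI}} +
#'   \frac{\beta_I - \beta_A}{r_A}\right) A -
#'   \frac{\beta_A r_I}{r_{AI} r_A} = 0,}
#' whose positive root is returned; \eqn{I} follows from the elimination, so
#' the solution is exact for general \eqn{r_A \ne r_I}. A warning is issued
#' when degradation is not negligible against sequestration
#' (\eqn{r_A/(r_{AI} A_{ss}) > 0.1}), outside the regime in which the
#' simplified closed forms are quantitative.
#'
#' @param beta_A,beta_I branch drive rates (>= 0).
#' @param circuit a \code{sequestration_circuit}.
#' @param warn warn when outside the sequestration-dominated regime.
#' @return An object of class \code{sequestration_state}: \code{A_ss},
#'   \code{I_ss}, \code{beta_A}, \code{beta_I}, and \code{residual_A},
#'   \code{residual_I}, the relative residuals of the stationarity
#'   conditions.
#' @export
steady_state <- function(beta_A, beta_I, circuit, warn = TRUE) {
  stopifnot(inherits(circuit, "sequestration_circuit"),
            beta_A >= 0, beta_I >= 0)
  rA <- circuit$rA; rI <- circuit$rI; rAI <- circuit$rAI
  b <- rI / rAI + (beta_I - beta_A) / rA
  q <- beta_A * rI / (rAI * rA)
  disc <- b^2 + 4 * q
  stopifnot(disc >= 0)  # always true for valid (non-negative) inputs
  # stable positive root: avoid cancellation when b > 0 and 4q << b^2
  A_ss <- if (b >= 0) 2 * q / (b + sqrt(disc)) else (-b + sqrt(disc)) / 2
  I_ss <- beta_I / (rI + rAI * A_ss)
  resid <- function(num, den) if (den > 0) abs(num) / den else abs(num)
  res_A <- resid(beta_A - rA * A_ss - rAI * A_ss * I_ss, max(beta_A, rA * A_ss))
  res_I <- resid(beta_I - rI * I_ss - rAI * A_ss * I_ss, max(beta_I, rI * I_ss))
  if (warn && A_ss > 0 && rA / (rAI * A_ss) > 0.1)
    warning("degradation is not negligible against sequestration ",
            "(rA / (rAI * A_ss) > 0.1); closed-form limits are approximate")
  structure(list(A_ss = A_ss, I_ss = I_ss, beta_A = beta_A,
                 beta_I = beta_I, residual_A = res_A, residual_I = res_I),
            class = "sequestration_state")
}

#' @export
print.sequestration_state <- function(x, ...) {
  cat("sequestration_state: A_ss =", format(x$A_ss),
      ", I_ss =", format(x$I_ss), "\n")
  invisible(x)
}

#' Integrate the sequestration dynamics
#'
#' Forward integration of the coupled nonlinear rate equations for (A, I)
#' with an adaptive-step solver (relative tolerance 1e-9). From zero initial
#' conditions the trajectory approaches the closed-form steady state
#' monotonically.
#'
#' @param circuit a \code{sequestration_circuit}.
#' @param beta_A,beta_I branch drive rates.
#' @param t_end integration end time.
#' @param init initial levels \code{c(A, I)}.
#' @param n_out number of output time points.
#' @return Data frame with columns \code{time}, \code{A}, \code{I}.
#' @export
integrate_dynamics <- function(circuit, beta_A, beta_I, t_end,
                               init = c(A = 0, I = 0), n_out = 200L) {
  stopifnot(inherits(circuit, "sequestration_circuit"), t_end > 0)
  deriv <- function(t, y, parms) {
    sAI <- circuit$rAI * y[1L] * y[2L]
    list(c(beta_A - circuit$rA * y[1L] - sAI,
           beta_I - circuit$rI * y[2L] - sAI))
  }
  times <- seq(0, t_end, length.out = n_out)
  y0 <- c(A = unname(init[1L]), I = unname(init[2L]))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      rtol = 1e-9, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time", "A", "I")
  out
}

#' Antagonism curve: steady-state activator vs non-cognate concentration
#'
#' Evaluates the steady-state activator level across a grid of non-cognate
#' concentrations at fixed cognate concentration. With matched gains and
#' sequestration dominating degradation, the activator level is a decreasing
#' function of the non-cognate concentration whenever the cognate ligand is
#' present (the non-cognate ligand antagonises the response), but an
#' increasing one when the cognate ligand is absent (a weak ligand alone is
#' an agonist).
#'
#' @param truth a \code{ligand_mixture} template; its non-cognate
#'   concentration is swept.
#' @param circuit a \code{sequestration_circuit}.
#' @param c_nc_grid numeric vector of non-cognate concentrations.
#' @return Data frame with columns \code{c_nc}, \code{beta_A}, \code{beta_I},
#'   \code{A_ss}, \code{I_ss}.
#' @export
antagonism_curve <- function(truth, circuit, c_nc_grid) {
  check_two_species(truth)
  rows <- lapply(c_nc_grid, function(cnc) {
    mix <- set_concentrations(truth, c(truth$c[1L], cnc))
    pr <- production_rates(mix, circuit)
    ss <- steady_state(pr$beta_A, pr$beta_I, circuit, warn = FALSE)
    data.frame(c_nc = cnc, beta_A = pr$beta_A, beta_I = pr$beta_I,
               A_ss = ss$A_ss, I_ss = ss$I_ss)
  })
  do.call(rbind, rows)
}

#' Read a sequestration circuit from JSON
#'
#' Layout: \code{{"kA_prod":..,"kI_prod":..,"Tc":..,"rA":..,"rI":..,
#' "rAI":..}}; \code{kA_prod} may be the string \code{"matched"} together
#' with a \code{"r_nc"} field, in which case the matched gain
#' \eqn{k_I e^{r_{nc} T^c}} is used.
#'
#' @param path file path.
#' @return A \code{sequestration_circuit}.
#' @export
read_circuit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kA <- obj$kA_prod
  if (identical(kA, "matched")) {
    if (is.null(obj$r_nc))
      stop("matched-gain circuit JSON needs an 'r_nc' field")
    kA <- matched_gain(obj$kI_prod, obj$r_nc, obj$Tc)
  }
  sequestration_circuit(kA_prod = kA, kI_prod = obj$kI_prod, Tc = obj$Tc,
                        rA = obj$rA, rI = obj$rI, rAI = obj$rAI)
}
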