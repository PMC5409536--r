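# Mean-field two-branch kinetic-proofreading readout: messenger A is produced
# only during bindings longer than the proofreading delay Tc, messenger B
# whenever the receptor is bound; inversion of the mean readouts back to the
# two concentrations, renormalization for a random proofreading delay, and
# the readout noise.

#' Two-branch kinetic-proofreading network parameters
#'
#' @param kA,kB production rates of the proofread (A) and occupancy (B)
#'   messengers (> 0).
#' @param rA,rB first-order deactivation rates (> 0).
#' @param Tc_mean mean kinetic-proofreading delay (>= 0).
#' @param Tc_var variance of the delay across proofreading realisations; 0
#'   for a deterministic (single path) delay.
#' @return An object of class \code{kpr_network}.
#' @export
kpr_network <- function(kA, rA, kB, rB, Tc_mean, Tc_var = 0) {
  vals <- c(kA = kA, rA = rA, kB = kB, rB = rB)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all production and deactivation rates must be positive")
  if (Tc_mean < 0 || Tc_var < 0) stop("Tc_mean and Tc_var must be >= 0")
  structure(list(kA = kA, rA = rA, kB = kB, rB = rB,
                 Tc_mean = Tc_mean, Tc_var = Tc_var),
            class = "kpr_network")
}

# occupancy weights: w_i = k_i c_i / r_i; denominator 1 + sum(w)
occupancy_parts <- function(truth) {
  w <- truth$k * truth$c / truth$r
  list(w = w, denom = 1 + sum(w))
}

#' Mean messenger levels of the two-branch KPR readout
#'
#' Closed-form stationary means of the two messengers driven by the receptor:
#' \deqn{\bar A = \frac{(k_c c_c/r_c) e^{-r_c T^c} +
#'   (k_{nc} c_{nc}/r_{nc}) e^{-r_{nc} T^c}}
#'   {1 + k_c c_c/r_c + k_{nc} c_{nc}/r_{nc}} \frac{k_A}{r_A}, \qquad
#'   \bar B = \frac{k_c c_c/r_c + k_{nc} c_{nc}/r_{nc}}
#'   {1 + k_c c_c/r_c + k_{nc} c_{nc}/r_{nc}} \frac{k_B}{r_B}.}
#'
#' @param truth a \code{ligand_mixture} with the true concentrations.
#' @param net a \code{kpr_network}; its \code{Tc_mean} is used as the delay.
#' @param cognate_only if \code{TRUE}, drop the non-cognate term from the
#'   numerator of \eqn{\bar A} (the rare-long-event idealisation under which
#'   the exact inversion is an identity).
#' @return List with \code{A_mean}, \code{B_mean} and \code{eps}, the
#'   receptor-occupancy saturation \eqn{\epsilon = \bar B/(k_B/r_B)}.
#' @export
mean_readouts <- function(truth, net, cognate_only = FALSE) {
  check_two_species(truth)
  stopifnot(inherits(net, "kpr_network"))
  oc <- occupancy_parts(truth)
  Tc <- net$Tc_mean
  numA <- oc$w[1L] * exp(-truth$r[1L] * Tc)
  if (!cognate_only) numA <- numA + oc$w[2L] * exp(-truth$r[2L] * Tc)
  A_mean <- numA / oc$denom * net$kA / net$rA
  B_mean <- sum(oc$w) / oc$denom * net$kB / net$rB
  list(A_mean = unname(A_mean), B_mean = unname(B_mean),
       eps = unname(B_mean / (net$kB / net$rB)))
}

#' Exact inversion of the mean readouts to concentrations
#'
#' Solves the stationary readout relations for the concentrations, keeping
#' the receptor-occupancy correction exactly:
#' \deqn{c_c = \bar A e^{r_c T^c} \frac{r_c r_A}{k_c k_A} (1 + q), \qquad
#'   c_{nc} = \frac{r_{nc}}{k_{nc}}\left[q - \bar A e^{r_c T^c}
#'   \frac{r_A}{k_A}(1 + q)\right],}
#' with \eqn{q = \bar B / (k_B/r_B - \bar B)}. Valid under the
#' all-long-events-are-cognate idealisation; applied to means computed from
#' the full numerator it inherits the same long-non-cognate-event bias as the
#' threshold estimator.
#'
#' @param A_mean,B_mean mean messenger levels.
#' @param net a \code{kpr_network}.
#' @param rates a \code{ligand_mixture} with the known rates.
#' @return Named concentration vector. Errors when \code{B_mean} is at or
#'   beyond the saturation level \eqn{k_B/r_B}.
#' @export
invert_exact <- function(A_mean, B_mean, net, rates) {
  check_two_species(rates)
  stopifnot(inherits(net, "kpr_network"))
  Bmax <- net$kB / net$rB
  if (B_mean >= Bmax)
    stop("readout saturated: B_mean >= kB/rB, inversion diverges")
  if (A_mean < 0 || B_mean < 0) stop("mean readouts must be non-negative")
  q <- B_mean / (Bmax - B_mean)
  Tc <- net$Tc_mean
  a_scaled <- A_mean * exp(rates$r[1L] * Tc) * net$rA / net$kA * (1 + q)
  c_c <- a_scaled * rates$r[1L] / rates$k[1L]
  c_nc <- rates$r[2L] / rates$k[2L] * (q - a_scaled)
  out <- c(c_c, c_nc)
  names(out) <- rates$labels
  out
}

#' Linearised inversion of the mean readouts
#'
#' First-order (small receptor occupancy, \eqn{\epsilon \ll 1}) inversion of
#' the mean readouts,
#' \deqn{c_c^{KPR} = \bar A e^{r_c T^c} \frac{r_c r_A}{k_c k_A}, \qquad
#'   c_{nc}^{KPR} = \frac{r_{nc}}{k_{nc}}\left(\frac{r_B \bar B}{k_B} -
#'   \bar A e^{r_c T^c} \frac{r_A}{k_A}\right),}
#' the biochemically realisable analogue of the threshold estimator: the
#' cognate estimate is a rescaling of the proofread messenger, and the
#' non-cognate one is the subtraction a downstream incoherent-feedforward
#' node (activated by B, suppressed by A) computes.
#'
#' @inheritParams invert_exact
#' @return Named concentration vector.
#' @export
invert_linear <- function(A_mean, B_mean, net, rates) {
  check_two_species(rates)
  stopifnot(inherits(net, "kpr_network"))
  if (A_mean < 0 || B_mean < 0) stop("mean readouts must be non-negative")
  Tc <- net$Tc_mean
  a_scaled <- A_mean * exp(rates$r[1L] * Tc) * net$rA / net$kA
  c_c <- a_scaled * rates$r[1L] / rates$k[1L]
  c_nc <- rates$r[2L] / rates$k[2L] * (net$rB * B_mean / net$kB - a_scaled)
  out <- c(c_c, c_nc)
  names(out) <- rates$labels
  out
}

#' Effective cutoff under a random proofreading delay
#'
#' A multi-step proofreading cascade traverses its intermediate states in a
#' random time, so the delay \eqn{T^c} has variance \eqn{\sigma^2_{T^c}}.
#' Averaging the rare-long-event count over the delay distribution
#' renormalises the cutoff to second order:
#' \deqn{T^c_{\mathrm{eff}} = \bar T^c - \tfrac{1}{2} r_c \sigma^2_{T^c}.}
#' Using the effective cutoff in the inversion removes the extra bias the
#' delay randomness would otherwise introduce.
#'
#' @param net a \code{kpr_network} (uses \code{Tc_mean} and \code{Tc_var}).
#' @param rates a \code{ligand_mixture} with the known rates (the cognate
#'   unbinding rate sets the correction).
#' @return Effective cutoff (time units).
#' @export
renormalized_cutoff <- function(net, rates) {
  check_two_species(rates)
  stopifnot(inherits(net, "kpr_network"))
  net$Tc_mean - 0.5 * rates$r[1L] * net$Tc_var
}

#' Expected long-event count under a random cutoff
#'
#' Second-order (in \eqn{r_c \sigma_{T^c}}) expansion of the expected number
#' of bound intervals exceeding a random cutoff with mean \code{Tc_mean} and
#' variance \code{Tc_var}, in the regime \eqn{\bar T^c \gg 1/r_{nc}} where
#' non-cognate long events are negligible:
#' \deqn{\bar{\langle n_l \rangle} \approx n\, \frac{k_c c_c\,
#'   e^{-r_c \bar T^c + \frac{1}{2} r_c^2 \sigma^2_{T^c}}}
#'   {k_c c_c + k_{nc} c_{nc}}.}
#'
#' @param truth a \code{ligand_mixture} with the true concentrations.
#' @param net a \code{kpr_network}.
#' @param n number of binding events.
#' @return Expected long-event count.
#' @export
expected_long_events <- function(truth, net, n) {
  check_two_species(truth)
  r_c <- truth$r[1L]
  n * truth$k[1L] * truth$c[1L] *
    exp(-r_c * net$Tc_mean + 0.5 * r_c^2 * net$Tc_var) /
    truth$total_on_rate
}

#' Relative variance of the proofread readout
#'
#' Stationary relative variance of the proofread messenger A in the
#' rare-long-event regime, from noise propagation through the linear
#' birth-death readout driven by Poissonian long-binding arrivals:
#' \deqn{\frac{\sigma^2_A}{\bar A^2} \approx
#'   \left(1 + \frac{k_c c_c}{r_c} + \frac{k_{nc} c_{nc}}{r_{nc}}\right)
#'   \frac{e^{r_c T^c - \frac{1}{2} r_c^2 \sigma^2_{T^c}}}
#'   {k_c c_c (1/r_c + 1/r_A)}.}
#' Intrinsic production shot noise is neglected (it can be made arbitrarily
#' small by raising \eqn{k_A}); dropping the occupancy factor gives the
#' leading small-\eqn{\epsilon} form. The same \eqn{e^{r_c T^c}} growth as in
#' the threshold-estimator variance appears: long events are what carries the
#' information and they are rare.
#'
#' @param truth a \code{ligand_mixture} with the true concentrations.
#' @param net a \code{kpr_network}.
#' @param occupancy_factor include the \eqn{1 + \sum k_i c_i / r_i} factor
#'   (default \code{TRUE}); \code{FALSE} gives the leading-order form.
#' @return Relative variance \eqn{\sigma^2_A/\bar A^2}.
#' @export
readout_relvar <- function(truth, net, occupancy_factor = TRUE) {
  check_two_species(truth)
  stopifnot(inherits(net, "kpr_network"))
  r_c <- truth$r[1L]
  fac <- if (occupancy_factor) occupancy_parts(truth)$denom else 1
  fac * exp(r_c * net$Tc_mean - 0.5 * r_c^2 * net$Tc_var) /
    (truth$k[1L] * truth$c[1L] * (1 / r_c + 1 / net$rA))
}

#' Read a KPR network from JSON
#'
#' Layout: \code{{"kA":..,"rA":..,"kB":..,"rB":..,"Tc_mean":..,"Tc_var":..}}.
#'
#' @param path file path.
#' @return A \code{kpr_network}.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kpr_network(kA = obj$kA, rA = obj$rA, kB = obj$kB, rB = obj$rB,
              Tc_mean = obj$Tc_mean,
              Tc_var = if (is.null(obj$Tc_var)) 0 else obj$Tc_var)
}
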