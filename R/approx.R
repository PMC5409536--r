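# Long-event threshold estimator of the two concentrations, its analytic
# bias/variance/loss, and the bias-variance-optimal cutoff.

check_two_species <- function(rates) {
  if (!inherits(rates, "ligand_mixture") || length(rates$k) != 2L)
    stop("expected a two-species ligand_mixture")
  invisible(rates)
}

#' Threshold (long-event) estimate of the two concentrations
#'
#' Counts the bound intervals at least as long as the cutoff \code{Tc},
#' attributes them to the cognate ligand, and rescales by
#' \eqn{e^{r_c T^c}} to correct for the cognate events shorter than the
#' cutoff:
#' \deqn{c_c^a = \frac{n_l e^{r_c T^c}}{k_c T^u}, \qquad
#'       c_{nc}^a = \frac{n - n_l e^{r_c T^c}}{k_{nc} T^u}.}
#' The two estimates satisfy
#' \eqn{k_c c_c^a + k_{nc} c_{nc}^a = n/T^u} exactly for every trace and
#' cutoff. A bound interval exactly equal to \code{Tc} counts as long.
#' \eqn{c_{nc}^a} can be negative in finite samples; it is returned as-is
#' (flagged) by default so that the bias/variance algebra of the error model
#' holds, with optional clipping at zero.
#'
#' @param trace a \code{binding_trace}.
#' @param Tc cutoff duration (>= 0).
#' @param rates a \code{ligand_mixture} with the known rates (two species).
#' @param clip if \code{TRUE}, clip a negative non-cognate estimate to zero.
#' @return An object of class \code{approx_result}: \code{Tc}, \code{n_l},
#'   \code{c_hat} (named estimates), \code{negative_nc} flag.
#' @export
approx_estimate <- function(trace, Tc, rates, clip = FALSE) {
  stopifnot(inherits(trace, "binding_trace"), Tc >= 0)
  check_two_species(rates)
  n_l <- sum(trace$tau_b >= Tc)
  scale <- n_l * exp(rates$r[1L] * Tc)
  c_c <- scale / (rates$k[1L] * trace$Tu)
  c_nc <- (trace$n - scale) / (rates$k[2L] * trace$Tu)
  negative_nc <- c_nc < 0
  if (clip && negative_nc) c_nc <- 0
  c_hat <- c(c_c, c_nc)
  names(c_hat) <- rates$labels
  structure(list(Tc = Tc, n_l = n_l, c_hat = c_hat,
                 negative_nc = negative_nc, clipped = clip && negative_nc,
                 n = trace$n, Tu = trace$Tu),
            class = "approx_result")
}

#' @export
print.approx_result <- function(x, ...) {
  cat("approx_result: Tc =", format(x$Tc), ", n_l =", x$n_l,
      ", c_hat =", paste(format(x$c_hat), collapse = ", "),
      if (x$negative_nc) "(negative non-cognate)" else "", "\n")
  invisible(x)
}

#' Analytic expectation of the threshold cognate estimate
#'
#' In the rare-long-event regime (\eqn{T^c \gg 1/r_{nc}}) the expected value
#' of the threshold cognate estimate is
#' \deqn{\langle c_c^a \rangle \approx c_c +
#'   \frac{k_{nc} c_{nc}}{k_c} e^{-(r_{nc}-r_c) T^c},}
#' i.e. the true concentration plus a positive bias from non-cognate events
#' that survive the cutoff.
#'
#' @param truth a \code{ligand_mixture} with the true concentrations.
#' @param Tc cutoff duration. A warning is issued when \code{r_nc * Tc < 3},
#'   outside the validity regime.
#' @return Expected value of \eqn{c_c^a}.
#' @export
analytic_bias_mean <- function(truth, Tc) {
  check_two_species(truth)
  if (truth$r[2L] * Tc < 3)
    warning("r_nc * Tc < 3: outside the rare-long-event validity regime")
  truth$c[1L] + (truth$k[2L] * truth$c[2L] / truth$k[1L]) *
    exp(-(truth$r[2L] - truth$r[1L]) * Tc)
}

#' Analytic variance of the threshold cognate estimate
#'
#' Long events are rare and independent, so their count is Poisson; the
#' resulting variance of the cognate estimate is
#' \deqn{\sigma^2(c_c^a) \approx \langle c_c^a \rangle
#'   \left(c_c + \frac{k_{nc} c_{nc}}{k_c}\right) \frac{e^{r_c T^c}}{n}.}
#'
#' @inheritParams analytic_bias_mean
#' @param n number of binding events per trace.
#' @return Variance of \eqn{c_c^a}.
#' @export
analytic_variance <- function(truth, Tc, n) {
  check_two_species(truth)
  mean_cca <- suppressWarnings(analytic_bias_mean(truth, Tc))
  mean_cca * (truth$c[1L] + truth$k[2L] * truth$c[2L] / truth$k[1L]) *
    exp(truth$r[1L] * Tc) / n
}

#' Analytic loss (variance + squared bias) of the threshold estimates
#'
#' \deqn{L_c = \sigma^2(c_c^a) + (c_c - \langle c_c^a \rangle)^2.}
#' The exact linear constraint \eqn{k_c c_c^a + k_{nc} c_{nc}^a = n/T^u}
#' propagates the cognate error model to the non-cognate estimate: to the
#' extent that the variability of \eqn{T^u} is negligible against that of the
#' long-event count, \eqn{\mathrm{bias}_{nc} = -(k_c/k_{nc})\,
#' \mathrm{bias}_c} and \eqn{\sigma^2(c_{nc}^a) = (k_c/k_{nc})^2
#' \sigma^2(c_c^a)}.
#'
#' @inheritParams analytic_variance
#' @return Named numeric vector \code{c(L_c, L_nc)}.
#' @export
approx_loss <- function(truth, Tc, n) {
  check_two_species(truth)
  bias_c <- suppressWarnings(analytic_bias_mean(truth, Tc)) - truth$c[1L]
  var_c <- analytic_variance(truth, Tc, n)
  ratio <- truth$k[1L] / truth$k[2L]
  c(L_c = var_c + bias_c^2,
    L_nc = ratio^2 * var_c + (ratio * bias_c)^2)
}

#' Bias-variance-optimal cutoff and the fixed reference cutoff
#'
#' The cutoff minimising the cognate loss \eqn{L_c} (with the true
#' concentration used in the variance, valid near the optimum where the bias
#' is small) has the closed form
#' \deqn{T^{c*} = \frac{1}{2 r_{nc} - r_c}
#'   \log\!\left[2 T^u \left(\frac{r_{nc}}{r_c} - 1\right)
#'   \frac{k_{nc}^2 c_{nc}^2}{k_c c_c}\right].}
#' It depends only logarithmically on the concentrations and on the
#' observation length, which is what makes a fixed cutoff near-optimal over a
#' broad concentration range. The reference cutoff \eqn{T_0} is \eqn{T^{c*}}
#' evaluated at the reference on-rates \eqn{k_c c_c = k_{nc} c_{nc} = 1/2}.
#'
#' @param truth a \code{ligand_mixture} with the true concentrations.
#' @param Tu total unbound time; defaults to its expectation
#'   \eqn{n / (k_c c_c + k_{nc} c_{nc})} when \code{n} is given instead.
#' @param n number of binding events, used to form the expected \code{Tu}
#'   when \code{Tu} is not supplied.
#' @return Optimal cutoff (time units). Errors when the argument of the
#'   logarithm is not greater than 1 (no finite positive optimum).
#' @export
optimal_cutoff <- function(truth, Tu = NULL, n = NULL) {
  check_two_species(truth)
  if (is.null(Tu)) {
    if (is.null(n)) stop("supply either Tu or n")
    Tu <- n / truth$total_on_rate
  }
  r_c <- truth$r[1L]; r_nc <- truth$r[2L]
  arg <- 2 * Tu * (r_nc / r_c - 1) *
    (truth$k[2L] * truth$c[2L])^2 / (truth$k[1L] * truth$c[1L])
  if (arg <= 1)
    stop("no finite positive optimal cutoff: log argument <= 1")
  log(arg) / (2 * r_nc - r_c)
}

#' @rdname optimal_cutoff
#' @param rates a \code{ligand_mixture} supplying the rates; its
#'   concentrations are replaced by the reference point
#'   \eqn{k_c c_c = k_{nc} c_{nc} = 1/2}.
#' @export
reference_cutoff <- function(rates, Tu = NULL, n = NULL) {
  check_two_species(rates)
  ref <- set_concentrations(rates, 0.5 / rates$k)
  optimal_cutoff(ref, Tu = Tu, n = n)
}
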