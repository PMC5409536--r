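# Exact maximum-likelihood inference of two ligand concentrations from a
# binding/unbinding trace, with Hessian (Cramer-Rao) error estimates.

# log of the bound-interval density weight
#   D(c, tau) = sum_i k_i c_i r_i exp(-tau r_i)
# evaluated per event in log space (tau * r can exceed 700).
log_D <- function(tau_b, k, r, c) {
  terms <- vapply(seq_along(k), function(i) {
    if (c[i] <= 0) rep(-Inf, length(tau_b))
    else log(k[i] * c[i] * r[i]) - tau_b * r[i]
  }, numeric(length(tau_b)))
  if (is.null(dim(terms))) terms <- matrix(terms, nrow = length(tau_b))
  m <- apply(terms, 1L, max)
  out <- m + log(rowSums(exp(terms - m)))
  out[!is.finite(m)] <- -Inf
  out
}

#' Log-likelihood of ligand concentrations given a trace
#'
#' Evaluates the log-likelihood of the concentration vector \code{c} given
#' the observed bound/unbound intervals,
#' \deqn{\log P = -T^u \sum_i k_i c_i + \sum_j \log D(c, \tau^b_j),}
#' with \eqn{D(c,\tau) = \sum_i k_i c_i r_i e^{-r_i \tau}}, up to an additive
#' constant independent of the concentrations (the sequence-count
#' normalisation is dropped, as its concentration derivatives vanish in the
#' estimation equations).
#'
#' @param trace a \code{binding_trace}.
#' @param c numeric vector of concentrations, one per species (>= 0, not all
#'   zero; an all-zero vector returns \code{-Inf}).
#' @param rates a \code{ligand_mixture} supplying the known binding and
#'   unbinding rates (its concentrations are ignored).
#' @return Scalar log-likelihood; \code{-Inf} when no species has positive
#'   concentration.
#' @examples
#' tr <- binding_trace(tau_b = 1, tau_u = 1)
#' mix <- ligand_mixture(ligand_species("only", k = 1, r = 1, c = 1))
#' log_likelihood(tr, c = 1, rates = mix)  # -2
#' @export
log_likelihood <- function(trace, c, rates) {
  stopifnot(inherits(trace, "binding_trace"),
            inherits(rates, "ligand_mixture"),
            length(c) == length(rates$k))
  if (any(c < 0)) stop("concentrations must be non-negative")
  if (all(c == 0)) return(-Inf)
  -trace$Tu * sum(rates$k * c) + sum(log_D(trace$tau_b, rates$k, rates$r, c))
}

# Profile of the log-likelihood along the total-on-rate constraint
#   k_c c_c + k_nc c_nc = n / Tu,
# parameterised by the cognate on-rate fraction f in [0, 1]. Along the line
# the unbound-time term is constant, so maximising reduces to maximising
#   g(f) = sum_j log(f a_j + (1 - f) b_j),
# a_j = r_c e^{-r_c tau_j}, b_j = r_nc e^{-r_nc tau_j}. g is concave, so the
# interior optimum is the unique root of g'(f).
profile_terms <- function(trace, rates) {
  la <- log(rates$r[1L]) - trace$tau_b * rates$r[1L]
  lb <- log(rates$r[2L]) - trace$tau_b * rates$r[2L]
  m <- pmax(la, lb)
  list(a = exp(la - m), b = exp(lb - m))   # common scale factors out of g'
}

profile_grad <- function(f, pt) {
  d <- pt$a - pt$b
  sum(d / (f * pt$a + (1 - f) * pt$b))
}

#' Maximum-likelihood fit of two ligand concentrations
#'
#' Solves the ML estimation equations for the two concentrations. The
#' stationarity conditions imply the exact identity
#' \eqn{k_c c_c^* + k_{nc} c_{nc}^* = n / T^u}: the total on-rate is fixed by
#' the mean unbound interval. The 2-D problem therefore reduces to a 1-D
#' concave maximisation along that constraint line, parameterised by the
#' cognate on-rate fraction \eqn{f \in [0,1]}; the interior optimum is
#' bracketed and found by root-finding on the profile gradient. When the
#' profile likelihood is monotone, the better endpoint (one concentration
#' exactly zero) is returned with \code{boundary = TRUE}.
#'
#' @param trace a \code{binding_trace} with at least 2 events.
#' @param rates a \code{ligand_mixture} with the known rates (two species).
#' @param tol relative tolerance on the on-rate fraction (default 1e-8).
#' @param truth optional \code{ligand_mixture} holding the true
#'   concentrations; when supplied, the scaled errors \code{E} use the true
#'   concentrations in the denominator, otherwise the estimates are used.
#' @return An object of class \code{ml_result}: \code{c_hat} (named
#'   estimates), \code{f} (cognate on-rate fraction), \code{loglik},
#'   \code{covariance} (inverse negative Hessian at the optimum; \code{NA}
#'   matrix at a boundary optimum), \code{E} (per-species scaled error
#'   \eqn{n \sigma^2(c^*)/c^2}), \code{rho} (correlation of the two
#'   estimates), \code{converged}, \code{boundary}.
#' @export
solve_ml <- function(trace, rates, tol = 1e-8, truth = NULL) {
  stopifnot(inherits(trace, "binding_trace"),
            inherits(rates, "ligand_mixture"))
  if (length(rates$k) != 2L)
    stop("solve_ml expects a two-species rate model")
  if (trace$n < 2L) stop("need at least 2 binding events")
  S <- trace$n / trace$Tu                  # total on-rate from Eq. identity
  pt <- profile_terms(trace, rates)
  g0 <- profile_grad(0, pt)
  g1 <- profile_grad(1, pt)
  boundary <- FALSE
  converged <- TRUE
  if (g0 <= 0) {            # likelihood decreasing in f: all non-cognate
    f <- 0; boundary <- TRUE
  } else if (g1 >= 0) {     # increasing throughout: all cognate
    f <- 1; boundary <- TRUE
  } else {
    sol <- stats::uniroot(profile_grad, c(0, 1), pt = pt,
                          tol = tol, maxiter = 200L)
    f <- sol$root
    converged <- sol$estim.prec <= max(tol * 10, 1e-6)
  }
  c_hat <- c(f * S / rates$k[1L], (1 - f) * S / rates$k[2L])
  names(c_hat) <- rates$labels
  ll <- log_likelihood(trace, c_hat, rates)

  covar <- matrix(NA_real_, 2L, 2L)
  E <- c(NA_real_, NA_real_)
  rho <- NA_real_
  if (!boundary) {
    H <- ml_hessian(trace, c_hat, rates)
    covar <- solve(-H)
    c_ref <- if (!is.null(truth)) truth$c else c_hat
    E <- trace$n * diag(covar) / c_ref^2
    rho <- covar[1L, 2L] / sqrt(covar[1L, 1L] * covar[2L, 2L])
  }
  names(E) <- rates$labels
  structure(list(c_hat = c_hat, f = f, loglik = ll, covariance = covar,
                 E = E, rho = rho, n = trace$n, Tu = trace$Tu,
                 converged = converged, boundary = boundary),
            class = "ml_result")
}

#' @export
print.ml_result <- function(x, ...) {
  cat("ml_result: c_hat =", paste(format(x$c_hat), collapse = ", "),
      if (x$boundary) "(boundary)" else "", "\n")
  if (!x$boundary)
    cat("  E =", paste(format(x$E), collapse = ", "),
        " rho =", format(x$rho), "\n")
  invisible(x)
}

#' Hessian of the log-likelihood in the concentrations
#'
#' Analytic second-derivative matrix of the log-likelihood with respect to
#' the two concentrations,
#' \deqn{H_{\alpha\beta} = -\sum_j D_j^{-2}\, k_\alpha k_\beta r_\alpha
#'   r_\beta e^{-\tau^b_j (r_\alpha + r_\beta)},}
#' each entry a sum of negative terms, so the matrix is negative
#' semidefinite. Its inverse (negated) is the Cramer-Rao covariance bound on
#' the concentration estimates.
#'
#' @param trace a \code{binding_trace}.
#' @param c concentration vector at which to evaluate; both components must
#'   be strictly positive (at a boundary optimum use a profile-likelihood
#'   fallback instead).
#' @param rates a \code{ligand_mixture} with the known rates.
#' @return 2x2 numeric matrix.
#' @export
ml_hessian <- function(trace, c, rates) {
  stopifnot(inherits(trace, "binding_trace"),
            inherits(rates, "ligand_mixture"), length(c) == 2L)
  if (any(c <= 0))
    stop("Hessian requires interior concentrations (> 0); ",
         "use a profile-likelihood fallback at the boundary")
  k <- rates$k; r <- rates$r
  # per-event ratios u/D, v/D computed on a common scale to avoid underflow
  lu <- log(k[1L] * r[1L]) - trace$tau_b * r[1L]
  lv <- log(k[2L] * r[2L]) - trace$tau_b * r[2L]
  m <- pmax(lu, lv)
  u <- exp(lu - m); v <- exp(lv - m)
  D <- c[1L] * u + c[2L] * v
  ru <- u / D; rv <- v / D
  H <- matrix(c(-sum(ru^2), -sum(ru * rv),
                -sum(ru * rv), -sum(rv^2)), 2L, 2L)
  dimnames(H) <- list(rates$labels, rates$labels)
  H
}

#' Aggregate ML error metrics over replicate traces
#'
#' Computes the scaled errors \eqn{E = n \sigma^2(c^*)/c^2} and the
#' correlation \eqn{\rho} of the two estimates from a collection of ML fits
#' to replicate traces, two ways: (a) from the average inverse-Hessian
#' (Cramer-Rao) covariance of the per-trace fits, and (b) from the ensemble
#' variance of the estimates across replicates. Boundary fits carry no
#' Hessian and are excluded from (a), with the count reported.
#'
#' @param results list of \code{ml_result} objects from replicate traces of a
#'   common size.
#' @param truth a \code{ligand_mixture} with the true concentrations.
#' @return A list: \code{E_hessian}, \code{rho_hessian} (definition (a)),
#'   \code{E_ensemble}, \code{rho_ensemble} (definition (b); \code{NA} with a
#'   warning when fewer than 2 replicates), \code{mean_c_hat},
#'   \code{se_c_hat}, \code{mean_covariance}, \code{n_events},
#'   \code{n_replicates}, \code{n_boundary}.
#' @export
error_metrics <- function(results, truth) {
  stopifnot(is.list(results), length(results) >= 1L,
            inherits(truth, "ligand_mixture"))
  ok <- vapply(results, inherits, logical(1L), what = "ml_result")
  if (!all(ok)) stop("results must be ml_result objects")
  n_events <- results[[1L]]$n
  chat <- t(vapply(results, `[[`, numeric(2L), "c_hat"))
  interior <- !vapply(results, `[[`, logical(1L), "boundary")
  n_boundary <- sum(!interior)

  covs <- lapply(results[interior], `[[`, "covariance")
  if (length(covs) >= 1L) {
    mean_cov <- Reduce(`+`, covs) / length(covs)
    E_h <- n_events * diag(mean_cov) / truth$c^2
    rho_h <- mean_cov[1L, 2L] / sqrt(mean_cov[1L, 1L] * mean_cov[2L, 2L])
  } else {
    mean_cov <- matrix(NA_real_, 2L, 2L)
    E_h <- c(NA_real_, NA_real_); rho_h <- NA_real_
  }

  if (nrow(chat) >= 2L) {
    v <- apply(chat, 2L, stats::var)
    E_e <- n_events * v / truth$c^2
    rho_e <- stats::cor(chat[, 1L], chat[, 2L])
  } else {
    warning("fewer than 2 replicates: ensemble error variant omitted")
    E_e <- c(NA_real_, NA_real_); rho_e <- NA_real_
  }
  names(E_h) <- names(E_e) <- truth$labels
  list(E_hessian = E_h, rho_hessian = rho_h,
       E_ensemble = E_e, rho_ensemble = rho_e,
       mean_c_hat = colMeans(chat),
       se_c_hat = apply(chat, 2L, stats::sd) / sqrt(nrow(chat)),
       mean_covariance = mean_cov,
       n_events = n_events, n_replicates = length(results),
       n_boundary = n_boundary)
}
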