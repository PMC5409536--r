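# Shared fixtures: the standard two-ligand study conditions
# (r_nc = 1, k_c = k_nc = 1, c_c + c_nc = 1).

std_mixture <- function(r_c = 0.1, c_c = 0.5) {
  two_ligand_mixture(k_c = 1, r_c = r_c, c_c = c_c,
                     k_nc = 1, r_nc = 1, c_nc = 1 - c_c)
}

single_species_mixture <- function(k = 1, r = 1, c = 1) {
  ligand_mixture(ligand_species("only", k = k, r = r, c = c))
}

# mixture bound-interval CDF: weights proportional to k_i c_i
mixture_bound_cdf <- function(mix) {
  w <- mix$k * mix$c / sum(mix$k * mix$c)
  function(q) w[1L] * stats::pexp(q, mix$r[1L]) +
    w[2L] * stats::pexp(q, mix$r[2L])
}

# replicate threshold + ML fits on paired traces; returns matrices
fit_replicates <- function(mix, n_events, n_rep, master_seed, Tc = NULL) {
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_rep)
  chat_ml <- matrix(NA_real_, n_rep, 2L)
  var_ml <- matrix(NA_real_, n_rep, 2L)
  chat_a <- if (is.null(Tc)) NULL else matrix(NA_real_, n_rep, 2L)
  fits <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    tr <- sample_trace(mix, n_events, seed = seeds[i])
    f <- solve_ml(tr, mix, truth = mix)
    fits[[i]] <- f
    chat_ml[i, ] <- f$c_hat
    var_ml[i, ] <- diag(f$covariance)
    if (!is.null(Tc)) chat_a[i, ] <- approx_estimate(tr, Tc, mix)$c_hat
  }
  list(fits = fits, chat_ml = chat_ml, var_ml = var_ml, chat_a = chat_a)
}
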