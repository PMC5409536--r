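# Replicate simulation sweeps over unbinding-rate and concentration ratios:
# the ML error surface and the paired comparison of the fixed-cutoff
# threshold estimator against the ML estimator.

#' Sweep configuration
#'
#' Defines the simulation study grid under the standard normalisation
#' \eqn{r_{nc} = 1}, \eqn{k_c = k_{nc} = 1}, \eqn{c_c + c_{nc} = 1}: unit
#' non-cognate unbinding rate sets the time unit, equal diffusion-limited
#' binding rates, and unit total concentration sets the concentration unit.
#'
#' @param r_ratio_grid values of \eqn{r_c/r_{nc}} (each in (0, 1)).
#' @param c_ratio_grid values of \eqn{c_c/c_{nc}}.
#' @param n_events binding events per trace (>= 100).
#' @param n_replicates traces per grid point (>= 2).
#' @param master_seed integer master seed; per-replicate seeds are drawn once
#'   from it, so the whole sweep is reproducible.
#' @return An object of class \code{sweep_config}.
#' @export
sweep_config <- function(r_ratio_grid, c_ratio_grid,
                         n_events = 3000L, n_replicates = 500L,
                         master_seed = 1L) {
  stopifnot(length(r_ratio_grid) >= 1L, length(c_ratio_grid) >= 1L,
            all(r_ratio_grid > 0), all(r_ratio_grid < 1),
            all(c_ratio_grid > 0),
            n_events >= 100L, n_replicates >= 2L)
  structure(list(r_ratio_grid = as.numeric(r_ratio_grid),
                 c_ratio_grid = as.numeric(c_ratio_grid),
                 n_events = as.integer(n_events),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "sweep_config")
}

# One seed per replicate, drawn once from the master seed.
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

grid_mixture <- function(r_ratio, c_ratio) {
  c_c <- c_ratio / (1 + c_ratio)
  two_ligand_mixture(k_c = 1, r_c = r_ratio, c_c = c_c,
                     k_nc = 1, r_nc = 1, c_nc = 1 - c_c)
}

# Fit ML (and optionally the threshold estimator) on replicate traces of one
# grid point; paired: both estimators consume identical traces.
run_grid_point <- function(truth, n_events, seeds, Tc = NULL) {
  fits <- vector("list", length(seeds))
  approx_c <- if (!is.null(Tc))
    matrix(NA_real_, length(seeds), 2L) else NULL
  for (i in seq_along(seeds)) {
    tr <- sample_trace(truth, n_events, seed = seeds[i])
    fits[[i]] <- solve_ml(tr, truth, truth = truth)
    if (!is.null(Tc))
      approx_c[i, ] <- approx_estimate(tr, Tc, truth)$c_hat
  }
  list(fits = fits, approx_c = approx_c)
}

ml_columns <- function(em) {
  data.frame(E_c = em$E_hessian[1L], E_nc = em$E_hessian[2L],
             rho = em$rho_hessian,
             E_c_ens = em$E_ensemble[1L], E_nc_ens = em$E_ensemble[2L],
             rho_ens = em$rho_ensemble,
             se_c = em$se_c_hat[1L], se_nc = em$se_c_hat[2L],
             n_boundary = em$n_boundary)
}

#' ML error surface over the rate/concentration grid
#'
#' For each grid point, simulates \code{n_replicates} traces, fits the ML
#' estimator to each, and tabulates the scaled errors \eqn{E_c},
#' \eqn{E_{nc}} (from the average inverse-Hessian covariance, with the
#' ensemble-variance definition alongside as a cross-check) and the estimate
#' correlation \eqn{\rho}. Deterministic given the master seed. Boundary
#' fits are excluded from the Hessian average and counted.
#'
#' @param config a \code{sweep_config}.
#' @param verbose print per-point progress to stderr.
#' @return Data frame with one row per grid point.
#' @export
run_ml_surface <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  seeds <- replicate_seeds(config$master_seed, config$n_replicates)
  grid <- expand.grid(r_ratio = config$r_ratio_grid,
                      c_ratio = config$c_ratio_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    truth <- grid_mixture(grid$r_ratio[g], grid$c_ratio[g])
    if (verbose)
      message(sprintf("ml surface: r_ratio=%g c_ratio=%g",
                      grid$r_ratio[g], grid$c_ratio[g]))
    pt <- run_grid_point(truth, config$n_events, seeds)
    em <- error_metrics(pt$fits, truth)
    cbind(grid[g, , drop = FALSE], ml_columns(em))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of the fixed-cutoff threshold estimator with ML
#'
#' For each grid point, simulates paired traces, computes the threshold
#' estimate at the fixed reference cutoff \eqn{T_0} (evaluated once per rate
#' ratio at the reference on-rates \eqn{k_c c_c = k_{nc} c_{nc} = 1/2} and
#' the configured number of events) and the ML fit on the same traces, and
#' tabulates the empirical losses \eqn{L_c(T_0)}, \eqn{L_{nc}(T_0)}
#' (ensemble variance + squared bias of the threshold estimates), the mean
#' inverse-Hessian ML variances, their ratios, and the threshold-estimate
#' correlation \eqn{\rho^a}.
#'
#' @inheritParams run_ml_surface
#' @return Data frame with one row per grid point, including columns
#'   \code{ratio_c} \eqn{= L_c(T_0)/\sigma^2(c_c^*)} and \code{ratio_nc}.
#' @export
run_approx_comparison <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  seeds <- replicate_seeds(config$master_seed, config$n_replicates)
  grid <- expand.grid(r_ratio = config$r_ratio_grid,
                      c_ratio = config$c_ratio_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    truth <- grid_mixture(grid$r_ratio[g], grid$c_ratio[g])
    T0 <- reference_cutoff(truth, n = config$n_events)
    if (verbose)
      message(sprintf("compare: r_ratio=%g c_ratio=%g T0=%.3f",
                      grid$r_ratio[g], grid$c_ratio[g], T0))
    pt <- run_grid_point(truth, config$n_events, seeds, Tc = T0)
    em <- error_metrics(pt$fits, truth)
    ac <- pt$approx_c
    nrep <- nrow(ac)
    L <- apply(ac, 2L, stats::var) * (nrep - 1) / nrep +
      (colMeans(ac) - truth$c)^2
    var_ml <- diag(em$mean_covariance)
    rho_a <- stats::cor(ac[, 1L], ac[, 2L])
    cbind(grid[g, , drop = FALSE], ml_columns(em),
          data.frame(T0 = T0, L_c = L[1L], L_nc = L[2L],
                     var_ml_c = var_ml[1L], var_ml_nc = var_ml[2L],
                     ratio_c = L[1L] / var_ml[1L],
                     ratio_nc = L[2L] / var_ml[2L],
                     rho_a = rho_a))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a sweep table with a provenance block
#'
#' Serialises a sweep result table together with the configuration, the
#' master seed and the package version, so that re-running with the same
#' configuration reproduces the artifact bit-for-bit.
#'
#' @param table data frame from \code{\link{run_ml_surface}} or
#'   \code{\link{run_approx_comparison}}.
#' @param config the \code{sweep_config} that produced it.
#' @param path output path.
#' @param format \code{"tsv"} (provenance in \code{#}-prefixed header lines)
#'   or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_sweep_report <- function(table, config, path,
                               format = c("tsv", "json")) {
  format <- match.arg(format)
  prov <- list(master_seed = config$master_seed,
               n_events = config$n_events,
               n_replicates = config$n_replicates,
               r_ratio_grid = config$r_ratio_grid,
               c_ratio_grid = config$c_ratio_grid,
               package_version =
                 as.character(utils::packageVersion("ligandsense")))
  if (format == "json") {
    jsonlite::write_json(list(provenance = prov, table = table), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    hdr <- sprintf("# %s: %s", names(prov),
                   vapply(prov, function(x) paste(x, collapse = ","),
                          character(1L)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a sweep report
#'
#' @param path path written by \code{\link{write_sweep_report}}.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return List with \code{provenance} (named character/list) and
#'   \code{table} (data frame).
#' @export
read_sweep_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(list(provenance = obj$provenance,
                table = as.data.frame(obj$table)))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^# ", "", hdr)
  prov <- stats::setNames(sub("^[^:]+: ", "", kv), sub(":.*$", "", kv))
  tbl <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  list(provenance = as.list(prov), table = tbl)
}
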