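#' Construct a binding trace
#'
#' A binding trace is the ordered record of bound and unbound interval
#' durations observed on a single receptor. By convention the i-th unbound
#' interval follows the i-th bound interval, and the n-th unbound interval
#' wraps around: it is the sum of the segment before the first binding and
#' the segment after the last unbinding, so that the total duration is
#' \eqn{T = \sum_i (\tau^b_i + \tau^u_i)}.
#'
#' @param tau_b numeric vector of bound durations (all > 0).
#' @param tau_u numeric vector of unbound durations (all > 0), same length.
#' @param species optional character vector of per-event true ligand labels
#'   (simulator bookkeeping; estimators never see it).
#' @return An object of class \code{binding_trace} with fields \code{tau_b},
#'   \code{tau_u}, \code{species}, \code{n} (number of binding events),
#'   \code{Tu} (total unbound time) and \code{T} (total duration).
#' @export
binding_trace <- function(tau_b, tau_u, species = NULL) {
  tau_b <- as.numeric(tau_b)
  tau_u <- as.numeric(tau_u)
  if (length(tau_b) != length(tau_u))
    stop("tau_b and tau_u must have the same length")
  if (length(tau_b) < 1L) stop("a trace needs at least one binding event")
  if (any(!is.finite(tau_b)) || any(tau_b <= 0))
    stop("all bound durations must be positive and finite")
  if (any(!is.finite(tau_u)) || any(tau_u <= 0))
    stop("all unbound durations must be positive and finite")
  if (!is.null(species) && length(species) != length(tau_b))
    stop("species labels must match the number of events")
  structure(list(tau_b = tau_b, tau_u = tau_u, species = species,
                 n = length(tau_b), Tu = sum(tau_u),
                 T = sum(tau_b) + sum(tau_u)),
            class = "binding_trace")
}

#' @export
print.binding_trace <- function(x, ...) {
  cat("binding_trace:", x$n, "events, T =", format(x$T),
      ", Tu =", format(x$Tu), "\n")
  invisible(x)
}

#' Simulate a receptor binding/unbinding trace
#'
#' Draws a trace from the exact generative model of the two-state receptor:
#' each unbound interval is exponential with rate \eqn{\sum_i k_i c_i}, the
#' identity of the binding ligand is categorical with probabilities
#' proportional to \eqn{k_i c_i}, and the bound interval is exponential with
#' that ligand's unbinding rate. For this two-state system the Gillespie
#' stochastic simulation algorithm reduces exactly to this direct sequential
#' sampling.
#'
#' @param mixture a \code{ligand_mixture} with positive total on-rate.
#' @param n_events number of binding events to simulate (>= 1).
#' @param seed optional integer seed; identical seeds give identical traces.
#' @return A \code{binding_trace} with \code{n_events} events and the true
#'   per-event species recorded.
#' @examples
#' mix <- two_ligand_mixture()
#' tr <- sample_trace(mix, n_events = 1000, seed = 1)
#' mean(tr$tau_u)  # ~ 1 / total on-rate
#' @export
sample_trace <- function(mixture, n_events, seed = NULL) {
  stopifnot(inherits(mixture, "ligand_mixture"))
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events < 1L)
    stop("n_events must be a positive integer")
  if (mixture$total_on_rate <= 0)
    stop("no binding possible: total on-rate is zero")
  if (!is.null(seed)) set.seed(seed)
  tau_u <- stats::rexp(n_events, rate = mixture$total_on_rate)
  w <- mixture$k * mixture$c
  if (length(w) == 1L) {
    idx <- rep.int(1L, n_events)
  } else {
    idx <- sample.int(length(w), n_events, replace = TRUE, prob = w)
  }
  tau_b <- stats::rexp(n_events, rate = mixture$r[idx])
  binding_trace(tau_b, tau_u, species = mixture$labels[idx])
}

#' Simulate a trace of fixed total duration
#'
#' Duration-parameterised variant of \code{\link{sample_trace}}: events are
#' generated until the total elapsed time reaches \code{t_end}. The final
#' unbound interval is wrapped: the unbound segment before the first binding
#' and the remainder after the last unbinding are summed into the last
#' unbound interval, so the returned trace has total duration exactly
#' \code{t_end}.
#'
#' @param mixture a \code{ligand_mixture}.
#' @param t_end total observation duration (> 0).
#' @param seed optional integer seed.
#' @return A \code{binding_trace}. Errors if no complete binding event fits
#'   in \code{t_end}.
#' @export
sample_trace_duration <- function(mixture, t_end, seed = NULL) {
  stopifnot(inherits(mixture, "ligand_mixture"), t_end > 0)
  if (mixture$total_on_rate <= 0)
    stop("no binding possible: total on-rate is zero")
  if (!is.null(seed)) set.seed(seed)
  w <- mixture$k * mixture$c
  tau_b <- numeric(0); tau_u <- numeric(0); idx <- integer(0)
  t <- 0
  repeat {
    u <- stats::rexp(1L, rate = mixture$total_on_rate)
    i <- if (length(w) == 1L) 1L else
      sample.int(length(w), 1L, prob = w)
    b <- stats::rexp(1L, rate = mixture$r[i])
    # event is kept only if its unbinding completes within t_end
    if (t + u + b > t_end) break
    tau_u <- c(tau_u, u); tau_b <- c(tau_b, b); idx <- c(idx, i)
    t <- t + u + b
  }
  n <- length(tau_b)
  if (n < 1L) stop("no complete binding event within t_end")
  # wrap-around: lead-in of each unbound interval is the gap before the NEXT
  # binding; the n-th unbound interval absorbs the tail out to t_end
  tau_u_shift <- c(tau_u[-1L], t_end - t + tau_u[1L])
  binding_trace(tau_b, tau_u_shift, species = mixture$labels[idx])
}

#' Read / write a binding trace as TSV
#'
#' Column layout: \code{event_index}, \code{tau_b}, \code{tau_u} and an
#' optional \code{species} column.
#'
#' @param path file path.
#' @return \code{read_trace_tsv} returns a \code{binding_trace};
#'   \code{write_trace_tsv} returns \code{path} invisibly.
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("event_index", "tau_b", "tau_u")
  if (!all(need %in% names(df)))
    stop("trace TSV must have columns event_index, tau_b, tau_u")
  df <- df[order(df$event_index), , drop = FALSE]
  binding_trace(df$tau_b, df$tau_u,
                species = if ("species" %in% names(df)) df$species else NULL)
}

#' @rdname read_trace_tsv
#' @param trace a \code{binding_trace} to serialise.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "binding_trace"))
  df <- data.frame(event_index = seq_len(trace$n),
                   tau_b = trace$tau_b, tau_u = trace$tau_u)
  if (!is.null(trace$species)) df$species <- trace$species
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Messenger birth-death parameters
#'
#' Parameters of a downstream messenger molecule produced while a gating
#' condition on the receptor holds and deactivated by a first-order reaction.
#' Gate \code{"bound"} produces whenever the receptor is occupied; gate
#' \code{"bound-longer-than-Tc"} produces only once the current binding has
#' lasted at least \code{Tc} (the kinetic-proofreading delay).
#'
#' @param k_prod production rate while the gate is open (> 0).
#' @param r_deg first-order deactivation rate (> 0).
#' @param gate \code{"bound"} or \code{"bound-longer-than-Tc"}.
#' @param Tc cutoff time, used only by the gated variant (>= 0).
#' @return An object of class \code{messenger_params}.
#' @export
messenger_params <- function(k_prod, r_deg,
                             gate = c("bound", "bound-longer-than-Tc"),
                             Tc = 0) {
  gate <- match.arg(gate)
  if (!is.numeric(k_prod) || k_prod < 0) stop("k_prod must be >= 0")
  if (!is.numeric(r_deg) || r_deg <= 0) stop("r_deg must be > 0")
  if (!is.numeric(Tc) || Tc < 0) stop("Tc must be >= 0")
  structure(list(k_prod = k_prod, r_deg = r_deg, gate = gate, Tc = Tc),
            class = "messenger_params")
}

# Split a trace into (length, gate-open) segments for one messenger.
trace_segments <- function(trace, params) {
  n <- trace$n
  if (params$gate == "bound") {
    len <- as.numeric(rbind(trace$tau_b, trace$tau_u))
    on <- rep(c(TRUE, FALSE), n)
  } else {
    Tc <- params$Tc
    len <- numeric(0); on <- logical(0)
    pre <- pmin(trace$tau_b, Tc)          # sub-threshold part: gate closed
    post <- pmax(trace$tau_b - Tc, 0)     # beyond the cutoff: gate open
    len <- as.numeric(rbind(pre, post, trace$tau_u))
    on <- rep(c(FALSE, TRUE, FALSE), n)
    keep <- len > 0
    len <- len[keep]; on <- on[keep]
  }
  list(len = len, on = on)
}

# Exact jump-process simulation of a birth-death messenger over piecewise
# constant gating; accumulates the time integrals of X and X^2.
simulate_bd_segments <- function(len, on, k_prod, r_deg, x0 = 0L) {
  x <- as.numeric(x0)
  int_x <- 0; int_x2 <- 0
  for (j in seq_along(len)) {
    t_rem <- len[j]
    b <- if (on[j]) k_prod else 0
    repeat {
      rate <- b + r_deg * x
      if (rate <= 0) {
        int_x <- int_x + x * t_rem
        int_x2 <- int_x2 + x * x * t_rem
        break
      }
      dt <- stats::rexp(1L, rate)
      if (dt >= t_rem) {
        int_x <- int_x + x * t_rem
        int_x2 <- int_x2 + x * x * t_rem
        break
      }
      int_x <- int_x + x * dt
      int_x2 <- int_x2 + x * x * dt
      t_rem <- t_rem - dt
      x <- x + if (stats::runif(1L) < b / rate) 1 else -1
    }
  }
  list(int_x = int_x, int_x2 = int_x2, x_final = x)
}

#' Simulate trace-driven messenger birth-death processes
#'
#' Drives one stochastic birth-death process per messenger along the receptor
#' occupancy timeline of \code{trace} and returns the time-averaged mean and
#' variance of each messenger copy number over the trace duration. This is
#' the Monte-Carlo counterpart of the mean-field readout formulas in
#' \code{\link{mean_readouts}} and of the readout noise formula in
#' \code{\link{readout_relvar}}.
#'
#' @param trace a \code{binding_trace}.
#' @param params a single \code{messenger_params} or a list of them.
#' @param seed optional integer seed.
#' @return A data frame with one row per messenger: \code{mean}, \code{var}
#'   (time averages over the trace) and \code{t_total}.
#' @export
simulate_messengers <- function(trace, params, seed = NULL) {
  stopifnot(inherits(trace, "binding_trace"))
  if (inherits(params, "messenger_params")) params <- list(params)
  if (length(params) < 1L) stop("need at least one messenger")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(params, function(p) {
    seg <- trace_segments(trace, p)
    sim <- simulate_bd_segments(seg$len, seg$on, p$k_prod, p$r_deg)
    tt <- sum(seg$len)
    m <- sim$int_x / tt
    data.frame(mean = m, var = sim$int_x2 / tt - m^2, t_total = tt)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
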