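#' Define a ligand species
#'
#' A ligand species is characterised by its binding (on) rate constant
#' \code{k}, its unbinding (off) rate \code{r}, and its concentration
#' \code{c}. Bound-interval durations for this species are exponential with
#' rate \code{r}; it contributes \code{k * c} to the total receptor on-rate.
#'
#' @param label character identifier, e.g. \code{"cognate"}.
#' @param k binding rate per unit concentration per unit time (> 0).
#' @param r unbinding rate per unit time (> 0).
#' @param c concentration in arbitrary concentration units (>= 0).
#' @return An object of class \code{ligand_species}.
#' @export
ligand_species <- function(label, k, r, c) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("binding rate 'k' must be a single positive number")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("unbinding rate 'r' must be a single positive number")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0)
    stop("concentration 'c' must be a single non-negative number")
  structure(list(label = label, k = k, r = r, c = c),
            class = "ligand_species")
}

#' Define a ligand mixture
#'
#' A mixture of one or more ligand species competing for a single receptor.
#' Species are ordered by decreasing binding duration (increasing unbinding
#' rate), so in the two-species case the cognate ligand (smaller \code{r})
#' comes first.
#'
#' @param ... \code{ligand_species} objects, or a single list of them.
#' @return An object of class \code{ligand_mixture} with elements
#'   \code{species} (the ordered list) and derived vectors \code{k},
#'   \code{r}, \code{c}, \code{labels} and scalar \code{total_on_rate}
#'   (\eqn{\sum_i k_i c_i}).
#' @examples
#' mix <- ligand_mixture(
#'   ligand_species("cognate",    k = 1, r = 0.1, c = 0.5),
#'   ligand_species("noncognate", k = 1, r = 1.0, c = 0.5))
#' mix$total_on_rate
#' @export
ligand_mixture <- function(...) {
  sp <- list(...)
  if (length(sp) == 1L && !inherits(sp[[1L]], "ligand_species"))
    sp <- sp[[1L]]
  if (length(sp) < 1L) stop("a mixture needs at least one species")
  ok <- vapply(sp, inherits, logical(1L), what = "ligand_species")
  if (!all(ok)) stop("all arguments must be ligand_species objects")
  r <- vapply(sp, `[[`, numeric(1L), "r")
  sp <- sp[order(r)]
  mix <- list(
    species = sp,
    labels = vapply(sp, `[[`, character(1L), "label"),
    k = vapply(sp, `[[`, numeric(1L), "k"),
    r = vapply(sp, `[[`, numeric(1L), "r"),
    c = vapply(sp, `[[`, numeric(1L), "c"))
  mix$total_on_rate <- sum(mix$k * mix$c)
  structure(mix, class = "ligand_mixture")
}

#' Convenience constructor for the two-ligand (cognate/non-cognate) mixture
#'
#' @param k_c,k_nc binding rates of the cognate and non-cognate ligand.
#' @param r_c,r_nc unbinding rates; the cognate ligand is the one that stays
#'   bound longer, so \code{r_c < r_nc} is required.
#' @param c_c,c_nc concentrations.
#' @return A \code{ligand_mixture} with the cognate species first.
#' @export
two_ligand_mixture <- function(k_c = 1, r_c = 0.1, c_c = 0.5,
                               k_nc = 1, r_nc = 1, c_nc = 0.5) {
  if (r_c >= r_nc)
    stop("the cognate ligand must unbind more slowly (r_c < r_nc)")
  ligand_mixture(ligand_species("cognate", k_c, r_c, c_c),
                 ligand_species("noncognate", k_nc, r_nc, c_nc))
}

#' @export
print.ligand_mixture <- function(x, ...) {
  cat("ligand_mixture with", length(x$species), "species\n")
  print(data.frame(label = x$labels, k = x$k, r = x$r, c = x$c),
        row.names = FALSE)
  cat("total on-rate:", format(x$total_on_rate), "\n")
  invisible(x)
}

#' Replace the concentrations of a mixture
#'
#' @param mixture a \code{ligand_mixture}.
#' @param c numeric vector of new concentrations, one per species.
#' @return A new \code{ligand_mixture}.
#' @export
set_concentrations <- function(mixture, c) {
  stopifnot(inherits(mixture, "ligand_mixture"),
            length(c) == length(mixture$species))
  sp <- mapply(function(s, ci) ligand_species(s$label, s$k, s$r, ci),
               mixture$species, c, SIMPLIFY = FALSE)
  ligand_mixture(sp)
}

#' Read / write a ligand mixture as JSON
#'
#' The JSON layout is
#' \code{{"species":[{"label":...,"k":...,"r":...,"c":...}, ...]}}.
#'
#' @param path file path.
#' @return \code{read_mixture_json} returns a \code{ligand_mixture};
#'   \code{write_mixture_json} returns \code{path} invisibly.
#' @export
read_mixture_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$species)) stop("mixture JSON must have a 'species' array")
  sp <- lapply(obj$species, function(s)
    ligand_species(s$label, as.numeric(s$k), as.numeric(s$r), as.numeric(s$c)))
  ligand_mixture(sp)
}

#' @rdname read_mixture_json
#' @param mixture a \code{ligand_mixture} to serialise.
#' @export
write_mixture_json <- function(mixture, path) {
  stopifnot(inherits(mixture, "ligand_mixture"))
  species <- lapply(mixture$species, function(s)
    list(label = s$label, k = s$k, r = s$r, c = s$c))
  jsonlite::write_json(list(species = species), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
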