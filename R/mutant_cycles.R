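# Double-mutant-cycle analysis.
#
# A cycle compares the unfolding free energies of a background construct
# (wt), the two single mutants (m1, m2) and the double mutant (dm). Any
# non-additivity of the mutational effects is the pairwise interaction
# (coupling) energy between the two mutated side chains; the
# Horovitz-Fersht sign convention is used, so a stabilising interaction
# between the two residues is positive.

#' Coupling energy of a double-mutant cycle
#'
#' \code{ddG_int = (g_wt - g_m1) - (g_m2 - g_dm) = g_wt - g_m1 - g_m2 + g_dm},
#' where each argument is an unfolding free energy at a shared reference
#' temperature. Zero when the two mutations are additive; positive when the
#' two residues interact favourably (e.g. an intact salt bridge).
#'
#' @param g_wt,g_m1,g_m2,g_dm unfolding free energies (kcal mol^-1) of the
#'   background, the two single mutants, and the double mutant
#' @return coupling energy, kcal mol^-1
#' @examples
#' coupling_energy(5.0, 3.0, 2.5, 1.5)  # 1.0
#' @export
coupling_energy <- function(g_wt, g_m1, g_m2, g_dm) {
  vals <- c(g_wt, g_m1, g_m2, g_dm)
  if (length(vals) != 4L || any(!is.finite(vals)))
    stop("all four free energies must be finite scalars", call. = FALSE)
  g_wt - g_m1 - g_m2 + g_dm
}

#' Define a double-mutant cycle
#'
#' @param cycle_id cycle label
#' @param wt background construct name
#' @param m1,m2 the two single-mutant construct names
#' @param dm double-mutant construct name
#' @param pair residue-pair label, e.g. \code{"D6-R29"}
#' @return an object of class \code{cycle_spec}
#' @export
cycle_spec <- function(cycle_id, wt, m1, m2, dm, pair = NA_character_) {
  nm <- c(wt, m1, m2, dm)
  if (any(!nzchar(nm)) || anyNA(nm))
    stop("all four construct names must be non-empty", call. = FALSE)
  if (anyDuplicated(nm))
    stop("the four constructs of a cycle must be distinct", call. = FALSE)
  structure(list(cycle_id = cycle_id, wt = wt, m1 = m1, m2 = m2, dm = dm,
                 pair = pair),
            class = "cycle_spec")
}

#' Evaluate a double-mutant cycle from two-state fits
#'
#' Computes the unfolding free energy of each of the four constructs at
#' \code{T_ref} via \code{\link{gibbs_free_energy}}, then the coupling
#' energy via \code{\link{coupling_energy}}.
#'
#' @param spec a \code{\link{cycle_spec}}
#' @param fits named list of \code{two_state_fit} objects covering the four
#'   constructs
#' @param T_ref reference temperature, Kelvin
#' @param force accept non-converged fits (default FALSE)
#' @return an object of class \code{cycle_result}: \code{cycle_id},
#'   \code{pair}, \code{ddG_int} (kcal mol^-1), \code{T_ref}, and
#'   \code{components} (the named four dG_u values used)
#' @export
run_cycle <- function(spec, fits, T_ref = 293.15, force = FALSE) {
  stopifnot(inherits(spec, "cycle_spec"))
  need <- c(spec$wt, spec$m1, spec$m2, spec$dm)
  missing <- setdiff(need, names(fits))
  if (length(missing))
    stop("missing construct fit(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in need) {
    f <- fits[[nm]]
    if (!inherits(f, "two_state_fit"))
      stop("fit for ", nm, " is not a two_state_fit", call. = FALSE)
    if (!force && !isTRUE(f$converged))
      stop("fit for ", nm, " did not converge (use force = TRUE to override)",
           call. = FALSE)
  }
  g <- vapply(need, function(nm) gibbs_free_energy(fits[[nm]], T_ref),
              numeric(1))
  names(g) <- c("wt", "m1", "m2", "dm")
  structure(list(cycle_id = spec$cycle_id, pair = spec$pair,
                 ddG_int = coupling_energy(g["wt"], g["m1"], g["m2"], g["dm"]),
                 T_ref = T_ref, components = g),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("<cycle_result> %s (%s): ddG_int = %.3f kcal/mol at %.2f K\n",
              x$cycle_id, ifelse(is.na(x$pair), "?", x$pair),
              x$ddG_int, x$T_ref))
  cat(sprintf("  dG_u: wt %.3f | m1 %.3f | m2 %.3f | dm %.3f\n",
              x$components["wt"], x$components["m1"],
              x$components["m2"], x$components["dm"]))
  invisible(x)
}
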