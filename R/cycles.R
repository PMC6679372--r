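#' Thermodynamic cycle for a relative binding free energy
#'
#' Collects the legs of the standard relative-binding-affinity cycle: the
#' alchemical transformation A > B simulated once with the ligand free in
#' water (unbound leg) and once bound to the receptor (bound leg). Because
#' the two physical binding legs of the cycle need never be simulated, the
#' relative binding free energy follows as
#' \eqn{\Delta\Delta G = \Delta G^b_{A>B} - \Delta G^u_{A>B}}.
#'
#' Optional flank legs extend the cycle to charge variants A* and B* of the
#' same compounds: one-step-perturbation estimates \eqn{\Delta G_{A>A^*}}
#' and \eqn{\Delta G_{B>B^*}} in each environment let the central TI legs be
#' reused for any charge distribution on the perturbed ring without new
#' sampling (\code{\link{apply_charge_flanks}}).
#'
#' @param unbound_leg,bound_leg \code{\link{free_energy}} estimates of the
#'   A > B transformation in water and in the receptor.
#' @param flank_A,flank_B Optional named lists
#'   \code{list(water = , protein = )} of \code{\link{free_energy}} OSP legs
#'   A > A* and B > B*.
#' @param label Compound/pose identifier.
#' @return An object of class \code{thermo_cycle}.
#' @export
thermo_cycle <- function(unbound_leg, bound_leg,
                         flank_A = NULL, flank_B = NULL, label = "") {
  stopifnot(inherits(unbound_leg, "free_energy"),
            inherits(bound_leg, "free_energy"))
  if (!identical(unbound_leg$direction, bound_leg$direction))
    stop(sprintf("legs disagree on the state pair: unbound %s>%s vs bound %s>%s",
                 unbound_leg$direction[1], unbound_leg$direction[2],
                 bound_leg$direction[1], bound_leg$direction[2]))
  for (fl in list(flank_A, flank_B)) {
    if (!is.null(fl)) {
      stopifnot(is.list(fl))
      if (!all(c("water", "protein") %in% names(fl)))
        stop("flank legs must be given for both environments (water and protein)")
      stopifnot(inherits(fl$water, "free_energy"),
                inherits(fl$protein, "free_energy"))
    }
  }
  structure(list(unbound_leg = unbound_leg, bound_leg = bound_leg,
                 flank_A = flank_A, flank_B = flank_B,
                 label = as.character(label)),
            class = "thermo_cycle")
}

#' @export
print.thermo_cycle <- function(x, ...) {
  cat(sprintf("<thermo_cycle> %s (%s > %s)%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$unbound_leg$direction[1], x$unbound_leg$direction[2],
              if (!is.null(x$flank_A)) " with charge flanks" else ""))
  cat("  unbound: "); print(x$unbound_leg)
  cat("  bound:   "); print(x$bound_leg)
  invisible(x)
}

#' Relative binding free energy from a thermodynamic cycle
#'
#' \eqn{\Delta\Delta G_{u>b} = \Delta G^b_{A>B} - \Delta G^u_{A>B}}, with
#' the leg uncertainties combined in quadrature. Positive values mean B
#' binds more weakly than A.
#'
#' @param cycle A \code{\link{thermo_cycle}}.
#' @return A \code{\link{free_energy}} with \code{method = "composite"}.
#' @export
relative_binding_dG <- function(cycle) {
  stopifnot(inherits(cycle, "thermo_cycle"))
  free_energy(cycle$bound_leg$value - cycle$unbound_leg$value,
              sqrt(cycle$bound_leg$sigma^2 + cycle$unbound_leg$sigma^2),
              method = "composite", direction = cycle$bound_leg$direction)
}

#' Relative binding free energy between charge variants via flank legs
#'
#' Combines the central TI legs with the one-step-perturbation flank legs to
#' obtain the binding free-energy difference between the charge-modified
#' compounds A* and B*: per environment
#' \deqn{\Delta G_{A^*>B^*} = -\Delta G^{OSP}_{A>A^*} + \Delta G^{TI}_{A>B}
#'   + \Delta G^{OSP}_{B>B^*},}
#' and the binding difference is the protein composite minus the water
#' composite. All leg uncertainties are combined in quadrature.
#'
#' @param cycle A \code{\link{thermo_cycle}} with both flank legs present.
#' @return A \code{\link{free_energy}} with \code{method = "composite"} and
#'   direction \code{c("A*", "B*")}-style labels.
#' @export
apply_charge_flanks <- function(cycle) {
  stopifnot(inherits(cycle, "thermo_cycle"))
  for (nm in c("flank_A", "flank_B")) {
    if (is.null(cycle[[nm]]))
      stop(sprintf("missing flank leg '%s': both charge-variant flanks are required", nm))
  }
  comp <- function(env) {
    leg <- if (env == "water") cycle$unbound_leg else cycle$bound_leg
    list(value = -cycle$flank_A[[env]]$value + leg$value + cycle$flank_B[[env]]$value,
         var = cycle$flank_A[[env]]$sigma^2 + leg$sigma^2 + cycle$flank_B[[env]]$sigma^2)
  }
  w <- comp("water"); p <- comp("protein")
  free_energy(p$value - w$value, sqrt(p$var + w$var),
              method = "composite",
              direction = paste0(cycle$bound_leg$direction, "*"))
}

#' Closure error of a loop of free-energy legs
#'
#' Checks that the legs chain head-to-tail into a closed loop and returns
#' the signed sum of their values. For exact estimates the sum is zero by
#' state-function consistency; the magnitude of the residual generalizes
#' the two-leg hysteresis diagnostic to arbitrary loops.
#'
#' @param legs List of \code{\link{free_energy}} objects whose directions
#'   chain (each leg starts where the previous one ended, and the last ends
#'   at the first state).
#' @return Signed closure error in kJ/mol.
#' @export
cycle_closure <- function(legs) {
  stopifnot(is.list(legs), length(legs) >= 2L,
            all(vapply(legs, inherits, logical(1), "free_energy")))
  k <- length(legs)
  for (j in seq_len(k)) {
    nxt <- legs[[if (j == k) 1L else j + 1L]]
    if (!identical(legs[[j]]$direction[2], nxt$direction[1]))
      stop(sprintf("legs do not chain: leg %d ends at '%s' but leg %d starts at '%s'",
                   j, legs[[j]]$direction[2],
                   if (j == k) 1L else j + 1L, nxt$direction[1]))
  }
  sum(vapply(legs, function(fe) fe$value, numeric(1)))
}
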