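#' Time series of dH/dlambda samples at one lambda point
#'
#' Either constructs the container directly from numeric samples, or
#' evaluates \eqn{\partial H/\partial \lambda} over the stored snapshots of a
#' toy-ensemble trajectory. Under linear coupling the derivative is simply
#' \eqn{H_B - H_A} at each configuration; for \code{softcore_insertion} the
#' analytic derivative of the soft-core coupled potential is used instead.
#'
#' @param x Numeric vector of samples (kJ/mol), or an \code{mc_trajectory}.
#' @param lambda_value Coupling value in \[0, 1\] (numeric method only; taken
#'   from the trajectory otherwise).
#' @param source_label Free-text provenance label.
#' @param ... Passed between methods.
#' @return An object of class \code{dhdl_series} with fields
#'   \code{lambda_value}, \code{samples}, \code{source_label}.
#' @export
dhdl_series <- function(x, ...) UseMethod("dhdl_series")

#' @rdname dhdl_series
#' @export
dhdl_series.numeric <- function(x, lambda_value, source_label = "", ...) {
  stopifnot(length(x) >= 1L, all(is.finite(x)),
            is.numeric(lambda_value), length(lambda_value) == 1L,
            lambda_value >= 0, lambda_value <= 1)
  structure(list(lambda_value = as.numeric(lambda_value),
                 samples = as.numeric(x),
                 source_label = as.character(source_label)),
            class = "dhdl_series")
}

#' @rdname dhdl_series
#' @export
dhdl_series.mc_trajectory <- function(x, ...) {
  traj <- x
  spec <- traj$spec
  X <- traj$configurations
  stopifnot(nrow(X) >= 1L)
  params <- .toy_params(spec)
  lambda <- traj$lambda_value
  vals <- switch(spec$system_kind,
    harmonic_morph = {
      0.5 * spec$k_B * (X[, 1] - spec$x_B)^2 -
        0.5 * spec$k_A * (X[, 1] - spec$x_A)^2
    },
    charging = {
      (spec$q_B - spec$q_A) * F_COULOMB *
        as.numeric(abs(X)^-1 %*% params$q_bath)
    },
    softcore_insertion = {
      d <- rep(0, nrow(X))
      for (i in seq_len(ncol(X))) {
        sc <- .softcore_pair(spec, params, lambda, abs(X[, i]), params$q_bath[i])
        d <- d + sc$dudl
      }
      d
    })
  dhdl_series(vals, lambda,
              source_label = sprintf("%s seed %d", spec$system_kind, spec$seed))
}

#' @export
print.dhdl_series <- function(x, ...) {
  cat(sprintf("<dhdl_series> lambda = %g, n = %d, mean = %.4g kJ/mol\n",
              x$lambda_value, length(x$samples), mean(x$samples)))
  invisible(x)
}

#' End-state energy time series container
#'
#' Holds an ordered series of ligand--surrounding interaction energies for
#' one end state in one environment. The environment tag distinguishes the
#' solvated ligand (\code{"water"}) from the receptor-bound ligand
#' (\code{"protein"}) legs of a thermodynamic cycle.
#'
#' @param samples Numeric vector of energies (kJ/mol).
#' @param state_label End-state identifier (e.g. \code{"A"}).
#' @param environment \code{"water"} or \code{"protein"}.
#' @return An object of class \code{energy_series}.
#' @export
energy_series <- function(samples, state_label = "A",
                          environment = c("water", "protein")) {
  environment <- match.arg(environment)
  stopifnot(is.numeric(samples), length(samples) >= 1L, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples),
                 state_label = as.character(state_label),
                 environment = environment),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> state %s in %s, n = %d, mean = %.4g kJ/mol\n",
              x$state_label, x$environment, length(x$samples), mean(x$samples)))
  invisible(x)
}

## Ligand--surrounding interaction energy per snapshot (intra-bath tether
## terms excluded by construction).
.ligand_surrounding <- function(spec, lambda, X, params,
                                component = c("all", "electrostatic", "vdw")) {
  component <- match.arg(component)
  n <- nrow(X)
  switch(spec$system_kind,
    harmonic_morph = rep(0, n),  # no ligand--bath coupling in this system
    charging = {
      if (component == "vdw") rep(0, n)
      else .lambda_charge(spec, lambda) * F_COULOMB *
        as.numeric(abs(X)^-1 %*% params$q_bath)
    },
    softcore_insertion = {
      e <- rep(0, n)
      for (i in seq_len(ncol(X))) {
        sc <- .softcore_pair(spec, params, lambda, abs(X[, i]), params$q_bath[i])
        e <- e + switch(component,
                        all = lambda * (sc$v_lj + sc$v_c),
                        electrostatic = lambda * sc$v_c,
                        vdw = lambda * sc$v_lj)
      }
      e
    })
}

#' Ligand--surrounding energy series at an end state
#'
#' Evaluates the interaction energy between the perturbed (ligand) site and
#' the bath over the stored snapshots of an end-state trajectory. Intra-bath
#' terms are excluded: in the energy--entropy decomposition of binding only
#' the ligand--surrounding part is informative, because the
#' surrounding--surrounding energetic and entropic contributions cancel.
#' Defined at the end states \eqn{\lambda \in \{0, 1\}} only, where the
#' Hamiltonian corresponds to a physical state.
#'
#' @param traj An \code{mc_trajectory} sampled at lambda 0 or 1.
#' @param environment Environment tag for the resulting series.
#' @param component Which part of the interaction to return:
#'   \code{"all"}, \code{"electrostatic"} or \code{"vdw"}.
#' @return An \code{\link{energy_series}}.
#' @export
endstate_energy_series <- function(traj, environment = c("water", "protein"),
                                   component = c("all", "electrostatic", "vdw")) {
  stopifnot(inherits(traj, "mc_trajectory"))
  environment <- match.arg(environment)
  component <- match.arg(component)
  lam <- traj$lambda_value
  if (!isTRUE(all.equal(lam, 0)) && !isTRUE(all.equal(lam, 1)))
    stop(sprintf(paste0("ligand-surrounding decomposition is defined at the end",
                        " states only (lambda = 0 or 1), got lambda = %g"), lam))
  params <- .toy_params(traj$spec)
  e <- .ligand_surrounding(traj$spec, lam, traj$configurations, params, component)
  energy_series(e, state_label = if (lam == 0) "A" else "B",
                environment = environment)
}

#' Perturbation energy series for a modified charge distribution
#'
#' Evaluates \eqn{\Delta U = U_{A^*} - U_A} on the snapshots of an existing
#' ensemble, where the modified state \eqn{A^*} differs from the simulated
#' state only in its charge-like parameters. This is the ingredient of
#' one-step perturbation: the simulated ensemble is reused to estimate the
#' free energy of nearby charge variants without new sampling. Because the
#' ligand--bath energy is linear in the site charge,
#' \eqn{\Delta U = (q^* - q)/q \cdot E^{elec}_{lig-surr}} per snapshot.
#'
#' @param traj An \code{mc_trajectory}.
#' @param modified_spec A \code{\link{toy_system_spec}} identical to
#'   \code{traj$spec} except in \code{q_A} and/or \code{q_B}.
#' @return An \code{\link{energy_series}} of per-snapshot \eqn{\Delta U}
#'   (state label \code{"A>A*"}-style).
#' @export
perturbed_energy_series <- function(traj, modified_spec,
                                    environment = c("water", "protein")) {
  stopifnot(inherits(traj, "mc_trajectory"), inherits(modified_spec, "toy_spec"))
  environment <- match.arg(environment)
  spec <- traj$spec
  same <- c("system_kind", "k_A", "k_B", "x_A", "x_B", "bath_size",
            "alpha_LJ", "alpha_C", "temperature", "n_samples", "stride")
  for (f in same) {
    if (!identical(spec[[f]], modified_spec[[f]]))
      stop(sprintf("one-step perturbation covers charge changes only; field '%s' differs", f))
  }
  params <- .toy_params(spec)
  lam <- traj$lambda_value
  e0 <- .ligand_surrounding(spec, lam, traj$configurations, params, "electrostatic")
  e1 <- .ligand_surrounding(modified_spec, lam, traj$configurations, params,
                            "electrostatic")
  energy_series(e1 - e0,
                state_label = sprintf("%s>%s*",
                                      if (lam <= 0.5) "A" else "B",
                                      if (lam <= 0.5) "A" else "B"),
                environment = environment)
}
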