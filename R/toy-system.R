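#' Specification of a lambda-coupled toy system
#'
#' Defines a one-dimensional model system whose Hamiltonian interpolates
#' between two end states A (\eqn{\lambda = 0}) and B (\eqn{\lambda = 1}).
#' Three system kinds are available:
#' \describe{
#'   \item{\code{harmonic_morph}}{A single particle whose harmonic well morphs
#'     from \eqn{(k_A, x_A)} to \eqn{(k_B, x_B)} under linear coupling
#'     \eqn{H(\lambda) = (1-\lambda) H_A + \lambda H_B}. The free-energy
#'     difference has the closed form \eqn{\Delta G = (RT/2)\ln(k_B/k_A)}
#'     (see \code{\link{analytic_dG}}), which makes this the primary
#'     validation system for thermodynamic integration.}
#'   \item{\code{charging}}{A charged site fixed at the origin whose charge is
#'     interpolated \eqn{q(\lambda) = (1-\lambda) q_A + \lambda q_B}, coupled
#'     by a Coulomb term to a bath of harmonically tethered charged particles.
#'     The ligand--bath energy is exactly linear in the site charge, which is
#'     what makes one-step perturbation between charge variants well behaved;
#'     this mimics the charge-redistribution perturbations applied to a
#'     heteroaromatic ring nitrogen.}
#'   \item{\code{softcore_insertion}}{A Lennard-Jones plus Coulomb site grown
#'     into the bath along \eqn{\lambda} with soft-core coupling, so that
#'     configurations where a bath particle overlaps the inserted site remain
#'     finite at intermediate \eqn{\lambda}.}
#' }
#'
#' The bath layout is fixed by the spec: \code{bath_size} particles tethered
#' at increasing distances from the origin with force constant \code{k_A},
#' each carrying a partial charge of \eqn{-0.1 e} (same sign as the default
#' site charge, so the Coulomb coupling is purely repulsive and the system
#' cannot collapse onto the singularity).
#'
#' @param system_kind One of \code{"harmonic_morph"}, \code{"charging"},
#'   \code{"softcore_insertion"}.
#' @param k_A,k_B Force constants in kJ mol^-1 nm^-2. For
#'   \code{harmonic_morph} these are the end-state well constants; for the
#'   bath systems \code{k_A} is the tether constant of every bath particle.
#' @param x_A,x_B Well minima in nm (\code{harmonic_morph} only).
#' @param q_A,q_B Site charges in e of the end states. Defaults mirror the
#'   partial charge of the perturbed ring nitrogen in the two force-field
#'   variants most often compared (-0.54 e and -0.34 e).
#' @param bath_size Number of tethered bath particles.
#' @param alpha_LJ Dimensionless van der Waals soft-core parameter
#'   (default 0.5).
#' @param alpha_C Electrostatic soft-core parameter in nm^2 (default 0.5).
#' @param temperature Temperature in K (default 300).
#' @param seed Integer seed; together with the spec and lambda it fixes the
#'   trajectory bit-for-bit.
#' @param n_samples Number of stored configurations.
#' @param stride Monte Carlo sweeps between stored configurations.
#' @return An object of class \code{toy_spec}.
#' @seealso \code{\link{sample_lambda}}, \code{\link{analytic_dG}}
#' @examples
#' spec <- toy_system_spec("harmonic_morph", k_A = 100, k_B = 400,
#'                         n_samples = 200, seed = 7)
#' analytic_dG(spec)
#' @export
toy_system_spec <- function(system_kind = c("harmonic_morph", "charging",
                                            "softcore_insertion"),
                            k_A = 100, k_B = if (identical(system_kind[1L], "harmonic_morph")) 400 else k_A,
                            x_A = 0, x_B = 0,
                            q_A = -0.54, q_B = -0.34,
                            bath_size = 5L,
                            alpha_LJ = 0.5, alpha_C = 0.5,
                            temperature = 300, seed = 1L,
                            n_samples = 1000L, stride = 5L) {
  system_kind <- match.arg(system_kind)
  stopifnot(k_A > 0, k_B > 0, temperature > 0, n_samples >= 1,
            stride >= 1, bath_size >= 1, alpha_LJ >= 0, alpha_C >= 0)
  spec <- list(system_kind = system_kind,
               k_A = as.numeric(k_A), k_B = as.numeric(k_B),
               x_A = as.numeric(x_A), x_B = as.numeric(x_B),
               q_A = as.numeric(q_A), q_B = as.numeric(q_B),
               bath_size = as.integer(bath_size),
               alpha_LJ = as.numeric(alpha_LJ),
               alpha_C = as.numeric(alpha_C),
               temperature = as.numeric(temperature),
               seed = as.integer(seed),
               n_samples = as.integer(n_samples),
               stride = as.integer(stride))
  class(spec) <- "toy_spec"
  spec
}

#' @export
print.toy_spec <- function(x, ...) {
  cat(sprintf("<toy_spec> %s, T = %g K, %d samples (stride %d), seed %d\n",
              x$system_kind, x$temperature, x$n_samples, x$stride, x$seed))
  if (x$system_kind == "harmonic_morph") {
    cat(sprintf("  k: %g -> %g kJ/mol/nm^2, x0: %g -> %g nm\n",
                x$k_A, x$k_B, x$x_A, x$x_B))
  } else {
    cat(sprintf("  q: %g -> %g e, bath of %d (tether k = %g)\n",
                x$q_A, x$q_B, x$bath_size, x$k_A))
  }
  invisible(x)
}

## Fixed bath layout and ligand-site parameters derived from a spec.
## Tether centres start close to the origin for softcore_insertion so that
## overlap configurations are actually visited at small coupling.
.toy_params <- function(spec) {
  m <- spec$bath_size
  if (spec$system_kind == "softcore_insertion") {
    centers <- 0.25 + 0.35 * (seq_len(m) - 1)
  } else {
    centers <- 0.4 + 0.2 * (seq_len(m) - 1)
  }
  list(centers   = centers,
       q_bath    = rep(-0.1, m),
       k_tether  = spec$k_A,
       lj_eps    = 0.65,  # kJ/mol, water-oxygen-like site
       lj_sig    = 0.30)  # nm
}

.lambda_charge <- function(spec, lambda) (1 - lambda) * spec$q_A + lambda * spec$q_B

## Soft-core pair terms for the inserted site at distances r from bath
## particles of charge qb (qb aligned with r, scalar or vector).
## Beutler-style coupling: the softness enters as alpha * (1 - lambda)^2, so
## the potential is the plain LJ + Coulomb at lambda = 1 and everywhere
## finite (including r = 0) for lambda < 1.
.softcore_pair <- function(spec, p, lambda, r, qb) {
  s <- spec$alpha_LJ * (1 - lambda)^2 + (r / p$lj_sig)^6
  t <- spec$alpha_C * (1 - lambda)^2 + r^2
  v_lj <- 4 * p$lj_eps * (s^-2 - s^-1)
  v_c  <- F_COULOMB * spec$q_B * qb * t^(-0.5)
  dv_lj <- 4 * p$lj_eps * (-2 * s^-3 + s^-2) * (-2 * spec$alpha_LJ * (1 - lambda))
  dv_c  <- F_COULOMB * spec$q_B * qb *
    (-0.5) * t^(-1.5) * (-2 * spec$alpha_C * (1 - lambda))
  list(v_lj = v_lj, v_c = v_c,
       u = lambda * (v_lj + v_c),
       dudl = (v_lj + v_c) + lambda * (dv_lj + dv_c))
}

## Total potential energy of a configuration x (coordinate vector) at lambda.
.u_total <- function(spec, lambda, x, params = .toy_params(spec)) {
  switch(spec$system_kind,
    harmonic_morph = {
      (1 - lambda) * 0.5 * spec$k_A * (x - spec$x_A)^2 +
        lambda * 0.5 * spec$k_B * (x - spec$x_B)^2
    },
    charging = {
      r <- abs(x)
      sum(0.5 * params$k_tether * (x - params$centers)^2) +
        .lambda_charge(spec, lambda) * F_COULOMB * sum(params$q_bath / r)
    },
    softcore_insertion = {
      r <- abs(x)
      sum(0.5 * params$k_tether * (x - params$centers)^2) +
        sum(.softcore_pair(spec, params, lambda, r, params$q_bath)$u)
    })
}

## Energy terms involving coordinate i only (used for O(1) Metropolis moves).
.u_site <- function(spec, lambda, xi, i, params) {
  switch(spec$system_kind,
    harmonic_morph = {
      (1 - lambda) * 0.5 * spec$k_A * (xi - spec$x_A)^2 +
        lambda * 0.5 * spec$k_B * (xi - spec$x_B)^2
    },
    charging = {
      0.5 * params$k_tether * (xi - params$centers[i])^2 +
        .lambda_charge(spec, lambda) * F_COULOMB * params$q_bath[i] / abs(xi)
    },
    softcore_insertion = {
      sc <- .softcore_pair(spec, params, lambda, abs(xi), params$q_bath[i])
      0.5 * params$k_tether * (xi - params$centers[i])^2 + sc$u
    })
}

#' Closed-form free-energy difference of a toy system
#'
#' For \code{harmonic_morph} the configurational partition function of
#' \eqn{H(\lambda)} is Gaussian at every \eqn{\lambda}, and the end-state
#' free-energy difference is \eqn{\Delta G_{A>B} = (RT/2)\ln(k_B/k_A)},
#' independent of the well minima.
#'
#' @param spec A \code{\link{toy_system_spec}}.
#' @return \eqn{\Delta G_{A>B}} in kJ/mol.
#' @export
analytic_dG <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  if (spec$system_kind != "harmonic_morph")
    stop("analytic_dG is available for harmonic_morph systems only")
  0.5 * kT(spec$temperature) * log(spec$k_B / spec$k_A)
}
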