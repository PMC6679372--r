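#' Ligand--surrounding energy difference between end states
#'
#' The energetic contribution to an alchemical transformation in one
#' environment: the difference of mean ligand--surrounding interaction
#' energies between the B and A end-state ensembles,
#' \eqn{\Delta E = \langle E \rangle_B - \langle E \rangle_A}. Only
#' ligand--surrounding terms are meaningful here because the
#' surrounding--surrounding energetic and entropic contributions to the
#' binding thermodynamics cancel exactly. Each mean's uncertainty comes
#' from block averaging, combined in quadrature.
#'
#' @param series_A,series_B \code{\link{energy_series}} from the A and B
#'   end states, same environment.
#' @return List with \code{dE} and \code{sigma_dE} (kJ/mol).
#' @export
delta_E <- function(series_A, series_B) {
  stopifnot(inherits(series_A, "energy_series"),
            inherits(series_B, "energy_series"))
  if (!identical(series_A$environment, series_B$environment))
    stop(sprintf("environment mismatch: '%s' vs '%s'",
                 series_A$environment, series_B$environment))
  sig <- function(s) {
    if (length(s$samples) >= 16L) block_average_sigma(s$samples)
    else stats::sd(s$samples) / sqrt(length(s$samples))
  }
  list(dE = mean(series_B$samples) - mean(series_A$samples),
       sigma_dE = sqrt(sig(series_A)^2 + sig(series_B)^2))
}

#' Entropic contribution from the energy/free-energy split
#'
#' With \eqn{\Delta G = \Delta E - T\Delta S} for the ligand--surrounding
#' terms, the entropy contribution follows as
#' \eqn{T\Delta S = \Delta E - \Delta G}. Applied per environment (water or
#' protein) to the same transformation and direction.
#'
#' @param dE Ligand--surrounding energy difference, kJ/mol.
#' @param dG Free-energy difference of the same transformation, kJ/mol.
#' @return \eqn{T\Delta S} in kJ/mol.
#' @export
entropy_from <- function(dE, dG) {
  stopifnot(is.numeric(dE), is.numeric(dG))
  dE - dG
}

#' Per-environment thermodynamic decomposition container
#'
#' @param environment \code{"water"} or \code{"protein"}.
#' @param dE,sigma_dE Energy difference and its standard error, kJ/mol.
#' @param TdS Entropic contribution \eqn{T\Delta S}, kJ/mol.
#' @param compound_label Transformation identifier (e.g. \code{"2a>3a"}).
#' @return An object of class \code{thermo_decomposition}.
#' @export
thermo_decomposition <- function(environment = c("water", "protein"),
                                 dE, sigma_dE, TdS, compound_label = "") {
  environment <- match.arg(environment)
  stopifnot(is.numeric(dE), is.numeric(sigma_dE), sigma_dE >= 0,
            is.numeric(TdS))
  structure(list(environment = environment, dE = as.numeric(dE),
                 sigma_dE = as.numeric(sigma_dE), TdS = as.numeric(TdS),
                 compound_label = as.character(compound_label)),
            class = "thermo_decomposition")
}

#' Bound-minus-unbound decomposition difference
#'
#' Combines the per-environment decompositions of one transformation into
#' the binding difference: \eqn{\Delta\Delta E = \Delta E^{protein} -
#' \Delta E^{water}} with uncertainties in quadrature, and
#' \eqn{T\Delta\Delta S = \Delta\Delta E - \Delta\Delta G} using the
#' relative binding free energy of the same transformation. The identity
#' \eqn{T\Delta\Delta S = \Delta\Delta E - \Delta\Delta G} holds exactly by
#' construction for every emitted row.
#'
#' @param water,protein \code{\link{thermo_decomposition}} objects for the
#'   same compound.
#' @param ddG Relative binding free energy \eqn{\Delta\Delta G} of the same
#'   transformation, kJ/mol.
#' @return List with \code{ddE}, \code{sigma_ddE}, \code{TddS} (kJ/mol) and
#'   \code{compound_label}.
#' @export
bound_minus_unbound <- function(water, protein, ddG) {
  stopifnot(inherits(water, "thermo_decomposition"),
            inherits(protein, "thermo_decomposition"),
            water$environment == "water", protein$environment == "protein",
            is.numeric(ddG))
  if (!identical(water$compound_label, protein$compound_label))
    stop(sprintf("compound label mismatch: '%s' vs '%s'",
                 water$compound_label, protein$compound_label))
  ddE <- protein$dE - water$dE
  list(ddE = ddE,
       sigma_ddE = sqrt(water$sigma_dE^2 + protein$sigma_dE^2),
       TddS = ddE - ddG,
       compound_label = water$compound_label)
}

#' Energy--entropy decomposition table from printed per-environment values
#'
#' Convenience wrapper that recomputes the bound-minus-unbound difference
#' columns of a decomposition report (\eqn{\Delta\Delta E},
#' \eqn{\sigma_{\Delta\Delta E}}, \eqn{T\Delta\Delta S}) from per-environment
#' energy/entropy columns plus the relative binding free energies.
#'
#' @param tab Data frame with columns \code{compound}, \code{dE_water},
#'   \code{sigma_water}, \code{TdS_water}, \code{dE_protein},
#'   \code{sigma_protein}, \code{TdS_protein}, \code{ddG}.
#' @return The input with columns \code{ddE}, \code{sigma_ddE}, \code{TddS}
#'   appended.
#' @export
decomposition_difference_table <- function(tab) {
  need <- c("compound", "dE_water", "sigma_water", "dE_protein",
            "sigma_protein", "ddG")
  stopifnot(is.data.frame(tab), all(need %in% names(tab)))
  out <- tab
  res <- lapply(seq_len(nrow(tab)), function(i) {
    w <- thermo_decomposition("water", tab$dE_water[i], tab$sigma_water[i],
                              if ("TdS_water" %in% names(tab)) tab$TdS_water[i] else NA_real_,
                              tab$compound[i])
    p <- thermo_decomposition("protein", tab$dE_protein[i], tab$sigma_protein[i],
                              if ("TdS_protein" %in% names(tab)) tab$TdS_protein[i] else NA_real_,
                              tab$compound[i])
    bound_minus_unbound(w, p, tab$ddG[i])
  })
  out$ddE <- vapply(res, `[[`, numeric(1), "ddE")
  out$sigma_ddE <- vapply(res, `[[`, numeric(1), "sigma_ddE")
  out$TddS <- vapply(res, `[[`, numeric(1), "TddS")
  out
}
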