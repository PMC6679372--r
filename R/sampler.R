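#' Sample a lambda-coupled toy ensemble by Metropolis Monte Carlo
#'
#' Draws configurations from the Boltzmann distribution of the coupled
#' Hamiltonian \eqn{H(\lambda) = (1-\lambda) H_A + \lambda H_B} at the
#' temperature of the spec, using single-particle Metropolis moves with a
#' symmetric uniform proposal. The proposal width is adapted during a
#' discarded burn-in (10\% of the production sweeps) to target roughly 40\%
#' acceptance, then frozen so the production chain satisfies detailed
#' balance. One sweep attempts one move per coordinate; every
#' \code{spec$stride}-th sweep is stored. Small strides leave deliberate
#' autocorrelation in the stored series, which is what the block-averaging
#' error estimator is designed to handle.
#'
#' The trajectory is a pure function of \code{spec} and \code{lambda_value}:
#' identical inputs reproduce it bit-for-bit. The caller's RNG state is left
#' untouched.
#'
#' @param spec A \code{\link{toy_system_spec}}.
#' @param lambda_value Coupling parameter in \[0, 1\].
#' @return An object of class \code{mc_trajectory} with fields \code{spec},
#'   \code{lambda_value}, \code{configurations} (matrix, one row per stored
#'   snapshot), \code{acceptance_rate} and \code{step_size}.
#' @examples
#' spec <- toy_system_spec("harmonic_morph", n_samples = 100, seed = 3)
#' traj <- sample_lambda(spec, 0)
#' var(traj$configurations[, 1]) # ~ RT / k_A
#' @export
sample_lambda <- function(spec, lambda_value) {
  stopifnot(inherits(spec, "toy_spec"),
            is.numeric(lambda_value), length(lambda_value) == 1L,
            lambda_value >= 0, lambda_value <= 1)
  params <- .toy_params(spec)
  beta <- 1 / kT(spec$temperature)
  ncoord <- if (spec$system_kind == "harmonic_morph") 1L else spec$bath_size

  ## initial configuration: the potential minima of the uncoupled terms
  x <- if (ncoord == 1L) {
    (1 - lambda_value) * spec$x_A + lambda_value * spec$x_B
  } else {
    params$centers
  }
  usite <- vapply(seq_len(ncoord), function(i)
    .u_site(spec, lambda_value, x[i], i, params), numeric(1))
  if (any(!is.finite(usite)))
    stop(sprintf("non-finite energy in the initial configuration at lambda = %g",
                 lambda_value))

  ## deterministic per-(seed, lambda) RNG stream, caller RNG preserved
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed((abs(spec$seed) * 7919L + as.integer(round(lambda_value * 1e4)) * 13L) %%
             .Machine$integer.max)

  n_prod <- spec$n_samples * spec$stride
  n_burn <- max(50L, ceiling(0.1 * n_prod))
  step <- 0.5 * sqrt(1 / (beta * max(spec$k_A, spec$k_B)))

  configurations <- matrix(NA_real_, nrow = spec$n_samples, ncol = ncoord)
  n_acc <- 0L; n_try <- 0L
  burn_acc <- 0L; burn_try <- 0L
  stored <- 0L

  for (sweep in seq_len(n_burn + n_prod)) {
    in_burn <- sweep <= n_burn
    dx <- stats::runif(ncoord, -step, step)
    uacc <- stats::runif(ncoord)
    for (i in seq_len(ncoord)) {
      xi_new <- x[i] + dx[i]
      u_new <- .u_site(spec, lambda_value, xi_new, i, params)
      if (is.nan(u_new))
        stop(sprintf("non-finite energy at lambda = %g, sweep %d", lambda_value, sweep))
      du <- u_new - usite[i]
      if (is.finite(du) && (du <= 0 || uacc[i] < exp(-beta * du))) {
        x[i] <- xi_new
        usite[i] <- u_new
        if (in_burn) burn_acc <- burn_acc + 1L else n_acc <- n_acc + 1L
      }
      if (in_burn) burn_try <- burn_try + 1L else n_try <- n_try + 1L
    }
    if (in_burn && sweep %% 25L == 0L && burn_try > 0L) {
      rate <- burn_acc / burn_try
      if (rate > 0.45) step <- step * 1.2
      if (rate < 0.35) step <- step * 0.8
      burn_acc <- 0L; burn_try <- 0L
    }
    if (!in_burn && (sweep - n_burn) %% spec$stride == 0L) {
      stored <- stored + 1L
      configurations[stored, ] <- x
    }
  }

  structure(list(spec = spec,
                 lambda_value = lambda_value,
                 configurations = configurations[seq_len(stored), , drop = FALSE],
                 acceptance_rate = n_acc / n_try,
                 step_size = step),
            class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("<mc_trajectory> %s at lambda = %g: %d snapshots, acceptance %.2f\n",
              x$spec$system_kind, x$lambda_value,
              nrow(x$configurations), x$acceptance_rate))
  invisible(x)
}
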