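#' Free-energy estimate container
#'
#' A scalar free-energy difference with its uncertainty, the estimator that
#' produced it, and an explicit direction (ordered pair of state labels).
#' Reversing the direction negates the value (\code{\link{fe_reverse}}).
#'
#' @param value Free-energy difference in kJ/mol.
#' @param sigma Nonnegative standard error in kJ/mol.
#' @param method One of \code{"TI"}, \code{"OSP"}, \code{"composite"}.
#' @param direction Character vector of length 2: \code{c(from, to)}.
#' @param ess Optional effective sample size of an exponential-averaging
#'   estimator.
#' @param low_overlap Logical flag set when the estimator judged the
#'   phase-space overlap to be poor.
#' @return An object of class \code{free_energy}.
#' @export
free_energy <- function(value, sigma = 0, method = c("TI", "OSP", "composite"),
                        direction = c("A", "B"), ess = NA_real_,
                        low_overlap = FALSE) {
  method <- match.arg(method)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            length(direction) == 2L)
  structure(list(value = as.numeric(value), sigma = as.numeric(sigma),
                 method = method, direction = as.character(direction),
                 ess = ess, low_overlap = isTRUE(low_overlap)),
            class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  cat(sprintf("dG(%s > %s) = %.3f +/- %.3f kJ/mol  [%s]%s\n",
              x$direction[1], x$direction[2], x$value, x$sigma, x$method,
              if (x$low_overlap) "  (low overlap)" else ""))
  invisible(x)
}

#' Reverse the direction of a free-energy estimate
#'
#' @param fe A \code{\link{free_energy}}.
#' @return The same estimate for the opposite direction (value negated).
#' @export
fe_reverse <- function(fe) {
  stopifnot(inherits(fe, "free_energy"))
  free_energy(-fe$value, fe$sigma, fe$method, rev(fe$direction),
              ess = fe$ess, low_overlap = fe$low_overlap)
}

#' Standard error of the mean of a correlated series by block averaging
#'
#' Estimates the standard error of the sample mean for a (possibly
#' autocorrelated) series by averaging over blocks of geometrically
#' increasing size (1, 2, 4, ...) and reading off the plateau of the
#' blocked standard-error estimates. Block sizes are limited so that at
#' least 32 blocks remain, and the plateau is taken as the maximum over
#' adjacent-pair-smoothed ladder estimates; smoothing damps the chi-squared
#' noise of the largest blocks, which would otherwise bias a raw maximum
#' upward.
#'
#' For uncorrelated data the result converges to the naive
#' \eqn{s/\sqrt{n}}; for positively correlated data it is inflated by the
#' statistical inefficiency, e.g. by \eqn{\sqrt{(1+\phi)/(1-\phi)}} for an
#' AR(1) process with lag-one autocorrelation \eqn{\phi}.
#'
#' @param series Numeric vector, at least 16 samples.
#' @return Standard error of the mean, same units as the input.
#' @export
block_average_sigma <- function(series) {
  stopifnot(is.numeric(series), all(is.finite(series)))
  n <- length(series)
  if (n < 16L)
    stop("block averaging needs at least 16 samples; collect a longer series")
  kmax <- floor(log2(n / 32))
  ks <- 0:max(kmax, 0L)
  ests <- vapply(ks, function(k) {
    b <- 2L^k
    m <- n %/% b
    bm <- colMeans(matrix(series[seq_len(m * b)], nrow = b))
    stats::sd(bm) / sqrt(m)
  }, numeric(1))
  if (length(ests) == 1L) return(ests)
  smoothed <- (ests[-1L] + ests[-length(ests)]) / 2
  max(ests[1L], smoothed)
}

#' Mean dH/dlambda profile over a lambda schedule
#'
#' Builds the per-lambda summary that thermodynamic integration consumes:
#' for each lambda point the mean of the \eqn{\partial H/\partial\lambda}
#' samples, its block-averaged standard error, and the sample count.
#'
#' @param x A list of \code{\link{dhdl_series}} (one per lambda point), or a
#'   data frame with columns \code{lambda}, \code{mean}, \code{sigma},
#'   \code{n}.
#' @return An object of class \code{ti_profile} wrapping a data frame
#'   \code{points} with those four columns, sorted by lambda.
#' @export
ti_profile <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("lambda", "mean", "sigma", "n") %in% names(x)))
    pts <- x[order(x$lambda), c("lambda", "mean", "sigma", "n")]
  } else {
    stopifnot(is.list(x), length(x) >= 2L,
              all(vapply(x, inherits, logical(1), "dhdl_series")))
    pts <- do.call(rbind, lapply(x, function(s) {
      data.frame(lambda = s$lambda_value,
                 mean = mean(s$samples),
                 sigma = if (length(s$samples) >= 16L)
                   block_average_sigma(s$samples)
                 else stats::sd(s$samples) / sqrt(length(s$samples)),
                 n = length(s$samples))
    }))
    pts <- pts[order(pts$lambda), ]
  }
  rownames(pts) <- NULL
  if (anyDuplicated(pts$lambda))
    stop("duplicate lambda values in TI profile")
  stopifnot(all(pts$lambda >= 0), all(pts$lambda <= 1), all(pts$sigma >= 0))
  structure(list(points = pts), class = "ti_profile")
}

#' @export
print.ti_profile <- function(x, ...) {
  cat(sprintf("<ti_profile> %d lambda points on [%g, %g]\n",
              nrow(x$points), min(x$points$lambda), max(x$points$lambda)))
  print(x$points, digits = 4)
  invisible(x)
}

## Trapezoid weights for (possibly non-uniform) ordered abscissae
.trapezoid_weights <- function(lambda) {
  k <- length(lambda)
  d <- diff(lambda)
  w <- numeric(k)
  w[1] <- d[1] / 2
  w[k] <- d[k - 1] / 2
  if (k > 2) w[2:(k - 1)] <- (d[-1] + d[-(k - 1)]) / 2
  w
}

#' Thermodynamic integration over a lambda profile
#'
#' Computes \eqn{\Delta G_{A>B} = \int_0^1 \langle \partial H/\partial
#' \lambda\rangle_\lambda \, d\lambda} by trapezoidal quadrature on the
#' given lambda grid. The uncertainty is propagated from the per-lambda
#' standard errors through the trapezoid weights in quadrature, treating
#' the lambda points as independent simulations.
#'
#' @param profile A \code{\link{ti_profile}} whose grid spans both end
#'   states (lambda 0 and 1 present).
#' @param direction Ordered state pair for the result.
#' @return A \code{\link{free_energy}} with \code{method = "TI"}.
#' @export
ti_integrate <- function(profile, direction = c("A", "B")) {
  stopifnot(inherits(profile, "ti_profile"))
  pts <- profile$points
  if (!isTRUE(all.equal(min(pts$lambda), 0)) ||
      !isTRUE(all.equal(max(pts$lambda), 1)))
    stop("TI profile must include both end states (lambda = 0 and lambda = 1)")
  w <- .trapezoid_weights(pts$lambda)
  free_energy(value = sum(w * pts$mean),
              sigma = sqrt(sum((w * pts$sigma)^2)),
              method = "TI", direction = direction)
}

## log(mean(exp(x))) without overflow
.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' One-step (Zwanzig) perturbation free energy
#'
#' Estimates the free-energy difference between the simulated state and a
#' perturbed state from the energy-difference series \eqn{\Delta U} on the
#' simulated ensemble, via exponential averaging:
#' \deqn{\Delta G = -RT \ln \langle e^{-\Delta U / RT} \rangle,}
#' evaluated with a log-sum-exp formulation so large \eqn{|\Delta U|} do not
#' overflow. The uncertainty is obtained by block averaging the per-sample
#' exponential weights and propagating through the logarithm, which respects
#' the autocorrelation of the underlying ensemble.
#'
#' Exponential averaging is reliable only when the perturbed state's
#' important configurations are sampled by the reference ensemble. The
#' effective sample size \eqn{n_{eff} = e^{-\sum_i p_i \ln p_i}} of the
#' normalised weights is attached to the result; below \code{min_ess} a
#' low-overlap flag is set and a warning raised.
#'
#' @param delta_u An \code{\link{energy_series}} (or numeric vector) of
#'   \eqn{U_{perturbed} - U_{reference}} per snapshot, kJ/mol.
#' @param temperature Temperature in K.
#' @param direction Ordered state pair for the result.
#' @param min_ess Effective-sample-size floor below which poor overlap is
#'   flagged (default 50).
#' @return A \code{\link{free_energy}} with \code{method = "OSP"}.
#' @export
osp_zwanzig <- function(delta_u, temperature = 300,
                        direction = c("A", "A*"), min_ess = 50) {
  if (inherits(delta_u, "energy_series")) delta_u <- delta_u$samples
  stopifnot(is.numeric(delta_u), length(delta_u) >= 1L, all(is.finite(delta_u)),
            temperature > 0)
  rt <- kT(temperature)
  n <- length(delta_u)
  lw <- -delta_u / rt
  dg <- -rt * .log_mean_exp(lw)

  ## normalised weights for the overlap diagnostic
  lp <- lw - (.log_mean_exp(lw) + log(n))
  p <- exp(lp)
  ess <- exp(-sum(p * ifelse(p > 0, log(p), 0)))

  ## sigma: block-average the (rescaled) weights w_i = exp(lw_i - max);
  ## the scale cancels in sigma(mean(w)) / mean(w).
  w <- exp(lw - max(lw))
  sw <- if (n >= 16L) block_average_sigma(w)
        else if (n >= 2L) stats::sd(w) / sqrt(n) else 0
  sigma <- rt * sw / mean(w)

  low <- n >= 2L && ess < min_ess && stats::sd(delta_u) > 0
  if (low)
    warning(sprintf(paste0("poor phase-space overlap: effective sample size ",
                           "%.1f < %g; the OSP estimate may be unreliable"),
                    ess, min_ess))
  free_energy(dg, sigma, method = "OSP", direction = direction,
              ess = ess, low_overlap = low)
}

#' Hysteresis of a forward/backward transformation pair
#'
#' The closure error of the loop A > B > A: with the backward leg stored in
#' its own direction (B > A), a perfectly converged pair satisfies
#' \eqn{\Delta G_{A>B} = -\Delta G_{B>A}} and the hysteresis
#' \eqn{|\Delta G_{A>B} + \Delta G_{B>A}|} vanishes. Non-zero values
#' diagnose insufficient sampling along the coupling path.
#'
#' @param forward A \code{\link{free_energy}} for A > B.
#' @param backward A \code{\link{free_energy}} for B > A.
#' @return Hysteresis in kJ/mol (nonnegative scalar).
#' @examples
#' f <- free_energy(5.6, method = "TI", direction = c("2g", "3g"))
#' b <- free_energy(-4.1, method = "TI", direction = c("3g", "2g"))
#' hysteresis(f, b) # 1.5
#' @export
hysteresis <- function(forward, backward) {
  stopifnot(inherits(forward, "free_energy"), inherits(backward, "free_energy"))
  if (!identical(forward$direction, rev(backward$direction)))
    stop(sprintf("direction mismatch: forward %s>%s vs backward %s>%s",
                 forward$direction[1], forward$direction[2],
                 backward$direction[1], backward$direction[2]))
  abs(forward$value + backward$value)
}

## Per-interval contribution to the TI error: a curvature-driven
## discretization term (second difference x width^2) plus the interval's
## share of the statistical variance under trapezoid weights.
.interval_scores <- function(pts) {
  lam <- pts$lambda; mu <- pts$mean; sig <- pts$sigma
  k <- length(lam)
  ni <- k - 1L
  ## central second differences at interior points, replicated to the ends
  curv <- rep(0, k)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      h1 <- lam[j] - lam[j - 1L]; h2 <- lam[j + 1L] - lam[j]
      curv[j] <- abs(2 * ((mu[j - 1L] - mu[j]) / h1 + (mu[j + 1L] - mu[j]) / h2) /
                       (h1 + h2))
    }
    curv[1L] <- curv[2L]; curv[k] <- curv[k - 1L]
  }
  width <- diff(lam)
  disc <- pmax(curv[-k], curv[-1L]) * width^2 / 12
  stat <- (width / 2) * sqrt(sig[-k]^2 + sig[-1L]^2)
  disc + stat
}

#' Propose additional lambda points to reduce the TI error
#'
#' When the propagated TI uncertainty exceeds \code{target_sigma}, proposes
#' midpoints of the intervals contributing most to the quadrature error.
#' Each interval is scored by a curvature-times-width-squared discretization
#' term plus its share of the statistical error under trapezoid weights;
#' intervals are ranked by decreasing score with ties broken toward lower
#' lambda. The default target reflects the common practice of refining the
#' schedule until the overall error estimate drops below 1 kJ/mol.
#'
#' @param profile A \code{\link{ti_profile}}.
#' @param target_sigma Acceptable propagated TI standard error, kJ/mol.
#' @param max_new Maximum number of midpoints to propose.
#' @return Numeric vector of new lambda values (possibly empty), ordered by
#'   decreasing expected benefit.
#' @export
refine_schedule <- function(profile, target_sigma = 1, max_new = 3L) {
  stopifnot(inherits(profile, "ti_profile"), target_sigma > 0, max_new >= 1L)
  current <- ti_integrate(profile)
  if (current$sigma <= target_sigma) return(numeric(0))
  pts <- profile$points
  score <- .interval_scores(pts)
  mids <- (pts$lambda[-nrow(pts)] + pts$lambda[-1L]) / 2
  ord <- order(-score, mids)
  mids[ord][seq_len(min(max_new, length(mids)))]
}
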