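---
title: "Free-energy estimators, toy ensembles, and the numerical choices behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy estimators, toy ensembles, and the numerical choices behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemr)
```

## The problem

Relative binding free energies between two closely related ligands A and B —
here the motivating case is a bioisosteric replacement of a ring nitrogen by
CH in a series of adenosine-receptor antagonists — are computed from
simulations of a nonphysical (alchemical) transformation. The Hamiltonian is
coupled linearly,

$$H(\lambda) = (1-\lambda)\,H_A + \lambda\,H_B,$$

and the transformation is simulated twice: with the ligand free in solution
(unbound, *u*) and bound to the receptor (*b*). By the state-function
property of the free energy around the thermodynamic cycle,

$$\Delta\Delta G_{u>b} = \Delta G^{b}_{A>B} - \Delta G^{u}_{A>B},$$

which is what `relative_binding_dG()` assembles. `alchemr` implements the
estimators that turn simulation time series into those leg free energies,
the diagnostics that decide whether they can be trusted, and the downstream
statistics (energy–entropy decomposition, comparison with experimental
affinities). The sampling engine behind the original application — receptor
molecular dynamics at cluster scale — is out of scope; in its place the
package provides toy ensembles with known answers (below).

## Thermodynamic integration

`ti_integrate()` evaluates
$\Delta G_{A>B} = \int_0^1 \langle \partial H/\partial\lambda \rangle_\lambda\, d\lambda$
by trapezoidal quadrature on the simulated λ grid. Choices and assumptions:

* **Grid.** Eleven equidistant λ points by default. The quadrature rule is
  not dictated by the physics; the trapezoid is the community default, is
  exact for integrands linear in λ, and makes the error analysis
  transparent. For a smooth integrand the leading discretization error is
  $h^2/12\,\overline{f''}$ per unit interval (the test suite pins this at
  $h^2/6$ for $f=\lambda^2$).
* **Error propagation.** Per-λ means are treated as independent (separate
  simulations), each with a block-averaged standard error $\sigma_i$; the TI
  error is $\sqrt{\sum_i w_i^2\sigma_i^2}$ with $w_i$ the trapezoid weights.
  How per-λ errors combine into the commonly quoted "overall error" is not
  standardized; quadrature-weight propagation is this package's choice and
  is stated here explicitly.
* **Schedule refinement.** `refine_schedule()` proposes midpoints of the
  intervals with the largest error contribution whenever the propagated TI
  error exceeds a target (1 kJ/mol by default, the conventional threshold
  for this kind of calculation). Each interval is scored by a discretization
  term (a central-second-difference curvature estimate × width²/12) plus its
  statistical share ((width/2)·√(σ_i²+σ_j²)); equal scores break toward
  lower λ so proposals are deterministic.

## One-step perturbation

For charge-redistribution questions — how would ΔΔG change if the perturbed
ring nitrogen carried a different partial charge? — resimulating every
variant is wasteful. `osp_zwanzig()` instead applies exponential averaging
on the existing end-state ensemble,

$$\Delta G_{A>A^*} = -RT\,\ln\left\langle e^{-\Delta U/RT} \right\rangle_A,
\qquad \Delta U = U_{A^*} - U_A,$$

computed with a log-sum-exp formulation so large $|\Delta U|$ cannot
overflow. The estimator is exact for constant ΔU regardless of sample count
(a useful degenerate case: a uniform energy shift). Its known failure mode
is poor phase-space overlap, where a few tail samples dominate the average;
the package quantifies this with the entropy-based effective sample size of
the normalized weights, $n_\mathrm{eff} = e^{-\sum_i p_i \ln p_i}$, and
flags results with $n_\mathrm{eff} < 50$. The floor is a diagnostic
threshold, not a rejection rule: the value is still returned, with
`low_overlap = TRUE` and a warning.

OSP uncertainties are obtained by block averaging the per-sample weights and
propagating through the logarithm, rather than by an analytic delta-method
formula, because the ensembles the estimator sees are autocorrelated and
block averaging handles that without a decorrelation model.

Combining the central TI legs with OSP flank legs gives the charge-variant
composite (`apply_charge_flanks()`):

$$\Delta G_{A^*>B^*} = -\Delta G^{OSP}_{A>A^*} + \Delta G^{TI}_{A>B}
  + \Delta G^{OSP}_{B>B^*}$$

per environment, and the binding difference is protein-minus-water of these
composites. The package's cycle-consistency test checks this composite
against a direct TI run at the modified charges on the toy charging system;
agreement within combined uncertainties is the same internal-consistency
argument that justifies reusing end states for a whole charge scan. Note
that OSP estimates from a single reference ensemble are *not* antisymmetric
under swapping the role of the two states — only TI along the full path is —
which is why `hysteresis()` (|forward + backward|) is the convergence
diagnostic, not a symmetry identity.

## Block averaging

`block_average_sigma()` estimates the standard error of the mean of a
correlated series: the series is cut into blocks of 1, 2, 4, … samples;
the naive SEM of the block means rises with block size until blocks are
longer than the correlation time, then plateaus at the true SEM.

Numerical choices: the ladder stops while at least 32 blocks remain, and the
plateau is read off as the maximum over adjacent-pair-smoothed ladder
estimates. Both choices respond to the chi-squared noise of large-block
estimates: with only 8–16 blocks the SEM-of-block-means estimate has ~20–30%
relative noise, and taking a raw maximum over such a ladder is biased high
by tens of percent. Smoothing adjacent ladder entries before taking the
maximum keeps the conservative bias (the result is never below the naive
SEM for positively correlated data, and the iid ratio converges to 1) while
damping the overshoot to a few percent on average. The estimator is
validated against the AR(1) closed form
$\mathrm{SEM} = s/\sqrt{n}\cdot\sqrt{(1+\phi)/(1-\phi)}$ at $\phi = 0.9$.
Sixteen samples is the hard floor below which the function refuses to
answer.

## The toy ensembles

`toy_system_spec()` + `sample_lambda()` generate seeded Metropolis Monte
Carlo ensembles of three one-dimensional λ-coupled systems, chosen so that
each estimator has an analytic oracle:

* **harmonic_morph** — one particle in a well morphing from $(k_A, x_A)$ to
  $(k_B, x_B)$. Every intermediate is Gaussian, and
  $\Delta G = (RT/2)\ln(k_B/k_A)$ exactly (independent of the minima), so TI
  is validated by parameter recovery. Defaults $k_A = 100$,
  $k_B = 400$ kJ mol⁻¹ nm⁻² give ΔG = RT ln 2 ≈ 1.73 kJ/mol at 300 K —
  large enough to resolve, small enough that eleven λ points suffice.
* **charging** — a site fixed at the origin whose charge interpolates
  between $q_A$ and $q_B$, Coulomb-coupled to a bath of harmonically
  tethered particles. The ligand–bath energy is exactly linear in the site
  charge, which makes OSP between charge variants well conditioned and
  gives a per-snapshot linearity identity
  ($\Delta U = (q^*-q)/q \cdot E^{elec}$) that the tests check exactly.
  Defaults $q_A = -0.54$ e → $q_B = -0.34$ e mirror the partial charge of
  the perturbed ring nitrogen in the two force-field variants most often
  compared; the bath carries −0.1 e per particle (same sign, so the Coulomb
  coupling is repulsive and the 1/r singularity is never attractive),
  tethered at 0.4 + 0.2(i−1) nm. The "water" and "protein" environments of
  the pipeline differ only in bath stiffness (tether constants 200 vs
  800 kJ mol⁻¹ nm⁻², a looser vs a tighter cage), enough to give the two
  legs genuinely different free energies.
* **softcore_insertion** — a Lennard-Jones + Coulomb site grown into the
  bath. The coupled pair potential follows the Beutler-style soft-core
  convention with the softness entering as $\alpha(1-\lambda)^2$:
  $$V(r,\lambda) = \lambda\left[4\varepsilon\left(s^{-2} - s^{-1}\right)
    + \frac{f\,q\,q_i}{\sqrt{\alpha_C (1-\lambda)^2 + r^2}}\right],
    \quad s = \alpha_{LJ}(1-\lambda)^2 + (r/\sigma)^6,$$
  with $\alpha_{LJ} = 0.5$ (dimensionless) and $\alpha_C = 0.5$ nm², the
  conventional values for perturbed atoms. At $\lambda < 1$ the potential
  and its λ-derivative are finite even at $r = 0$ (overlap of the bath with
  the inserted site); at $\lambda = 1$ the interaction is the plain
  LJ + Coulomb. `dhdl_series()` uses the analytic λ-derivative, which the
  tests verify against a central finite difference of the total potential.

Units throughout: kJ/mol, nm, e, K, with
R = 0.008314463 kJ mol⁻¹ K⁻¹ and the Coulomb factor 138.935458 kJ mol⁻¹ nm e⁻².

**Sampler.** Single-particle Metropolis moves with symmetric uniform
proposals; the step size is adapted every 25 sweeps during a discarded
burn-in (10% of the production length) toward ~40% acceptance, then frozen
so production sampling is exactly Boltzmann. Autocorrelation is deliberate —
small steps and a user-set storage stride leave enough correlation in the
stored series that block averaging has something real to measure.
Trajectories are a pure function of (spec, seed, λ): the λ value is mixed
into the seed so different λ points are statistically independent streams,
and the caller's RNG state is saved and restored.

**What the toys do and do not emulate.** They reproduce the *statistical*
structure of the real pipeline's inputs: correlated per-λ dH/dλ series,
end-state ligand–surrounding energy series, charge-linear perturbation
energies, and two environments with different stiffness. They do not contain
solvent granularity, a binding site, conformational substates/poses, long
correlation-time collective motions, or entropy–energy compensation of
water-network origin. Passing the toy-based tests therefore demonstrates
estimator correctness (the arithmetic and statistics are right), not that a
given receptor system is converged; for real data the hysteresis and
effective-sample-size diagnostics carry that burden.

## Decomposition and affinity statistics

`delta_E()`/`entropy_from()`/`bound_minus_unbound()` implement the
energy–entropy split: only ligand–surrounding interaction energies enter ΔE
because the surrounding–surrounding energetic and entropic contributions
cancel in the difference; the entropy follows as TΔS = ΔE − ΔG per
environment and TΔΔS = ΔΔE − ΔΔG for binding. These identities hold exactly
by construction in every emitted row; uncertainties on ΔE are block-averaged
per end state and combined in quadrature. Report rendering rounds to one
decimal; internal arithmetic is full precision.

The affinity statistics follow the conventions needed for censored
experimental data: compounds whose measured affinity is only a lower bound
("> x") have no point estimate, so they are excluded from the MAE (computed
over the four fully measured compounds, with the two poses of the
meta-substituted compound averaged since they are experimentally
indistinguishable), while correlations use all points except the pose known
to be inconsistent with the binding mode (j pose 1), with censored rows
entering at their bound value. These are exactly the conventions under
which the packaged table reproduces the published MAE and r² rows; one
column (−0.44 e) is an exact rounding half-case (MAE 2.15) where printed and
IEEE round-half-even digits differ by 0.1.

## Problem sizes and determinism

The test suite and the acceptance script run the toy systems at 400–2500
stored samples per λ (stride 5, bath of 5 particles), sizes at which the
harmonic TI recovery lands within ~0.03 kJ/mol of the closed form and a full
cycle-consistency comparison (4 TI runs + 4 OSP flanks) completes in well
under a minute. All randomness flows from explicit integer seeds; the
pipeline's JSON summary is byte-identical across repeated runs with the same
config.

## Known limitations

* One-dimensional toys: no rotational/conformational degrees of freedom, so
  pose-dependent effects (the j/m compounds' two binding modes) can only be
  represented as separate labelled runs, not discovered.
* The trapezoid rule converges as $h^2$; strongly curved dH/dλ profiles
  (e.g. near-singular insertion paths with inadequate soft-core parameters)
  need `refine_schedule()` rather than a higher-order rule.
* `block_average_sigma()` assumes stationarity; trending series (incomplete
  equilibration) inflate the plateau and should be truncated upstream.
* OSP is one-directional by design; no bidirectional (BAR/MBAR-style)
  reweighting is provided, matching the scope of the TI + OSP workflow it
  supports.
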