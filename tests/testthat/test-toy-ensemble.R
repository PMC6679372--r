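test_that("identical end states sample around the shared minimum with zero dH/dl", {
  spec <- quick_harmonic(k_A = 150, k_B = 150, x_A = 0.2, x_B = 0.2)
  for (lam in c(0, 0.5, 1)) {
    traj <- sample_lambda(spec, lam)
    x <- traj$configurations[, 1]
    expect_lt(abs(mean(x) - 0.2), 4 * sd(x) / sqrt(length(x) / 10))
    expect_equal(dhdl_series(traj)$samples, rep(0, spec$n_samples))
  }
})

test_that("sampled variance matches equipartition at the end state", {
  spec <- quick_harmonic(k_A = 100, k_B = 400, n_samples = 2000, stride = 10)
  traj <- sample_lambda(spec, 0)
  expect_equal(var(traj$configurations[, 1]), kT(300) / 100, tolerance = 0.15)
})

test_that("sampler honours the trajectory contract", {
  spec <- quick_charging()
  traj <- sample_lambda(spec, 0.5)
  expect_gt(traj$acceptance_rate, 0)
  expect_lt(traj$acceptance_rate, 1)
  expect_identical(nrow(traj$configurations), spec$n_samples)
  ## adaptive burn-in targets moderate acceptance
  expect_gt(traj$acceptance_rate, 0.2)
  expect_lt(traj$acceptance_rate, 0.6)
})

test_that("identical seed, spec and lambda reproduce the trajectory bit-for-bit", {
  spec <- quick_charging(n_samples = 100)
  t1 <- sample_lambda(spec, 0.3)
  t2 <- sample_lambda(spec, 0.3)
  expect_identical(t1$configurations, t2$configurations)
  expect_identical(t1$acceptance_rate, t2$acceptance_rate)
  t3 <- sample_lambda(toy_system_spec("charging", k_A = 300, k_B = 300,
                                      n_samples = 100, seed = 6), 0.3)
  expect_false(identical(t1$configurations, t3$configurations))
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(123); a <- runif(3)
  set.seed(123); invisible(sample_lambda(quick_harmonic(n_samples = 50), 0.5))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("harmonic coordinates agree with the analytic Gaussian density", {
  ## detailed-balance check: KS distance of sampled x against N(x_A, RT/k)
  spec <- quick_harmonic(k_A = 200, k_B = 200, n_samples = 2000, stride = 10)
  x <- sample_lambda(spec, 0)$configurations[, 1]
  ks <- suppressWarnings(ks.test(x, "pnorm", mean = 0, sd = sqrt(kT(300) / 200)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("dH/dlambda matches hand arithmetic on a known snapshot", {
  spec <- toy_system_spec("harmonic_morph", k_A = 100, k_B = 200,
                          x_A = 0, x_B = 0, n_samples = 1)
  traj <- structure(list(spec = spec, lambda_value = 0.5,
                         configurations = matrix(0.1, 1, 1),
                         acceptance_rate = 0.5, step_size = 0.1),
                    class = "mc_trajectory")
  expect_equal(dhdl_series(traj)$samples,
               0.5 * 200 * 0.01 - 0.5 * 100 * 0.01) # 0.5 kJ/mol
})

test_that("dH/dlambda equals the numerical lambda-derivative of the potential", {
  ## independent oracle: central finite difference of the total coupled
  ## potential, for every system kind, on a handful of snapshots
  h <- 1e-6
  for (kind in c("harmonic_morph", "charging", "softcore_insertion")) {
    spec <- toy_system_spec(kind, k_A = 120, k_B = if (kind == "harmonic_morph") 350 else 120,
                            bath_size = 3, n_samples = 25, seed = 9)
    for (lam in c(0.2, 0.7)) {
      traj <- sample_lambda(spec, lam)
      d <- dhdl_series(traj)$samples
      num <- vapply(seq_len(nrow(traj$configurations)), function(s) {
        x <- traj$configurations[s, ]
        (alchemr:::.u_total(spec, lam + h, x) -
           alchemr:::.u_total(spec, lam - h, x)) / (2 * h)
      }, numeric(1))
      expect_equal(d, num, tolerance = 1e-5)
    }
  }
})

test_that("soft-core interaction stays finite at particle overlap", {
  spec <- toy_system_spec("softcore_insertion", bath_size = 2, n_samples = 50,
                          seed = 3)
  p <- alchemr:::.toy_params(spec)
  for (lam in c(0.1, 0.5, 0.9)) {
    sc <- alchemr:::.softcore_pair(spec, p, lam, r = 0, qb = -0.1)
    expect_true(all(is.finite(unlist(sc))))
    ## and matches a direct evaluation of the documented formula
    s <- spec$alpha_LJ * (1 - lam)^2
    t <- spec$alpha_C * (1 - lam)^2
    expect_equal(sc$v_lj, 4 * 0.65 * (s^-2 - s^-1))
    expect_equal(sc$v_c, 138.935458 * spec$q_B * (-0.1) / sqrt(t))
  }
  ## fully coupled end state: sampled derivatives all finite
  traj <- sample_lambda(spec, 1)
  expect_true(all(is.finite(dhdl_series(traj)$samples)))
})

test_that("end-state energy series isolates the ligand-surrounding part", {
  ## no ligand-bath coupling at all -> identically zero
  spec <- quick_harmonic(n_samples = 30)
  expect_equal(endstate_energy_series(sample_lambda(spec, 0))$samples, rep(0, 30))

  ## zero charge -> zero electrostatic component
  spec0 <- quick_charging(q_A = 0, q_B = -0.3, n_samples = 30)
  es <- endstate_energy_series(sample_lambda(spec0, 0), component = "electrostatic")
  expect_equal(es$samples, rep(0, 30))

  ## charged end state matches a brute-force pairwise Coulomb re-evaluation
  spec <- quick_charging(n_samples = 200)
  traj <- sample_lambda(spec, 0)
  es <- endstate_energy_series(traj, environment = "protein")
  expect_equal(es$samples, brute_coulomb(traj, spec$q_A))
  expect_identical(es$environment, "protein")
  expect_identical(es$state_label, "A")

  ## decomposition undefined away from the end states
  expect_error(endstate_energy_series(sample_lambda(spec, 0.5)), "end state")
})

test_that("perturbation energies are linear in the site charge", {
  spec <- quick_charging(q_A = -0.5, q_B = -0.5, n_samples = 150)
  traj <- sample_lambda(spec, 0)
  e_elec <- endstate_energy_series(traj, component = "electrostatic")$samples

  same <- spec
  expect_equal(perturbed_energy_series(traj, same)$samples, rep(0, 150))

  doubled <- quick_charging(q_A = -1.0, q_B = -1.0, n_samples = 150)
  expect_equal(perturbed_energy_series(traj, doubled)$samples, e_elec)

  flipped <- quick_charging(q_A = 0.5, q_B = 0.5, n_samples = 150)
  expect_equal(perturbed_energy_series(traj, flipped)$samples, -2 * e_elec)
})

test_that("perturbations that alter geometry or stiffness are rejected", {
  spec <- quick_charging(n_samples = 30)
  traj <- sample_lambda(spec, 0)
  stiffer <- quick_charging(k = 500, n_samples = 30)
  expect_error(perturbed_energy_series(traj, stiffer), "charge changes only")
})

test_that("spec validation rejects unphysical parameters", {
  expect_error(toy_system_spec("harmonic_morph", k_A = -1))
  expect_error(toy_system_spec("harmonic_morph", temperature = 0))
  expect_error(toy_system_spec("harmonic_morph", n_samples = 0))
  expect_error(sample_lambda(quick_harmonic(), 1.2))
})
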