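test_that("block averaging handles constant, iid and correlated series", {
  expect_equal(block_average_sigma(rep(3.2, 64)), 0)
  expect_error(block_average_sigma(rnorm(10)), "at least 16")

  set.seed(42)
  x <- rnorm(1e4)
  expect_equal(block_average_sigma(x), 1 / sqrt(1e4), tolerance = 0.2)

  ## AR(1): inflation by the statistical-inefficiency closed form
  phi <- 0.9
  y <- as.numeric(arima.sim(list(ar = phi), 32768))
  naive <- sd(y) / sqrt(length(y))
  expect_equal(block_average_sigma(y), naive * sqrt((1 + phi) / (1 - phi)),
               tolerance = 0.2)
  ## never below the naive SEM for positively correlated data
  expect_gte(block_average_sigma(y), naive)
})

test_that("trapezoidal TI is exact for constant and linear integrands", {
  lam <- seq(0, 1, 0.1)
  const <- ti_profile(data.frame(lambda = lam, mean = 7.3, sigma = 0.1, n = 100))
  expect_equal(ti_integrate(const)$value, 7.3)

  lin <- ti_profile(data.frame(lambda = lam, mean = 2 + 3 * lam,
                               sigma = 0, n = 100))
  expect_equal(ti_integrate(lin)$value, (2 + 5) / 2)
})

test_that("TI quadrature error on a curved integrand matches a fine-grid oracle", {
  lam <- seq(0, 1, 0.1)
  prof <- ti_profile(data.frame(lambda = lam, mean = lam^2, sigma = 0, n = 1))
  fine <- seq(0, 1, length.out = 1e5)
  oracle <- sum(diff(fine) * (fine[-1]^2 + fine[-length(fine)]^2) / 2)
  ## 11-point trapezoid of x^2 carries h^2/6 = 1/600 discretization error
  expect_lt(abs(ti_integrate(prof)$value - oracle), 1 / 400)
  expect_equal(ti_integrate(prof)$value - oracle, 0.1^2 / 6, tolerance = 1e-4)
})

test_that("TI propagates per-lambda errors through the trapezoid weights", {
  lam <- c(0, 0.5, 1)
  prof <- ti_profile(data.frame(lambda = lam, mean = 0, sigma = c(1, 2, 1), n = 10))
  expect_equal(ti_integrate(prof)$sigma,
               sqrt(0.25^2 * 1 + 0.5^2 * 4 + 0.25^2 * 1))
})

test_that("TI refuses a profile missing an end state", {
  expect_error(ti_integrate(ti_profile(data.frame(lambda = c(0, 0.5),
                                                  mean = 0, sigma = 0, n = 1))),
               "lambda = 1")
})

test_that("Zwanzig estimator is exact for constant perturbation energies", {
  expect_equal(osp_zwanzig(rep(0, 5), 300)$value, 0)
  expect_equal(osp_zwanzig(rep(4.7, 3), 300)$value, 4.7)
  expect_equal(osp_zwanzig(rep(-12, 100), 250)$value, -12)
  expect_equal(osp_zwanzig(rep(4.7, 3), 300)$sigma, 0)
})

test_that("Zwanzig matches the Gaussian closed form on normal perturbations", {
  set.seed(42)
  rt <- kT(300)
  du <- rnorm(1e5, mean = 5, sd = 2)
  est <- osp_zwanzig(du, 300)
  closed <- mean(du) - var(du) / (2 * rt)
  expect_equal(est$value, closed, tolerance = 0.02)
  expect_gt(est$sigma, 0)
})

test_that("poor phase-space overlap is flagged via the effective sample size", {
  set.seed(1)
  wide <- rnorm(200, 0, 30)  # weights dominated by a few samples
  expect_warning(res <- osp_zwanzig(wide, 300), "overlap")
  expect_true(res$low_overlap)
  expect_lt(res$ess, 50)
  narrow <- rnorm(200, 0, 0.5)
  expect_silent(res2 <- osp_zwanzig(narrow, 300))
  expect_false(res2$low_overlap)
})

test_that("hysteresis is the absolute closure of the forward/backward loop", {
  f <- fe(5.6, 1.6, "TI", c("2g", "3g"))
  b <- fe(-4.1, 1.9, "TI", c("3g", "2g"))
  expect_equal(hysteresis(f, b), 1.5)
  expect_equal(hysteresis(fe(3.3), fe(-3.3, direction = c("B", "A"))), 0)
  expect_equal(hysteresis(fe(0), fe(2, direction = c("B", "A"))), 2)
  expect_error(hysteresis(f, fe(-4.1, direction = c("2g", "3g"))),
               "direction mismatch")
})

test_that("reversing a free energy negates its value and flips the direction", {
  x <- fe(2.5, 0.3, "OSP", c("A", "A*"))
  r <- fe_reverse(x)
  expect_equal(r$value, -2.5)
  expect_identical(r$direction, c("A*", "A"))
  expect_equal(r$sigma, 0.3)
})

test_that("schedule refinement is silent when the error target is met", {
  lam <- seq(0, 1, 0.1)
  prof <- ti_profile(data.frame(lambda = lam, mean = 1, sigma = 0.4, n = 100))
  expect_gt(ti_integrate(prof)$sigma, 0.1)
  expect_identical(refine_schedule(prof, target_sigma = 1), numeric(0))
})

test_that("refinement targets the intervals flanking a noisy lambda point", {
  lam <- seq(0, 1, 0.1)
  sig <- rep(1e-3, 11); sig[5] <- 50  # lambda = 0.4 is noisy
  prof <- ti_profile(data.frame(lambda = lam, mean = 1, sigma = sig, n = 100))
  prop <- refine_schedule(prof, target_sigma = 1, max_new = 2)
  ## equal scores break ties toward lower lambda
  expect_equal(prop, c(0.35, 0.45))
})

test_that("refinement ranking matches a brute-force interval-error ranking", {
  ## flat integrand: the only error source is statistical, so the interval
  ## contribution to the TI variance is (width/2)^2 (sigma_i^2 + sigma_j^2)
  set.seed(7)
  lam <- c(0, 0.1, 0.25, 0.5, 0.65, 0.9, 1)
  sig <- runif(7, 0.5, 5)
  prof <- ti_profile(data.frame(lambda = lam, mean = 2, sigma = sig, n = 100))
  contrib <- sapply(seq_len(6), function(i)
    (diff(lam)[i] / 2)^2 * (sig[i]^2 + sig[i + 1]^2))
  mids <- (lam[-7] + lam[-1]) / 2
  oracle <- mids[order(-contrib)]
  expect_equal(refine_schedule(prof, target_sigma = 1e-6, max_new = 6), oracle)
})
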