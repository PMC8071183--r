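test_that("k_off is the reciprocal deactivation time constant", {
  expect_equal(koff_from_tau(5.076), 0.197, tolerance = 0.001)
  expect_equal(koff_from_tau(1), 1)
  expect_equal(koff_from_tau(33.3), 0.030, tolerance = 0.002)
  expect_error(koff_from_tau(0), "> 0")
  expect_error(koff_from_tau(-2), "> 0")
})

test_that("a perfectly linear k_obs relation keeps all points, slope exact", {
  conc <- c(1, 3, 10, 30) * 1e-9
  pts <- tibble::tibble(concentration = conc,
                        k_obs = 9.70e7 * conc + 0.197)
  fit <- suppressWarnings(select_linear_range(pts))
  expect_equal(fit$included_concentrations, conc)
  expect_length(fit$excluded_concentrations, 0)
  expect_equal(fit$slope, 9.70e7, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.197, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
})

test_that("three linear points reproduce the closed-form OLS solution", {
  conc <- c(1, 3, 10) * 1e-9
  k <- c(0.30, 0.49, 1.18)
  fit <- select_linear_range(tibble::tibble(concentration = conc, k_obs = k))
  beta <- cov(conc, k) / var(conc)
  expect_equal(fit$slope, beta, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(k) - beta * mean(conc), tolerance = 1e-12)
})

test_that("saturating k_obs data lose their top concentrations", {
  # k_obs = k_max c / (c + c_half): initial slope k_max / c_half
  k_max <- 2
  c_half <- 5e-8
  conc <- 10^seq(-9.5, -6.5, by = 0.5)
  pts <- tibble::tibble(concentration = conc,
                        k_obs = k_max * conc / (conc + c_half))
  fit <- select_linear_range(pts)
  expect_gt(length(fit$excluded_concentrations), 0)
  expect_lt(max(fit$included_concentrations), max(conc))
  expect_lt(abs(fit$slope - k_max / c_half) / (k_max / c_half), 0.15)
})

test_that("estimate_kon validates distinctness and returns the slope", {
  pts <- tibble::tibble(concentration = c(1, 1, 3) * 1e-9,
                        k_obs = c(0.3, 0.31, 0.5))
  expect_error(estimate_kon(pts), "distinct")
  pts2 <- tibble::tibble(concentration = c(1, 3, 10) * 1e-9,
                         k_obs = 9.70e7 * c(1, 3, 10) * 1e-9 + 0.197)
  fit <- suppressWarnings(estimate_kon(pts2))
  expect_equal(fit$slope, 9.70e7, tolerance = 1e-9)
})

test_that("kinetic Kd and pKd reproduce the reference arithmetic", {
  kk <- kinetic_kd(0.197, 9.70e7)
  expect_equal(round(kk$pkd, 2), 8.69)
  kk2 <- kinetic_kd(0.028, 2.86e7)
  expect_equal(round(kk2$pkd, 2), 9.01)
  kk3 <- kinetic_kd(1.5, 1.5)
  expect_equal(kk3$kd, 1)
  expect_equal(kk3$pkd, 0)
  expect_error(kinetic_kd(0, 1), "> 0")

  # identity: pkd + log10(koff/kon) == 0 for random positive pairs
  set.seed(20)
  for (i in 1:25) {
    koff <- 10^runif(1, -3, 1)
    kon <- 10^runif(1, 2, 9)
    expect_equal(kinetic_kd(koff, kon)$pkd + log10(koff / kon), 0,
                 tolerance = 1e-12)
  }
})

test_that("pKd SEM uses the relative-error convention", {
  expect_equal(round(pkd_sem(0.197, 0.012, 9.70e7, 1.23e7), 2), 0.14)
  expect_equal(round(pkd_sem(0.030, 0.008, 8.65e5, 1.21e5), 2), 0.30)
  expect_equal(pkd_sem(0.1, 0, 1e6, 0), 0)
  expect_error(pkd_sem(0.1, -0.01, 1e6, 1e5), ">= 0")
})

test_that("shift classification assigns the expected arrows", {
  # dopamine potency collapse at the mutant: ~2.7 decades
  expect_equal(classify_shift(2e-8, 9.333e-6, "potency"), "↓↓↓")
  # p-tyramine k_off essentially unchanged
  expect_equal(classify_shift(0.123, 0.112, "rate"), "-")
  expect_equal(classify_shift(0.5, 0.5, "rate"), "-")
  # weak, strong and very strong increases
  expect_equal(classify_shift(1, 3, "rate"), "↑")
  expect_equal(classify_shift(1, 10^1.2, "rate"), "↑↑")
  expect_equal(classify_shift(1, 10^2.5, "rate"), "↑↑↑")
  expect_error(classify_shift(-1, 1, "rate"), "> 0")
})

test_that("full activation pipeline recovers k_on for a slow-binding agonist", {
  # (S)-5-OH-DPAT at WT: k_on 2.86e7; pooled k_obs points across seeds
  lig <- ligand_kinetics("(S)-5-OH-DPAT", 2.86e7, 0.028, efficacy = 0.52)
  p <- cascade_params()
  concs <- activation_concentrations(2.86e7, 0.028)
  pts <- purrr::map_dfr(1:3, function(s) {
    purrr::map_dfr(concs, function(cc) {
      run_activation_experiment(lig, p, cc, seed = s * 31)
    })
  })
  fit <- estimate_kon(pts)
  expect_lt(abs(fit$slope - 2.86e7) / 2.86e7, 0.20)
})
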