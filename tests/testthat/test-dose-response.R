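sigmoid_points <- function(pec50, top, conc, noise_sd = 0, seed = 1) {
  y <- top / (1 + 10^(-pec50 - log10(conc)))
  if (noise_sd > 0) {
    y <- y * (1 + withr::with_seed(seed, rnorm(length(y), sd = noise_sd)))
  }
  tibble::tibble(concentration = conc,
                 log10_concentration = log10(conc),
                 normalized_response = y)
}

test_that("normalization divides by the reference and keeps zeros", {
  expect_equal(normalize_to_reference(c(0.5, 1.0), 1.0), c(0.5, 1.0))
  expect_equal(normalize_to_reference(c(0, 0, 0), 2), c(0, 0, 0))
  expect_error(normalize_to_reference(1, 0), "> 0")
  expect_error(normalize_to_reference(1, -1), "> 0")
})

test_that("the fitted curve passes through Top/2 at X = -pEC50", {
  pts <- sigmoid_points(7.5, 0.8, 10^seq(-9.5, -5.5, by = 0.5))
  fit <- fit_concentration_response(pts)
  y_mid <- fit$top / (1 + 10^(-fit$pec50 - (-fit$pec50)))
  expect_equal(y_mid, fit$top / 2)
  expect_equal(fit$pec50, 7.5, tolerance = 1e-6)
})

test_that("noise-free points are recovered exactly; 2% noise stays within 0.1 log", {
  # exact recovery at a partial-agonist parameter set
  pts <- sigmoid_points(6.56, 0.64, 10^seq(-8.5, -4.5, by = 0.5))
  fit <- fit_concentration_response(pts)
  expect_equal(fit$pec50, 6.56, tolerance = 1e-6)
  expect_equal(fit$top, 0.64, tolerance = 1e-6)

  # full-agonist series with 2% multiplicative noise
  for (s in 1:5) {
    pts <- sigmoid_points(7.70, 1.0, c(1, 3, 10, 30, 100) * 1e-9,
                          noise_sd = 0.02, seed = s)
    fit <- fit_concentration_response(pts)
    expect_lt(abs(fit$pec50 - 7.70), 0.1)
  }
})

test_that("degenerate concentration-response inputs are flagged or rejected", {
  flat <- tibble::tibble(log10_concentration = c(-9, -8, -7),
                         normalized_response = c(0.5, 0.5, 0.5))
  fit <- fit_concentration_response(flat)
  expect_false(fit$converged)
  expect_match(fit$reasons, "non-identifiable")

  expect_error(
    fit_concentration_response(
      tibble::tibble(log10_concentration = c(-9, -9, -9),
                     normalized_response = c(0.1, 0.5, 0.9))
    ),
    "distinct"
  )
})

test_that("pEC50 is invariant to common rescaling; Top scales linearly", {
  conc <- 10^seq(-9, -6, by = 0.5)
  amps <- 2.0 / (1 + 10^(log10(3e-8) - log10(conc)))
  for (scale in c(0.5, 1, 4)) {
    pts <- tibble::tibble(
      log10_concentration = log10(conc),
      normalized_response = normalize_to_reference(amps * scale, 2.0 * scale)
    )
    fit <- fit_concentration_response(pts)
    expect_equal(fit$pec50, -log10(3e-8), tolerance = 1e-6)
    expect_equal(fit$top, 1.0, tolerance = 1e-6)
  }
  pts2 <- tibble::tibble(
    log10_concentration = log10(conc),
    normalized_response = normalize_to_reference(amps, 2.0 / 3)
  )
  expect_equal(fit_concentration_response(pts2)$top, 3.0, tolerance = 1e-5)
})

test_that("EC50 back-transforms and fold changes match the printed arithmetic", {
  expect_equal(ec50_from_pec50(7.70), 2.0e-8, tolerance = 0.003)
  expect_equal(ec50_from_pec50(9), 1e-9)
  expect_equal(signif(1e9 * ec50_from_pec50(6.56), 3), 275)

  expect_equal(potency_fold_change(7.70, 5.03), 468, tolerance = 0.002)
  expect_equal(potency_fold_change(8.28, 6.56), 52.5, tolerance = 0.002)
  expect_equal(potency_fold_change(6.2, 6.2), 1)

  expect_equal(efficacy_fold_change(0.63, 0.11), 5.73, tolerance = 0.001)
  expect_equal(efficacy_fold_change(0.37, 0.09), 4.11, tolerance = 0.001)
  expect_equal(efficacy_fold_change(0.4, 0.4), 1)
  expect_error(efficacy_fold_change(0.5, 0), "> 0")
})

test_that("pipeline pEC50 tracks the occupancy pK_d in the reserve-free regime", {
  # simulate staircase -> amplitudes -> sigmoid fit; the near-linear
  # reporter cascade should put pEC50 within 0.15 log units of pK_d
  lig <- da_wt()
  ref <- da_wt()
  st <- run_staircase_experiment(lig, ref, cascade_params(), seed = 9)
  pkd_true <- -log10(lig$k_off / lig$k_on)
  expect_lt(abs(st$fit$pec50 - pkd_true), 0.15)
  expect_equal(st$fit$top, 1.0, tolerance = 0.05)
})
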