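test_that("basal subtraction zeroes a constant trace and is idempotent", {
  tr <- as_trace(tibble::tibble(time = seq(0, 10, by = 1 / 156),
                                current = -1.0))
  out <- subtract_basal(tr, baseline_window = c(0, 5))
  expect_true(all(out$current == 0))
  again <- subtract_basal(out, baseline_window = c(0, 5))
  expect_equal(again$current, out$current)

  noisy <- as_trace(tibble::tibble(
    time = seq(0, 10, by = 1 / 156),
    current = -1 + withr::with_seed(3, rnorm(1561, sd = 0.005))
  ))
  b1 <- subtract_basal(noisy, baseline_window = c(0, 10))
  b2 <- subtract_basal(b1, baseline_window = c(0, 10))
  expect_lt(abs(mean(b2$current) - mean(b1$current)),
            3 * 0.005 / sqrt(1561))
})

test_that("basal subtraction rejects bad windows", {
  pr <- make_protocol("activation", "x", 1e-8)
  tr <- simulate_trace(da_wt(), quiet_params(), pr, seed = 1)
  expect_error(subtract_basal(tr, baseline_window = c(-5, 2)), "outside")
  expect_error(subtract_basal(tr, baseline_window = c(5, 20)), "overlaps")
})

test_that("staircase amplitudes equal the closed-form steady-state levels", {
  p <- quiet_params()
  lig <- ligand_kinetics("x", k_on = 1e8, k_off = 0.2, efficacy = 0.8)
  conc <- c(1e-9, 4e-9, 2e-8, 1e-7)
  pr <- make_protocol("staircase", "x", conc, step_s = 90)
  tr <- subtract_basal(simulate_trace(lig, p, pr, seed = 1))
  amps <- vapply(seq_len(nrow(pr)), function(i) response_amplitude(tr, pr[i, ]),
                 numeric(1))
  expected <- steady_state_response(conc, lig, p)$evoked
  expect_equal(amps, expected, tolerance = 0.02)
  # zero-concentration step reads ~0
  pr0 <- make_protocol("activation", "x", 0, step_s = 30)
  tr0 <- subtract_basal(simulate_trace(lig, p, pr0, seed = 1))
  expect_lt(abs(response_amplitude(tr0, pr0[1, ])), 1e-9)
})

test_that("amplitude at the half-occupancy concentration is half-maximal when gating is linear", {
  # near-linear gate regime: g_act << g_deact keeps Ga far below girk_half
  p <- quiet_params(g_act_rate = 0.1, g_deact_rate = 50, girk_half = 0.9)
  lig <- ligand_kinetics("x", 1e8, 0.1)
  kd <- 1e-9
  sat <- steady_state_response(1e-4, lig, p)$evoked
  half <- steady_state_response(kd, lig, p)$evoked
  expect_equal(half / sat, 0.5, tolerance = 0.01)
})

test_that("deactivation fit recovers tau from pure exponentials", {
  # noise-free: < 0.1% over two decades of tau
  for (tau in c(1, 10, 100)) {
    tr <- as_trace(pure_decay(tau, duration = 6 * tau))
    fit <- fit_deactivation(tr, washout_start = 0, window_s = 6 * tau)
    expect_lt(abs(fit$tau - tau) / tau, 0.001)
  }
  # definition of tau: one time constant into the window the fitted curve
  # has decayed to e^-1 of its amplitude, matching the data there
  tr <- as_trace(pure_decay(10))
  fit <- fit_deactivation(tr, washout_start = 0, window_s = 60,
                          fix_offset = TRUE)
  expect_equal(fit$tau, 10, tolerance = 1e-4)
  data_at <- approx(tr$time, -tr$current, xout = fit$window[1] + 10)$y
  expect_equal(fit$amplitude * exp(-1), data_at, tolerance = 1e-4)

  # recording-level noise: 1/tau within 3% at the dopamine residence time
  tr <- as_trace(pure_decay(1 / 0.197, duration = 42, noise_sd = 0.005,
                            seed = 5))
  fit <- fit_deactivation(tr, washout_start = 0, window_s = 42)
  expect_lt(abs(1 / fit$tau - 0.197) / 0.197, 0.03)
})

test_that("washout of a simulated slow ligand recovers k_off within 10%", {
  lig <- ligand_kinetics("(R)-5-OH-DPAT", k_on = 8.65e5, k_off = 0.030)
  pr <- make_protocol("washout", "(R)-5-OH-DPAT", 3e-7, tail_s = 114)
  tr <- simulate_trace(lig, cascade_params(), pr, seed = 2)
  fit <- fit_deactivation(tr, washout_start = pr$t_end[1], window_s = 104)
  expect_lt(abs(1 / fit$tau - 0.030) / 0.030, 0.10)
})

test_that("activation fit is exact on noise-free exponential rises", {
  t <- seq(0, 30, by = 1 / 156)
  for (rf in c(0.8, 0.95)) {
    y <- 1 - exp(-t / 2)
    tr <- as_trace(tibble::tibble(time = t, current = -y))
    fit <- fit_activation(tr, app_start = 0, rise_fraction = rf,
                          app_end = 30)
    expect_equal(fit$tau, 2, tolerance = 1e-4)
  }
})

test_that("simulated activation yields k_obs near k_on*c + k_off", {
  # 2 nM dopamine: expected rate 0.391 s^-1, well below the exchange rate,
  # recovered within 10%
  tr2 <- simulate_trace(da_wt(), cascade_params(),
                        make_protocol("activation", "dopamine", 2e-9),
                        seed = 3)
  k2 <- 1 / fit_activation(tr2, app_start = 10)$tau
  expect_lt(abs(k2 - 0.391) / 0.391, 0.10)

  # 10 nM dopamine: expected rate 1.167 s^-1 approaches the ~2.2 s^-1
  # exchange rate, so k_obs saturates: biased low, never high
  tr10 <- simulate_trace(da_wt(), cascade_params(),
                         make_protocol("activation", "dopamine", 1e-8),
                         seed = 3)
  k10 <- 1 / fit_activation(tr10, app_start = 10)$tau
  expect_lt(k10, 1.167)
  expect_gt(k10, 1.167 * 0.6)
})

test_that("activation fit errors when the plateau is not reached", {
  lig <- ligand_kinetics("slow", k_on = 1e6, k_off = 0.01)
  pr <- make_protocol("activation", "slow", 1e-9, step_s = 20)
  tr <- simulate_trace(lig, quiet_params(), pr, seed = 1)
  expect_error(fit_activation(tr, app_start = 10), "longer application")
})

test_that("widening the fit window to the whole rise degrades tau stability", {
  # rise_fraction ~ 1 pulls the window back to the exchange-limited foot
  # and out over the flat plateau; across seeds the fitted tau then
  # scatters more than with the central-80% window
  pr <- make_protocol("activation", "dopamine", 3e-9)
  p <- cascade_params()
  taus <- sapply(1:10, function(s) {
    tr <- simulate_trace(da_wt(), p, pr, seed = s)
    c(narrow = fit_activation(tr, 10, rise_fraction = 0.8)$tau,
      wide = fit_activation(tr, 10, rise_fraction = 0.999)$tau)
  })
  expect_gt(sd(taus["wide", ]), sd(taus["narrow", ]))
})

test_that("peak normalization and averaging behave as expected", {
  pr <- make_protocol("washout", "dopamine", 1e-8, tail_s = 40)
  p <- cascade_params()
  traces <- lapply(1:10, function(s) simulate_trace(da_wt(), p, pr, seed = s))

  one <- peak_normalize_and_average(traces[1], align_time = pr$t_end[1])
  expect_equal(max(-one$current), 1, tolerance = 0.02)
  expect_equal(one$time[1], -pr$t_end[1])

  # N identical traces average to the same as one
  same <- peak_normalize_and_average(traces[c(1, 1, 1)])
  expect_equal(same$current, peak_normalize_and_average(traces[1])$current)

  # averaging 10 replicates shrinks pointwise noise ~ sqrt(10), judged
  # against the noise-free normalized trace
  avg <- peak_normalize_and_average(traces)
  nf <- peak_normalize_and_average(
    list(simulate_trace(da_wt(), quiet_params(), pr, seed = 1))
  )
  ratio <- sd(one$current - nf$current) / sd(avg$current - nf$current)
  expect_gt(ratio, 2.2)
  expect_lt(ratio, 4.5)

  expect_error(peak_normalize_and_average(list()), "at least one")
})

test_that("trace QC applies the basal-current rule and flags bad samples", {
  pr <- make_protocol("activation", "x", 1e-8)
  ok <- simulate_trace(da_wt(), quiet_params(i_basal = 0.1), pr, seed = 1)
  expect_true(qc_trace(ok)$passed)
  expect_length(qc_trace(ok)$reasons, 0)

  high <- simulate_trace(da_wt(), quiet_params(i_basal = 0.6), pr, seed = 1)
  qc <- qc_trace(high)
  expect_false(qc$passed)
  expect_match(qc$reasons, "basal current exceeds limit", all = FALSE)

  bad <- ok
  bad$current[100] <- NaN
  qc2 <- qc_trace(bad)
  expect_false(qc2$passed)
  expect_match(qc2$reasons, "non-finite", all = FALSE)
})
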