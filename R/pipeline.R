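#' Default kinetic-experiment design for a ligand
#'
#' Chooses the activation (k_obs) concentration series for a ligand from its
#' expected kinetics: four concentrations log-spaced over
#' `Kd * [0.25, min(2, kobs_cap/k_off - 1)]`, which keeps every expected
#' k_obs below `kobs_cap` -- about one fifth of the solution-exchange rate --
#' so that the k_obs-concentration relation stays in its linear range, the
#' design constraint of the assay.
#'
#' @param k_on,k_off Expected rate constants of the ligand.
#' @param n Number of concentrations.
#' @param kobs_cap Largest acceptable expected k_obs (s^-1).
#' @return Concentrations in molar.
#' @export
activation_concentrations <- function(k_on, k_off, n = 4, kobs_cap = 0.45) {
  kd <- k_off / k_on
  f_max <- min(2, kobs_cap / k_off - 1)
  if (f_max <= 0.25) f_max <- 0.3
  kd * exp(seq(log(0.25), log(f_max), length.out = n))
}

#' Simulate one washout experiment and fit its decay
#'
#' @param ligand A [ligand_kinetics()] row.
#' @param params A [cascade_params()].
#' @param concentration Applied agonist concentration (M).
#' @param window_s Deactivation fit window (s).
#' @param seed Noise seed.
#' @return One-row tibble from [glance()] of the deactivation [exp_fit],
#'   plus `k_off_hat = 1/tau`.
#' @export
run_washout_experiment <- function(ligand, params, concentration, window_s,
                                   seed) {
  protocol <- make_protocol("washout", ligand$name, concentration,
                            tail_s = window_s + 10)
  trace <- simulate_trace(ligand, params, protocol, seed = seed)
  fit <- fit_deactivation(trace, washout_start = protocol$t_end[1],
                          window_s = window_s)
  out <- glance(fit)
  out$k_off_hat <- 1 / out$tau
  out$concentration <- concentration
  out$seed <- seed
  out
}

#' Simulate one activation experiment and extract k_obs
#'
#' The application is sized so the response reaches its plateau
#' (`>= 5 expected time constants`, minimum 30 s).
#'
#' @inheritParams run_washout_experiment
#' @return One-row tibble with `concentration`, `k_obs`, `tau`, `seed`.
#' @export
run_activation_experiment <- function(ligand, params, concentration, seed) {
  kobs_exp <- ligand$k_on * concentration + ligand$k_off
  dur <- max(30, ceiling(5 / kobs_exp))
  protocol <- make_protocol("activation", ligand$name, concentration,
                            step_s = dur)
  trace <- simulate_trace(ligand, params, protocol, seed = seed)
  fit <- fit_activation(trace, app_start = protocol$t_start[1])
  tibble(concentration = concentration, k_obs = 1 / fit$tau,
         tau = fit$tau, converged = fit$converged, seed = seed)
}

#' Simulate a concentration-response experiment and fit the sigmoid
#'
#' Runs a concentration staircase for the test ligand plus a separate
#' maximal-dopamine reference application (1 uM at WT, 300 uM at the
#' mutant), normalizes the steady-state amplitudes to the reference
#' response, and fits the concentration-response model.
#'
#' @param ligand A [ligand_kinetics()] row for the test agonist.
#' @param reference A [ligand_kinetics()] row for the reference full agonist
#'   (dopamine at the same receptor).
#' @param params A [cascade_params()].
#' @param concentrations Staircase concentrations (M); defaults to a
#'   2.5-decade series centered on the ligand's equilibrium `k_off/k_on`.
#' @param reference_conc Reference application concentration (M).
#' @param seed Noise seed.
#' @return List with `fit` (a `sigmoid_fit`) and `points` (the normalized
#'   concentration-response tibble).
#' @export
run_staircase_experiment <- function(ligand, reference, params,
                                     concentrations = NULL,
                                     reference_conc = 1e-6, seed = 1) {
  kd <- ligand$k_off / ligand$k_on
  concentrations <- concentrations %||% (kd * 10^seq(-1, 1.5, by = 0.5))
  protocol <- make_protocol("staircase", ligand$name, concentrations)
  trace <- subtract_basal(
    simulate_trace(ligand, params, protocol, seed = seed)
  )
  amps <- purrr::map_dbl(seq_len(nrow(protocol)),
                         ~ response_amplitude(trace, protocol[.x, ]))
  ref_protocol <- make_protocol("activation", reference$name, reference_conc)
  ref_trace <- subtract_basal(
    simulate_trace(reference, params, ref_protocol, seed = seed + 131)
  )
  ref_amp <- response_amplitude(ref_trace, ref_protocol[1, ])
  points <- tibble(
    ligand = ligand$name,
    concentration = concentrations,
    log10_concentration = log10(concentrations),
    normalized_response = normalize_to_reference(amps, ref_amp),
    oocyte_id = seed
  )
  list(fit = fit_concentration_response(points), points = points)
}

#' Estimate binding kinetics for one ligand/receptor condition
#'
#' The full kinetic workflow for one condition: `n_seeds` replicate washout
#' experiments give k_off as the mean of the fitted `1/tau_deact` (SEM
#' across replicates); replicate activation experiments at the design
#' concentrations give pooled (concentration, k_obs) points whose
#' linear-range slope is the k_on estimate; the kinetic K_d is their ratio.
#'
#' @param ligand A [ligand_kinetics()] row.
#' @param params A [cascade_params()].
#' @param washout_conc,washout_window Washout experiment design.
#' @param act_concs Activation concentrations (M); default from
#'   [activation_concentrations()].
#' @param n_seeds Number of replicate simulated oocytes.
#' @param seed Base seed.
#' @return List with `estimate` (one-row tibble: k_off, k_on, kd, pkd with
#'   SEMs), `kobs_points`, `kon_fit` (the `linear_range_fit`), and
#'   `washout_fits`.
#' @export
estimate_binding_kinetics <- function(ligand, params, washout_conc,
                                      washout_window, act_concs = NULL,
                                      n_seeds = 20, seed = 1) {
  act_concs <- act_concs %||%
    activation_concentrations(ligand$k_on, ligand$k_off)
  seeds <- seed + 1000L * seq_len(n_seeds)
  washouts <- purrr::map_dfr(
    seeds,
    ~ run_washout_experiment(ligand, params, washout_conc, washout_window, .x)
  )
  kobs_points <- purrr::map_dfr(seeds, function(s) {
    purrr::map_dfr(
      seq_along(act_concs),
      ~ run_activation_experiment(ligand, params, act_concs[.x],
                                  seed = s + 17L * .x)
    )
  })
  k_off <- mean(washouts$k_off_hat)
  k_off_sem <- sd(washouts$k_off_hat) / sqrt(nrow(washouts))
  kon_fit <- estimate_kon(kobs_points)
  kk <- kinetic_kd(k_off, kon_fit$slope)
  estimate <- tibble(
    ligand = ligand$name,
    k_off = k_off, k_off_sem = k_off_sem,
    k_on = kon_fit$slope, k_on_sem = kon_fit$slope_sem,
    intercept = kon_fit$intercept, intercept_sem = kon_fit$intercept_sem,
    kd = kk$kd, pkd = kk$pkd,
    pkd_sem = pkd_sem(k_off, k_off_sem, kon_fit$slope, kon_fit$slope_sem),
    n_seeds = n_seeds
  )
  list(estimate = estimate, kobs_points = kobs_points, kon_fit = kon_fit,
       washout_fits = washouts)
}

#' Run the full simulated kinetics study
#'
#' Chains every stage of the assay for a set of ligand x receptor
#' conditions: washout experiments (k_off), activation series (k_on),
#' concentration staircases (pEC50, Top), kinetic K_d computation, and the
#' cross-ligand Spearman correlation of pEC50 against kinetic pK_d. Fully
#' reproducible from the base `seed`.
#'
#' @param study Tibble of conditions; defaults to the reference agonist set
#'   of [d2_reference_kinetics()]. Required columns: `ligand`, `receptor`,
#'   `k_on`, `k_off`, `efficacy`, `washout_conc`, `washout_window`.
#' @param params A [cascade_params()].
#' @param n_seeds Replicate simulated oocytes per kinetic experiment.
#' @param seed Base seed; every simulated trace derives its noise seed from
#'   it.
#' @param run_staircase Also run concentration-response staircases (needed
#'   for the correlation and the summary table).
#' @return A list of class `girk_study`: `estimates`, `cr_fits`,
#'   `correlation`, `summary`, `shifts` (when both receptors are present),
#'   `kobs_points`, `washout_fits`, and `provenance` (seed, config hash).
#' @export
run_study_pipeline <- function(study = d2_reference_kinetics(),
                               params = cascade_params(),
                               n_seeds = 20, seed = 1,
                               run_staircase = TRUE) {
  study <- as_tibble(study)
  if (nrow(study) == 0) abort("`study` must contain at least one condition")
  req <- c("ligand", "receptor", "k_on", "k_off", "efficacy",
           "washout_conc", "washout_window")
  if (!all(req %in% names(study))) {
    abort(paste("`study` needs columns:", paste(req, collapse = ", ")))
  }
  results <- purrr::map(seq_len(nrow(study)), function(i) {
    row <- study[i, ]
    lig <- ligand_kinetics(row$ligand, row$k_on, row$k_off,
                           min(1, row$efficacy))
    res <- estimate_binding_kinetics(
      lig, params, row$washout_conc, row$washout_window,
      n_seeds = n_seeds, seed = seed + 100000L * i
    )
    res$estimate <- dplyr::mutate(res$estimate, receptor = row$receptor,
                                  .after = "ligand")
    res$kobs_points <- dplyr::mutate(res$kobs_points, ligand = row$ligand,
                                     receptor = row$receptor)
    res$washout_fits <- dplyr::mutate(res$washout_fits, ligand = row$ligand,
                                      receptor = row$receptor)
    res
  })
  estimates <- purrr::map_dfr(results, "estimate")
  cr_fits <- NULL
  correlation <- NULL
  summary_tbl <- NULL
  shifts <- NULL
  if (run_staircase) {
    cr_fits <- purrr::map_dfr(seq_len(nrow(study)), function(i) {
      row <- study[i, ]
      lig <- ligand_kinetics(row$ligand, row$k_on, row$k_off,
                             min(1, row$efficacy))
      ref_row <- study[study$ligand == "dopamine" &
                         study$receptor == row$receptor, ]
      ref <- if (nrow(ref_row) == 1) {
        ligand_kinetics("dopamine", ref_row$k_on, ref_row$k_off,
                        min(1, ref_row$efficacy))
      } else {
        lig
      }
      ref_conc <- if (identical(row$receptor, "S193A")) 3e-4 else 1e-6
      st <- run_staircase_experiment(lig, ref, params,
                                     reference_conc = ref_conc,
                                     seed = seed + 100000L * i + 7L)
      dplyr::mutate(glance(st$fit), ligand = row$ligand,
                    receptor = row$receptor, .before = 1)
    })
    if (nrow(estimates) >= 4) {
      correlation <- spearman_exact(cr_fits$pec50, estimates$pkd)
    }
    summary_tbl <- build_summary_table(estimates, cr_fits)
    both <- intersect(
      estimates$ligand[estimates$receptor == "WT"],
      estimates$ligand[estimates$receptor == "S193A"]
    )
    if (length(both) > 0) {
      mk <- function(rec) {
        dplyr::inner_join(
          dplyr::select(
            dplyr::filter(estimates, .data$receptor == rec,
                          .data$ligand %in% both),
            "ligand", "k_off", "k_on"
          ),
          dplyr::select(
            dplyr::filter(cr_fits, .data$receptor == rec,
                          .data$ligand %in% both),
            "ligand", "pec50", efficacy = "top"
          ),
          by = "ligand"
        )
      }
      shifts <- shift_table(mk("WT"), mk("S193A"))
    }
  }
  structure(
    list(
      estimates = estimates, cr_fits = cr_fits, correlation = correlation,
      summary = summary_tbl, shifts = shifts,
      kobs_points = purrr::map_dfr(results, "kobs_points"),
      washout_fits = purrr::map_dfr(results, "washout_fits"),
      provenance = list(
        seed = seed, n_seeds = n_seeds,
        config_hash = rlang::hash(list(study, unclass(params), n_seeds, seed))
      )
    ),
    class = "girk_study"
  )
}

#' @export
print.girk_study <- function(x, ...) {
  cat("<girk_study>", nrow(x$estimates), "conditions,",
      x$provenance$n_seeds, "seeds each (base seed",
      paste0(x$provenance$seed, ")"), "\n")
  print(x$estimates)
  if (!is.null(x$correlation)) print(x$correlation)
  invisible(x)
}

#' Recompute the reference-dataset arithmetic and report agreement
#'
#' From the embedded reference values (rate constants, potencies,
#' efficacies) this recomputes every derived quantity the package's methods
#' produce -- kinetic pK_ds and their SEMs, the pEC50 vs pK_d Spearman
#' correlation with exact permutation p, EC50 back-transforms, potency and
#' efficacy fold changes, and the full arrow grid -- and compares each
#' against its reported value. Failures are reported, never raised.
#'
#' @param tol_rel Relative tolerance for value checks (the reported values
#'   are rounded to their printed precision).
#' @return Tibble with `check`, `computed`, `reference`, `pass`.
#' @examples
#' reference_checks()
#' @export
reference_checks <- function(tol_rel = 0.01) {
  ref <- d2_reference_kinetics()
  eff <- d2_reference_efficacy()
  rows <- list()
  add <- function(check, computed, reference, tol = tol_rel,
                  tol_abs = NULL) {
    ok <- if (!is.null(tol_abs)) {
      abs(computed - reference) <= tol_abs + 1e-12
    } else {
      abs(computed - reference) <= tol * max(abs(reference), 1e-12)
    }
    rows[[length(rows) + 1]] <<- tibble(
      check = check, computed = computed, reference = reference,
      pass = is.finite(computed) && ok
    )
  }
  for (i in seq_len(nrow(ref))) {
    key <- paste0(ref$ligand[i], "/", ref$receptor[i])
    add(paste0("pkd ", key),
        round(kinetic_kd(ref$k_off[i], ref$k_on[i])$pkd, 2), ref$pkd[i],
        tol_abs = 0.005)
    add(paste0("pkd_sem ", key),
        round(pkd_sem(ref$k_off[i], ref$k_off_sem[i],
                      ref$k_on[i], ref$k_on_sem[i]), 2),
        ref$pkd_sem[i], tol_abs = 0.005)
  }
  corr <- spearman_exact(ref$pec50, ref$pkd)
  add("spearman_rho", round(corr$rho, 4), 0.9048, tol_abs = 5e-5)
  add("spearman_p", round(corr$p_two_sided, 4), 0.0046, tol_abs = 5e-5)
  add("ec50_nM dopamine/WT",
      1e9 * ec50_from_pec50(ref$pec50[ref$ligand == "dopamine" &
                                        ref$receptor == "WT"]),
      20, tol = 0.005)
  p_wt <- function(l) ref$pec50[ref$ligand == l & ref$receptor == "WT"]
  p_mu <- function(l) ref$pec50[ref$ligand == l & ref$receptor == "S193A"]
  add("potency_fold dopamine", potency_fold_change(p_wt("dopamine"),
                                                   p_mu("dopamine")), 467)
  add("potency_fold (S)-5-OH-DPAT",
      potency_fold_change(p_wt("(S)-5-OH-DPAT"), p_mu("(S)-5-OH-DPAT")), 52)
  e_of <- function(l, r) eff$top[eff$ligand == l & eff$receptor == r]
  add("efficacy_fold (R)-5-OH-DPAT",
      efficacy_fold_change(e_of("(R)-5-OH-DPAT", "S193A"),
                           e_of("(R)-5-OH-DPAT", "WT")), 5.7)
  add("efficacy_fold p-tyramine",
      efficacy_fold_change(e_of("p-tyramine", "S193A"),
                           e_of("p-tyramine", "WT")), 4.1)
  arrows <- shift_table(
    reference_shift_input(ref, eff, "WT"),
    reference_shift_input(ref, eff, "S193A")
  )
  expected <- reference_shift_arrows()
  arrows <- arrows[match(expected$ligand, arrows$ligand), ]
  add("table2_arrows_matched",
      sum(arrows$potency == expected$potency) +
        sum(arrows$efficacy == expected$efficacy) +
        sum(arrows$k_off == expected$k_off) +
        sum(arrows$k_on == expected$k_on),
      16, tol = 0)
  dplyr::bind_rows(rows)
}

reference_shift_input <- function(ref, eff, receptor) {
  sub <- ref[ref$receptor == receptor, ]
  ef <- eff[eff$receptor == receptor, ]
  tibble(
    ligand = sub$ligand, pec50 = sub$pec50,
    efficacy = ef$top[match(sub$ligand, ef$ligand)],
    k_off = sub$k_off, k_on = sub$k_on
  )
}

# Reported arrow grid for the S193A-vs-WT comparison.
reference_shift_arrows <- function() {
  tibble::tribble(
    ~ligand,         ~potency, ~efficacy, ~k_off, ~k_on,
    "dopamine",      "↓↓↓", "-", "-", "↓↓↓",
    "p-tyramine",    "↑", "↑", "-", "↑",
    "(S)-5-OH-DPAT", "↓↓", "-", "↑", "↓↓",
    "(R)-5-OH-DPAT", "↑", "↑↑", "↑", "↑"
  )
}
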