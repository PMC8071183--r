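#' Subtract the basal (agonist-independent) current
#'
#' References the trace to zero evoked response by subtracting the mean
#' current over a buffer-only baseline window, the first processing step for
#' amplitude quantification.
#'
#' @param trace A `girk_trace`.
#' @param baseline_window Two times (s) delimiting a buffer-only period;
#'   defaults to the protocol's pre-application baseline.
#' @return The trace with the baseline mean removed (evoked response now
#'   referenced to 0); the estimated basal magnitude is kept in the
#'   `"i_basal_estimate"` attribute.
#' @export
subtract_basal <- function(trace, baseline_window = NULL) {
  protocol <- attr(trace, "protocol")
  baseline_window <- baseline_window %||% attr(protocol, "baseline_window")
  if (is.null(baseline_window) || length(baseline_window) != 2) {
    abort("supply `baseline_window` (the trace has no protocol baseline)")
  }
  if (baseline_window[1] < min(trace$time) - 1e-9 ||
      baseline_window[2] > max(trace$time) + 1e-9) {
    abort("`baseline_window` lies outside the trace")
  }
  if (!is.null(protocol)) {
    active <- protocol[protocol$concentration > 0, , drop = FALSE]
    overlaps <- active$t_start < baseline_window[2] - 1e-9 &
      active$t_end > baseline_window[1] + 1e-9
    if (any(overlaps)) {
      abort("`baseline_window` overlaps an application step")
    }
  }
  sel <- trace$time >= baseline_window[1] & trace$time <= baseline_window[2]
  if (!any(sel)) abort("`baseline_window` contains no samples")
  basal <- mean(trace$current[sel])
  out <- trace
  out$current <- trace$current - basal
  new_girk_trace(out, protocol = protocol, params = attr(trace, "params"),
                 ligand = attr(trace, "ligand"), seed = attr(trace, "seed"),
                 baseline_subtracted = TRUE)
}

# Evoked magnitude (positive-up) of an inward-negative trace.
evoked_magnitude <- function(trace) {
  -trace$current
}

# Centered running mean used for robust event detection on noisy traces.
smooth_signal <- function(y, sample_rate, width_s = 0.25) {
  k <- max(1L, round(width_s * sample_rate))
  if (k %% 2 == 0) k <- k + 1L
  if (k >= length(y)) return(y)
  sm <- stats::filter(y, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- y[is.na(sm)]
  as.numeric(sm)
}

trace_sample_rate <- function(trace) {
  p <- attr(trace, "params")
  if (!is.null(p)) p$sample_rate else 1 / stats::median(diff(trace$time))
}

#' Steady-state evoked response amplitude for a protocol step
#'
#' Quantifies the response to one application step as the mean evoked
#' magnitude over the final `eval_s` seconds of the step, by which time a
#' steady-state response has been achieved for a 60-s application.
#'
#' @param trace A baseline-subtracted `girk_trace` (see [subtract_basal()]).
#' @param step A single row of the trace's perfusion protocol (or its row
#'   index).
#' @param eval_s Evaluation window at the end of the step (s).
#' @return Amplitude in uA (positive = inward evoked current).
#' @export
response_amplitude <- function(trace, step, eval_s = 1) {
  if (!isTRUE(attr(trace, "baseline_subtracted"))) {
    abort("`trace` must be baseline-subtracted first (see subtract_basal())")
  }
  if (is.numeric(step) && length(step) == 1) {
    step <- attr(trace, "protocol")[step, ]
  }
  dur <- step$t_end - step$t_start
  if (dur < eval_s) abort("step is shorter than the evaluation window")
  sel <- trace$time >= step$t_end - eval_s & trace$time <= step$t_end
  mean(evoked_magnitude(trace)[sel])
}

new_exp_fit <- function(tau, tau_se, amplitude, offset, rmse, window,
                        converged, reasons = character()) {
  structure(
    list(tau = tau, tau_se = tau_se, amplitude = amplitude, offset = offset,
         rmse = rmse, window = window, converged = converged,
         reasons = reasons),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> tau = %.4g s (1/tau = %.4g s^-1), amplitude = %.4g, offset = %.4g\n",
    x$tau, 1 / x$tau, x$amplitude, x$offset
  ))
  cat(sprintf("  window [%.2f, %.2f] s, rmse = %.3g, converged = %s\n",
              x$window[1], x$window[2], x$rmse, x$converged))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.exp_fit <- function(x, ...) {
  tibble(
    term = c("tau", "amplitude", "offset"),
    estimate = c(x$tau, x$amplitude, x$offset),
    std.error = c(x$tau_se, NA_real_, NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.exp_fit <- function(x, ...) {
  tibble(
    tau = x$tau, tau_se = x$tau_se, rate = 1 / x$tau,
    amplitude = x$amplitude, offset = x$offset, rmse = x$rmse,
    t0 = x$window[1], t1 = x$window[2], converged = x$converged
  )
}

# Levenberg-Marquardt monoexponential fit y = A exp(-(t - t[1])/tau) + C
# (decay) or y = Yinf - A exp(-(t - t[1])/tau) (rise). Bounds keep tau
# within [1/sample_rate, 10 * window].
fit_monoexp <- function(t, y, sample_rate, rise = FALSE, fix_offset = FALSE) {
  td <- t - t[1]
  win <- max(td)
  n <- length(td)
  tau0 <- max(win / 3, 2 / sample_rate)
  lower <- c(-Inf, 1 / sample_rate, if (!fix_offset) -Inf)
  upper <- c(Inf, 10 * win, if (!fix_offset) Inf)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
  fit <- tryCatch({
    if (rise && fix_offset) {
      minpack.lm::nlsLM(y ~ A * (1 - exp(-td / tau)),
                        start = list(A = y[n], tau = tau0),
                        lower = lower[1:2], upper = upper[1:2], control = ctrl)
    } else if (rise) {
      minpack.lm::nlsLM(y ~ (A + C) - A * exp(-td / tau),
                        start = list(A = y[n] - y[1], tau = tau0, C = y[1]),
                        lower = lower, upper = upper, control = ctrl)
    } else if (fix_offset) {
      minpack.lm::nlsLM(y ~ A * exp(-td / tau),
                        start = list(A = y[1], tau = tau0),
                        lower = lower[1:2], upper = upper[1:2], control = ctrl)
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-td / tau) + C,
                        start = list(A = y[1] - y[n], tau = tau0, C = y[n]),
                        lower = lower, upper = upper, control = ctrl)
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_exp_fit(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                       c(t[1], t[n]), FALSE,
                       paste("fit failed:", conditionMessage(fit))))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  tau <- cf[["tau"]]
  reasons <- character()
  if (tau <= 1 / sample_rate * (1 + 1e-6) || tau >= 10 * win * (1 - 1e-6)) {
    reasons <- c(reasons, "tau at fit bound")
  }
  offset <- if (fix_offset) 0 else if (rise) cf[["A"]] + cf[["C"]] else cf[["C"]]
  new_exp_fit(
    tau = tau, tau_se = unname(se["tau"]), amplitude = unname(cf[["A"]]),
    offset = unname(offset),
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    window = c(t[1], t[n]),
    converged = length(reasons) == 0, reasons = reasons
  )
}

#' Fit the deactivation (washout) time constant
#'
#' Fits a monoexponential decay to the response decline after agonist
#' washout, yielding the deactivation time constant tau_deact whose
#' reciprocal estimates the agonist dissociation rate constant k_off.
#'
#' The fitted interval starts at the decay onset, not the nominal washout
#' command: the bath concentration decays with the solution-exchange time
#' constant, so the first ~1-2 s after washout show a rebinding shoulder
#' rather than exponential decay. Onset is detected as the first time the
#' smoothed evoked magnitude falls below `onset_frac` of its post-washout
#' peak; the window still ends `window_s` seconds after `washout_start`.
#'
#' @param trace A `girk_trace` (baseline subtraction is not required: the fit
#'   has a free offset unless `fix_offset = TRUE`).
#' @param washout_start Time of the washout command (s), usually the end of
#'   the application step.
#' @param window_s Length of the analysis window following washout (s); in
#'   the reference experiments 42 s (dopamine, p-tyramine at WT), 104 s
#'   (5-OH-DPAT enantiomers at WT), or 24 s (all ligands at the mutant).
#' @param fix_offset Force the decay to an offset of 0 (requires a
#'   baseline-subtracted trace to be meaningful).
#' @param onset_frac Fraction of the post-washout peak below which the decay
#'   is deemed to have begun.
#' @return An `exp_fit` (tau, amplitude, offset, rmse, window, convergence).
#' @export
fit_deactivation <- function(trace, washout_start, window_s,
                             fix_offset = FALSE, onset_frac = 0.98) {
  if (washout_start + window_s > max(trace$time) + 1e-6) {
    abort("washout window extends past the end of the trace")
  }
  sr <- trace_sample_rate(trace)
  ev <- evoked_magnitude(trace)
  sm <- smooth_signal(ev, sr)
  t <- trace$time
  search <- which(t >= washout_start & t <= washout_start + min(6, window_s / 3))
  ipk <- search[which.max(sm[search])]
  after <- which(t >= t[ipk] & t <= washout_start + window_s &
                   sm <= onset_frac * sm[ipk])
  istart <- if (length(after)) min(after) else ipk
  idx <- which(t >= t[istart] & t <= washout_start + window_s)
  fit_monoexp(t[idx], ev[idx], sr, rise = FALSE, fix_offset = fix_offset)
}

#' Fit the activation time constant and observed activation rate
#'
#' Fits a monoexponential rise to the current increase after agonist
#' application. The fitted segment covers the central `rise_fraction` of the
#' current increase (for the default 0.8, from the 10% to the 90% crossing),
#' which excludes the solution-exchange-limited foot of the response; the
#' observed activation rate is `k_obs = 1/tau_act`. The plateau is taken as
#' the mean evoked magnitude over the final 10% of the application step.
#'
#' @param trace A `girk_trace`.
#' @param app_start Application onset time (s).
#' @param rise_fraction Fraction of the current increase the fitted window
#'   covers (centered), in (0, 1).
#' @param app_end Application end time (s); defaults to the end of the
#'   protocol step starting at `app_start`.
#' @param anchor_baseline If `TRUE`, anchor the rise at the pre-application
#'   level and fit from `app_start` (offset not free).
#' @return An `exp_fit`; `1/tau` is k_obs.
#' @export
fit_activation <- function(trace, app_start, rise_fraction = 0.8,
                           app_end = NULL, anchor_baseline = FALSE) {
  protocol <- attr(trace, "protocol")
  if (is.null(app_end)) {
    if (is.null(protocol)) abort("supply `app_end` (trace has no protocol)")
    step <- protocol[abs(protocol$t_start - app_start) < 1e-6 &
                       protocol$role == "agonist", ]
    if (nrow(step) == 0) abort("no protocol step starts at `app_start`")
    app_end <- step$t_end[1]
  }
  if (rise_fraction <= 0 || rise_fraction >= 1) {
    abort("`rise_fraction` must be in (0, 1)")
  }
  sr <- trace_sample_rate(trace)
  t <- trace$time
  ev <- evoked_magnitude(trace)
  sm <- smooth_signal(ev, sr)
  plat_sel <- t >= app_end - 0.1 * (app_end - app_start) & t <= app_end
  plateau <- mean(ev[plat_sel])
  i0 <- which.min(abs(t - app_start))
  y0 <- sm[i0]
  rise <- plateau - y0
  if (!is.finite(rise) || rise <= 0) {
    abort("no current increase detected during the application")
  }
  lo <- (1 - rise_fraction) / 2
  hi <- 1 - lo
  in_app <- which(t >= app_start & t <= app_end)
  cross <- function(frac) {
    i <- in_app[sm[in_app] >= y0 + frac * rise]
    if (!length(i)) NA_integer_ else min(i)
  }
  i_lo <- if (anchor_baseline) i0 else cross(lo)
  i_hi <- cross(hi)
  # a response still rising at the end of the step crosses its (biased-low)
  # plateau estimate only near the step end; require headroom after t_hi
  if (is.na(i_lo) || is.na(i_hi) ||
      t[i_hi] > app_end - 0.5 * (t[i_hi] - t[i_lo])) {
    abort(paste(
      "plateau not reached within the application step;",
      "use a longer application"
    ))
  }
  idx <- i_lo:i_hi
  fit_monoexp(t[idx], ev[idx], sr, rise = TRUE,
              fix_offset = anchor_baseline)
}

#' Peak-normalize and average traces
#'
#' Scales each trace to unit peak evoked magnitude, aligns them at
#' `align_time` (which becomes t = 0), and returns the pointwise mean --
#' the standard preprocessing for overlaying washout decays from replicate
#' oocytes.
#'
#' @param traces List of `girk_trace` objects on identical time grids.
#' @param align_time Time (s) mapped to 0 in the output.
#' @return A `girk_trace` whose `current` is the mean unit-peak-normalized
#'   current (dimensionless, still inward-negative), with an `n_traces`
#'   attribute.
#' @export
peak_normalize_and_average <- function(traces, align_time = 0) {
  if (length(traces) == 0) abort("`traces` must contain at least one trace")
  grids <- purrr::map(traces, "time")
  if (!all(purrr::map_lgl(grids, ~ length(.x) == length(grids[[1]]) &&
                            max(abs(.x - grids[[1]])) < 1e-9))) {
    abort("all traces must share the same time grid")
  }
  normed <- purrr::map(traces, function(tr) {
    tr_b <- if (isTRUE(attr(tr, "baseline_subtracted"))) tr else {
      subtract_basal(tr)
    }
    ev <- evoked_magnitude(tr_b)
    ev / max(smooth_signal(ev, trace_sample_rate(tr_b)))
  })
  avg <- Reduce(`+`, normed) / length(normed)
  out <- tibble(time = grids[[1]] - align_time, current = -avg)
  out <- new_girk_trace(out, protocol = attr(traces[[1]], "protocol"),
                        params = attr(traces[[1]], "params"),
                        baseline_subtracted = TRUE)
  attr(out, "n_traces") <- length(traces)
  out
}

#' Quality-control check for a recorded trace
#'
#' Applies the selection rules used for oocyte recordings: the basal
#' (holding) current magnitude must stay below `basal_limit` and the trace
#' must contain no non-finite samples. QC never raises an error; it reports.
#'
#' @param trace A `girk_trace`.
#' @param basal_limit Maximum acceptable basal current magnitude (uA).
#' @return A list of class `qc_result` with `passed` (flag) and `reasons`
#'   (character vector, empty iff passed).
#' @export
qc_trace <- function(trace, basal_limit = 0.5) {
  reasons <- character()
  if (any(!is.finite(trace$current))) {
    reasons <- c(reasons, "trace contains non-finite samples")
  }
  basal <- NA_real_
  bw <- attr(attr(trace, "protocol"), "baseline_window")
  finite_cur <- trace$current[is.finite(trace$current)]
  if (!is.null(bw)) {
    sel <- trace$time >= bw[1] & trace$time <= bw[2] & is.finite(trace$current)
    if (any(sel)) basal <- abs(mean(trace$current[sel]))
  }
  if (is.na(basal) && length(finite_cur)) {
    basal <- abs(mean(head(finite_cur, max(1, round(length(finite_cur) / 20)))))
  }
  if (is.finite(basal) && basal > basal_limit) {
    reasons <- c(reasons, "basal current exceeds limit")
  }
  structure(list(passed = length(reasons) == 0, reasons = reasons,
                 basal = basal),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>", if (x$passed) "PASS" else "FAIL", "\n")
  if (length(x$reasons)) cat(paste(" -", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}
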