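#' Parameters of the receptor - G protein - GIRK reporter cascade
#'
#' The simulator treats the signaling cascade downstream of agonist binding
#' as a fast, near-linear reporter of receptor occupancy: occupied receptors
#' catalyse activation of a single pool of G protein, RGS-accelerated GTP
#' hydrolysis deactivates it, and the GIRK conductance follows the active-G
#' fraction through an instantaneous Hill gate. Channel current is read out
#' at -80 mV in high-K+ (25 mM) buffer as an inward (negative) current.
#'
#' Defaults put the cascade in the regime the assay is designed for:
#' G-protein turnover much faster than ligand unbinding (`g_deact_rate` = 25
#' s^-1 with RGS4 co-expression) and weak fractional G activation
#' (`g_act_rate` = 0.5 s^-1, `girk_half` = 0.9), so that the evoked current
#' is close to proportional to occupancy and the washout decay is close to
#' monoexponential with rate k_off. The Hill gate is normalized to its value
#' at full occupancy by a full agonist, so `i_max` is the saturating evoked
#' current amplitude a full agonist can elicit.
#'
#' @param g_act_rate G-protein activation rate per fully occupied receptor
#'   (s^-1).
#' @param g_deact_rate GTP-hydrolysis (deactivation) rate, RGS-accelerated
#'   (s^-1).
#' @param girk_half Active-G fraction giving half-maximal channel opening,
#'   in (0, 1).
#' @param girk_hill Hill coefficient of the gate, >= 1.
#' @param i_max Maximal agonist-evoked inward current magnitude (uA).
#' @param i_basal Agonist-independent inward current magnitude (uA).
#' @param exchange_tau Solution-exchange time constant around the oocyte (s);
#'   0.45 s corresponds to the measured exchange rate of ~2.2 s^-1.
#' @param noise_sd SD of additive white Gaussian recording noise (uA).
#' @param rundown_rate Optional linear rundown of the evoked component
#'   (s^-1, >= 0); 0 disables it.
#' @param sample_rate Acquisition rate (Hz).
#' @param rtol Relative tolerance of the stiff-capable ODE integrator.
#'
#' @return A list of class `cascade_params`.
#' @examples
#' cascade_params()
#' @export
cascade_params <- function(g_act_rate = 0.5, g_deact_rate = 25,
                           girk_half = 0.9, girk_hill = 1,
                           i_max = 1.5, i_basal = 0.2,
                           exchange_tau = 0.45, noise_sd = 0.005,
                           rundown_rate = 0, sample_rate = 156,
                           rtol = 1e-8) {
  p <- list(
    g_act_rate = g_act_rate, g_deact_rate = g_deact_rate,
    girk_half = girk_half, girk_hill = girk_hill,
    i_max = i_max, i_basal = i_basal, exchange_tau = exchange_tau,
    noise_sd = noise_sd, rundown_rate = rundown_rate,
    sample_rate = sample_rate, rtol = rtol
  )
  pos <- c("g_act_rate", "g_deact_rate", "girk_hill", "i_max",
           "exchange_tau", "sample_rate", "rtol")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      abort(paste0("`", nm, "` must be finite and > 0"))
    }
  }
  if (girk_half <= 0 || girk_half >= 1) abort("`girk_half` must be in (0, 1)")
  if (girk_hill < 1) abort("`girk_hill` must be >= 1")
  if (i_basal < 0) abort("`i_basal` must be >= 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (rundown_rate < 0) abort("`rundown_rate` must be >= 0")
  structure(p, class = "cascade_params")
}

# Hill gate on the active-G fraction, normalized so a full agonist at full
# occupancy yields gate = 1 (hence evoked current = i_max).
girk_gate <- function(ga, params) {
  ga_ref <- params$g_act_rate / (params$g_act_rate + params$g_deact_rate)
  h <- params$girk_hill
  raw <- ga^h / (ga^h + params$girk_half^h)
  ref <- ga_ref^h / (ga_ref^h + params$girk_half^h)
  raw / ref
}

#' Closed-form steady-state response at constant agonist concentration
#'
#' At constant effective concentration `c` the cascade settles to occupancy
#' `RL = c / (c + k_off/k_on)`, active-G fraction
#' `Ga = a / (a + g_deact_rate)` with `a = g_act_rate * efficacy * RL`, and
#' evoked current magnitude `i_max * gate(Ga)`. Used as the analytic oracle
#' for steady-state amplitudes.
#'
#' @param concentration Agonist concentration(s), M.
#' @param ligand A [ligand_kinetics()] row.
#' @param params A [cascade_params()] object.
#' @return Tibble with `concentration`, `occupancy`, `g_active`, and
#'   `evoked` (uA, magnitude of the agonist-evoked inward current).
#' @export
steady_state_response <- function(concentration, ligand, params) {
  rl <- concentration / (concentration + ligand$k_off / ligand$k_on)
  a <- params$g_act_rate * ligand$efficacy * rl
  ga <- a / (a + params$g_deact_rate)
  tibble(
    concentration = concentration, occupancy = rl, g_active = ga,
    evoked = params$i_max * girk_gate(ga, params)
  )
}

# Integrate the cascade ODEs over one constant-command segment.
# y = (RL, RA, Ga); agonist/antagonist bath concentrations follow exact
# first-order exchange within the segment.
integrate_segment <- function(y0, t_local, seg, lig, ant, params) {
  tau <- params$exchange_tau
  deriv <- function(t, y, p) {
    ca <- seg$a_target + (seg$a_start - seg$a_target) * exp(-t / tau)
    free <- 1 - y[1] - y[2]
    d1 <- lig$k_on * ca * free - lig$k_off * y[1]
    d2 <- if (is.null(ant)) 0 else {
      cb <- seg$b_target + (seg$b_start - seg$b_target) * exp(-t / tau)
      ant$k_on * cb * free - ant$k_off * y[2]
    }
    d3 <- params$g_act_rate * lig$efficacy * y[1] * (1 - y[3]) -
      params$g_deact_rate * y[3]
    list(c(d1, d2, d3))
  }
  times <- unique(c(0, t_local, seg$len))
  sol <- deSolve::ode(y0, times, deriv, NULL, method = "lsoda",
                      rtol = params$rtol, atol = params$rtol * 1e-4)
  if (any(!is.finite(sol))) {
    abort(paste0(
      "non-finite state during cascade integration; check the parameter ",
      "regime (k_on = ", format(lig$k_on), ", g_act_rate = ",
      format(params$g_act_rate), ")"
    ))
  }
  sol
}

#' Simulate the noise-free state of the signaling cascade
#'
#' Integrates the three-state cascade model -- receptor occupancy by agonist
#' (and optionally by a competitive antagonist), active G-protein fraction,
#' and the implied GIRK current -- over a perfusion protocol:
#' \deqn{dRL/dt = k_{on} c_{eff}(t) (1 - RL - RA) - k_{off} RL}
#' \deqn{dGa/dt = g_{act} \epsilon RL (1 - Ga) - g_{deact} Ga}
#' with the effective bath concentration following first-order solution
#' exchange. The current magnitude is
#' `i_basal + i_max * rundown(t) * gate(Ga)`, stored inward-negative.
#' Integration is piecewise over the protocol's command segments with a
#' stiff-capable adaptive integrator, evaluated on the uniform sampling grid.
#'
#' @param ligand A [ligand_kinetics()] row (the agonist).
#' @param params A [cascade_params()] object.
#' @param protocol A `perfusion_protocol`.
#' @param antagonist Optional [ligand_kinetics()] row for the protocol's
#'   antagonist channel (efficacy is ignored; an antagonist occupies without
#'   activating).
#' @return Tibble with `time` (s), `conc_eff` (M), `occupancy`,
#'   `antagonist_occupancy`, `g_active`, and noise-free `current` (uA,
#'   inward-negative).
#' @export
simulate_cascade <- function(ligand, params, protocol, antagonist = NULL) {
  validate_protocol(protocol)
  stopifnot(inherits(params, "cascade_params"))
  total <- attr(protocol, "total_duration") %||% max(protocol$t_end)
  dt <- 1 / params$sample_rate
  t_grid <- seq(0, total, by = dt)
  tau <- params$exchange_tau

  segs_a <- concentration_segments(protocol, total, "agonist")
  segs_b <- concentration_segments(protocol, total, "antagonist")
  bk <- sort(unique(round(c(segs_a$t0, segs_a$t1, segs_b$t0, segs_b$t1), 9)))
  ant <- antagonist
  has_ant <- !is.null(ant) && any(protocol$role == "antagonist")
  if (!has_ant) ant <- NULL

  target_at <- function(segs, t) {
    i <- findInterval(t, segs$t0, rightmost.closed = FALSE)
    segs$target[pmax(i, 1)]
  }

  y <- c(RL = 0, RA = 0, Ga = 0)
  a_start <- 0
  b_start <- 0
  rows <- vector("list", length(bk) - 1)
  for (i in seq_len(length(bk) - 1)) {
    t0 <- bk[i]; t1 <- bk[i + 1]
    tm <- (t0 + t1) / 2
    seg <- list(
      len = t1 - t0,
      a_start = a_start, a_target = target_at(segs_a, tm),
      b_start = b_start, b_target = target_at(segs_b, tm)
    )
    tl <- t_grid[t_grid >= t0 - 1e-9 & t_grid < t1 - 1e-9] - t0
    sol <- integrate_segment(y, tl, seg, ligand, ant, params)
    keep <- sol[match(round(tl, 9), round(sol[, "time"], 9)), , drop = FALSE]
    ca <- seg$a_target + (seg$a_start - seg$a_target) * exp(-keep[, "time"] / tau)
    rows[[i]] <- tibble(
      time = keep[, "time"] + t0, conc_eff = ca,
      occupancy = keep[, "RL"], antagonist_occupancy = keep[, "RA"],
      g_active = keep[, "Ga"]
    )
    y <- sol[nrow(sol), c("RL", "RA", "Ga")]
    a_start <- seg$a_target + (seg$a_start - seg$a_target) * exp(-seg$len / tau)
    b_start <- seg$b_target + (seg$b_start - seg$b_target) * exp(-seg$len / tau)
  }
  out <- dplyr::bind_rows(rows)
  # close the grid with the final state
  if (abs(max(t_grid) - max(out$time)) > 1e-9) {
    out <- dplyr::bind_rows(out, tibble(
      time = max(t_grid),
      conc_eff = a_start, occupancy = unname(y["RL"]),
      antagonist_occupancy = unname(y["RA"]), g_active = unname(y["Ga"])
    ))
  }
  evoked <- params$i_max * exp(-params$rundown_rate * out$time) *
    girk_gate(out$g_active, params)
  out$current <- -(params$i_basal + evoked)
  out
}

#' Simulate a voltage-clamp GIRK current trace
#'
#' Runs [simulate_cascade()] and adds seeded white Gaussian recording noise,
#' producing a synthetic two-electrode voltage-clamp trace sampled uniformly
#' (156 Hz by default). Identical inputs and seed give a bit-identical trace;
#' the global RNG state is left untouched.
#'
#' @inheritParams simulate_cascade
#' @param seed Integer seed for the recording noise.
#' @return A `girk_trace`: tibble with `time` (s) and `current` (uA,
#'   inward-negative), carrying the protocol, parameters, ligand and seed as
#'   attributes.
#' @examples
#' lig <- ligand_kinetics("dopamine", 9.7e7, 0.197)
#' pr <- make_protocol("washout", "dopamine", 1e-8, tail_s = 30)
#' tr <- simulate_trace(lig, cascade_params(), pr, seed = 1)
#' head(tr)
#' @export
simulate_trace <- function(ligand, params, protocol, seed,
                           antagonist = NULL) {
  states <- simulate_cascade(ligand, params, protocol, antagonist)
  noise <- if (params$noise_sd > 0) {
    withr::with_seed(seed, rnorm(nrow(states), sd = params$noise_sd))
  } else {
    numeric(nrow(states))
  }
  out <- tibble(time = states$time, current = states$current + noise)
  new_girk_trace(out, protocol = protocol, params = params, ligand = ligand,
                 seed = seed)
}

new_girk_trace <- function(df, protocol = NULL, params = NULL, ligand = NULL,
                           seed = NULL, baseline_subtracted = FALSE) {
  out <- as_tibble(df)
  attr(out, "protocol") <- protocol
  attr(out, "params") <- params
  attr(out, "ligand") <- ligand
  attr(out, "seed") <- seed
  attr(out, "baseline_subtracted") <- baseline_subtracted
  class(out) <- unique(c("girk_trace", class(out)))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.girk_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Current (µA)") +
    ggplot2::theme_minimal()
}
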