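#' Build a perfusion protocol
#'
#' Constructs the timed sequence of solution applications used in the four
#' experiment shapes of the assay: a concentration staircase for
#' concentration-response curves, a short application followed by washout for
#' dissociation (k_off) experiments, a single sustained application for
#' activation (k_obs) experiments, and an antagonist chase in which a
#' competitive blocker is co-applied in the continued presence of agonist.
#'
#' Timing conventions follow the assay design: the staircase applies each
#' concentration for 60 s back-to-back after a 60 s buffer stabilization
#' period; the washout protocol applies agonist for 13 s.
#'
#' @param kind One of `"staircase"`, `"washout"`, `"activation"`,
#'   `"antagonist_chase"`.
#' @param ligand_name Name of the applied agonist.
#' @param concentrations Applied concentration(s) in molar. Must be strictly
#'   increasing for `"staircase"`; a single value otherwise.
#' @param baseline_s Buffer-only period before the first application
#'   (seconds). Defaults to 60 for the staircase and 10 otherwise; also used
#'   as the baseline window for basal-current subtraction.
#' @param step_s Application duration per staircase step or for
#'   `"activation"`/`"antagonist_chase"` (seconds).
#' @param tail_s Buffer tail after the last application (seconds).
#' @param antagonist_name,antagonist_conc,antagonist_from For
#'   `"antagonist_chase"`: blocker identity, concentration (M) and the time
#'   after agonist onset at which it is co-applied (seconds).
#'
#' @return A `perfusion_protocol`: a tibble of steps with columns `t_start`,
#'   `t_end` (s), `ligand`, `concentration` (M) and `role`
#'   (`"agonist"`/`"antagonist"`), with attributes `total_duration` and
#'   `baseline_window`.
#' @examples
#' make_protocol("staircase", "dopamine", c(1e-9, 1e-8, 1e-7))
#' make_protocol("washout", "dopamine", 1e-8)
#' @export
make_protocol <- function(kind = c("staircase", "washout", "activation",
                                   "antagonist_chase"),
                          ligand_name, concentrations,
                          baseline_s = NULL, step_s = NULL, tail_s = NULL,
                          antagonist_name = "antagonist",
                          antagonist_conc = 1e-6, antagonist_from = 30) {
  kind <- match.arg(kind)
  if (length(concentrations) == 0) abort("`concentrations` must be non-empty")
  if (any(!is.finite(concentrations) | concentrations < 0)) {
    abort("`concentrations` must be finite and >= 0")
  }
  steps <- switch(kind,
    staircase = {
      if (is.unsorted(concentrations, strictly = TRUE)) {
        abort("staircase `concentrations` must be strictly increasing")
      }
      baseline_s <- baseline_s %||% 60
      step_s <- step_s %||% 60
      tail_s <- tail_s %||% 60
      n <- length(concentrations)
      tibble(
        t_start = baseline_s + (seq_len(n) - 1) * step_s,
        t_end = baseline_s + seq_len(n) * step_s,
        ligand = ligand_name, concentration = concentrations,
        role = "agonist"
      )
    },
    washout = {
      if (length(concentrations) != 1) {
        abort("washout protocol takes a single concentration")
      }
      baseline_s <- baseline_s %||% 10
      step_s <- step_s %||% 13
      tail_s <- tail_s %||% 120
      tibble(
        t_start = baseline_s, t_end = baseline_s + step_s,
        ligand = ligand_name, concentration = concentrations,
        role = "agonist"
      )
    },
    activation = {
      if (length(concentrations) != 1) {
        abort("activation protocol takes a single concentration")
      }
      baseline_s <- baseline_s %||% 10
      step_s <- step_s %||% 60
      tail_s <- tail_s %||% 0
      tibble(
        t_start = baseline_s, t_end = baseline_s + step_s,
        ligand = ligand_name, concentration = concentrations,
        role = "agonist"
      )
    },
    antagonist_chase = {
      if (length(concentrations) != 1) {
        abort("antagonist_chase protocol takes a single agonist concentration")
      }
      baseline_s <- baseline_s %||% 10
      step_s <- step_s %||% 90
      tail_s <- tail_s %||% 0
      if (antagonist_from >= step_s) {
        abort("`antagonist_from` must fall within the agonist application")
      }
      tibble(
        t_start = c(baseline_s, baseline_s + antagonist_from),
        t_end = baseline_s + step_s,
        ligand = c(ligand_name, antagonist_name),
        concentration = c(concentrations, antagonist_conc),
        role = c("agonist", "antagonist")
      )
    }
  )
  new_perfusion_protocol(
    steps,
    total_duration = max(steps$t_end) + tail_s,
    baseline_window = c(0, baseline_s)
  )
}

new_perfusion_protocol <- function(steps, total_duration, baseline_window) {
  out <- as_tibble(steps)
  attr(out, "total_duration") <- total_duration
  attr(out, "baseline_window") <- baseline_window
  class(out) <- c("perfusion_protocol", class(out))
  validate_protocol(out)
}

#' Validate a perfusion protocol
#'
#' Checks step ordering, non-overlap (within each of the agonist and
#' antagonist channels), non-negative concentrations and total duration.
#' Called by all protocol consumers; returns its input invisibly unchanged.
#'
#' @param protocol A `perfusion_protocol` (see [make_protocol()]).
#' @return `protocol`, invisibly.
#' @export
validate_protocol <- function(protocol) {
  req <- c("t_start", "t_end", "ligand", "concentration", "role")
  if (!all(req %in% names(protocol))) {
    abort("protocol must have columns t_start, t_end, ligand, concentration, role")
  }
  if (any(protocol$t_end <= protocol$t_start)) {
    abort("protocol steps must have t_end > t_start")
  }
  if (any(protocol$concentration < 0)) abort("concentrations must be >= 0")
  for (r in unique(protocol$role)) {
    st <- protocol[protocol$role == r, ]
    st <- st[order(st$t_start), ]
    if (nrow(st) > 1 &&
        any(st$t_start[-1] < st$t_end[-nrow(st)] - 1e-9)) {
      abort(paste0("overlapping ", r, " steps in protocol"))
    }
  }
  total <- attr(protocol, "total_duration") %||% max(protocol$t_end)
  if (total < max(protocol$t_end)) {
    abort("total_duration must cover the last protocol step")
  }
  invisible(protocol)
}

#' Nominal applied concentration on a time grid
#'
#' @param protocol A `perfusion_protocol`.
#' @param t_grid Times (s).
#' @param role `"agonist"` or `"antagonist"` channel.
#' @return Vector of applied (commanded) concentrations, M.
#' @keywords internal
applied_concentration <- function(protocol, t_grid, role = "agonist") {
  steps <- protocol[protocol$role == role, , drop = FALSE]
  out <- numeric(length(t_grid))
  for (i in seq_len(nrow(steps))) {
    sel <- t_grid >= steps$t_start[i] & t_grid < steps$t_end[i]
    out[sel] <- steps$concentration[i]
  }
  out
}

# Breakpoints at which the commanded concentration changes, for a role.
concentration_segments <- function(protocol, total_duration,
                                   role = "agonist") {
  steps <- protocol[protocol$role == role, , drop = FALSE]
  bk <- sort(unique(c(0, steps$t_start, steps$t_end, total_duration)))
  bk <- bk[bk <= total_duration + 1e-12]
  mids <- (head(bk, -1) + tail(bk, -1)) / 2
  tibble(
    t0 = head(bk, -1), t1 = tail(bk, -1),
    target = applied_concentration(protocol, mids, role)
  )
}

#' Effective concentration at the cell under finite solution exchange
#'
#' The bath concentration around a large oocyte follows a commanded perfusion
#' switch with first-order lag: `dc/dt = (c_applied(t) - c) / exchange_tau`.
#' This solves that relation exactly, as a piecewise-exponential approach to
#' each step's nominal concentration (the bath starts in agonist-free
#' buffer, `c(0) = 0` unless a step covers t = 0).
#'
#' @param protocol A `perfusion_protocol` from [make_protocol()].
#' @param exchange_tau Solution-exchange time constant (s), > 0.
#' @param t_grid Times at which to evaluate (s).
#' @param role Which protocol channel to evaluate (`"agonist"` or
#'   `"antagonist"`).
#' @return Tibble with columns `time` (s) and `concentration` (M).
#' @examples
#' p <- make_protocol("washout", "dopamine", 1e-8, baseline_s = 0)
#' effective_concentration(p, exchange_tau = 0.4, t_grid = c(0, 0.4, 13))
#' @export
effective_concentration <- function(protocol, exchange_tau, t_grid,
                                    role = "agonist") {
  validate_protocol(protocol)
  if (!is.finite(exchange_tau) || exchange_tau <= 0) {
    abort("`exchange_tau` must be > 0")
  }
  segs <- concentration_segments(
    protocol, max(attr(protocol, "total_duration") %||% max(t_grid),
                  max(t_grid)),
    role
  )
  out <- numeric(length(t_grid))
  c0 <- 0
  for (i in seq_len(nrow(segs))) {
    sel <- t_grid >= segs$t0[i] - 1e-12 & t_grid <= segs$t1[i] + 1e-12
    if (any(sel)) {
      out[sel] <- segs$target[i] +
        (c0 - segs$target[i]) * exp(-(t_grid[sel] - segs$t0[i]) / exchange_tau)
    }
    c0 <- segs$target[i] +
      (c0 - segs$target[i]) * exp(-(segs$t1[i] - segs$t0[i]) / exchange_tau)
  }
  tibble(time = t_grid, concentration = out)
}
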