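#' Define the binding kinetics of a ligand
#'
#' Bundles the microscopic rate constants and intrinsic efficacy of a ligand
#' at a receptor. These are the ground-truth parameters consumed by
#' [simulate_trace()]; the estimation side of the package tries to recover
#' them from simulated current traces.
#'
#' @param name Ligand name.
#' @param k_on Association rate constant (M^-1 s^-1), > 0.
#' @param k_off Dissociation rate constant (s^-1), > 0. The residence time of
#'   the ligand-receptor complex is `1/k_off`.
#' @param efficacy Intrinsic efficacy in `[0, 1]`: the ability of the occupied
#'   receptor to catalyse G-protein activation, relative to a full agonist.
#'   Use 0 for a neutral antagonist.
#'
#' @return A one-row tibble with columns `name`, `k_on`, `k_off`, `efficacy`
#'   and the implied equilibrium `true_kd = k_off / k_on` (molar).
#' @examples
#' ligand_kinetics("dopamine", k_on = 9.7e7, k_off = 0.197, efficacy = 1)
#' @export
ligand_kinetics <- function(name, k_on, k_off, efficacy = 1) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(k_on) || k_on <= 0) abort("`k_on` must be finite and > 0")
  if (!is.finite(k_off) || k_off <= 0) abort("`k_off` must be finite and > 0")
  if (!is.finite(efficacy) || efficacy < 0 || efficacy > 1) {
    abort("`efficacy` must lie in [0, 1]")
  }
  tibble(
    name = name, k_on = k_on, k_off = k_off, efficacy = efficacy,
    true_kd = k_off / k_on
  )
}

#' Reference agonist kinetics at wild-type and S193A D2 receptors
#'
#' Published point estimates of k_on, k_off (with SEMs) and relative efficacy
#' for four dopamine D2 receptor agonists -- dopamine, p-tyramine, and the two
#' enantiomers of 5-OH-DPAT -- at the wild-type receptor and the S193(5.42)A
#' mutant, measured with the GIRK-current assay this package models. They
#' serve two roles: as simulation ground truths for parameter-recovery
#' studies, and as inputs to the arithmetic reproduced by
#' [reference_checks()].
#'
#' `efficacy` is the relative maximal response normalized to dopamine
#' (clamped to 1 where the fitted value marginally exceeded it).
#'
#' @return A tibble with one row per ligand x receptor condition: `ligand`,
#'   `receptor` (`"WT"` or `"S193A"`), `k_on`, `k_on_sem` (M^-1 s^-1),
#'   `k_off`, `k_off_sem` (s^-1), `efficacy`, `efficacy_sem`, `pec50`,
#'   `pec50_sem`, `pkd`, `pkd_sem` (reported values), and the per-ligand
#'   washout-experiment design: `washout_conc` (M) and `washout_window` (s).
#' @examples
#' d2_reference_kinetics()
#' @export
d2_reference_kinetics <- function() {
  tibble::tribble(
    ~ligand,         ~receptor, ~k_on,  ~k_on_sem, ~k_off, ~k_off_sem,
      ~efficacy, ~efficacy_sem, ~pec50, ~pec50_sem, ~pkd, ~pkd_sem,
      ~washout_conc, ~washout_window,
    "dopamine",      "WT",    9.70e7, 1.23e7, 0.197, 0.012,
      1.00, 0.02, 7.70, 0.07, 8.69, 0.14, 1e-8, 42,
    "p-tyramine",    "WT",    4.94e3, 1.15e3, 0.123, 0.008,
      0.09, 0.01, 4.00, 0.21, 4.61, 0.24, 1e-5, 42,
    "(S)-5-OH-DPAT", "WT",    2.86e7, 0.31e7, 0.028, 0.010,
      0.52, 0.01, 8.28, 0.08, 9.01, 0.35, 1e-8, 104,
    "(R)-5-OH-DPAT", "WT",    8.65e5, 1.21e5, 0.030, 0.008,
      0.11, 0.01, 6.85, 0.16, 7.46, 0.30, 3e-7, 104,
    "dopamine",      "S193A", 3.69e4, 0.48e4, 0.207, 0.012,
      1.00, 0.04, 5.03, 0.04, 5.25, 0.14, 1e-5, 24,
    "p-tyramine",    "S193A", 9.41e3, 2.34e3, 0.112, 0.008,
      0.37, 0.01, 4.32, 0.12, 4.93, 0.26, 1e-3, 24,
    "(S)-5-OH-DPAT", "S193A", 2.82e6, 0.34e6, 0.096, 0.009,
      0.64, 0.01, 6.56, 0.05, 7.47, 0.15, 1e-6, 24,
    "(R)-5-OH-DPAT", "S193A", 1.95e6, 0.15e6, 0.069, 0.008,
      0.63, 0.02, 7.07, 0.08, 7.45, 0.14, 3e-7, 24
  )
}

#' Reported relative efficacy (Top) values used for fold-change comparisons
#'
#' Unclamped fitted `Top` values (dopamine-normalized maximal responses) for
#' the reference dataset, including the mutant dopamine value of 1.04 that
#' [d2_reference_kinetics()] clamps for use as a simulator efficacy.
#'
#' @return A tibble with `ligand`, `receptor`, `top`, `top_sem`.
#' @keywords internal
#' @export
d2_reference_efficacy <- function() {
  tibble::tribble(
    ~ligand,         ~receptor, ~top, ~top_sem,
    "dopamine",      "WT",      1.00, 0.02,
    "p-tyramine",    "WT",      0.09, 0.01,
    "(S)-5-OH-DPAT", "WT",      0.52, 0.01,
    "(R)-5-OH-DPAT", "WT",      0.11, 0.01,
    "dopamine",      "S193A",   1.04, 0.04,
    "p-tyramine",    "S193A",   0.37, 0.01,
    "(S)-5-OH-DPAT", "S193A",   0.64, 0.01,
    "(R)-5-OH-DPAT", "S193A",   0.63, 0.02
  )
}
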