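#' Build the kinetics summary table
#'
#' Joins concentration-response potencies with the kinetic rate-constant
#' estimates into the standard report layout: one row per
#' ligand x receptor condition with pEC50, EC50 (nM), k_off +/- SEM,
#' k_on +/- SEM and kinetic pK_d +/- SEM.
#'
#' @param estimates Tibble of kinetic estimates with columns `ligand`,
#'   `receptor`, `k_off`, `k_off_sem`, `k_on`, `k_on_sem` (and optionally
#'   `pkd`, `pkd_sem`, recomputed if absent).
#' @param fits Tibble of concentration-response results with columns
#'   `ligand`, `receptor`, `pec50`, `pec50_sem` (and optionally `top`,
#'   `top_sem`).
#' @return A tibble keyed by (`ligand`, `receptor`) with numeric columns and
#'   pre-formatted display strings (`pec50_label`, `k_off_label`,
#'   `k_on_label`, `pkd_label`).
#' @export
build_summary_table <- function(estimates, fits) {
  estimates <- as_tibble(estimates)
  fits <- as_tibble(fits)
  if (nrow(estimates) == 0) {
    return(tibble(
      ligand = character(), receptor = character(),
      pec50 = numeric(), pec50_sem = numeric(), ec50_nM = numeric(),
      k_off = numeric(), k_off_sem = numeric(),
      k_on = numeric(), k_on_sem = numeric(),
      pkd = numeric(), pkd_sem = numeric(),
      pec50_label = character(), k_off_label = character(),
      k_on_label = character(), pkd_label = character()
    ))
  }
  keys_e <- paste(estimates$ligand, estimates$receptor)
  keys_f <- paste(fits$ligand, fits$receptor)
  if (!setequal(keys_e, keys_f)) {
    abort("`estimates` and `fits` must cover the same ligand/receptor keys")
  }
  out <- dplyr::inner_join(
    fits, estimates, by = c("ligand", "receptor")
  )
  if (!"pkd" %in% names(out)) {
    kk <- kinetic_kd(out$k_off, out$k_on)
    out$pkd <- kk$pkd
  }
  if (!"pkd_sem" %in% names(out)) {
    out$pkd_sem <- pkd_sem(out$k_off, out$k_off_sem, out$k_on, out$k_on_sem)
  }
  out$ec50_nM <- 1e9 * ec50_from_pec50(out$pec50)
  dplyr::mutate(
    out,
    pec50_label = sprintf("%.2f ± %.2f (%s)", .data$pec50,
                          .data$pec50_sem, format_ec50_nM(.data$ec50_nM)),
    k_off_label = sprintf("%.3f ± %.3f", .data$k_off, .data$k_off_sem),
    k_on_label = format_kon(.data$k_on, .data$k_on_sem),
    pkd_label = sprintf("%.2f ± %.2f", .data$pkd, .data$pkd_sem)
  )
}

format_ec50_nM <- function(x) {
  vapply(x, function(v) {
    prettyNum(format(signif(v, 3), scientific = FALSE, trim = TRUE),
              big.mark = ",")
  }, character(1))
}

# "9.70 ± 1.23 × 10^7"-style mantissa/exponent formatting.
format_kon <- function(k_on, k_on_sem) {
  expo <- floor(log10(k_on))
  sprintf("%.2f ± %.2f × 10^%d",
          k_on / 10^expo, k_on_sem / 10^expo, expo)
}

#' Arrow grid of mutation-induced shifts
#'
#' Applies [classify_shift()] across ligands to produce the comparative
#' arrow table (potency, relative efficacy, k_off, k_on) of mutant versus
#' wild-type values.
#'
#' @param wt,mut Tibbles with one row per ligand, columns `ligand`, `pec50`,
#'   `efficacy`, `k_off`, `k_on`, for the wild-type and mutant receptor.
#' @return Tibble with `ligand` and arrow-string columns `potency`,
#'   `efficacy`, `k_off`, `k_on`.
#' @export
shift_table <- function(wt, mut) {
  wt <- as_tibble(wt)
  mut <- as_tibble(mut)
  if (!setequal(wt$ligand, mut$ligand)) {
    abort("`wt` and `mut` must cover the same ligands")
  }
  mut <- mut[match(wt$ligand, mut$ligand), ]
  tibble(
    ligand = wt$ligand,
    potency = purrr::map2_chr(
      ec50_from_pec50(wt$pec50), ec50_from_pec50(mut$pec50),
      classify_shift, kind = "potency"
    ),
    efficacy = purrr::map2_chr(wt$efficacy, mut$efficacy,
                               classify_shift, kind = "efficacy"),
    k_off = purrr::map2_chr(wt$k_off, mut$k_off,
                            classify_shift, kind = "rate"),
    k_on = purrr::map2_chr(wt$k_on, mut$k_on,
                           classify_shift, kind = "rate")
  )
}
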