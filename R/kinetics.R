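#' Dissociation rate constant from the deactivation time constant
#'
#' The agonist residence time is read from the washout decay: k_off is
#' estimated as `1/tau_deact`.
#'
#' @param tau_deact Deactivation time constant (s), > 0.
#' @return k_off in s^-1.
#' @examples
#' koff_from_tau(5.076) # ~0.197 s^-1
#' @export
koff_from_tau <- function(tau_deact) {
  if (any(!is.finite(tau_deact) | tau_deact <= 0)) {
    abort("`tau_deact` must be finite and > 0")
  }
  1 / tau_deact
}

new_linear_range_fit <- function(slope, slope_sem, intercept, intercept_sem,
                                 included, excluded, r_squared, n_total) {
  structure(
    list(slope = slope, slope_sem = slope_sem, intercept = intercept,
         intercept_sem = intercept_sem,
         included_concentrations = included,
         excluded_concentrations = excluded,
         r_squared = r_squared, n_total = n_total),
    class = "linear_range_fit"
  )
}

#' Select the linear range of the k_obs-concentration relation and fit it
#'
#' At low agonist concentrations the observed activation rate is linear in
#' concentration (`k_obs = k_on [A] + k_off`); at higher concentrations it
#' saturates as the response outruns solution exchange and G-protein
#' turnover. This operationalizes "the range where the relation is linear":
#' concentrations are sorted, and the largest low-concentration prefix of at
#' least `min_points` points is retained for which (i) adding a quadratic
#' term is not significant (extra-sum-of-squares F-test at `alpha`) and (ii)
#' the top included point deviates from the straight line by less than
#' `max_top_deviation`. Ordinary least squares is then fit on that prefix.
#'
#' @param points Data frame with `concentration` (M) and `k_obs` (s^-1),
#'   both > 0, at least 3 distinct concentrations. Replicate k_obs values at
#'   the same concentration are allowed and pooled.
#' @param alpha Significance level of the curvature F-test.
#' @param max_top_deviation Maximum allowed relative deviation of the top
#'   included point from the fitted line.
#' @param min_points Minimum number of distinct concentrations retained.
#' @return A `linear_range_fit` with slope (the k_on estimate) and intercept
#'   (a k_off diagnostic, not the k_off estimate) each with SEM, the
#'   included/excluded concentrations and R^2.
#' @export
select_linear_range <- function(points, alpha = 0.05,
                                max_top_deviation = 0.15, min_points = 3) {
  points <- as_tibble(points)
  if (!all(c("concentration", "k_obs") %in% names(points))) {
    abort("`points` needs `concentration` and `k_obs` columns")
  }
  if (any(!is.finite(points$concentration) | points$concentration <= 0) ||
      any(!is.finite(points$k_obs) | points$k_obs <= 0)) {
    abort("`concentration` and `k_obs` must be finite and > 0")
  }
  conc_levels <- sort(unique(points$concentration))
  if (length(conc_levels) < min_points) {
    abort("need at least 3 distinct concentrations")
  }
  points <- dplyr::arrange(points, .data$concentration)
  for (k in rev(seq(min_points, length(conc_levels)))) {
    keep_conc <- conc_levels[seq_len(k)]
    sub <- points[points$concentration <= max(keep_conc), ]
    lin <- lm(k_obs ~ concentration, data = sub)
    ok_quad <- TRUE
    if (k > 3) {
      quad <- lm(k_obs ~ concentration + I(concentration^2), data = sub)
      p_quad <- tryCatch(anova(lin, quad)[2, "Pr(>F)"],
                         error = function(e) NA_real_)
      ok_quad <- is.na(p_quad) || p_quad >= alpha
    }
    top <- sub[sub$concentration == max(keep_conc), ]
    pred_top <- predict(lin, newdata = top)
    dev_top <- max(abs(top$k_obs - pred_top) / abs(pred_top))
    if (ok_quad && dev_top < max_top_deviation) {
      sm <- summary(lin)
      return(new_linear_range_fit(
        slope = unname(coef(lin)[2]),
        slope_sem = sm$coefficients["concentration", "Std. Error"],
        intercept = unname(coef(lin)[1]),
        intercept_sem = sm$coefficients["(Intercept)", "Std. Error"],
        included = keep_conc,
        excluded = setdiff(conc_levels, keep_conc),
        r_squared = sm$r.squared,
        n_total = length(conc_levels)
      ))
    }
  }
  abort(paste(
    "no admissible linear range found;",
    "acquire k_obs at lower agonist concentrations"
  ))
}

#' @export
print.linear_range_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_range_fit> k_on (slope) = %.4g ± %.2g M^-1 s^-1, intercept = %.4g s^-1\n",
    x$slope, x$slope_sem, x$intercept
  ))
  cat(sprintf("  %d/%d concentrations in linear range, R^2 = %.4f\n",
              length(x$included_concentrations), x$n_total, x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.linear_range_fit <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std.error = c(x$slope_sem, x$intercept_sem)
  )
}

#' @exportS3Method generics::glance
glance.linear_range_fit <- function(x, ...) {
  tibble(
    k_on = x$slope, k_on_sem = x$slope_sem,
    intercept = x$intercept, intercept_sem = x$intercept_sem,
    r_squared = x$r_squared,
    n_included = length(x$included_concentrations),
    n_excluded = length(x$excluded_concentrations)
  )
}

#' Estimate k_on from the concentration dependence of k_obs
#'
#' Fits `k_obs = k_on [A] + k_off` over the automatically selected linear
#' range (see [select_linear_range()]); the slope is the k_on estimate. The
#' intercept is retained as a diagnostic to compare against the
#' washout-derived k_off, but is not itself used as the k_off estimate --
#' k_off is always taken from the deactivation time constant.
#'
#' @inheritParams select_linear_range
#' @return A `linear_range_fit`.
#' @examples
#' pts <- tibble::tibble(
#'   concentration = c(1, 3, 10) * 1e-9,
#'   k_obs = 9.7e7 * c(1, 3, 10) * 1e-9 + 0.197
#' )
#' estimate_kon(pts)
#' @export
estimate_kon <- function(points, alpha = 0.05, max_top_deviation = 0.15) {
  pts <- as_tibble(points)
  if (anyDuplicated(pts$concentration) &&
      length(unique(pts$concentration)) < 3) {
    abort("need at least 3 distinct concentrations")
  }
  select_linear_range(pts, alpha = alpha,
                      max_top_deviation = max_top_deviation)
}

#' @exportS3Method ggplot2::autoplot
autoplot.linear_range_fit <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(points)) {
    pts <- as_tibble(points)
    pts$included <- pts$concentration %in% object$included_concentrations
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$concentration, y = .data$k_obs,
                   shape = .data$included)
    )
  }
  xmax <- max(object$included_concentrations)
  line <- tibble(concentration = seq(0, xmax * 1.1, length.out = 50))
  line$k_obs <- object$intercept + object$slope * line$concentration
  p +
    ggplot2::geom_line(data = line,
                       ggplot2::aes(x = .data$concentration, y = .data$k_obs)) +
    ggplot2::labs(x = "[Agonist] (M)", y = expression(k[obs] ~ (s^-1))) +
    ggplot2::theme_minimal()
}

#' Kinetic dissociation constant from the rate constants
#'
#' `K_d = k_off / k_on`, with `pK_d = -log10(K_d)`.
#'
#' @param k_off Dissociation rate constant (s^-1), > 0.
#' @param k_on Association rate constant (M^-1 s^-1), > 0.
#' @return Tibble with `kd` (M) and `pkd`.
#' @examples
#' kinetic_kd(0.197, 9.70e7) # pKd 8.69
#' @export
kinetic_kd <- function(k_off, k_on) {
  if (any(!is.finite(k_off) | k_off <= 0) ||
      any(!is.finite(k_on) | k_on <= 0)) {
    abort("`k_off` and `k_on` must be finite and > 0")
  }
  kd <- k_off / k_on
  tibble(kd = kd, pkd = -log10(kd))
}

#' Standard error of the kinetic pK_d
#'
#' Propagates the SEMs of k_off and k_on into the pK_d as the relative
#' standard error of K_d:
#' `sqrt((k_off_sem/k_off)^2 + (k_on_sem/k_on)^2)`, used directly as the
#' pK_d SEM (without the ln(10) divisor of the delta method -- the
#' convention under which the reference dataset's printed SEMs reproduce).
#'
#' @param k_off,k_on Rate constants, > 0.
#' @param k_off_sem,k_on_sem Their SEMs, >= 0.
#' @return The pK_d SEM (dimensionless).
#' @examples
#' pkd_sem(0.197, 0.012, 9.70e7, 1.23e7) # 0.14
#' @export
pkd_sem <- function(k_off, k_off_sem, k_on, k_on_sem) {
  if (any(k_off <= 0) || any(k_on <= 0)) {
    abort("`k_off` and `k_on` must be > 0")
  }
  if (any(k_off_sem < 0) || any(k_on_sem < 0)) abort("SEMs must be >= 0")
  sqrt((k_off_sem / k_off)^2 + (k_on_sem / k_on)^2)
}

#' Classify a mutation-induced shift as an ordinal arrow category
#'
#' Summarizes the fold change between wild-type and mutant values as the
#' arrow notation used in comparative kinetics tables: no change ("-"), weak
#' (single arrow), strong (double), or very strong (triple), with cut points
#' on the log10 fold change at 0.15, 0.7 and 2 decades.
#'
#' For `kind = "potency"` supply EC50 values (M); the ratio is inverted so
#' that an up-arrow means increased potency. For `"efficacy"` and `"rate"`
#' the fold change is `mut_value / wt_value` directly.
#'
#' @param wt_value,mut_value Positive values at wild-type and mutant.
#' @param kind One of `"potency"`, `"efficacy"`, `"rate"`.
#' @param thresholds Cut points (log10 decades) separating no-change, weak,
#'   strong and very strong shifts.
#' @return A single string: one of `"-"`, `"↑"`, `"↑↑"`, `"↑↑↑"`,
#'   `"↓"`, `"↓↓"`, `"↓↓↓"`.
#' @examples
#' classify_shift(2e-8, 9.33e-6, "potency") # dopamine EC50 WT vs mutant
#' @export
classify_shift <- function(wt_value, mut_value,
                           kind = c("potency", "efficacy", "rate"),
                           thresholds = c(0.15, 0.7, 2)) {
  kind <- match.arg(kind)
  if (wt_value <= 0 || mut_value <= 0) abort("values must be > 0")
  fold <- if (kind == "potency") wt_value / mut_value else mut_value / wt_value
  l <- log10(fold)
  if (abs(l) < thresholds[1]) return("-")
  arrow <- if (l > 0) "↑" else "↓"
  n <- if (abs(l) < thresholds[2]) 1 else if (abs(l) <= thresholds[3]) 2 else 3
  paste(rep(arrow, n), collapse = "")
}
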