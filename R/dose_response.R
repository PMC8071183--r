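#' Normalize response amplitudes to a reference response
#'
#' Expresses evoked amplitudes relative to the response to a maximally
#' effective concentration of the reference full agonist (1 uM dopamine at
#' the wild-type receptor; 300 uM dopamine at the S193A mutant), the
#' convention that makes fitted `Top` values directly comparable as relative
#' efficacies.
#'
#' @param amplitudes Evoked amplitudes (uA).
#' @param reference_amplitude Amplitude of the reference response (uA), > 0.
#' @return Dimensionless normalized responses.
#' @examples
#' normalize_to_reference(c(0.5, 1.0), 1.0)
#' @export
normalize_to_reference <- function(amplitudes, reference_amplitude) {
  if (!is.finite(reference_amplitude) || reference_amplitude <= 0) {
    abort("`reference_amplitude` must be finite and > 0")
  }
  amplitudes / reference_amplitude
}

new_sigmoid_fit <- function(pec50, pec50_sem, top, top_sem, n_points,
                            converged, reasons = character()) {
  structure(
    list(pec50 = pec50, pec50_sem = pec50_sem, top = top, top_sem = top_sem,
         n_points = n_points, converged = converged, reasons = reasons),
    class = "sigmoid_fit"
  )
}

#' Fit a sigmoidal concentration-response curve
#'
#' Fits the two-parameter log-logistic model
#' \deqn{Y = Top / (1 + 10^{(LogEC50 - X)})}
#' by Levenberg-Marquardt nonlinear least squares, where `X` is
#' log10(agonist concentration, M) and `Y` the reference-normalized response.
#' Bottom is fixed at 0 and the Hill slope at 1, as implied by the model; the
#' reported potency is `pEC50 = -LogEC50`. Standard errors come from the fit
#' covariance.
#'
#' @param points A data frame with either `log10_concentration` or
#'   `concentration` (M), and `normalized_response`.
#' @return A `sigmoid_fit` with `pec50`, `top`, their SEMs, `n_points` and a
#'   convergence flag. Flagged non-identifiable when all responses are equal.
#' @examples
#' pts <- tibble::tibble(
#'   concentration = c(1, 3, 10, 30, 100) * 1e-9,
#'   normalized_response = 1 / (1 + 10^(log10(2e-8) - log10(c(1, 3, 10, 30, 100) * 1e-9)))
#' )
#' fit_concentration_response(pts)
#' @export
fit_concentration_response <- function(points) {
  points <- as_tibble(points)
  if (!"log10_concentration" %in% names(points)) {
    if (!"concentration" %in% names(points)) {
      abort("`points` needs `log10_concentration` or `concentration`")
    }
    points$log10_concentration <- log10(points$concentration)
  }
  if (!"normalized_response" %in% names(points)) {
    abort("`points` needs a `normalized_response` column")
  }
  x <- points$log10_concentration
  y <- points$normalized_response
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("non-finite concentration-response points")
  }
  if (length(unique(round(x, 10))) < 3) {
    abort("need at least 3 distinct concentrations")
  }
  if (diff(range(y)) < 1e-12) {
    return(new_sigmoid_fit(NA_real_, NA_real_, mean(y), NA_real_,
                           length(y), FALSE,
                           "non-identifiable: all responses equal"))
  }
  top0 <- max(y)
  lec0 <- x[which.min(abs(y - top0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Top / (1 + 10^(LogEC50 - x)),
      start = list(Top = top0, LogEC50 = lec0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_sigmoid_fit(NA_real_, NA_real_, NA_real_, NA_real_, length(y),
                           FALSE, paste("fit failed:", conditionMessage(fit))))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))),
                 error = function(e) c(Top = NA_real_, LogEC50 = NA_real_))
  new_sigmoid_fit(
    pec50 = -unname(cf[["LogEC50"]]), pec50_sem = unname(se[["LogEC50"]]),
    top = unname(cf[["Top"]]), top_sem = unname(se[["Top"]]),
    n_points = length(y), converged = TRUE
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> pEC50 = %.3f ± %.3f (EC50 = %.3g nM), Top = %.3f ± %.3f, n = %d\n",
    x$pec50, x$pec50_sem, 1e9 * ec50_from_pec50(x$pec50), x$top, x$top_sem,
    x$n_points
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sigmoid_fit <- function(x, ...) {
  tibble(
    term = c("pec50", "top"),
    estimate = c(x$pec50, x$top),
    std.error = c(x$pec50_sem, x$top_sem)
  )
}

#' @exportS3Method generics::glance
glance.sigmoid_fit <- function(x, ...) {
  tibble(
    pec50 = x$pec50, pec50_sem = x$pec50_sem,
    ec50_nM = 1e9 * ec50_from_pec50(x$pec50),
    top = x$top, top_sem = x$top_sem,
    n_points = x$n_points, converged = x$converged
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.sigmoid_fit <- function(object, points = NULL, ...) {
  rng <- if (!is.null(points)) {
    range(points$log10_concentration %||% log10(points$concentration))
  } else {
    -object$pec50 + c(-2.5, 2.5)
  }
  grid <- tibble(
    x = seq(rng[1] - 0.5, rng[2] + 0.5, length.out = 200)
  )
  grid$y <- object$top / (1 + 10^(-object$pec50 - grid$x))
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10[agonist] (M)", y = "Normalized response") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    pts <- as_tibble(points)
    if (!"log10_concentration" %in% names(pts)) {
      pts$log10_concentration <- log10(pts$concentration)
    }
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$log10_concentration, y = .data$normalized_response)
    )
  }
  p
}

#' Convert pEC50 to EC50
#'
#' @param pec50 Negative log10 of the EC50 (M).
#' @return EC50 in molar.
#' @examples
#' ec50_from_pec50(7.70) # 2e-8 M = 20 nM
#' @export
ec50_from_pec50 <- function(pec50) {
  10^(-pec50)
}

#' Potency fold change between two conditions
#'
#' The EC50 ratio expressed from pEC50s: `10^(pec50_a - pec50_b)`, i.e. how
#' many fold more potent condition `a` is than condition `b`.
#'
#' @param pec50_a,pec50_b pEC50 values.
#' @return Dimensionless fold change.
#' @examples
#' potency_fold_change(7.70, 5.03) # ~468-fold potency loss at the mutant
#' @export
potency_fold_change <- function(pec50_a, pec50_b) {
  stopifnot(is.finite(pec50_a), is.finite(pec50_b))
  10^(pec50_a - pec50_b)
}

#' Relative-efficacy fold change
#'
#' Ratio of fitted maximal responses (`Top`) between two conditions.
#'
#' @param top_a,top_b Fitted Top values; `top_b` > 0.
#' @return `top_a / top_b`.
#' @examples
#' efficacy_fold_change(0.63, 0.11) # (R)-5-OH-DPAT efficacy gain at the mutant
#' @export
efficacy_fold_change <- function(top_a, top_b) {
  if (!is.finite(top_b) || top_b <= 0) abort("`top_b` must be > 0")
  top_a / top_b
}
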