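#' All permutations of 1..n
#'
#' Lexicographic enumeration, used for the exact permutation null of the
#' Spearman correlation at small n.
#'
#' @param n Integer, 1..9.
#' @return An `n! x n` integer matrix, one permutation per row.
#' @keywords internal
permutation_matrix <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutation_matrix(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (lead in seq_len(n)) {
    rest <- setdiff(seq_len(n), lead)
    block <- matrix(rest[sub], nrow = nrow(sub))
    out[row:(row + nrow(sub) - 1L), ] <- cbind(lead, block)
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Computes Spearman's rho from the rank-difference formula
#' `rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))` and, for tie-free samples of
#' n <= `exact_max`, the exact two-sided p-value by full enumeration of all
#' n! rank permutations: `p = #\{|rho*| >= |rho|\} / n!`. For larger n, or
#' when ties are present (with a warning), the t-approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` is used instead.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return A list of class `correlation_result` with `rho`, `p_two_sided`,
#'   `n` and `method` (`"exact_permutation"` or `"t_approximation"`).
#' @examples
#' ref <- d2_reference_kinetics()
#' spearman_exact(ref$pec50, ref$pkd)
#' @export
spearman_exact <- function(x, y, exact_max = 9) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 4) abort("need n >= 4")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite input")
  rx <- rank(x)
  ry <- rank(y)
  rho <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (!ties && n <= exact_max) {
    perms <- permutation_matrix(n)
    d2 <- rowSums((perms - matrix(ry, nrow(perms), n, byrow = TRUE))^2)
    rho_star <- 1 - 6 * d2 / (n * (n^2 - 1))
    p <- sum(abs(rho_star) >= abs(rho) - 1e-12) / factorial(n)
    method <- "exact_permutation"
  } else {
    if (ties && n <= exact_max) {
      warn("ties present; falling back to the t-approximation")
    }
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t_approximation"
  }
  structure(
    list(rho = rho, p_two_sided = p, n = n, method = method),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Spearman rho = %.4f, p = %.4f (n = %d, %s)\n",
              x$rho, x$p_two_sided, x$n, x$method))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.correlation_result <- function(x, ...) {
  tibble(rho = x$rho, p_two_sided = x$p_two_sided, n = x$n,
         method = x$method)
}

#' Two-way between-subjects ANOVA from cell summary statistics
#'
#' Reconstructs a two-factor ANOVA when only per-cell means, SEMs and sample
#' sizes are available (as in published bar charts). Cell SDs are recovered
#' as `sem * sqrt(n)`; for unbalanced designs the unweighted-means solution
#' is used: factor and interaction sums of squares are computed from the
#' unweighted marginal means scaled by the harmonic mean cell size, and the
#' error sum of squares pools the within-cell variances with
#' `df = sum(n - 1)`.
#'
#' @param cells Data frame with columns `factor_a`, `factor_b`, `mean`,
#'   `sem`, `n` -- one row per cell of a complete a x b grid.
#' @return Tibble with one row per term (`factor_a`, `factor_b`,
#'   `interaction`) giving `df`, `df_error`, `ss`, `ms`, `f` and `p`.
#' @export
anova_two_way_summary <- function(cells) {
  cells <- as_tibble(cells)
  req <- c("factor_a", "factor_b", "mean", "sem", "n")
  if (!all(req %in% names(cells))) {
    abort("`cells` needs columns factor_a, factor_b, mean, sem, n")
  }
  if (any(cells$n < 1) || any(cells$sem < 0)) {
    abort("cell `n` must be >= 1 and `sem` >= 0")
  }
  cells$factor_a <- as.character(cells$factor_a)
  cells$factor_b <- as.character(cells$factor_b)
  a_lev <- unique(cells$factor_a)
  b_lev <- unique(cells$factor_b)
  grid <- tidyr::expand_grid(factor_a = a_lev, factor_b = b_lev)
  if (nrow(dplyr::anti_join(grid, cells,
                            by = c("factor_a", "factor_b"))) > 0 ||
      nrow(cells) != nrow(grid)) {
    abort("`cells` must form a complete factor_a x factor_b grid")
  }
  m <- matrix(NA_real_, length(a_lev), length(b_lev),
              dimnames = list(a_lev, b_lev))
  nn <- m
  sdm <- m
  for (i in seq_len(nrow(cells))) {
    m[cells$factor_a[i], cells$factor_b[i]] <- cells$mean[i]
    nn[cells$factor_a[i], cells$factor_b[i]] <- cells$n[i]
    sdm[cells$factor_a[i], cells$factor_b[i]] <- cells$sem[i] * sqrt(cells$n[i])
  }
  a <- nrow(m)
  b <- ncol(m)
  n_h <- 1 / mean(1 / nn)  # harmonic mean cell size
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_a <- n_h * b * sum((row_m - grand)^2)
  ss_b <- n_h * a * sum((col_m - grand)^2)
  inter <- sweep(sweep(m, 1, row_m), 2, col_m) + grand
  ss_ab <- n_h * sum(inter^2)
  ss_e <- sum((nn - 1) * sdm^2)
  df_e <- sum(nn - 1)
  ms_e <- ss_e / df_e
  terms <- tibble(
    term = c("factor_a", "factor_b", "interaction"),
    df = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df_error = df_e,
    ss = c(ss_a, ss_b, ss_ab)
  )
  terms$ms <- terms$ss / terms$df
  terms$f <- terms$ms / ms_e
  terms$p <- pf(terms$f, terms$df, df_e, lower.tail = FALSE)
  terms
}

#' Sidak correction for multiple comparisons
#'
#' Adjusts each p-value for `m` comparisons as
#' `p_adj = 1 - (1 - p)^m`, clipped to 1. The adjustment is monotone and is
#' bounded above by the Bonferroni correction `m * p`.
#'
#' @param p_values Probabilities in `[0, 1]`.
#' @param m Number of comparisons; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @examples
#' sidak_adjust(c(0.01, 0.04), m = 4)
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("`p_values` must lie in [0, 1]")
  }
  pmin(1, 1 - (1 - p_values)^m)
}
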