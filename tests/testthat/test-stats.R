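test_that("Spearman rho matches the rank-Pearson cross-check", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(7)
    y <- rnorm(7)
    res <- spearman_exact(x, y)
    expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("exact permutation p agrees with the exact test oracle at small n", {
  set.seed(9)
  for (i in 1:5) {
    x <- sample(100, 6)
    y <- sample(100, 6)
    res <- spearman_exact(x, y)
    oracle <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)
    )
    expect_equal(res$rho, unname(oracle$estimate), tolerance = 1e-12)
    expect_equal(res$p_two_sided, oracle$p.value, tolerance = 1e-10)
    expect_equal(res$method, "exact_permutation")
  }
})

test_that("perfect monotone association gives p = 2/n! for distinct values", {
  x <- c(3, 1, 4, 7, 6)
  res <- spearman_exact(x, x)
  expect_equal(res$rho, 1)
  expect_equal(res$p_two_sided, 2 / factorial(5))
})

test_that("exact p is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- runif(7)
  y <- runif(7)
  base <- spearman_exact(x, y)
  tr1 <- spearman_exact(exp(3 * x), y)
  tr2 <- spearman_exact(x, -1 / (y + 2))
  expect_equal(tr1$rho, base$rho)
  expect_equal(tr1$p_two_sided, base$p_two_sided)
  # -1/(y+2) is increasing in y, so rho and p are unchanged
  expect_equal(tr2$rho, base$rho)
  expect_equal(tr2$p_two_sided, base$p_two_sided)
})

test_that("ties or large n fall back to the t-approximation", {
  expect_warning(res <- spearman_exact(c(1, 1, 2, 3, 4), c(5, 4, 3, 2, 1)),
                 "ties")
  expect_equal(res$method, "t_approximation")
  res2 <- spearman_exact(rnorm(25), rnorm(25))
  expect_equal(res2$method, "t_approximation")
})

test_that("summary-statistics ANOVA matches aov on reconstructed balanced data", {
  # raw-data reconstruction with exact cell means and SDs
  make_cell <- function(m, s, n) {
    z <- seq_len(n)
    z <- (z - mean(z)) / sd(z)
    m + s * z
  }
  set.seed(33)
  n <- 8
  grid <- tidyr::expand_grid(factor_a = c("a1", "a2", "a3"),
                             factor_b = c("b1", "b2"))
  grid$mean <- rnorm(nrow(grid), 10, 3)
  grid$sd <- runif(nrow(grid), 0.5, 2)
  raw <- purrr::pmap_dfr(grid, function(factor_a, factor_b, mean, sd) {
    tibble::tibble(factor_a = factor_a, factor_b = factor_b,
                   y = make_cell(mean, sd, n))
  })
  ref <- anova(aov(y ~ factor_a * factor_b, data = raw))
  cells <- dplyr::mutate(grid, sem = sd / sqrt(n), n = n)
  out <- anova_two_way_summary(cells)
  expect_equal(out$f, ref$`F value`[1:3], tolerance = 1e-8)
  expect_equal(out$df, ref$Df[1:3])
  expect_equal(out$df_error, rep(ref$Df[4], 3))
  expect_equal(out$p, ref$`Pr(>F)`[1:3], tolerance = 1e-8)
})

test_that("a 2-level one-factor reduction equals the pooled t-test squared", {
  m <- c(4.2, 5.1)
  s <- c(1.0, 1.3)
  n <- c(9, 9)
  cells <- tibble::tibble(
    factor_a = c("g1", "g2"), factor_b = "only",
    mean = m, sem = s / sqrt(n), n = n
  )
  # collapse to one factor by a singleton second factor
  out <- anova_two_way_summary(cells)
  sp2 <- sum((n - 1) * s^2) / sum(n - 1)
  t_stat <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  expect_equal(out$f[out$term == "factor_a"], t_stat^2, tolerance = 1e-10)
})

test_that("equal cell means give F = 0 and missing cells error", {
  cells <- tidyr::expand_grid(factor_a = c("x", "y"),
                              factor_b = c("u", "v"))
  cells$mean <- 3
  cells$sem <- 0.2
  cells$n <- 5
  out <- anova_two_way_summary(cells)
  expect_equal(out$f, rep(0, 3))
  expect_error(anova_two_way_summary(cells[-1, ]), "complete")
})

test_that("Sidak adjustment is correct, monotone and Bonferroni-bounded", {
  expect_equal(sidak_adjust(0.3, m = 1), 0.3)
  expect_equal(sidak_adjust(0.01, m = 4), 1 - 0.99^4)
  expect_equal(sidak_adjust(0, m = 10), 0)
  expect_equal(sidak_adjust(1, m = 3), 1)
  expect_error(sidak_adjust(1.2), "\\[0, 1\\]")

  set.seed(5)
  p <- sort(runif(20))
  adj <- sidak_adjust(p, m = 6)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj <= pmin(1, 6 * p) + 1e-12))
})
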