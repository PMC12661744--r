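test_that("closed-form normal KLD matches the quadrature oracle", {
  # frozen oracle values (quadrature of the defining integral)
  expect_equal(kld_normal(0, 1, 0, 1), 0)
  expect_equal(kld_normal(1.17, 1, 0, 2), 0.4387986, tolerance = 1e-6)
  expect_equal(kld_normal(0, 2, 1.17, 1), 0.8378764, tolerance = 1e-6)
  expect_equal(kld_normal(0.3, 0.16, -0.1, 0.25), 0.3631436, tolerance = 1e-6)

  grid <- expand.grid(mu_p = c(-1, 0, 0.5), sd_p = c(0.3, 1),
                      mu_q = c(0, 2), sd_q = c(0.5, 1.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(kld_normal(g$mu_p, g$sd_p^2, g$mu_q, g$sd_q^2),
                 kld_quadrature(g$mu_p, g$sd_p^2, g$mu_q, g$sd_q^2),
                 tolerance = 1e-8)
  }
  expect_error(kld_normal(0, 0, 0, 1), "positive")
  expect_error(kld_normal(0, 1, 0, -1), "positive")
})

test_that("interpretation index averages the directed divergences", {
  same <- interpretation_index(c(mean = 0.2, sd = 0.3),
                               c(mean = 0.2, sd = 0.3))
  expect_equal(same$index, 0)

  thr_case <- interpretation_index(c(mean = 1.17, sd = 1),
                                   c(mean = 0, sd = sqrt(2)))
  expect_equal(thr_case$index, (thr_case$d_di + thr_case$d_id) / 2)
  expect_equal(round(thr_case$index, 2), 0.64)

  ex <- interpretation_index(c(mean = 0.3, sd = 0.4),
                             c(mean = -0.1, sd = 0.5))
  expect_equal(ex$index, 0.4606250, tolerance = 1e-6)

  expect_error(interpretation_index(c(mean = 0, sd = 0), c(mean = 0, sd = 1)),
               "positive")
})

test_that("index is symmetric under role swap plus mean negation", {
  cases <- list(c(0.5, 0.3, -0.2, 0.6), c(1.2, 1, 0.1, 0.4),
                c(-0.3, 0.2, 0.3, 0.2))
  for (cs in cases) {
    a <- interpretation_index(c(mean = cs[1], sd = cs[2]),
                              c(mean = cs[3], sd = cs[4]))
    b <- interpretation_index(c(mean = -cs[3], sd = cs[4]),
                              c(mean = -cs[1], sd = cs[2]))
    expect_equal(a$index, b$index, tolerance = 1e-12)
    # the directed divergences swap roles under the transformation
    expect_equal(a$d_di, b$d_id, tolerance = 1e-12)
  }
})

test_that("the acceptably-low threshold is tau-free and rounds to 0.64", {
  thr <- low_inconsistency_threshold()
  expect_equal(round(thr, 2), 0.64)
  expect_equal(thr, 0.6383375, tolerance = 1e-6)
  expect_equal(round(half_normal_median_multiplier(rounded = FALSE), 2), 1.17)

  # exact multiplier variant still rounds to 0.64
  thr_exact <- low_inconsistency_threshold(
    multiplier = half_normal_median_multiplier(rounded = FALSE))
  expect_equal(round(thr_exact, 2), 0.64)

  # scale-free: the clinical-delta form at delta = 1.17 tau reproduces it
  for (tau in c(0.05, 0.3, 1.5)) {
    expect_equal(threshold_from_clinical_delta(1.17 * tau, tau), thr,
                 tolerance = 1e-12)
  }
})

test_that("clinically anchored thresholds behave like the zero-intercept parabola", {
  # delta = 0 intercept: 0.5 * (0.5*(0.5 - 1 + log 2) + 0.5*(2 - 1 - log 2))
  expect_equal(threshold_from_clinical_delta(0, 1), 0.125, tolerance = 1e-12)
  expect_equal(threshold_from_clinical_delta(0, 0.2), 0.125, tolerance = 1e-12)

  # strict monotonicity in |delta| at fixed tau
  deltas <- seq(0, 2, by = 0.1)
  vals <- threshold_from_clinical_delta(deltas, 0.5)
  expect_true(all(diff(vals) > 0))
  expect_equal(threshold_from_clinical_delta(-1.3, 0.5),
               threshold_from_clinical_delta(1.3, 0.5))
  expect_error(threshold_from_clinical_delta(1, 0), "positive")

  grid <- threshold_sensitivity_grid(c(0, 0.5, 1), c(0.1, 0.5))
  expect_equal(nrow(grid), 6L)
  expect_equal(grid$threshold,
               threshold_from_clinical_delta(grid$delta, grid$tau))
})

test_that("index vs mean difference is an exact quadratic with zero linear term", {
  s2_d <- 1; s2_i <- 2
  idx <- function(x) {
    vapply(x, function(d) {
      interpretation_index(c(mean = d, sd = sqrt(s2_d)),
                           c(mean = 0, sd = sqrt(s2_i)))$index
    }, numeric(1))
  }
  x <- c(-1.5, -0.5, 0, 0.5, 1.5)
  fit <- lm(idx(x) ~ x + I(x^2))
  b <- unname(coef(fit)[2])
  a <- unname(coef(fit)[3])
  expect_lt(abs(b), 1e-10)
  expect_equal(a, (1 / s2_d + 1 / s2_i) / 4, tolerance = 1e-10)

  # residuals vanish: the relation is exactly quadratic
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("heterogeneity bands follow the conventional cut-offs", {
  expect_equal(heterogeneity_band(c(0, 0.05, 0.1, 0.3, 0.49999, 0.5, 1, 1.2)),
               c("low", "low", "low", "reasonable", "reasonable",
                 "fairly_high", "fairly_high", "fairly_extreme"))
  expect_error(heterogeneity_band(-0.1), "non-negative")
})

test_that("node classification applies the two decision rules with material ties", {
  v1 <- classify_node(fake_result(0.5, -0.2, 0.3))
  expect_equal(v1$extent, "acceptably_low")
  expect_equal(v1$conclusiveness, "inconclusive")

  v2 <- classify_node(fake_result(0.8, 0.1, 0.9))
  expect_equal(v2$extent, "material")
  expect_equal(v2$conclusiveness, "conclusive")

  v3 <- classify_node(fake_result(0.9, -0.5, 1.4))
  expect_equal(v3$extent, "material")
  expect_equal(v3$conclusiveness, "inconclusive")

  # boundary index is material; negative-side exclusion is conclusive
  thr <- low_inconsistency_threshold()
  expect_equal(classify_node(fake_result(thr, -1, 1))$extent, "material")
  expect_equal(classify_node(fake_result(0.1, -0.9, -0.1))$conclusiveness,
               "conclusive")
})

test_that("network verdicts follow the at-least-one rule", {
  lows <- lapply(1:3, function(i) classify_node(fake_result(0.2, -0.3, 0.4)))
  nv <- classify_network(lows)
  expect_equal(nv$index_based, "consistent")
  expect_equal(nv$cri_based, "inconclusive")

  with_material <- c(lows, list(classify_node(fake_result(1.2, -0.5, 1))))
  expect_equal(classify_network(with_material)$index_based,
               "potentially_inconsistent")

  with_conclusive <- c(lows, list(classify_node(fake_result(0.3, 0.1, 0.6))))
  nv3 <- classify_network(with_conclusive)
  expect_equal(nv3$index_based, "potentially_inconsistent")
  expect_equal(nv3$cri_based, "conclusive")

  expect_error(classify_network(list()), "no split nodes")
})

test_that("draw-based KLD audit approaches the closed form for normal draws", {
  set.seed(42)
  p <- rnorm(4000, 0.5, 1)
  q <- rnorm(4000, 0, 1.2)
  est <- kld_from_draws(p, q)
  closed <- kld_normal(0.5, 1, 0, 1.2^2)
  expect_equal(est, closed, tolerance = 0.1)
  expect_error(kld_from_draws(p[1:5], q), "at least 10")
})
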