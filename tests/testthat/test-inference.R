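# Bootstrap bands, AUC-difference machinery, chart correlation, group
# median-percentile comparisons and rank-sum tests.

test_that("AUC difference matches hand trapezoid sums and is antisymmetric", {
  g <- c(0, 2, 5, 10)
  a <- c(1, 2, 0, 4); b <- c(0, 1, 1, 1)
  d <- a - b
  hand <- 2 * (d[1] + d[2]) / 2 + 3 * (d[2] + d[3]) / 2 + 5 * (d[3] + d[4]) / 2
  expect_equal(auc_difference(a, b, g), hand)
  expect_equal(auc_difference(b, a, g), -hand)
  expect_equal(auc_difference(a, a, g), 0)
  # constant offset 0.2 over a 10-year span -> 2.0
  g2 <- seq(20, 30, length.out = 7)
  expect_equal(auc_difference(rep(1.2, 7), rep(1.0, 7), g2), 2.0)
  expect_error(auc_difference(1, 1, 5), "at least 2")
})

test_that("zero-noise data give a zero-width band; seeds reproduce bands", {
  reg <- deterministic_registry()
  grid <- seq(10, 36, length.out = 9)
  bd <- bootstrap_band(reg, "fev1", "M", "age", tau = 0.5, grid = grid,
                       B = 30, seed = 7, n_basis = 6)
  expect_close(bd$upper - bd$lower, 0, 1e-7)
  expect_close(bd$estimate, 1 + 0.05 * grid, 1e-7)
  fx <- chart_fixture()
  b1 <- bootstrap_band(fx$registry, "fev1", "M", "age", tau = 0.5,
                       grid = grid, B = 25, seed = 42)
  b2 <- bootstrap_band(fx$registry, "fev1", "M", "age", tau = 0.5,
                       grid = grid, B = 25, seed = 42)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_true(all(b1$lower <= b1$estimate & b1$estimate <= b1$upper))
})

test_that("identical registries give a zero AUC statistic", {
  fx <- chart_fixture()
  tst <- auc_difference_test(fx$registry, fx$registry, "fev1", "M", "age",
                             tau = 0.5, B = 19, seed = 3, n_basis = 6)
  expect_equal(tst$statistic, 0)
  expect_s3_class(tst, "cf_test")
  expect_true(tst$p_value >= 0 && tst$p_value <= 1)
})

test_that("a shifted registry is detected by the AUC test", {
  cfgA <- sim_config(n_patients_per_sex = 1500, age_range = c(6, 40),
                     countries = unselected_countries(), seed = 61L)
  cfgB <- sim_config(n_patients_per_sex = 1500, age_range = c(6, 40),
                     countries = unselected_countries(), seed = 62L)
  rA <- filter_registry(simulate_registry(cfgA), "fev1")
  rB <- filter_registry(simulate_registry(cfgB), "fev1")
  rB$records$fev1_l <- rB$records$fev1_l + 0.3
  tst <- auc_difference_test(rA, rB, "fev1", "M", "age", tau = 0.5,
                             B = 99, seed = 9, n_basis = 6)
  expect_lt(tst$p_value, 0.05)
  expect_lt(tst$statistic, 0)          # A sits below the shifted B
})

test_that("chart correlation is 1 for identical or shifted charts", {
  fx <- chart_fixture()
  ch <- fixture("chart_M", function()
    fit_chart(fx$registry, "fev1", "M", c("age", "height"),
              taus = c(0.1, 0.25, 0.5, 0.75, 0.9)))
  expect_equal(chart_correlation(ch, ch), 1.0)
  ch2 <- ch
  i_age <- grep("^age_", rownames(ch$coef))
  ch2$coef[i_age, ] <- ch$coef[i_age, ] + 0.4   # +0.4 L everywhere
  expect_equal(chart_correlation(ch, ch2), 1.0, tolerance = 1e-12)
  chc <- ch
  chc$coef[] <- 0
  chc$coef[i_age, ] <- 1               # constant chart: undefined
  expect_error(chart_correlation(ch, chc), "undefined")
})

test_that("Bonferroni arithmetic and group median cells behave", {
  expect_equal(bonferroni_level(0.05, 12), 0.05 / 12)
  # degenerate cell: all ranks 70 -> median 70, zero-width CI, flagged
  rk <- data.frame(rank = rep(70, 40), group = "G", age_class = "adults")
  out <- group_median_percentile(rk, B = 50, alpha = 0.05,
                                 m_comparisons = 12, seed = 1)
  expect_equal(out$median_rank, 70)
  expect_equal(out$ci_lo, 70)
  expect_equal(out$ci_hi, 70)
  expect_true(out$excludes_50)
  expect_equal(attr(out, "level"), 1 - 0.05 / 12)
  # empty cells are skipped with a warning
  rk2 <- rbind(rk, data.frame(rank = numeric(0), group = character(0),
                              age_class = character(0)))
  rk2$age_class <- factor(rk2$age_class, levels = c("adults", "children"))
  expect_warning(group_median_percentile(rk2, B = 20, seed = 1), "empty cell")
})

test_that("uniform null ranks rarely exclude the 50th percentile", {
  set.seed(33)
  rk <- data.frame(rank = runif(12 * 300, 1, 99),
                   group = rep(c("FR", "DE", "HC", "LC"), each = 3 * 300),
                   age_class = rep(rep(c("children", "teenagers", "adults"),
                                       each = 300), times = 4))
  out <- group_median_percentile(rk, B = 199, alpha = 0.05, seed = 8)
  expect_identical(attr(out, "m"), 12L)
  expect_gte(mean(!out$excludes_50), 11 / 12)
})

test_that("bonferroni-adjusted intervals widen as m grows", {
  set.seed(12)
  rk <- data.frame(rank = runif(400, 1, 99), group = "G",
                   age_class = "adults")
  w <- sapply(c(1, 12), function(m) {
    out <- group_median_percentile(rk, B = 299, alpha = 0.05,
                                   m_comparisons = m, seed = 5)
    out$ci_hi - out$ci_lo
  })
  expect_gte(w[2], w[1])
})

test_that("rank-sum comparison matches exact enumeration", {
  # A = {1,2,3}, B = {7,8,9}: enumerate all 20 assignments of 6 ranks
  A <- c(1, 2, 3); B <- c(7, 8, 9)
  p <- rank_compare_groups(A, B)
  pool <- c(A, B)
  splits <- utils::combn(6, 3)
  stat <- apply(splits, 2, function(i) sum(rank(pool)[i]))
  obs <- sum(rank(pool)[1:3])
  p_exact <- mean(abs(stat - mean(range(stat))) >= abs(obs - mean(range(stat))))
  expect_equal(p, p_exact)
  # identical multisets -> p = 1 (tied data forces the normal approximation)
  expect_equal(suppressWarnings(rank_compare_groups(c(1, 2, 3), c(1, 2, 3))), 1)
  # shift both groups by a constant: invariant
  expect_equal(rank_compare_groups(A + 10, B + 10), p)
  expect_error(rank_compare_groups(numeric(0), B), "nonempty")
})
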