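# Chart fitting: filters, in-sample calibration, oracle recovery, rank
# lookup and its round trips, evaluation contract, S3 surface.

test_that("outcome filters implement the analysis windows", {
  reg <- cf_registry(toy_records())
  f <- filter_registry(reg, "fev1")
  # of 5 records: one transplanted, one aged 45 -> 3 survive
  expect_identical(nrow(f$records), 3L)
  # closed interval: ages exactly 6.0 and 40.0 retained
  expect_true(all(c(6, 40) %in% f$records$age_years))
  expect_true("no_transplant" %in% f$filters_applied)
  # BMI filter keeps the age-3 record the FEV1 filter would drop
  reg2 <- cf_registry(transform(toy_records(), age_years = c(3, 45, 6, 40, 20)))
  expect_identical(nrow(filter_registry(reg2, "bmi")$records), 3L)
  expect_identical(nrow(filter_registry(reg2, "fev1")$records), 2L)
})

test_that("training-sample calibration matches the fitted tau levels", {
  fx <- chart_fixture()
  ch <- fixture("chart_M", function()
    fit_chart(fx$registry, "fev1", "M", c("age", "height"),
              taus = c(0.1, 0.25, 0.5, 0.75, 0.9)))
  for (tau in ch$taus) {
    frac <- mean(ch$data$.y < predict(ch, ch$data, tau = tau))
    bound <- 2 * sqrt(tau * (1 - tau) / ch$n) + nrow(ch$coef) / ch$n
    expect_lt(abs(frac - tau), bound + 0.005)
  }
})

test_that("median curve recovers the generator oracle along the ridge", {
  fx <- chart_fixture()
  ch <- fit_chart(fx$registry, "fev1", "F", c("age", "height"), taus = 0.5)
  ages <- seq(6 + 0.1 * 34, 40 - 0.1 * 34, length.out = 30)
  hm <- cfcentile:::median_height(fx$config, "F", ages)
  est <- predict(ch, data.frame(age = ages, height = hm), tau = 0.5)
  tru <- true_quantile(fx$config, "fev1", "F", 0.5, ages, hm)
  expect_lt(max(abs(est - tru)), 0.03 * diff(range(ch$data$.y)))
})

test_that("duplicating every record leaves fitted curves unchanged", {
  fx <- chart_fixture()
  rec <- fx$registry$records[1:400, ]
  ch1 <- fit_chart(rec, "fev1", "M", "age", taus = c(0.25, 0.75))
  ch2 <- fit_chart(rbind(rec, rec), "fev1", "M", "age", taus = c(0.25, 0.75))
  nd <- data.frame(age = seq(min(ch1$ranges$age), max(ch1$ranges$age),
                             length.out = 20))
  expect_close(predict(ch1, nd), predict(ch2, nd), 1e-6)
})

test_that("evaluation respects the no-extrapolation contract", {
  fx <- chart_fixture()
  ch <- fixture("chart_M", function()
    fit_chart(fx$registry, "fev1", "M", c("age", "height"),
              taus = c(0.1, 0.25, 0.5, 0.75, 0.9)))
  bnd <- data.frame(age = ch$ranges$age[2], height = ch$ranges$height[1])
  expect_true(is.finite(predict(ch, bnd, tau = 0.5)))     # boundary defined
  out <- data.frame(age = ch$ranges$age[2] + 1, height = 160)
  expect_error(predict(ch, out, tau = 0.5), "outside the training range")
  expect_warning(v <- predict(ch, out, tau = 0.5, allow_extrapolation = TRUE),
                 "extrapolating")
  expect_true(is.finite(v))
  expect_error(predict(ch, data.frame(age = 20, height = 160), tau = 0.33),
               "not in the chart")
})

test_that("percentile ranks invert the evaluated curves on the tau grid", {
  fx <- chart_fixture()
  ch <- fixture("chart_M99", function()
    fit_chart(fx$registry, "fev1", "M", c("age", "height")))
  nd <- data.frame(age = c(10, 18, 30), height = c(138, 172, 174))
  V <- predict(ch, nd, rearrange = TRUE)
  for (tau in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    j <- which(abs(ch$taus - tau) < 1e-9)
    rk <- percentile_rank(ch, nd, V[, j])
    expect_close(rk, 100 * tau, 1)
  }
  # observed equal to the median curve -> rank 50
  med <- predict(ch, nd, tau = 0.5, rearrange = FALSE)
  expect_close(percentile_rank(ch, nd, med), 50, 1)
  # clamping below the 1st percentile curve, flagged
  rk_low <- percentile_rank(ch, nd[1, , drop = FALSE], 0.01)
  expect_equal(as.numeric(rk_low), 1)
  expect_true(attr(rk_low, "below_min"))
  rk_hi <- percentile_rank(ch, nd[1, , drop = FALSE], 99)
  expect_equal(as.numeric(rk_hi), 99)
  expect_true(attr(rk_hi, "above_max"))
})

test_that("self-ranks of the training sample are near-uniform", {
  fx <- chart_fixture()
  ch <- fixture("chart_M99", function()
    fit_chart(fx$registry, "fev1", "M", c("age", "height")))
  rk <- percentile_rank(ch, ch$data, ch$data$.y)
  # probability-integral-transform: ECDF close to uniform on [1, 99]
  u <- (rk - 1) / 98
  D <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(D, 0.045)
  expect_lt(abs(median(rk) - 50), 2)
  # monotone in the observed value
  nd <- data.frame(age = 20, height = 170)
  obs <- seq(0.5, 5, length.out = 30)
  rks <- vapply(obs, function(o) as.numeric(percentile_rank(ch, nd, o)),
                numeric(1))
  expect_true(all(diff(rks) >= 0))
})

test_that("chart errors are informative for unusable inputs", {
  fx <- chart_fixture()
  rec <- fx$registry$records
  expect_error(fit_chart(rec[1:8, ], "fev1", "M", "age"), "too few records")
  expect_error(fit_chart(rec, "fev1", "M", "age", taus = c(0.5, 0.5)),
               "strictly increasing")
  expect_error(fit_chart(rec[0, ], "fev1", "M", "age"), "no usable")
})

test_that("the S3 surface behaves like a fitted model object", {
  fx <- chart_fixture()
  ch <- fixture("chart_M", function()
    fit_chart(fx$registry, "fev1", "M", c("age", "height"),
              taus = c(0.1, 0.25, 0.5, 0.75, 0.9)))
  expect_output(print(ch), "percentile chart")
  sm <- summary(ch)
  expect_output(print(sm), "calibration")
  expect_lt(abs(sm$median_self_rank - 50), 3)
  expect_identical(dim(coef(ch)), c(nrow(ch$coef), length(ch$taus)))
  expect_identical(length(residuals(ch)), ch$n)
  expect_lt(abs(median(residuals(ch))), 0.05)
  expect_identical(length(fitted(ch)), ch$n)
  pdf(NULL)
  expect_silent(plot(ch, taus = c(0.25, 0.5, 0.75)))
  dev.off()
  chs <- fit_chart(fx$registry, "fev1", "M", "age", taus = 0.5, model = FALSE)
  expect_error(summary(chs), "model = FALSE")
})
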