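# Best-annual-value correction: estimator on hand-built visit tables,
# application rules, and bias removal on simulated data.

visits_df <- function(id, year, sex, age, fev1) {
  data.frame(patient_id = id, year = year, sex = sex, age_years = age,
             visit = seq_along(fev1), fev1_l = fev1,
             stringsAsFactors = FALSE)
}

test_that("per-patient-year difference is max minus mean of visits", {
  v <- visits_df("A", 2005, "M", 12, c(2.0, 1.8, 1.6))
  tab <- suppressWarnings(estimate_correction(v, age_bands = c(6, 40)))
  expect_equal(tab$delta[tab$sex == "M"], 2.0 - 1.8)
  expect_identical(tab$n_patient_years[tab$sex == "M"], 1L)
})

test_that("equal visits give zero delta; band averages patient-years", {
  v <- rbind(visits_df("A", 2005, "M", 12, c(2, 2, 2)),
             visits_df("B", 2005, "M", 13, c(1.5, 1.5)))
  tab <- suppressWarnings(estimate_correction(v, age_bands = c(6, 40)))
  expect_equal(tab$delta[tab$sex == "M"], 0)
  # two patient-years with differences 0.2 and 0.4 -> 0.3
  v2 <- rbind(visits_df("A", 2005, "M", 12, c(2.0, 1.6)),   # max-mean = 0.2
              visits_df("B", 2006, "M", 14, c(2.4, 1.6)))   # max-mean = 0.4
  tab2 <- suppressWarnings(estimate_correction(v2, age_bands = c(6, 40)))
  expect_equal(tab2$delta[tab2$sex == "M"], 0.3)
})

test_that("bands without eligible patient-years are flagged missing", {
  v <- visits_df("A", 2005, "F", 8, c(1.2, 1.0))
  expect_warning(tab <- estimate_correction(v, age_bands = c(6, 10, 40)),
                 "missing")
  expect_true(is.na(tab$delta[tab$sex == "F" & tab$age_lo == 10]))
  expect_false(is.na(tab$delta[tab$sex == "F" & tab$age_lo == 6]))
  # single-visit patient-years are not eligible
  expect_error(estimate_correction(visits_df("A", 2005, "M", 8, 1.5)),
               "two or more")
})

test_that("the random-visit estimator is seeded and unbiased-ish", {
  v <- rbind(visits_df("A", 2005, "M", 12, c(2.0, 1.8, 1.6)),
             visits_df("B", 2005, "M", 13, c(2.2, 2.0)))
  t1 <- suppressWarnings(estimate_correction(v, age_bands = c(6, 40),
                                             method = "random", seed = 1))
  t2 <- suppressWarnings(estimate_correction(v, age_bands = c(6, 40),
                                             method = "random", seed = 1))
  expect_identical(t1$delta, t2$delta)
  # differences drawn from non-best visits only
  expect_true(min(abs(t1$delta[t1$sex == "M"] - c(0.2, 0.3))) < 1e-9)
})

test_that("application corrects best records only, with positivity floor", {
  tab <- data.frame(sex = c("M", "F"), age_lo = 6, age_hi = 40,
                    delta = c(0.2, 0.15), n_patient_years = 10L)
  rec <- toy_records()[c(1, 3), ]           # M age 10, F age 6
  rec$measurement_type <- c("best", "unselected")
  out <- apply_correction(rec, tab)
  expect_equal(out$fev1_l, c(1.8 - 0.2, 1.1))
  expect_identical(out$measurement_type, c("corrected", "unselected"))
  # floor at epsilon with warning
  rec2 <- rec[1, ]; rec2$fev1_l <- 0.1; rec2$measurement_type <- "best"
  expect_warning(out2 <- apply_correction(rec2, tab, epsilon = 0.05),
                 "floored")
  expect_equal(out2$fev1_l, 0.05)
  # uncovered band is an error naming the gap
  rec3 <- rec[1, ]; rec3$age_years <- 50; rec3$measurement_type <- "best"
  expect_error(apply_correction(rec3, tab), "no correction band")
})

test_that("correction removes most of the best-value bias", {
  cfg <- sim_config(n_patients_per_sex = 1200, visits_per_year = 4,
                    seed = 404L)
  reg <- simulate_registry(cfg)
  tab <- estimate_correction(reg)
  v <- reg$visits
  key <- paste(v$patient_id, v$year)
  best <- tapply(v$fev1_l, key, max)
  unsel <- tapply(v$fev1_l, key, function(x) x[1])
  bias0 <- mean(best) - mean(unsel)
  expect_gt(bias0, 0)
  # treat every eligible record as best-reported, then correct
  rec <- reg$records[!is.na(reg$records$fev1_l), ]
  rec$fev1_l <- as.numeric(best[paste(rec$patient_id, rec$year)])
  rec$measurement_type <- "best"
  cor_rec <- apply_correction(rec, tab)
  bias1 <- mean(cor_rec$fev1_l) -
    mean(as.numeric(unsel[paste(rec$patient_id, rec$year)]))
  expect_lt(abs(bias1), 0.2 * bias0)
})

test_that("charts with and without correction differ by at most the deltas", {
  cfg <- sim_config(n_patients_per_sex = 1500, age_range = c(6, 40),
                    seed = 505L)
  reg <- filter_registry(simulate_registry(cfg), "fev1")
  tab <- estimate_correction(reg)
  creg <- apply_correction(reg, tab)
  ch_raw <- fit_chart(reg, "fev1", "M", "age", taus = 0.5)
  ch_cor <- fit_chart(creg, "fev1", "M", "age", taus = 0.5)
  nd <- data.frame(age = seq(8, 38, length.out = 20))
  gap <- predict(ch_raw, nd, tau = 0.5) - predict(ch_cor, nd, tau = 0.5)
  # correction applies only to best-reporting countries, so the median
  # moves by at most the largest band delta (plus fitting noise)
  expect_true(all(gap > -0.05))
  expect_lt(max(gap), max(tab$delta, na.rm = TRUE) + 0.05)
})
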