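# Synthetic registry generator: determinism, calibration of the median
# surface, agreement of empirical quantiles with the closed-form oracle,
# and the best-vs-unselected selection mechanism.

test_that("identical config and seed give identical registries", {
  cfg <- sim_config(n_patients_per_sex = 200, seed = 99L)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1, r2)
  r3 <- simulate_registry(sim_config(n_patients_per_sex = 200, seed = 100L))
  expect_false(identical(r1$records$fev1_l, r3$records$fev1_l))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(simulate_registry(sim_config(n_patients_per_sex = 50,
                                                      seed = 5)))
  expect_identical(rnorm(1), a)
})

test_that("male median FEV1 near age 18 is close to 3 L", {
  reg <- fixture("big_sim", function()
    simulate_registry(sim_config(n_patients_per_sex = 20000,
                                 age_range = c(6, 40),
                                 countries = unselected_countries(),
                                 seed = 314L)))
  rec <- reg$records
  b <- rec$sex == "M" & rec$age_years >= 17.5 & rec$age_years <= 18.5
  expect_gt(sum(b), 300)
  expect_lt(abs(median(rec$fev1_l[b]) - 3.0), 0.1)
  # and ~1 L at age 6 irrespective of sex, ~2.3 L females at 16
  b6 <- rec$age_years >= 6 & rec$age_years <= 6.6
  expect_lt(abs(median(rec$fev1_l[b6]) - 1.0), 0.12)
  bf <- rec$sex == "F" & rec$age_years >= 15.5 & rec$age_years <= 16.5
  expect_lt(abs(median(rec$fev1_l[bf]) - 2.3), 0.1)
})

test_that("empirical quantiles converge to the closed-form oracle", {
  cfg <- sim_config(n_patients_per_sex = 50000, age_range = c(6, 40),
                    countries = unselected_countries(), seed = 2718L)
  reg <- fixture("huge_sim", function() simulate_registry(cfg))
  rec <- reg$records
  cells <- list(c(12, 0.5), c(18, 0.75), c(30, 0.25))  # (age, tau)
  for (cell in cells) {
    a0 <- cell[1]; tau <- cell[2]
    hm <- cfcentile:::median_height(cfg, "M", a0)
    b <- rec$sex == "M" & abs(rec$age_years - a0) < 0.5 &
      abs(rec$height_cm - hm) < 3
    emp <- as.numeric(quantile(rec$fev1_l[b], tau))
    tru <- true_quantile(cfg, "fev1", "M", tau, a0, hm)
    # 3*SE of an empirical quantile via the closed-form log-normal density
    dens <- dnorm(qnorm(tau)) / (cfg$fev1_log_sigma * tru)
    se <- sqrt(tau * (1 - tau) / sum(b)) / dens
    # allowance for covariate spread within the finite cell
    expect_lt(abs(emp - tru), 3 * se + 0.04)
  }
})

test_that("true_quantile has the closed forms and is monotone in tau", {
  cfg <- sim_config()
  hm <- cfcentile:::median_height(cfg, "M", 18)
  m <- cfcentile:::fev1_median_surface(cfg, "M", 18, 175)
  expect_equal(true_quantile(cfg, "fev1", "M", 0.5, 18, 175), m)
  expect_equal(true_quantile(cfg, "fev1", "M", 0.9, 18, 175),
               m * exp(cfg$fev1_log_sigma * qnorm(0.9)))
  # BMI with L = 1 median is exactly M(age)
  cfg1 <- sim_config(bmi_lms = list(
    M = list(L = 1, S = 0.1,
             anchor = data.frame(age = c(0, 20, 40), M = c(15, 21, 22))),
    F = list(L = 1, S = 0.1,
             anchor = data.frame(age = c(0, 20, 40), M = c(15, 20, 21)))))
  expect_equal(true_quantile(cfg1, "bmi", "M", 0.5, 20), 21)
  # strict monotonicity across outcomes, sexes, ages
  set.seed(4)
  for (i in 1:20) {
    sex <- sample(c("M", "F"), 1)
    outcome <- sample(c("fev1", "bmi"), 1)
    age <- runif(1, if (outcome == "fev1") 6 else 0, 40)
    q <- true_quantile(cfg, outcome, sex, seq(0.05, 0.95, 0.05), age)
    expect_true(all(diff(q) > 0))
  }
  expect_error(true_quantile(cfg, "fev1", "M", 1.5, 18), "strictly in")
  expect_error(true_quantile(cfg, "fev1", "M", 0.5, 55), "outside")
})

test_that("median FEV1 rises ~0.25 L per additional 10 cm of height", {
  cfg <- sim_config()
  q1 <- true_quantile(cfg, "fev1", "M", 0.5, 20, 170)
  q2 <- true_quantile(cfg, "fev1", "M", 0.5, 20, 180)
  expect_lt(abs((q2 - q1) - 0.25), 0.08)
})

test_that("best annual value exceeds an unselected visit in expectation", {
  cfg <- sim_config(n_patients_per_sex = 1500, visits_per_year = 3,
                    seed = 55L)
  reg <- simulate_registry(cfg)
  v <- reg$visits
  key <- paste(v$patient_id, v$year)
  best <- tapply(v$fev1_l, key, max)
  one <- tapply(v$fev1_l, key, function(x) x[1])
  expect_gt(mean(best) - mean(one), 0)
  # reported values from best-reporting countries equal the max visit
  rec <- reg$records
  i <- which(rec$measurement_type == "best" & !is.na(rec$fev1_l))[1:50]
  expect_equal(rec$fev1_l[i],
               as.numeric(best[paste(rec$patient_id[i], rec$year[i])]))
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_patients_per_sex = 0), "n_patients_per_sex")
  expect_error(sim_config(fev1_log_sigma = -1), "fev1_log_sigma")
  expect_error(sim_config(age_range = c(0, 50)), "age_range")
  expect_error(sim_config(visits_per_year = 0), "visits_per_year")
  expect_error(sim_config(prop_transplanted = 1.2), "prop_transplanted")
})
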