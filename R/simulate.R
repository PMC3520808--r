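#' Configuration for the synthetic CF registry generator
#'
#' Defines the data-generating process of [simulate_registry()].  Defaults
#' emulate the statistical structure of a multinational CF registry: two
#' sexes; ages 0-40 years; FEV1 measured from age 6, rising from about 1 L
#' at age 6 to a sex-specific peak (3 L at 18 y in males, 2.3 L at 16 y in
#' females) and declining thereafter; FEV1 increasing with height by about
#' 0.25 L per 10 cm at the median; BMI following LMS curves that fall below
#' a healthy standard after childhood; several within-year visits per
#' patient from which "best"-reporting countries report the maximum; and
#' country groups with configurable sampling weights and reporting modes.
#'
#' The median FEV1 surface is multiplicative,
#' `m(sex, age, height) = f(sex, age) * (1 + height_effect * (height - h_med(sex, age)))`,
#' where `f` rises as a smooth quintic from `fev1_median_at_start` at
#' `fev1_age_start` to the sex-specific peak (zero slope at the peak) and
#' declines quadratically to `fev1_median_at_max` at the upper age limit.
#' Measurements are log-normal around the median surface; within-year
#' visits share a patient-year level (between-patient log-SD
#' `sqrt(fev1_log_sigma^2 - fev1_visit_sigma^2)`) with visit-to-visit
#' log-SD `fev1_visit_sigma`, so an unselected visit has total log-SD
#' `fev1_log_sigma` and closed-form quantiles (see [true_quantile()]).
#' BMI is generated from the configured LMS curves; heights follow a
#' two-phase (infancy + pubertal-spurt) logistic-type median growth curve
#' with Gaussian noise, giving realistic age-height collinearity.
#'
#' @param n_patients_per_sex patients simulated per sex.
#' @param age_range length-2 ages in years, within [0, 40]; patient ages are
#'   uniform over this range.
#' @param peak_age named vector `c(M=, F=)`, age of peak median FEV1.
#' @param peak_median_fev1 named vector, peak median FEV1 in liters.
#' @param fev1_age_start age (years) from which FEV1 is measured.
#' @param fev1_median_at_start median FEV1 (L) at `fev1_age_start`.
#' @param fev1_median_at_max named vector, median FEV1 (L) at age 40.
#' @param fev1_log_sigma total log-scale SD of an unselected measurement.
#' @param fev1_visit_sigma within-year visit-to-visit log-scale SD.
#' @param height_effect relative FEV1 change per cm of height.
#' @param height_curve list of per-sex height growth parameters
#'   (`h_birth`, `h_child`, `k`, `h_adult`, `a_puberty`, `r_puberty`).
#' @param height_sd SD (cm) of height around the median growth curve.
#' @param bmi_lms list with per-sex CF BMI LMS curves: `L`, `S` scalars and
#'   an `anchor` data.frame of (age, M) interpolated by natural splines.
#' @param visits_per_year number k of within-year visits (>= 1).
#' @param countries data.frame with columns `country`, `group`, `weight`,
#'   `reporting` ("best" or "unselected").
#' @param year_range calendar years sampled uniformly.
#' @param prop_transplanted fraction of post-transplant records.
#' @param genotype_probs named probabilities for
#'   `F508del_hom`, `other`, `unknown`.
#' @param seed integer seed; every simulation is deterministic given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients_per_sex = 1000L,
                       age_range = c(0, 40),
                       peak_age = c(M = 18, F = 16),
                       peak_median_fev1 = c(M = 3.0, F = 2.3),
                       fev1_age_start = 6,
                       fev1_median_at_start = 1.0,
                       fev1_median_at_max = c(M = 2.3, F = 1.8),
                       fev1_log_sigma = 0.38,
                       fev1_visit_sigma = 0.06,
                       height_effect = 0.010,
                       height_curve = NULL,
                       height_sd = 6,
                       bmi_lms = NULL,
                       visits_per_year = 4L,
                       countries = NULL,
                       year_range = c(2004, 2007),
                       prop_transplanted = 0.03,
                       genotype_probs = c(F508del_hom = 0.478, other = 0.42,
                                          unknown = 0.102),
                       seed = 20120907L) {
  if (is.null(height_curve))
    height_curve <- list(
      M = list(h_birth = 50, h_child = 148, k = 0.18, h_adult = 177,
               a_puberty = 13.5, r_puberty = 0.9),
      F = list(h_birth = 50, h_child = 145, k = 0.19, h_adult = 164,
               a_puberty = 11.5, r_puberty = 0.9))
  if (is.null(bmi_lms))
    bmi_lms <- list(
      M = list(L = -0.8, S = 0.12, anchor = data.frame(
        age = c(0, 0.5, 2, 6, 10, 14, 18, 25, 40),
        M = c(13.5, 16.5, 15.8, 15.3, 16.3, 18.0, 19.8, 20.8, 21.5))),
      F = list(L = -0.8, S = 0.12, anchor = data.frame(
        age = c(0, 0.5, 2, 6, 10, 14, 18, 25, 40),
        M = c(13.3, 16.2, 15.6, 15.2, 16.2, 17.8, 19.2, 20.0, 20.5))))
  if (is.null(countries))
    countries <- data.frame(
      country = c("FR", "DE", "HC", "LC"),
      group = c("France", "Germany", "HighCoverage", "LowCoverage"),
      weight = c(0.36, 0.38, 0.18, 0.08),
      reporting = c("unselected", "unselected", "best", "best"),
      stringsAsFactors = FALSE)

  cfg <- list(n_patients_per_sex = as.integer(n_patients_per_sex),
              age_range = as.numeric(age_range), peak_age = peak_age,
              peak_median_fev1 = peak_median_fev1,
              fev1_age_start = fev1_age_start,
              fev1_median_at_start = fev1_median_at_start,
              fev1_median_at_max = fev1_median_at_max,
              fev1_log_sigma = fev1_log_sigma,
              fev1_visit_sigma = fev1_visit_sigma,
              height_effect = height_effect, height_curve = height_curve,
              height_sd = height_sd, bmi_lms = bmi_lms,
              visits_per_year = as.integer(visits_per_year),
              countries = countries, year_range = year_range,
              prop_transplanted = prop_transplanted,
              genotype_probs = genotype_probs, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) if (!ok)
    stop_domain("invalid sim_config field '", field, "': ", why)
  chk(cfg$n_patients_per_sex > 0, "n_patients_per_sex", "must be positive")
  chk(length(cfg$age_range) == 2 && cfg$age_range[1] < cfg$age_range[2] &&
        cfg$age_range[1] >= 0 && cfg$age_range[2] <= 40,
      "age_range", "must be an increasing interval within [0, 40]")
  chk(all(cfg$peak_median_fev1 > 0), "peak_median_fev1", "must be positive")
  chk(cfg$fev1_log_sigma > 0, "fev1_log_sigma", "must be positive")
  chk(cfg$fev1_visit_sigma >= 0 &&
        cfg$fev1_visit_sigma < cfg$fev1_log_sigma,
      "fev1_visit_sigma", "must be in [0, fev1_log_sigma)")
  chk(cfg$visits_per_year >= 1, "visits_per_year", "must be at least 1")
  chk(all(c("M", "F") %in% names(cfg$peak_age)), "peak_age",
      "needs named entries M and F")
  chk(is.data.frame(cfg$countries) &&
        all(c("country", "group", "weight", "reporting") %in%
              names(cfg$countries)) &&
        all(cfg$countries$weight > 0) &&
        all(cfg$countries$reporting %in% c("best", "unselected")),
      "countries", "needs columns country/group/weight/reporting")
  chk(cfg$prop_transplanted >= 0 && cfg$prop_transplanted < 1,
      "prop_transplanted", "must be in [0, 1)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic CF registry configuration\n")
  cat(sprintf("  %d patients/sex, ages %g-%g y, %d visits/year, seed %d\n",
              x$n_patients_per_sex, x$age_range[1], x$age_range[2],
              x$visits_per_year, x$seed))
  cat(sprintf("  FEV1 peak: M %.2f L @ %g y, F %.2f L @ %g y; log-SD %.3g\n",
              x$peak_median_fev1["M"], x$peak_age["M"],
              x$peak_median_fev1["F"], x$peak_age["F"], x$fev1_log_sigma))
  invisible(x)
}

# median height (cm) at age: infancy monomolecular rise toward h_child plus
# a logistic pubertal spurt toward h_adult
median_height <- function(config, sex, age) {
  hc <- config$height_curve[[sex]]
  hc$h_birth + (hc$h_child - hc$h_birth) * (1 - exp(-hc$k * age)) +
    (hc$h_adult - hc$h_child) /
      (1 + exp(-hc$r_puberty * (age - hc$a_puberty)))
}

# smooth quintic step: s(0)=0, s(1)=1, zero 1st/2nd derivative at both ends
smootherstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t^3 * (10 - 15 * t + 6 * t^2)
}

# median FEV1 (L) at median height: quintic rise to the peak, quadratic decline
fev1_age_curve <- function(config, sex, age) {
  pa <- config$peak_age[[sex]]
  fp <- config$peak_median_fev1[[sex]]
  f0 <- config$fev1_median_at_start
  a0 <- config$fev1_age_start
  f40 <- config$fev1_median_at_max[[sex]]
  d <- (fp - f40) / (40 - pa)^2
  ifelse(age <= pa,
         f0 + (fp - f0) * smootherstep((age - a0) / (pa - a0)),
         fp - d * (age - pa)^2)
}

# median FEV1 surface m(sex, age, height)
fev1_median_surface <- function(config, sex, age, height) {
  f <- fev1_age_curve(config, sex, age)
  fac <- 1 + config$height_effect * (height - median_height(config, sex, age))
  f * pmax(fac, 0.2)
}

cf_bmi_lms <- function(config, sex, age) {
  lms <- config$bmi_lms[[sex]]
  mfun <- stats::splinefun(lms$anchor$age, lms$anchor$M, method = "natural")
  list(L = lms$L, M = mfun(age), S = lms$S)
}

#' Ground-truth conditional quantiles of the generator
#'
#' Closed-form quantiles of the synthetic data-generating process, the
#' oracle against which fitted charts can be checked.  For FEV1 the
#' tau-quantile of an unselected measurement is
#' `m(sex, age, height) * exp(sigma * qnorm(tau))`; when `height` is omitted
#' the surface is evaluated at the median height for that sex and age.  For
#' BMI the LMS inverse `M * (1 + L * S * qnorm(tau))^(1/L)` is used
#' (`M * exp(S * qnorm(tau))` when `L = 0`).
#'
#' @param config a [sim_config()].
#' @param outcome `"fev1"` or `"bmi"`.
#' @param sex `"M"` or `"F"`.
#' @param tau quantile level(s) in (0, 1).
#' @param age age(s) in years, within the configured range.
#' @param height height(s) in cm, or `NULL` for the median height.
#' @return numeric vector of quantile values (liters or kg/m^2).
#' @export
true_quantile <- function(config, outcome = c("fev1", "bmi"), sex, tau, age,
                          height = NULL) {
  stopifnot(inherits(config, "sim_config"))
  outcome <- match.arg(outcome)
  sex <- match_code(sex, c("M", "F"), "sex")
  if (any(tau <= 0 | tau >= 1)) stop_domain("tau must lie strictly in (0, 1)")
  if (any(age < config$age_range[1] | age > config$age_range[2]))
    stop_domain("age outside the configured range [",
                config$age_range[1], ", ", config$age_range[2], "]")
  z <- stats::qnorm(tau)
  if (outcome == "fev1") {
    if (any(age < config$fev1_age_start))
      stop_domain("FEV1 quantiles are defined from age ",
                  config$fev1_age_start)
    if (is.null(height)) height <- median_height(config, sex, age)
    m <- fev1_median_surface(config, sex, age, height)
    m * exp(config$fev1_log_sigma * z)
  } else {
    lms <- cf_bmi_lms(config, sex, age)
    lms_quantile(tau, lms$L, lms$M, lms$S)
  }
}

#' Simulate a synthetic CF registry
#'
#' Draws a seeded synthetic registry from the process described in
#' [sim_config()].  Each patient contributes one reported measurement record
#' for one calendar year; countries flagged as `"best"` reporters record the
#' maximum of the `visits_per_year` within-year FEV1 visits, `"unselected"`
#' reporters record the first visit.  All within-year visits are retained in
#' the companion longitudinal table (`$visits`), from which the best-value
#' correction can be estimated.  BMI (weight) is generated for all ages;
#' FEV1 only from the configured starting age.
#'
#' @param config a [sim_config()].
#' @return a [cf_registry()] whose `visits` table holds the longitudinal
#'   FEV1 visit draws.
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    per_sex <- lapply(c("M", "F"), function(sex) simulate_sex(config, sex))
    records <- rbind(per_sex[[1]]$records, per_sex[[2]]$records)
    visits <- rbind(per_sex[[1]]$visits, per_sex[[2]]$visits)
    cf_registry(records, visits = visits,
                provenance = sprintf(
                  "synthetic registry (seed %d, %d patients/sex)",
                  config$seed, config$n_patients_per_sex))
  })
}

simulate_sex <- function(config, sex) {
  n <- config$n_patients_per_sex
  id <- sprintf("%s%06d", sex, seq_len(n))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  hmed <- median_height(config, sex, age)
  height <- pmax(45, hmed + stats::rnorm(n, 0, config$height_sd))
  country_i <- sample.int(nrow(config$countries), n, replace = TRUE,
                          prob = config$countries$weight)
  country <- config$countries$country[country_i]
  reporting <- config$countries$reporting[country_i]
  year <- sample(seq(config$year_range[1], config$year_range[2]), n,
                 replace = TRUE)
  transplanted <- stats::runif(n) < config$prop_transplanted
  genotype <- sample(names(config$genotype_probs), n, replace = TRUE,
                     prob = config$genotype_probs)

  lms <- cf_bmi_lms(config, sex, age)
  zb <- stats::rnorm(n)
  bmi <- lms_quantile(stats::pnorm(zb), lms$L, lms$M, lms$S)
  weight <- bmi * (height / 100)^2

  has_fev1 <- age >= config$fev1_age_start
  k <- config$visits_per_year
  sigma_b <- sqrt(config$fev1_log_sigma^2 - config$fev1_visit_sigma^2)
  m <- fev1_median_surface(config, sex, age, height)
  level <- m * exp(sigma_b * stats::rnorm(n))
  visit_mat <- matrix(NA_real_, n, k)
  visit_mat[has_fev1, ] <- level[has_fev1] *
    exp(config$fev1_visit_sigma *
          matrix(stats::rnorm(sum(has_fev1) * k), sum(has_fev1), k))
  reported <- ifelse(has_fev1,
                     ifelse(reporting == "best",
                            apply(visit_mat, 1, max),
                            visit_mat[, 1]),
                     NA_real_)
  measurement_type <- ifelse(reporting == "best", "best", "unselected")

  records <- data.frame(
    patient_id = id, country = country, year = year, sex = sex,
    age_years = age, height_cm = height, weight_kg = weight,
    fev1_l = reported, measurement_type = measurement_type,
    transplanted = transplanted, genotype_class = genotype,
    stringsAsFactors = FALSE)

  iv <- which(has_fev1)
  visits <- data.frame(
    patient_id = rep(id[iv], each = k),
    year = rep(year[iv], each = k),
    sex = sex,
    age_years = rep(age[iv], each = k),
    visit = rep(seq_len(k), times = length(iv)),
    fev1_l = as.vector(t(visit_mat[iv, , drop = FALSE])),
    stringsAsFactors = FALSE)
  list(records = records, visits = visits)
}
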