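#' LMS z-score
#'
#' Standardizes a measurement against an LMS reference:
#' `z = ((x/M)^L - 1) / (L*S)` when `L != 0` and `z = log(x/M) / S` when
#' `L = 0`.  L is the Box-Cox skewness power, M the median and S the
#' coefficient of variation at the matching age and sex.
#'
#' @param x positive measurement value(s).
#' @param L,M,S LMS parameters (M > 0, S > 0); recycled against `x`.
#' @return numeric z-score(s).
#' @examples
#' lms_zscore(22, L = 1, M = 20, S = 0.1)  # 1
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0))
    stop_domain("x, M and S must all be positive")
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Quantiles of an LMS reference
#'
#' Inverts the LMS transform: the `tau`-quantile is
#' `M * (1 + L*S*qnorm(tau))^(1/L)` (or `M * exp(S * qnorm(tau))` when
#' `L = 0`).
#'
#' @param tau quantile level(s) in (0, 1).
#' @inheritParams lms_zscore
#' @return numeric quantile value(s).
#' @export
lms_quantile <- function(tau, L, M, S) {
  if (any(tau <= 0 | tau >= 1)) stop_domain("tau must lie strictly in (0, 1)")
  if (any(M <= 0) || any(S <= 0)) stop_domain("M and S must be positive")
  z <- stats::qnorm(tau)
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  base <- 1 + L * S * z
  if (any(base <= 0 & L != 0))
    stop_domain("LMS quantile undefined: 1 + L*S*qnorm(tau) <= 0")
  ifelse(L == 0, M * exp(S * z), M * base^(1 / L))
}

#' Read an LMS reference table
#'
#' Reads a CSV with columns `sex`, `age_years`, `L`, `M`, `S` (comment lines
#' starting with `#` allowed) describing an age- and sex-indexed LMS
#' standard.  Ages must be strictly increasing within each sex, M and S
#' positive.  The package ships a clearly synthetic stand-in BMI-for-age
#' standard (`inst/extdata/bmi_lms_reference_synthetic.csv`) with plausible
#' magnitudes; substitute a published standard's table for real referencing.
#'
#' @param path CSV file path; default is the bundled synthetic table.
#' @return an object of class `lms_reference`.
#' @export
read_lms_reference <- function(path = system.file(
  "extdata", "bmi_lms_reference_synthetic.csv", package = "cfcentile")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sex", "age_years", "L", "M", "S")
  if (!all(need %in% names(tab)))
    stop_domain("LMS table must have columns ", paste(need, collapse = ", "))
  if (any(tab$M <= 0) || any(tab$S <= 0))
    stop_domain("LMS table: M and S must be positive")
  for (sx in unique(tab$sex)) {
    a <- tab$age_years[tab$sex == sx]
    if (any(diff(a) <= 0))
      stop_domain("LMS table: ages must be strictly increasing within sex ", sx)
  }
  structure(list(table = tab, source = path), class = "lms_reference")
}

#' Interpolate LMS parameters at an age
#'
#' Linear interpolation of L, M and S between the bracketing rows of an
#' [read_lms_reference()] table; exact at tabulated ages.  Ages outside the
#' tabulated range are a domain error (no extrapolation).
#'
#' @param reference an `lms_reference`.
#' @param sex `"M"` or `"F"`.
#' @param age age(s) in years.
#' @return list with numeric components `L`, `M`, `S`.
#' @export
lookup_lms <- function(reference, sex, age) {
  stopifnot(inherits(reference, "lms_reference"))
  sex <- match_code(sex, unique(reference$table$sex), "sex")
  tab <- reference$table[reference$table$sex == sex, ]
  rng <- range(tab$age_years)
  if (any(age < rng[1] | age > rng[2]))
    stop_domain("age outside the LMS table range [", rng[1], ", ", rng[2],
                "] for sex ", sex)
  list(L = stats::approx(tab$age_years, tab$L, age)$y,
       M = stats::approx(tab$age_years, tab$M, age)$y,
       S = stats::approx(tab$age_years, tab$S, age)$y)
}

#' Read an FEV1 prediction-equation table
#'
#' Reads a CSV of healthy-reference FEV1 prediction equations with columns
#' `sex`, `age_lo`, `age_hi`, `intercept`, `age_coef`, `height_coef`: within
#' a stratum `[age_lo, age_hi)` the predicted FEV1 (liters) is
#' `intercept + age_coef * age + height_coef * height_cm`.  Strata must not
#' overlap within a sex.  The bundled default
#' (`inst/extdata/fev1_pred_equations_synthetic.csv`) is a clearly synthetic
#' stand-in with plausible healthy-population magnitudes; substitute a
#' published equation set (e.g. Knudson-style coefficients) for real use.
#'
#' @param path CSV file path; default is the bundled synthetic table.
#' @return object of class `prediction_equations`.
#' @export
read_prediction_equations <- function(path = system.file(
  "extdata", "fev1_pred_equations_synthetic.csv", package = "cfcentile")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "intercept", "age_coef", "height_coef")
  if (!all(need %in% names(tab)))
    stop_domain("equation table must have columns ",
                paste(need, collapse = ", "))
  for (sx in unique(tab$sex)) {
    s <- tab[tab$sex == sx, ]
    s <- s[order(s$age_lo), ]
    if (any(s$age_hi <= s$age_lo) ||
        (nrow(s) > 1 && any(s$age_lo[-1] < s$age_hi[-nrow(s)])))
      stop_domain("overlapping or empty age strata for sex ", sx)
  }
  structure(list(table = tab, source = path), class = "prediction_equations")
}

#' Predicted healthy FEV1
#'
#' Evaluates the stratum-specific linear prediction equation for given sex,
#' age and height.  Strata are half-open `[age_lo, age_hi)` except the last
#' stratum of each sex, which is closed at its upper end.  Values are
#' continuous within a stratum; discontinuities at stratum boundaries are a
#' property of such published equation sets and are not smoothed.
#'
#' @param equations a [read_prediction_equations()] object.
#' @param sex `"M"` or `"F"` (recycled against `age`).
#' @param age age(s) in years; must fall in a declared stratum.
#' @param height height(s) in cm, in a plausible range (50-220).
#' @return predicted FEV1 in liters.
#' @export
predicted_fev1 <- function(equations, sex, age, height) {
  stopifnot(inherits(equations, "prediction_equations"))
  n <- max(length(sex), length(age), length(height))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  height <- rep_len(height, n)
  if (any(!sex %in% c("M", "F"))) stop_domain("sex must be M or F")
  if (any(height < 50 | height > 220))
    stop_domain("height outside the plausible range 50-220 cm")
  tab <- equations$table
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- tab[tab$sex == sex[i], ]
    last_hi <- max(s$age_hi)
    hit <- which(age[i] >= s$age_lo &
                   (age[i] < s$age_hi | (age[i] == last_hi & s$age_hi == last_hi)))
    if (!length(hit)) {
      supp <- paste0("[", min(s$age_lo), ", ", max(s$age_hi), "]")
      stop_domain("age ", age[i], " outside the supported range ", supp,
                  " for sex ", sex[i])
    }
    s <- s[hit[1], ]
    out[i] <- s$intercept + s$age_coef * age[i] + s$height_coef * height[i]
  }
  out
}

#' FEV1 percent predicted
#'
#' `100 * observed / predicted`, the conventional healthy-referenced lung
#' function scale.
#'
#' @param observed observed FEV1 (liters), nonnegative.
#' @param predicted predicted healthy FEV1 (liters), positive.
#' @return percent predicted.
#' @export
percent_predicted <- function(observed, predicted) {
  if (any(predicted <= 0)) stop_domain("predicted FEV1 must be positive")
  if (any(observed < 0)) stop_domain("observed FEV1 must be nonnegative")
  100 * observed / predicted
}
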