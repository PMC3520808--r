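#' Estimate the best-annual-value correction table
#'
#' Some registries report the best (highest) FEV1 of the year while others
#' report an unselected measurement; charts built from best values
#' overestimate the distribution.  Using longitudinal within-year visit data
#' (where all visits were recorded, as in the French collection), this
#' estimates, by sex and age band, the mean difference between the best
#' annual FEV1 and an unselected value of the same year.  Per patient-year
#' the difference is `max(visits) - mean(visits)` — the expectation of
#' `max - (random visit)` over a uniformly drawn visit — or, with
#' `method = "random"`, `max(visits)` minus one seeded random visit draw.
#' Band entries average these differences over patient-years.
#'
#' @param registry a [cf_registry()] with a longitudinal `visits` table, or
#'   such a table directly (columns `patient_id`, `year`, `sex`,
#'   `age_years`, `fev1_l`).
#' @param age_bands numeric vector of band edges; bands are `[lo, hi)` with
#'   the last band closed.  Default `c(6, 10, 15, 20, 30, 40)`.
#' @param method `"mean"` (expectation over a uniform visit; default) or
#'   `"random"` (one seeded random visit).
#' @param seed used only by `method = "random"`.
#' @return object of class `correction_table`: data.frame with columns
#'   `sex`, `age_lo`, `age_hi`, `delta` (liters, NA when a band has no
#'   eligible patient-years), `n_patient_years`.
#' @export
estimate_correction <- function(registry, age_bands = c(6, 10, 15, 20, 30, 40),
                                method = c("mean", "random"), seed = NULL) {
  method <- match.arg(method)
  visits <- if (inherits(registry, "cf_registry")) registry$visits else
    as.data.frame(registry)
  if (is.null(visits) || !nrow(visits))
    stop_domain("no longitudinal visit data available")
  if (length(age_bands) < 2 || is.unsorted(age_bands, strictly = TRUE))
    stop_domain("age_bands must be strictly increasing with >= 2 edges")
  key <- interaction(visits$patient_id, visits$year, drop = TRUE)
  nv <- tapply(visits$fev1_l, key, length)
  eligible <- names(nv)[nv >= 2L]
  if (!length(eligible))
    stop_domain("no patient-year has two or more visits")
  sub <- visits[key %in% eligible, ]
  key2 <- interaction(sub$patient_id, sub$year, drop = TRUE)
  py_diff <- with_seed(seed, tapply(seq_len(nrow(sub)), key2, function(i) {
    v <- sub$fev1_l[i]
    if (method == "mean") {
      max(v) - mean(v)              # expectation over a uniform visit draw
    } else {
      rest <- v[-which.max(v)]      # one random non-best visit
      max(v) - rest[sample.int(length(rest), 1L)]
    }
  }))
  first <- !duplicated(key2)
  py <- data.frame(sex = sub$sex[first][match(names(py_diff), key2[first])],
                   age = sub$age_years[first][match(names(py_diff), key2[first])],
                   diff = as.numeric(py_diff))
  lo <- age_bands[-length(age_bands)]
  hi <- age_bands[-1]
  out <- do.call(rbind, lapply(c("M", "F"), function(sx) {
    data.frame(sex = sx, age_lo = lo, age_hi = hi, delta = NA_real_,
               n_patient_years = 0L, stringsAsFactors = FALSE)
  }))
  for (r in seq_len(nrow(out))) {
    last <- out$age_hi[r] == max(age_bands)
    inb <- py$sex == out$sex[r] & py$age >= out$age_lo[r] &
      (py$age < out$age_hi[r] | (last & py$age == out$age_hi[r]))
    out$n_patient_years[r] <- sum(inb)
    if (any(inb)) out$delta[r] <- mean(py$diff[inb])
  }
  if (any(is.na(out$delta)))
    warning("band(s) with no eligible patient-years flagged missing: ",
            paste(sprintf("%s[%g,%g)", out$sex[is.na(out$delta)],
                          out$age_lo[is.na(out$delta)],
                          out$age_hi[is.na(out$delta)]), collapse = ", "))
  if (any(out$delta < 0, na.rm = TRUE))
    warning("negative correction delta estimated in some band(s)")
  structure(out, class = c("correction_table", "data.frame"),
            method = method)
}

#' @export
print.correction_table <- function(x, ...) {
  cat("Best-annual-FEV1 correction table (delta = mean best - unselected, L)\n")
  print.data.frame(transform(x, delta = round(delta, 4)), row.names = FALSE)
  invisible(x)
}

#' Apply the best-value correction to a registry
#'
#' Subtracts the sex/age-band correction delta from the FEV1 of records
#' whose `measurement_type` is `"best"`, relabelling them `"corrected"`;
#' unselected records are unchanged.  Corrected values that would become
#' nonpositive are floored at a small positive epsilon with a warning.  The
#' correction is intended to be applied before chart fitting.
#'
#' @param registry a [cf_registry()] (or records data.frame).
#' @param table a [estimate_correction()] result (or a data.frame with its
#'   columns).
#' @param epsilon positivity floor in liters.
#' @return the corrected registry (same class as the input).
#' @export
apply_correction <- function(registry, table, epsilon = 0.05) {
  is_reg <- inherits(registry, "cf_registry")
  rec <- if (is_reg) registry$records else as.data.frame(registry)
  tab <- as.data.frame(table)
  todo <- which(rec$measurement_type == "best" & !is.na(rec$fev1_l))
  if (length(todo)) {
    delta <- numeric(length(todo))
    for (jj in seq_along(todo)) {
      i <- todo[jj]
      last_hi <- max(tab$age_hi[tab$sex == rec$sex[i]])
      hit <- which(tab$sex == rec$sex[i] & rec$age_years[i] >= tab$age_lo &
                     (rec$age_years[i] < tab$age_hi |
                        (tab$age_hi == last_hi & rec$age_years[i] == last_hi)))
      if (!length(hit) || is.na(tab$delta[hit[1]])) {
        gaps <- sprintf("%s outside [%g, %g]", rec$sex[i],
                        min(tab$age_lo[tab$sex == rec$sex[i]]), last_hi)
        stop_domain("no correction band covers sex ", rec$sex[i], ", age ",
                    signif(rec$age_years[i], 4), " (", gaps, ")")
      }
      delta[jj] <- tab$delta[hit[1]]
    }
    newv <- rec$fev1_l[todo] - delta
    if (any(newv <= 0)) {
      warning(sum(newv <= 0), " corrected FEV1 value(s) floored at ",
              epsilon, " L")
      newv <- pmax(newv, epsilon)
    }
    rec$fev1_l[todo] <- newv
    rec$measurement_type[todo] <- "corrected"
  }
  if (is_reg) {
    registry$records <- rec
    registry$filters_applied <- c(registry$filters_applied,
                                  "best_value_correction")
    registry
  } else rec
}
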