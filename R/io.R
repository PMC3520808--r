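# Registry CSV dialect, chart serialization and registry summaries.
#
# Registry CSV: comma-separated, UTF-8, header row mandatory, "." decimal
# point.  Columns: patient_id, country, year, sex {M,F}, age_years,
# height_cm, weight_kg, fev1_l (blank allowed), measurement_type
# {best,unselected,corrected}, transplanted {0,1}, genotype_class
# {F508del_hom,other,unknown}.  Unknown columns are preserved on read but
# ignored by the analyses.

#' Read a registry CSV file
#'
#' Reads and validates the registry CSV dialect (see the package vignette).
#' Row-level schema violations (bad sex or measurement-type code,
#' nonpositive height, ...) are collected and reported with their row
#' numbers; offending rows are dropped with a warning unless more than
#' `max_invalid` of rows are invalid, which is an error.  BMI is computed
#' as `weight/(height/100)^2` when not supplied.
#'
#' @param path CSV file path.
#' @param visits_path optional CSV of longitudinal visits (columns
#'   `patient_id`, `year`, `sex`, `age_years`, `visit`, `fev1_l`).
#' @param max_invalid maximum tolerated fraction of invalid rows.
#' @return a [cf_registry()].
#' @export
read_registry_csv <- function(path, visits_path = NULL, max_invalid = 0.05) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(required_record_cols, names(raw))
  if (length(missing_cols))
    stop_domain("registry CSV lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  raw$transplanted <- raw$transplanted %in% c(1, "1", TRUE, "TRUE", "true")
  raw$fev1_l <- suppressWarnings(as.numeric(raw$fev1_l))
  problems <- validate_records(raw)
  bad_rows <- unique(as.integer(sub("^row (\\d+):.*", "\\1",
                                    grep("^row ", problems, value = TRUE))))
  if (length(bad_rows) > max_invalid * nrow(raw))
    stop_domain("more than ", round(100 * max_invalid), "% of rows invalid:\n  ",
                paste(utils::head(problems, 20), collapse = "\n  "))
  if (length(bad_rows)) {
    warning(length(bad_rows), " invalid row(s) dropped:\n  ",
            paste(utils::head(problems, 10), collapse = "\n  "))
    raw <- raw[-bad_rows, , drop = FALSE]
  }
  visits <- NULL
  if (!is.null(visits_path)) {
    visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8")
  }
  cf_registry(raw, visits = visits, provenance = paste("read from", path))
}

#' Write a registry to CSV
#'
#' Writes the registry records (and optionally the longitudinal visits) in
#' the registry CSV dialect.  Writes are atomic (temp file + rename).
#'
#' @param registry a [cf_registry()].
#' @param path output CSV path.
#' @param visits_path optional path for the longitudinal visits table.
#' @return `path`, invisibly.
#' @export
write_registry_csv <- function(registry, path, visits_path = NULL) {
  stopifnot(inherits(registry, "cf_registry"))
  rec <- registry$records
  rec$transplanted <- as.integer(rec$transplanted)
  atomic_write(path, function(tmp)
    utils::write.csv(rec, tmp, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = ""))
  if (!is.null(visits_path) && !is.null(registry$visits))
    atomic_write(visits_path, function(tmp)
      utils::write.csv(registry$visits, tmp, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8", na = ""))
  invisible(path)
}

#' Write / read a correction table as CSV
#'
#' @param table a [estimate_correction()] result.
#' @param path CSV path.
#' @return `path` invisibly (write); a `correction_table` (read).
#' @export
write_correction_csv <- function(table, path) {
  atomic_write(path, function(tmp)
    utils::write.csv(as.data.frame(table), tmp, row.names = FALSE,
                     quote = FALSE))
  invisible(path)
}

#' @rdname write_correction_csv
#' @export
read_correction_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "delta", "n_patient_years")
  if (!all(need %in% names(tab)))
    stop_domain("correction CSV must have columns ",
                paste(need, collapse = ", "))
  structure(tab, class = c("correction_table", "data.frame"))
}

#' Serialize a fitted chart to JSON
#'
#' Writes everything needed to re-evaluate a chart — outcome, sex,
#' covariates, tau grid, spline specification (degree, knots), per-tau
#' coefficients and fit metadata — as JSON.  Training data are not
#' serialized.  [read_chart_json()] reconstructs an equivalent `cf_chart`.
#'
#' @param chart a [fit_chart()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_chart_json <- function(chart, path) {
  stopifnot(inherits(chart, "cf_chart"))
  obj <- list(
    outcome = chart$outcome, sex = chart$sex, covariates = chart$covariates,
    taus = chart$taus, tensor = chart$tensor,
    specs = lapply(chart$specs, function(sp)
      list(degree = sp$degree, n_basis = sp$n_basis,
           boundary = sp$boundary, interior = sp$interior)),
    coef = unname(as.list(as.data.frame(chart$coef))),
    coef_names = rownames(chart$coef),
    metadata = list(n = chart$n, ranges = chart$ranges,
                    filters = chart$filters,
                    correction_applied = chart$correction_applied,
                    version = chart$version))
  atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  invisible(path)
}

#' Read a chart serialized by [write_chart_json()]
#'
#' @param path JSON path.
#' @return a `cf_chart` (without training data).
#' @export
read_chart_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(obj$specs, function(sp)
    spline_spec(n_basis = sp$n_basis, degree = sp$degree,
                boundary = sp$boundary, interior = sp$interior))
  coef <- obj$coef
  if (is.list(coef)) coef <- do.call(cbind, lapply(coef, as.numeric))
  else if (is.matrix(coef)) coef <- t(coef)      # rows were per-tau vectors
  else coef <- matrix(as.numeric(coef), ncol = 1L)
  dimnames(coef) <- list(obj$coef_names, sprintf("tau%.2f", obj$taus))
  structure(list(outcome = obj$outcome, sex = obj$sex,
                 covariates = obj$covariates, taus = as.numeric(obj$taus),
                 specs = specs, coef = coef,
                 tensor = isTRUE(obj$tensor),
                 n = obj$metadata$n,
                 ranges = lapply(obj$metadata$ranges, as.numeric),
                 filters = as.character(obj$metadata$filters %||% character(0)),
                 correction_applied = obj$metadata$correction_applied,
                 data = NULL, version = obj$metadata$version),
            class = "cf_chart")
}

#' Export chart curves as long-format CSV
#'
#' Writes fitted curve values over a covariate grid as tidy rows
#' (`outcome`, `sex`, `tau`, covariate columns, `value`) for plotting or
#' interchange.
#'
#' @param chart a [fit_chart()] result.
#' @param path output CSV path.
#' @param grid data.frame of covariate values; defaults to 50 points over
#'   the first covariate's range (second covariate at its range midpoint).
#' @param taus levels to export; default all fitted.
#' @return `path`, invisibly.
#' @export
write_chart_csv <- function(chart, path, grid = NULL, taus = chart$taus) {
  if (is.null(grid)) {
    cv <- chart$covariates[1L]
    grid <- data.frame(seq(chart$ranges[[cv]][1], chart$ranges[[cv]][2],
                           length.out = 50L))
    names(grid) <- cv
    if (length(chart$covariates) > 1L)
      grid[[chart$covariates[2L]]] <- mean(chart$ranges[[chart$covariates[2L]]])
  }
  V <- predict(chart, grid, tau = taus)
  if (is.null(dim(V))) V <- matrix(V, ncol = length(taus))
  long <- do.call(rbind, lapply(seq_along(taus), function(j)
    cbind(data.frame(outcome = chart$outcome, sex = chart$sex,
                     tau = taus[j]), grid, value = V[, j])))
  atomic_write(path, function(tmp)
    utils::write.csv(long, tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Summarize a registry by country group
#'
#' Per country group: number of patients and measurements, percent female,
#' mean and SD of FEV1 percent predicted (against `equations`), mean and SD
#' of the BMI z-score (against `lms`), and percent of measurements in
#' adults (over 20 years).
#'
#' @param registry a [cf_registry()].
#' @param equations a [read_prediction_equations()] object (or `NULL` to
#'   skip the FEV1pp columns).
#' @param lms an [read_lms_reference()] object (or `NULL` to skip BMI z).
#' @return data.frame, one row per group plus an overall row.
#' @export
summarize_registry <- function(registry,
                               equations = read_prediction_equations(),
                               lms = read_lms_reference()) {
  stopifnot(inherits(registry, "cf_registry"))
  rec <- registry$records
  if (!nrow(rec)) stop_domain("registry is empty")
  groups <- c(sort(unique(rec$country)), "Overall")
  rows <- lapply(groups, function(g) {
    r <- if (g == "Overall") rec else rec[rec$country == g, ]
    fpp <- rep(NA_real_, nrow(r))
    if (!is.null(equations)) {
      ok <- !is.na(r$fev1_l)
      if (any(ok)) {
        pr <- tryCatch(predicted_fev1(equations, r$sex[ok], r$age_years[ok],
                                      r$height_cm[ok]),
                       cfcentile_domain_error = function(e) NULL)
        if (!is.null(pr)) fpp[ok] <- percent_predicted(r$fev1_l[ok], pr)
      }
    }
    bz <- rep(NA_real_, nrow(r))
    if (!is.null(lms)) {
      for (sx in c("M", "F")) {
        i <- which(r$sex == sx)
        if (!length(i)) next
        p <- tryCatch(lookup_lms(lms, sx, r$age_years[i]),
                      cfcentile_domain_error = function(e) NULL)
        if (!is.null(p)) bz[i] <- lms_zscore(r$bmi[i], p$L, p$M, p$S)
      }
    }
    data.frame(group = g,
               n_patients = length(unique(r$patient_id)),
               n_measurements = nrow(r),
               pct_female = 100 * mean(r$sex == "F"),
               fev1pp_mean = mean(fpp, na.rm = TRUE),
               fev1pp_sd = stats::sd(fpp[!is.na(fpp)]),
               bmi_z_mean = mean(bz, na.rm = TRUE),
               bmi_z_sd = stats::sd(bz[!is.na(bz)]),
               pct_adults = 100 * mean(r$age_years > 20))
  })
  do.call(rbind, rows)
}

#' Read a simulation configuration from YAML
#'
#' Reads a plain-text YAML file whose top-level keys are [sim_config()]
#' arguments (`countries` as a list of records; `peak_age` etc. as `M:`/
#' `F:` maps) and builds the config.  Keys absent from the file keep the
#' package defaults.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$countries))
    raw$countries <- do.call(rbind, lapply(raw$countries, as.data.frame))
  for (nm in c("peak_age", "peak_median_fev1", "fev1_median_at_max"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}
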