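#' Patient-registry container
#'
#' A `cf_registry` bundles one row per reported measurement (the registry
#' reality: one FEV1/BMI observation per patient per year) with optional
#' companion longitudinal visit data (all within-year spirometry visits,
#' needed to estimate the best-annual-value correction), provenance text and
#' the list of filters already applied.
#'
#' Required record columns: `patient_id`, `country`, `year`, `sex` (M/F),
#' `age_years`, `height_cm`, `weight_kg`, `fev1_l` (NA allowed),
#' `measurement_type` (best/unselected/corrected), `transplanted` (logical),
#' `genotype_class` (F508del_hom/other/unknown).  A `bmi` column is derived
#' as `weight_kg / (height_cm/100)^2` if absent.
#'
#' @param records data.frame of measurement records (one row per
#'   patient-year observation).
#' @param visits optional data.frame of within-year visits with columns
#'   `patient_id`, `year`, `sex`, `age_years`, `visit`, `fev1_l`.
#' @param provenance free-text description of where the data came from.
#' @param filters_applied character vector naming filters already applied.
#' @return an object of class `cf_registry`.
#' @export
cf_registry <- function(records, visits = NULL, provenance = "unspecified",
                        filters_applied = character(0)) {
  records <- as.data.frame(records)
  problems <- validate_records(records)
  if (length(problems))
    stop_domain("invalid registry records:\n  ",
                paste(utils::head(problems, 20), collapse = "\n  "))
  if (!"bmi" %in% names(records))
    records$bmi <- records$weight_kg / (records$height_cm / 100)^2
  structure(list(records = records, visits = visits,
                 provenance = provenance,
                 filters_applied = filters_applied),
            class = "cf_registry")
}

required_record_cols <- c("patient_id", "country", "year", "sex", "age_years",
                          "height_cm", "weight_kg", "fev1_l",
                          "measurement_type", "transplanted", "genotype_class")

# returns character vector of row-tagged problems (empty when valid)
validate_records <- function(records) {
  missing_cols <- setdiff(required_record_cols, names(records))
  if (length(missing_cols))
    return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  bad <- function(cond, what) {
    i <- which(cond)
    if (!length(i)) return(character(0))
    paste0("row ", i, ": ", what)
  }
  c(bad(!records$sex %in% c("M", "F"), "sex must be M or F"),
    bad(!records$measurement_type %in% c("best", "unselected", "corrected"),
        "measurement_type must be best, unselected or corrected"),
    bad(!records$genotype_class %in% c("F508del_hom", "other", "unknown"),
        "unknown genotype_class"),
    bad(!is.na(records$age_years) & records$age_years < 0, "negative age"),
    bad(is.na(records$height_cm) | records$height_cm <= 0,
        "height must be positive"),
    bad(!is.na(records$weight_kg) & records$weight_kg <= 0,
        "weight must be positive"),
    bad(!is.na(records$fev1_l) & records$fev1_l <= 0,
        "FEV1 must be positive when present"))
}

#' @export
print.cf_registry <- function(x, ...) {
  cat("CF patient registry:", nrow(x$records), "measurement records,",
      length(unique(x$records$patient_id)), "patients\n")
  cat("  provenance:", x$provenance, "\n")
  if (length(x$filters_applied))
    cat("  filters applied:", paste(x$filters_applied, collapse = "; "), "\n")
  if (!is.null(x$visits))
    cat("  longitudinal visits:", nrow(x$visits), "rows\n")
  invisible(x)
}

#' Apply the analysis filters for an outcome
#'
#' Removes measurements taken after lung transplantation (always) and
#' restricts to the analysis age window: ages 6-40 years for FEV1 (records
#' must carry an FEV1 value) and 0-40 years for BMI.  Both windows are
#' closed intervals.  The applied filters are recorded in the registry's
#' `filters_applied` field.
#'
#' @param registry a [cf_registry()].
#' @param outcome `"fev1"` or `"bmi"`.
#' @return the filtered [cf_registry()].
#' @export
filter_registry <- function(registry, outcome = c("fev1", "bmi")) {
  stopifnot(inherits(registry, "cf_registry"))
  outcome <- match.arg(outcome)
  rec <- registry$records
  keep <- !rec$transplanted
  window <- if (outcome == "fev1") c(6, 40) else c(0, 40)
  keep <- keep & rec$age_years >= window[1] & rec$age_years <= window[2]
  if (outcome == "fev1") keep <- keep & !is.na(rec$fev1_l)
  if (outcome == "bmi") keep <- keep & !is.na(rec$weight_kg)
  out <- registry
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  if (!is.null(registry$visits)) {
    key <- paste(out$records$patient_id, out$records$year)
    vkey <- paste(registry$visits$patient_id, registry$visits$year)
    out$visits <- registry$visits[vkey %in% key, , drop = FALSE]
  }
  out$filters_applied <- c(registry$filters_applied,
                           "no_transplant",
                           sprintf("%s_age_%g_%g", outcome, window[1], window[2]))
  if (nrow(out$records) == 0L)
    warning("no records survive the ", outcome, " filters")
  out
}

#' Age classes used for group comparisons
#'
#' Classifies decimal ages into the standard chart comparison classes:
#' infants 2 to <6 y, children 6 to <13 y, teenagers 13 to <20 y, adults
#' 20 y and over.  Ages below 2 return `NA`.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `infants`, `children`, `teenagers`, `adults`.
#' @export
age_class <- function(age) {
  cls <- cut(age, breaks = c(2, 6, 13, 20, Inf), right = FALSE,
             labels = c("infants", "children", "teenagers", "adults"))
  cls
}
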