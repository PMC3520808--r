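#' Fit a disease-specific percentile chart
#'
#' The package's central fitting function.  For one outcome (FEV1 in liters
#' or BMI in kg/m^2) and one sex, fits conditional quantile curves at every
#' requested level `tau` by quantile regression on cubic B-spline bases of
#' the covariates (age and/or height).  With two covariates the model is
#' additive by default: a spline in age plus a spline in height sharing one
#' intercept (`tensor = TRUE` fits a full tensor-product basis instead).
#' Each tau is fitted independently by minimizing the pinball loss with the
#' interior-point solver of [fit_quantile()].
#'
#' The registry should normally be passed through [filter_registry()] (and,
#' for registries mixing best/unselected reporting, [apply_correction()])
#' first; the chart records the filters, sample size and basis knots in its
#' metadata.
#'
#' @param registry a [cf_registry()], or a data.frame with the registry
#'   record columns.
#' @param outcome `"fev1"` or `"bmi"`.
#' @param sex `"M"` or `"F"`; only that sex's records are used.
#' @param covariates character subset of `c("age", "height")`.
#' @param taus quantile levels; default the 1st-99th percentiles.
#' @param nodes number of interior spline knots per covariate (default 6),
#'   placed at equally spaced quantiles of the training covariate with
#'   boundary knots at its min/max.  Six interior knots give a 10-function
#'   cubic basis — parsimonious at registry sample sizes yet flexible
#'   enough to track growth-shaped curves without visible approximation
#'   bias.  (Historical chart analyses describe this as a "6-node" cubic
#'   B-spline; if your reading of that phrase is 6 basis functions, pass
#'   `n_basis = 6` instead.)
#' @param n_basis basis functions per covariate spline; overrides `nodes`.
#' @param tensor use a tensor-product basis for two covariates.
#' @param model keep the training data in the object (needed by
#'   [summary.cf_chart()], [residuals.cf_chart()] and self-ranking).
#' @param correction_applied metadata flag recorded in the chart.
#' @return an object of class `cf_chart`.
#' @seealso [predict.cf_chart()], [percentile_rank()], [plot.cf_chart()],
#'   [write_chart_json()]
#' @examples
#' reg <- simulate_registry(sim_config(n_patients_per_sex = 400, seed = 1))
#' ch <- fit_chart(filter_registry(reg, "fev1"), "fev1", "M",
#'                 covariates = "age", taus = c(0.1, 0.5, 0.9))
#' predict(ch, data.frame(age = 18), tau = 0.5)
#' @export
fit_chart <- function(registry, outcome = c("fev1", "bmi"),
                      sex = c("M", "F"), covariates = c("age", "height"),
                      taus = seq(0.01, 0.99, by = 0.01),
                      nodes = 6L, n_basis = nodes + 4L,
                      tensor = FALSE, model = TRUE,
                      correction_applied = NA) {
  outcome <- match.arg(outcome)
  sex <- match.arg(sex)
  covariates <- match.arg(covariates, several.ok = TRUE)
  if (any(taus <= 0 | taus >= 1)) stop_domain("taus must lie in (0, 1)")
  if (is.unsorted(taus, strictly = TRUE))
    stop_domain("taus must be strictly increasing")
  filters <- character(0)
  if (inherits(registry, "cf_registry")) {
    filters <- registry$filters_applied
    rec <- registry$records
  } else rec <- as.data.frame(registry)
  rec <- rec[rec$sex == sex, , drop = FALSE]
  y <- if (outcome == "fev1") rec$fev1_l else
    rec$weight_kg / (rec$height_cm / 100)^2
  dat <- data.frame(age = rec$age_years, height = rec$height_cm)[covariates]
  ok <- stats::complete.cases(dat) & !is.na(y)
  dat <- dat[ok, , drop = FALSE]; y <- y[ok]
  if (!nrow(dat))
    stop_domain("no usable ", outcome, " records for sex ", sex)

  specs <- lapply(dat, spline_spec, n_basis = n_basis)
  X <- chart_design(specs, dat, tensor = tensor)
  if (nrow(X) < ncol(X) + 1L)
    stop_domain("too few records (", nrow(X), ") for a ", ncol(X),
                "-column spline design; reduce n_basis")
  coefs <- vapply(taus, function(tv) fit_quantile(X, y, tv)$coefficients,
                  numeric(ncol(X)))
  coefs <- matrix(coefs, nrow = ncol(X),
                  dimnames = list(colnames(X), sprintf("tau%.2f", taus)))
  structure(list(outcome = outcome, sex = sex, covariates = covariates,
                 taus = taus, specs = specs, coef = coefs, tensor = tensor,
                 n = nrow(X),
                 ranges = lapply(dat, range),
                 filters = filters,
                 correction_applied = correction_applied,
                 data = if (model) cbind(dat, .y = y) else NULL,
                 version = pkg_version()),
            class = "cf_chart")
}

new_chart_data <- function(chart, newdata) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(chart$covariates, names(newdata))
  if (length(missing))
    stop_domain("newdata lacks covariate(s): ", paste(missing, collapse = ", "))
  newdata[chart$covariates]
}

#' Evaluate percentile curves of a fitted chart
#'
#' Evaluates the fitted tau-quantile curve(s) at new covariate values (the
#' spline basis dotted with that tau's coefficients).  Covariates outside
#' the training range are a domain error unless
#' `allow_extrapolation = TRUE`, which evaluates the spline's polynomial
#' tails with a warning.
#'
#' @param object a [fit_chart()] result.
#' @param newdata data.frame with the chart's covariate columns
#'   (`age`, `height`).
#' @param tau levels to evaluate; must belong to the chart's tau grid.
#'   Default: all of them.
#' @param allow_extrapolation see Description.
#' @param rearrange sort the evaluated levels rowwise so curves cannot
#'   cross (used for rank lookup); only meaningful when evaluating several
#'   taus.
#' @param ... unused.
#' @return numeric matrix (rows = newdata rows, columns = taus); a vector
#'   if a single tau is requested.
#' @export
predict.cf_chart <- function(object, newdata, tau = object$taus,
                             allow_extrapolation = FALSE, rearrange = FALSE,
                             ...) {
  idx <- vapply(tau, function(tv) {
    j <- which(abs(object$taus - tv) < 1e-8)
    if (length(j)) j[1L] else NA_integer_
  }, integer(1))
  if (anyNA(idx))
    stop_domain("tau not in the chart's fitted grid: ",
                paste(tau[is.na(idx)], collapse = ", "))
  dat <- new_chart_data(object, newdata)
  X <- chart_design(object$specs, dat,
                    allow_extrapolation = allow_extrapolation,
                    tensor = object$tensor)
  V <- X %*% object$coef[, idx, drop = FALSE]
  if (rearrange && ncol(V) > 1L)
    V <- t(apply(V, 1L, sort))
  colnames(V) <- sprintf("tau%.2f", tau)
  if (length(tau) == 1L) drop(V) else V
}

#' @rdname predict.cf_chart
#' @param chart a [fit_chart()] result.
#' @export
evaluate_chart <- function(chart, tau, newdata, allow_extrapolation = FALSE) {
  predict(chart, newdata = newdata, tau = tau,
          allow_extrapolation = allow_extrapolation)
}

#' Percentile rank of observations against a chart
#'
#' Ranks observed outcome values against the fitted percentile family: the
#' rank is found by locating the observation among the chart's evaluated
#' tau-curves at the observation's covariates, interpolating linearly in
#' tau between adjacent curves.  Because independently fitted quantile
#' curves may cross, the evaluated curve values are monotonically
#' rearranged (sorted) at each covariate point first, which guarantees a
#' well-defined inverse.  Ranks are clamped to the chart's tau range
#' (1-99 by default); clamped observations are flagged in the
#' `below_min`/`above_max` attributes.
#'
#' @param chart a [fit_chart()] result.
#' @param newdata data.frame of covariates (one row per observation).
#' @param observed observed outcome values, same length as `nrow(newdata)`.
#' @param allow_extrapolation passed to [predict.cf_chart()].
#' @return numeric vector of percentile ranks in `[100*min(tau),
#'   100*max(tau)]`, with logical attributes `below_min` and `above_max`.
#' @export
percentile_rank <- function(chart, newdata, observed,
                            allow_extrapolation = FALSE) {
  stopifnot(inherits(chart, "cf_chart"))
  V <- predict(chart, newdata, tau = chart$taus,
               allow_extrapolation = allow_extrapolation, rearrange = TRUE)
  if (is.null(dim(V))) V <- matrix(V, nrow = 1L)
  if (length(observed) != nrow(V))
    stop_domain("observed must have one value per newdata row")
  pct <- 100 * chart$taus
  n <- nrow(V)
  rank <- numeric(n)
  below <- observed < V[, 1L]
  above <- observed >= V[, ncol(V)]
  for (i in seq_len(n)) {
    if (below[i]) { rank[i] <- pct[1L]; next }
    if (above[i]) { rank[i] <- pct[length(pct)]; next }
    j <- findInterval(observed[i], V[i, ])
    gap <- V[i, j + 1L] - V[i, j]
    frac <- if (gap > 0) (observed[i] - V[i, j]) / gap else 0
    rank[i] <- pct[j] + frac * (pct[j + 1L] - pct[j])
  }
  structure(rank, below_min = below, above_max = above)
}

#' @export
print.cf_chart <- function(x, ...) {
  cat(sprintf("CF-specific %s percentile chart, sex %s\n",
              toupper(x$outcome), x$sex))
  cat(sprintf("  %d quantile curves (tau %.2f-%.2f), covariates: %s%s\n",
              length(x$taus), min(x$taus), max(x$taus),
              paste(x$covariates, collapse = " + "),
              if (x$tensor) " (tensor product)" else ""))
  cat(sprintf("  fitted on n = %d records\n", x$n))
  for (nm in names(x$ranges))
    cat(sprintf("  %s range: [%.3g, %.3g]\n", nm,
                x$ranges[[nm]][1], x$ranges[[nm]][2]))
  if (length(x$filters))
    cat("  filters:", paste(x$filters, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.cf_chart <- function(object, ...) object$coef

#' Training-sample summary of a fitted chart
#'
#' Reports, for a few representative levels, the fraction of training
#' observations lying below each fitted curve — the in-sample calibration
#' of the chart (should be close to tau) — plus the median self-rank.
#' Requires the chart to have been fitted with `model = TRUE`.
#'
#' @param object a [fit_chart()] result.
#' @param taus levels to tabulate (subset of the fitted grid).
#' @param ... unused.
#' @export
summary.cf_chart <- function(object, taus = NULL, ...) {
  if (is.null(taus)) {
    want <- c(0.1, 0.25, 0.5, 0.75, 0.9)
    taus <- unique(unlist(lapply(want, function(tv)
      object$taus[abs(object$taus - tv) < 1e-8])))
  }
  if (is.null(object$data))
    stop_domain("chart was fitted with model = FALSE; no training data kept")
  dat <- object$data
  below <- vapply(taus, function(tv) {
    v <- predict(object, dat, tau = tv)
    mean(dat$.y < v)
  }, numeric(1))
  ranks <- percentile_rank(object, dat, dat$.y)
  out <- list(chart = object,
              coverage = data.frame(tau = taus, frac_below = below),
              median_self_rank = stats::median(ranks))
  class(out) <- "summary.cf_chart"
  out
}

#' @export
print.summary.cf_chart <- function(x, ...) {
  print(x$chart)
  cat("\nIn-sample calibration (fraction of training data below curve):\n")
  print(transform(x$coverage, frac_below = round(frac_below, 4)),
        row.names = FALSE)
  cat(sprintf("\nMedian self-rank of training data: %.1f (expected 50)\n",
              x$median_self_rank))
  invisible(x)
}

#' @export
residuals.cf_chart <- function(object, tau = 0.5, ...) {
  if (is.null(object$data))
    stop_domain("chart was fitted with model = FALSE; no training data kept")
  object$data$.y - predict(object, object$data, tau = tau)
}

#' @export
fitted.cf_chart <- function(object, tau = 0.5, ...) {
  if (is.null(object$data))
    stop_domain("chart was fitted with model = FALSE; no training data kept")
  predict(object, object$data, tau = tau)
}

#' Plot a percentile chart
#'
#' Draws selected percentile curves against the chart's first covariate,
#' holding any second covariate at its training median, optionally shading
#' a [bootstrap_band()] around the median curve.
#'
#' @param x a [fit_chart()] result.
#' @param taus levels to draw (subset of the fitted grid).
#' @param band optional `bootstrap_band` for the shaded envelope.
#' @param n_grid evaluation points along the covariate.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cf_chart <- function(x, taus = NULL, band = NULL, n_grid = 100L, ...) {
  if (is.null(taus)) {
    want <- c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95)
    taus <- unique(unlist(lapply(want, function(tv)
      x$taus[abs(x$taus - tv) < 1e-8])))
    if (!length(taus)) taus <- x$taus[ceiling(length(x$taus) / 2)]
  }
  cv <- x$covariates[1L]
  grid <- seq(x$ranges[[cv]][1], x$ranges[[cv]][2], length.out = n_grid)
  nd <- data.frame(grid)
  names(nd) <- cv
  if (length(x$covariates) > 1L) {
    cv2 <- x$covariates[2L]
    nd[[cv2]] <- if (!is.null(x$data)) stats::median(x$data[[cv2]]) else
      mean(x$ranges[[cv2]])
  }
  V <- predict(x, nd, tau = taus)
  if (is.null(dim(V))) V <- matrix(V, ncol = 1L)
  ylab <- if (x$outcome == "fev1") "FEV1 (L)" else expression(BMI ~ (kg/m^2))
  graphics::matplot(grid, V, type = "l", lty = 1,
                    col = grDevices::grey(seq(0.7, 0, length.out = ncol(V))),
                    xlab = paste0(cv, if (cv == "age") " (years)" else " (cm)"),
                    ylab = ylab,
                    main = sprintf("%s percentiles, sex %s",
                                   toupper(x$outcome), x$sex), ...)
  if (!is.null(band)) {
    graphics::polygon(c(band$grid, rev(band$grid)),
                      c(band$lower, rev(band$upper)),
                      col = grDevices::adjustcolor("grey", 0.4), border = NA)
  }
  graphics::text(rep(grid[n_grid], ncol(V)), V[n_grid, ],
                 labels = paste0("P", round(100 * taus)), pos = 4, cex = 0.6,
                 xpd = NA)
  invisible(x)
}
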