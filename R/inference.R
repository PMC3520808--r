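# Bootstrap inference for percentile charts: pointwise confidence bands,
# chart-vs-chart AUC-difference tests, chart correlation and group
# median-percentile comparisons.  The resampling unit throughout is the
# PATIENT — all of a patient's records (and visits) move together — which is
# conservative under repeated measures.

resample_patients <- function(registry) {
  rec <- registry$records
  by_id <- split(seq_len(nrow(rec)), rec$patient_id)
  take <- sample.int(length(by_id), length(by_id), replace = TRUE)
  picked <- by_id[take]
  idx <- unlist(picked, use.names = FALSE)
  out <- registry
  out$records <- rec[idx, , drop = FALSE]
  # duplicated draws get fresh ids so patients stay distinct units
  out$records$patient_id <- rep(seq_along(take), times = lengths(picked))
  out$visits <- NULL
  out
}

#' Pointwise bootstrap confidence band for a percentile curve
#'
#' Resamples patients with replacement `B` times, refits the tau-quantile
#' curve on each replicate and takes pointwise percentile envelopes of the
#' refitted curves over a covariate grid.  Replicates whose refit fails are
#' dropped and counted; more than 10 percent failures is an error.  The
#' envelope is widened, if necessary, to contain the full-sample point
#' estimate at every grid point.
#'
#' @param registry filtered [cf_registry()] to resample.
#' @param outcome,sex,covariates,n_basis chart specification as in
#'   [fit_chart()] (a single covariate is typical for display bands).
#' @param tau quantile level of the curve.
#' @param grid data.frame of covariate values at which the band is
#'   evaluated (or a numeric vector for one covariate).
#' @param B number of bootstrap replicates (>= 2).
#' @param level nominal pointwise confidence level.
#' @param seed integer seed; identical seeds reproduce the band exactly.
#' @return object of class `bootstrap_band`: list with `grid`, `estimate`,
#'   `lower`, `upper`, `tau`, `level`, `B`, `failed`, `seed`.
#' @export
bootstrap_band <- function(registry, outcome, sex, covariates = "age",
                           tau = 0.5, grid, B = 200L, level = 0.95,
                           seed = NULL, n_basis = 10L) {
  if (B < 2) stop_domain("B must be at least 2")
  if (!is.data.frame(grid)) {
    grid <- data.frame(grid)
    names(grid) <- covariates[1L]
  }
  fit0 <- fit_chart(registry, outcome, sex, covariates, taus = tau,
                    n_basis = n_basis, model = FALSE)
  est <- predict(fit0, grid, tau = tau)
  reps <- matrix(NA_real_, B, nrow(grid))
  failed <- 0L
  with_seed(seed, for (b in seq_len(B)) {
    rb <- resample_patients(registry)
    fb <- tryCatch(fit_chart(rb, outcome, sex, covariates, taus = tau,
                             n_basis = n_basis, model = FALSE),
                   error = function(e) NULL)
    vb <- if (is.null(fb)) NULL else
      tryCatch(suppressWarnings(
        predict(fb, grid, tau = tau, allow_extrapolation = TRUE)),
        error = function(e) NULL)
    if (is.null(vb)) failed <- failed + 1L else reps[b, ] <- vb
  })
  if (failed > 0.1 * B)
    stop_domain(failed, " of ", B, " bootstrap refits failed")
  alpha <- (1 - level) / 2
  qs <- apply(reps[stats::complete.cases(reps), , drop = FALSE], 2L,
              stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  structure(list(grid = grid[[1L]], grid_frame = grid,
                 estimate = as.numeric(est),
                 lower = pmin(qs[1L, ], est), upper = pmax(qs[2L, ], est),
                 tau = tau, level = level, B = B, failed = failed,
                 seed = seed),
            class = "bootstrap_band")
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf(
    "Bootstrap band: tau = %.2f, %g%% pointwise, B = %d (%d failed)\n",
    x$tau, 100 * x$level, x$B, x$failed))
  cat(sprintf("  grid: %d points in [%.3g, %.3g]; mean half-width %.4g\n",
              length(x$grid), min(x$grid), max(x$grid),
              mean((x$upper - x$lower) / 2)))
  invisible(x)
}

#' Area-under-curve difference between two curves
#'
#' Trapezoid integral of `curveA - curveB` over a common grid — the summary
#' statistic used to compare two percentile charts.  Antisymmetric in its
#' arguments.
#'
#' @param curveA,curveB numeric curve values on `grid`.
#' @param grid increasing numeric grid (>= 2 points).
#' @return signed area (outcome units x covariate units).
#' @export
auc_difference <- function(curveA, curveB, grid) {
  if (length(grid) < 2) stop_domain("grid needs at least 2 points")
  if (length(curveA) != length(grid) || length(curveB) != length(grid))
    stop_domain("curves and grid must have equal length")
  d <- curveA - curveB
  sum(diff(grid) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' Bootstrap test for the AUC difference between two charts
#'
#' Fits the tau-quantile curve on each registry, takes the observed
#' [auc_difference()] over the grid, and obtains a two-sided equal-tail
#' p-value from the bootstrap distribution of the statistic recentered at
#' zero: both registries are resampled (patient-level) independently `B`
#' times, the recentered replicates `H_b = D*_b - D_obs` form the null
#' distribution, and
#' `p = 2 min{ (1 + #{H_b >= D_obs}) / (B+1), (1 + #{H_b <= D_obs}) / (B+1) }`.
#' The percentile confidence interval of the statistic is reported
#' alongside.
#'
#' @param registryA,registryB filtered registries to compare.
#' @param outcome,sex,covariates,n_basis chart specification as in
#'   [fit_chart()].
#' @param tau quantile level of the compared curves.
#' @param grid numeric grid (first covariate) over which curves are
#'   integrated; defaults to 50 points over the common covariate range.
#' @param B bootstrap replicates (>= 100 recommended).
#' @param level confidence level of the reported interval.
#' @param seed integer seed.
#' @return object of class `cf_test`: list with `statistic` (observed AUC
#'   difference), `ci`, `p_value`, `B`, `seed`, `adjustment`.
#' @export
auc_difference_test <- function(registryA, registryB, outcome, sex,
                                covariates = "age", tau = 0.5, grid = NULL,
                                B = 999L, level = 0.95, seed = NULL,
                                n_basis = 10L) {
  fitA <- fit_chart(registryA, outcome, sex, covariates, taus = tau,
                    n_basis = n_basis, model = FALSE)
  fitB <- fit_chart(registryB, outcome, sex, covariates, taus = tau,
                    n_basis = n_basis, model = FALSE)
  cv <- covariates[1L]
  if (is.null(grid)) {
    lo <- max(fitA$ranges[[cv]][1], fitB$ranges[[cv]][1])
    hi <- min(fitA$ranges[[cv]][2], fitB$ranges[[cv]][2])
    if (hi <= lo) stop_domain("registries have no common covariate range")
    grid <- seq(lo, hi, length.out = 50L)
  }
  nd <- data.frame(grid); names(nd) <- cv
  ev <- function(fit)
    suppressWarnings(predict(fit, nd, tau = tau, allow_extrapolation = TRUE))
  d_obs <- auc_difference(ev(fitA), ev(fitB), grid)
  d_boot <- rep(NA_real_, B)
  failed <- 0L
  with_seed(seed, for (b in seq_len(B)) {
    db <- tryCatch({
      fa <- fit_chart(resample_patients(registryA), outcome, sex, covariates,
                      taus = tau, n_basis = n_basis, model = FALSE)
      fb <- fit_chart(resample_patients(registryB), outcome, sex, covariates,
                      taus = tau, n_basis = n_basis, model = FALSE)
      auc_difference(ev(fa), ev(fb), grid)
    }, error = function(e) NA_real_)
    if (is.na(db)) failed <- failed + 1L
    d_boot[b] <- db
  })
  if (failed > 0.1 * B)
    stop_domain(failed, " of ", B, " bootstrap replicates failed")
  d_boot <- d_boot[!is.na(d_boot)]
  h <- d_boot - d_obs                  # bootstrap null: statistic recentered at 0
  nb <- length(h)
  p <- min(1, 2 * min((1 + sum(h >= d_obs)) / (nb + 1),
                      (1 + sum(h <= d_obs)) / (nb + 1)))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(d_boot, c(alpha, 1 - alpha), names = FALSE)
  structure(list(statistic = d_obs, statistic_name = "AUC difference",
                 ci = ci, level = level, p_value = p,
                 B = length(d_boot), seed = seed, adjustment = "none"),
            class = "cf_test")
}

#' @export
print.cf_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, %g%% CI [%.4g, %.4g], p = %.4g (B = %d%s)\n",
              x$statistic_name, x$statistic, 100 * x$level, x$ci[1], x$ci[2],
              x$p_value, x$B,
              if (x$adjustment != "none") paste0(", ", x$adjustment) else ""))
  invisible(x)
}

#' Correlation between two fitted charts
#'
#' Pearson correlation of the two charts' curve values evaluated over a
#' tau-by-covariate lattice: all shared taus crossed with `n_grid` equally
#' spaced points over the common range of the first covariate (any second
#' covariate held at the midpoint of its common range).  A chart that is
#' constant over the lattice has zero variance and is an error.
#'
#' @param chartA,chartB [fit_chart()] results with the same outcome and
#'   covariates.
#' @param taus levels to evaluate; defaults to the shared tau grid.
#' @param n_grid lattice points along the first covariate.
#' @return Pearson correlation coefficient.
#' @export
chart_correlation <- function(chartA, chartB, taus = NULL, n_grid = 50L) {
  if (chartA$outcome != chartB$outcome ||
      !identical(chartA$covariates, chartB$covariates))
    stop_domain("charts must share outcome and covariates")
  if (is.null(taus)) taus <- intersect(chartA$taus, chartB$taus)
  if (!length(taus)) stop_domain("charts share no tau levels")
  cv <- chartA$covariates[1L]
  lo <- max(chartA$ranges[[cv]][1], chartB$ranges[[cv]][1])
  hi <- min(chartA$ranges[[cv]][2], chartB$ranges[[cv]][2])
  if (hi <= lo) stop_domain("charts have no common covariate range")
  nd <- data.frame(seq(lo, hi, length.out = n_grid))
  names(nd) <- cv
  if (length(chartA$covariates) > 1L) {
    cv2 <- chartA$covariates[2L]
    nd[[cv2]] <- mean(c(max(chartA$ranges[[cv2]][1], chartB$ranges[[cv2]][1]),
                        min(chartA$ranges[[cv2]][2], chartB$ranges[[cv2]][2])))
  }
  VA <- as.numeric(predict(chartA, nd, tau = taus))
  VB <- as.numeric(predict(chartB, nd, tau = taus))
  tol <- 1e-10
  if (stats::sd(VA) <= tol * (1 + mean(abs(VA))) ||
      stats::sd(VB) <= tol * (1 + mean(abs(VB))))
    stop_domain("chart constant over the lattice: correlation undefined")
  stats::cor(VA, VB)
}

#' Bonferroni-adjusted group median percentile ranks
#'
#' For each group-by-age-class cell of ranked patients, reports the median
#' percentile rank with a patient-level bootstrap percentile confidence
#' interval at the Bonferroni-adjusted level `1 - alpha/m`, and flags cells
#' whose interval excludes the expected median of 50 (the population median
#' rank of a self-referenced chart).  Empty cells are skipped with a
#' warning.
#'
#' @param ranks data.frame with columns `rank` (percentile in `[1, 99]`),
#'   `group`, `age_class`, and optionally `patient_id` (the resampling
#'   unit; rows are resampled independently if absent).
#' @param B bootstrap replicates.
#' @param alpha family-wise significance level.
#' @param m_comparisons number of comparisons for the Bonferroni rule;
#'   defaults to (number of groups) x (number of age classes).
#' @param seed integer seed.
#' @return data.frame of class `group_median_table` with one row per cell:
#'   `group`, `age_class`, `n`, `median_rank`, `ci_lo`, `ci_hi`,
#'   `excludes_50`; attributes `level`, `m`, `B`, `seed`.
#' @export
group_median_percentile <- function(ranks, B = 999L, alpha = 0.05,
                                    m_comparisons = NULL, seed = NULL) {
  ranks <- as.data.frame(ranks)
  if (!all(c("rank", "group", "age_class") %in% names(ranks)))
    stop_domain("ranks needs columns rank, group, age_class")
  if (any(ranks$rank < 1 | ranks$rank > 99, na.rm = TRUE))
    stop_domain("ranks must lie in [1, 99]")
  ranks <- ranks[!is.na(ranks$rank) & !is.na(ranks$age_class), ]
  groups <- unique(ranks$group)
  classes <- if (is.factor(ranks$age_class)) levels(ranks$age_class) else
    unique(ranks$age_class)
  if (is.null(m_comparisons))
    m_comparisons <- length(groups) * length(classes)
  level <- 1 - alpha / m_comparisons
  out <- expand.grid(group = groups, age_class = classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- 0L
  out$median_rank <- out$ci_lo <- out$ci_hi <- NA_real_
  out$excludes_50 <- NA
  with_seed(seed, for (r in seq_len(nrow(out))) {
    cell <- ranks[ranks$group == out$group[r] &
                    ranks$age_class == out$age_class[r], ]
    if (!nrow(cell)) {
      warning("empty cell skipped: ", out$group[r], " / ", out$age_class[r])
      next
    }
    out$n[r] <- nrow(cell)
    out$median_rank[r] <- stats::median(cell$rank)
    unit <- if ("patient_id" %in% names(cell)) cell$patient_id else
      seq_len(nrow(cell))
    by_unit <- split(cell$rank, unit)
    meds <- vapply(seq_len(B), function(b) {
      take <- sample.int(length(by_unit), length(by_unit), replace = TRUE)
      stats::median(unlist(by_unit[take], use.names = FALSE))
    }, numeric(1))
    qa <- (1 - level) / 2
    ci <- stats::quantile(meds, c(qa, 1 - qa), names = FALSE)
    out$ci_lo[r] <- min(ci[1], out$median_rank[r])
    out$ci_hi[r] <- max(ci[2], out$median_rank[r])
    out$excludes_50[r] <- out$ci_lo[r] > 50 || out$ci_hi[r] < 50
  })
  structure(out, class = c("group_median_table", "data.frame"),
            level = level, m = m_comparisons, alpha = alpha, B = B,
            seed = seed)
}

#' @export
print.group_median_table <- function(x, ...) {
  cat(sprintf(
    "Group median percentile ranks (Bonferroni m = %d, per-cell level %.4g%%)\n",
    attr(x, "m"), 100 * attr(x, "level")))
  df <- as.data.frame(x)
  df$median_rank <- round(df$median_rank, 1)
  df$ci_lo <- round(df$ci_lo, 1); df$ci_hi <- round(df$ci_hi, 1)
  df$flag <- ifelse(!is.na(df$excludes_50) & df$excludes_50, "*", "")
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Rank-sum comparison of two groups of percentile ranks
#'
#' Two-sided Mann-Whitney-Wilcoxon test that the percentile-rank
#' distributions of two groups coincide (exact for small samples without
#' ties, normal approximation otherwise).
#'
#' @param ranksA,ranksB numeric vectors of percentile ranks.
#' @return two-sided p-value.
#' @export
rank_compare_groups <- function(ranksA, ranksB) {
  if (!length(ranksA) || !length(ranksB))
    stop_domain("both groups must be nonempty")
  stats::wilcox.test(ranksA, ranksB, alternative = "two.sided",
                     exact = NULL)$p.value
}

#' Bonferroni-adjusted per-comparison level
#'
#' `alpha / m`: the per-comparison significance level under the Bonferroni
#' rule for `m` comparisons.
#'
#' @param alpha family-wise level.
#' @param m number of comparisons.
#' @export
bonferroni_level <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1 || m < 1) stop_domain("need 0<alpha<1, m>=1")
  alpha / m
}
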