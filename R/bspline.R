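#' Cubic B-spline basis specification
#'
#' Defines the spline basis used for the percentile charts: a cubic B-spline
#' with a fixed number of basis functions ("nodes").  Interior knots are
#' placed at equally spaced quantiles of the training covariate and boundary
#' knots at its minimum and maximum, so the basis is fully determined by the
#' data it was built from and is recorded verbatim in fitted charts for
#' reproducibility.
#'
#' With `degree = 3` and `n_basis` basis functions there are
#' `n_basis - degree - 1` interior knots; `n_basis = 6` (the default used for
#' the charts) therefore puts interior knots at the 1/3 and 2/3 quantiles.
#'
#' @param x numeric vector of training covariate values used to place knots,
#'   or `NULL` if `boundary` and `interior` are given explicitly.
#' @param n_basis number of basis functions (>= degree + 1).
#' @param degree polynomial degree (cubic by default).
#' @param boundary length-2 numeric, boundary knots; defaults to `range(x)`.
#' @param interior numeric vector of interior knots; defaults to quantiles
#'   of `x`.
#' @return an object of class `spline_spec`.
#' @examples
#' sp <- spline_spec(runif(100, 6, 40))
#' rowSums(bspline_basis(sp, c(10, 20, 30)))  # partition of unity
#' @export
spline_spec <- function(x = NULL, n_basis = 6L, degree = 3L,
                        boundary = NULL, interior = NULL) {
  n_basis <- as.integer(n_basis)
  degree <- as.integer(degree)
  if (n_basis < degree + 1L)
    stop_domain("n_basis must be at least degree + 1 (got ", n_basis, ")")
  if (is.null(boundary)) {
    if (is.null(x)) stop_domain("either x or boundary knots must be supplied")
    boundary <- range(x, na.rm = TRUE)
  }
  if (boundary[2] <= boundary[1])
    stop_domain("degenerate boundary knots: covariate has no spread")
  n_int <- n_basis - degree - 1L
  if (is.null(interior)) {
    interior <- if (n_int > 0L) {
      if (is.null(x)) stop_domain("x needed to place interior knots")
      as.numeric(stats::quantile(x, probs = seq_len(n_int) / (n_int + 1L),
                                 na.rm = TRUE, names = FALSE, type = 7))
    } else numeric(0)
  }
  interior <- as.numeric(interior)
  if (length(interior) != n_int)
    stop_domain("expected ", n_int, " interior knots, got ", length(interior))
  if (is.unsorted(interior))
    stop_domain("interior knots must be nondecreasing")
  if (n_int > 0L && (min(interior) <= boundary[1] || max(interior) >= boundary[2]))
    stop_domain("interior knots must lie strictly inside the boundary knots")
  structure(list(degree = degree, n_basis = n_basis,
                 boundary = as.numeric(boundary), interior = interior),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat(sprintf("B-spline basis: degree %d, %d basis functions\n",
              x$degree, x$n_basis))
  cat(sprintf("  boundary knots: [%.4g, %.4g]\n", x$boundary[1], x$boundary[2]))
  if (length(x$interior))
    cat("  interior knots:", paste(signif(x$interior, 5), collapse = ", "), "\n")
  invisible(x)
}

# Extended knot vector with boundary knots repeated degree+1 times.
extended_knots <- function(spec) {
  c(rep(spec$boundary[1], spec$degree + 1L), spec$interior,
    rep(spec$boundary[2], spec$degree + 1L))
}

#' Evaluate a B-spline basis
#'
#' Evaluates all basis functions of a [spline_spec()] at covariate values `x`
#' using the Cox-de Boor recursion (span-local de Boor algorithm).  Inside
#' the boundary knots the basis functions are nonnegative and sum to one.
#' Values outside the boundary are a domain error unless
#' `allow_extrapolation = TRUE`, in which case the polynomial pieces of the
#' first/last knot span are extended (entries may then be negative).
#'
#' @param spec a [spline_spec()].
#' @param x numeric vector of evaluation points.
#' @param allow_extrapolation evaluate polynomial tails outside the boundary
#'   knots instead of raising an error.
#' @return numeric matrix, `length(x)` rows by `spec$n_basis` columns.
#' @export
bspline_basis <- function(spec, x, allow_extrapolation = FALSE) {
  stopifnot(inherits(spec, "spline_spec"))
  x <- as.numeric(x)
  if (anyNA(x)) stop_domain("missing values in spline covariate")
  lo <- spec$boundary[1]; hi <- spec$boundary[2]
  out <- x < lo | x > hi
  if (any(out) && !allow_extrapolation)
    stop_domain("covariate value outside the training range [",
                signif(lo, 6), ", ", signif(hi, 6),
                "]; no extrapolation by default")
  if (any(out))
    warning("extrapolating spline polynomial tails for ", sum(out),
            " value(s) outside [", signif(lo, 6), ", ", signif(hi, 6), "]")
  d <- spec$degree
  kn <- extended_knots(spec)
  n_spans <- spec$n_basis - d          # number of non-degenerate intervals
  # span index within interior knot sequence: 1..n_spans, clamped (clamping
  # also selects the boundary polynomial piece for extrapolated points)
  breaks <- c(spec$boundary[1], spec$interior, spec$boundary[2])
  span <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  B <- matrix(0, length(x), spec$n_basis)
  for (sp in unique(span)) {
    idx <- which(span == sp)
    xi <- x[idx]
    off <- sp + d                      # index of t_span in extended knots
    # de Boor basis-function algorithm, vectorized over points in this span
    N <- matrix(0, length(xi), d + 1L)
    N[, 1] <- 1
    left <- matrix(0, length(xi), d)
    right <- matrix(0, length(xi), d)
    for (j in seq_len(d)) {
      left[, j] <- xi - kn[off + 1L - j]
      right[, j] <- kn[off + j] - xi
      saved <- numeric(length(xi))
      for (r in seq_len(j)) {
        den <- right[, r] + left[, j - r + 1L]
        temp <- N[, r] / den
        temp[den == 0] <- 0
        N[, r] <- saved + right[, r] * temp
        saved <- left[, j - r + 1L] * temp
      }
      N[, j + 1L] <- saved
    }
    B[idx, (sp):(sp + d)] <- N
  }
  colnames(B) <- paste0("b", seq_len(spec$n_basis))
  B
}

# Additive design matrix for one or two covariates.  With two covariates the
# second basis drops its first column (each B-spline basis spans the
# intercept, so keeping both full bases would be rank-deficient by one).
# With `tensor = TRUE` a full tensor-product basis is built instead.
chart_design <- function(specs, data, allow_extrapolation = FALSE,
                         tensor = FALSE) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  bases <- lapply(names(specs), function(nm) {
    bspline_basis(specs[[nm]], data[[nm]], allow_extrapolation)
  })
  names(bases) <- names(specs)
  if (length(bases) == 1L) return(bases[[1L]])
  if (tensor) {
    A <- bases[[1L]]; Bm <- bases[[2L]]
    X <- matrix(0, nrow(A), ncol(A) * ncol(Bm))
    k <- 0L
    for (j in seq_len(ncol(Bm))) for (i in seq_len(ncol(A))) {
      k <- k + 1L
      X[, k] <- A[, i] * Bm[, j]
    }
    colnames(X) <- paste0("t", seq_len(ncol(X)))
    return(X)
  }
  X <- cbind(bases[[1L]], bases[[2L]][, -1L, drop = FALSE])
  colnames(X) <- c(paste0(names(specs)[1], "_b", seq_len(ncol(bases[[1L]]))),
                   paste0(names(specs)[2], "_b", 1L + seq_len(ncol(bases[[2L]]) - 1L)))
  X
}
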