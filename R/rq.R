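#' Pinball (check) loss
#'
#' The asymmetric absolute loss minimized by quantile regression:
#' `r * (tau - (r < 0))` for a residual `r` and quantile level `tau`.
#'
#' @param tau quantile level in (0, 1).
#' @param residual numeric vector of residuals (observed minus fitted).
#' @return numeric vector of losses.
#' @examples
#' pinball_loss(0.5, 2)    # 1
#' pinball_loss(0.25, -4)  # 3
#' @export
pinball_loss <- function(tau, residual) {
  if (any(tau <= 0 | tau >= 1)) stop_domain("tau must lie strictly in (0, 1)")
  residual * (tau - (residual < 0))
}

#' Fit one conditional quantile by linear programming
#'
#' Minimizes the total pinball loss `sum(pinball_loss(tau, y - X b))` over
#' coefficient vectors `b`.  The problem is solved as a linear program: a
#' primal-dual interior-point iteration on the bounded-variable dual
#' (`max a'y` subject to `X'a = (1 - tau) X'1`, `0 <= a <= 1`) is run to a
#' small optimality gap, then the solution is polished onto an exact vertex
#' (a coefficient vector interpolating p observations) whenever that does not
#' increase the loss.  Solutions need not be unique; compare achieved losses,
#' not coefficients.
#'
#' @param X design matrix (rows = observations; must have full column rank).
#' @param y numeric response vector.
#' @param tau quantile level in (0, 1).
#' @param tol relative optimality-gap tolerance.
#' @param max_iter interior-point iteration cap.
#' @return a list with elements `coefficients`, `fitted`, `residuals`,
#'   `loss` (achieved total pinball loss), `tau`, `iterations`, `gap`.
#' @export
fit_quantile <- function(X, y, tau, tol = 1e-9, max_iter = 200L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_domain("length(y) must equal nrow(X)")
  if (length(tau) != 1 || tau <= 0 || tau >= 1)
    stop_domain("tau must lie strictly in (0, 1)")
  if (n < p)
    stop_domain("need at least as many observations (", n,
                ") as design columns (", p, ")")
  qrx <- qr(X)
  if (qrx$rank < p)
    stop_domain("design matrix is rank deficient (rank ", qrx$rank, " < ", p,
                " columns); reduce the number of spline nodes")

  fit <- rq_ip(X, y, tau, tol = tol, max_iter = max_iter)
  b <- rq_polish(X, y, tau, fit$b, qr_tol = 1e-10)
  r <- y - drop(X %*% b)
  list(coefficients = b, fitted = y - r, residuals = r,
       loss = sum(pinball_loss(tau, r)), tau = tau,
       iterations = fit$iterations, gap = fit$gap)
}

# Primal-dual interior point with Mehrotra predictor-corrector on
#   min -y'a  s.t.  X'a = (1-tau) X'1,  a + s = 1,  a, s >= 0.
# Primal/bound feasibility holds exactly from the start (a = (1-tau)1) and is
# preserved by the Newton directions, so only complementarity is driven to 0.
# The equality multiplier beta satisfies z - w = -y - X beta at optimality,
# i.e. the quantile-regression coefficients are b = -beta.
rq_ip <- function(X, y, tau, tol = 1e-9, max_iter = 200L) {
  n <- nrow(X); p <- ncol(X)
  a <- rep(1 - tau, n)
  s <- rep(tau, n)
  # dual start from a least-squares fit
  beta <- -qr.coef(qr(X), y)
  dr <- -y - drop(X %*% beta)          # must equal z - w
  shift <- pmax(1e-4, 0.1 * mean(abs(dr)))
  z <- pmax(dr, 0) + shift
  w <- z - dr
  yty <- sum(y) * (1 - tau)
  best <- list(b = -beta, gap = Inf)
  it <- 0L
  for (it in seq_len(max_iter)) {
    b <- -beta
    loss <- sum(pinball_loss(tau, y - drop(X %*% b)))
    dual_obj <- sum(y * a) - yty
    gap <- loss - dual_obj
    if (gap < best$gap) best <- list(b = b, gap = gap)
    if (gap <= tol * (abs(loss) + 1)) break

    q <- 1 / (z / a + w / s)
    rzw <- z - w
    M <- crossprod(X * sqrt(q))
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) break             # numerically singular; keep best
    solveM <- function(v) backsolve(ch, forwardsolve(t(ch), v))

    # affine (predictor) direction
    dbeta_a <- solveM(crossprod(X, q * rzw))
    da_a <- q * (drop(X %*% dbeta_a) - rzw)
    dz_a <- -z - (z / a) * da_a
    dw_a <- -w + (w / s) * da_a
    alP_a <- step_len(a, da_a, s, -da_a)
    alD_a <- step_len(z, dz_a, w, dw_a)
    mu <- sum(a * z + s * w)
    gap_aff <- sum((a + alP_a * da_a) * (z + alD_a * dz_a) +
                   (s - alP_a * da_a) * (w + alD_a * dw_a))
    sigma <- (gap_aff / mu)^3
    mu_t <- sigma * mu / (2 * n)

    # corrected direction
    xi <- mu_t * (1 / a - 1 / s) - (da_a * dz_a) / a - (da_a * dw_a) / s
    dbeta <- solveM(crossprod(X, q * (rzw - xi)))
    da <- q * (drop(X %*% dbeta) - rzw + xi)
    dz <- mu_t / a - z - (z / a) * da - (da_a * dz_a) / a
    dw <- mu_t / s - w + (w / s) * da + (da_a * dw_a) / s
    alP <- step_len(a, da, s, -da)
    alD <- step_len(z, dz, w, dw)
    a <- a + alP * da
    s <- s - alP * da
    z <- z + alD * dz
    w <- w + alD * dw
    beta <- beta + alD * dbeta
    if (sum(a * z + s * w) < 1e-14 * n) {
      b <- -beta
      loss <- sum(pinball_loss(tau, y - drop(X %*% b)))
      gap <- loss - (sum(y * a) - yty)
      if (gap < best$gap) best <- list(b = b, gap = gap)
      break
    }
  }
  list(b = best$b, gap = best$gap, iterations = it)
}

# largest step in (0, 1] keeping u + al*du > 0 and v + al*dv > 0, damped
step_len <- function(u, du, v, dv, damp = 0.9995) {
  i <- du < 0; j <- dv < 0
  m <- min(if (any(i)) min(u[i] / -du[i]) else Inf,
           if (any(j)) min(v[j] / -dv[j]) else Inf)
  min(1, damp * m)
}

# Snap an interior-point solution onto an optimal vertex: quantile-regression
# solutions interpolate p observations, so refit exactly through the p
# smallest-|residual| points (choosing a linearly independent subset) and keep
# the result if it does not increase the loss.
rq_polish <- function(X, y, tau, b, qr_tol = 1e-10, rounds = 3L) {
  n <- nrow(X); p <- ncol(X)
  loss <- sum(pinball_loss(tau, y - drop(X %*% b)))
  prev_idx <- integer(0)
  for (k in seq_len(rounds)) {
    r <- y - drop(X %*% b)
    ord <- order(abs(r))
    take <- seq_len(min(n, max(4L * p, p + 4L)))
    Xk <- X[ord[take], , drop = FALSE]
    # selecting independent rows == selecting pivot columns of t(Xk)
    qrt <- qr(t(Xk), tol = qr_tol)
    if (qrt$rank < p) break
    idx <- ord[take][qrt$pivot[seq_len(p)]]
    if (setequal(idx, prev_idx)) break
    prev_idx <- idx
    b_try <- tryCatch(qr.solve(X[idx, , drop = FALSE], y[idx], tol = qr_tol),
                      error = function(e) NULL)
    if (is.null(b_try)) break
    loss_try <- sum(pinball_loss(tau, y - drop(X %*% b_try)))
    if (loss_try <= loss + 1e-12 * (1 + abs(loss))) {
      if (loss_try >= loss - 1e-14 * (1 + abs(loss))) { b <- b_try; loss <- loss_try; break }
      b <- b_try; loss <- loss_try
    } else break
  }
  b
}
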