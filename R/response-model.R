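#' Gamma response function for scan speed
#'
#' The canonical response of scan speed to CS onset is modeled as a shifted
#' gamma probability density scaled by an amplitude:
#' `y(t) = A / (mu^k Gamma(k)) * (t - t0)^(k-1) * exp(-(t - t0) / mu)`
#' for `t > t0` and 0 otherwise. `t0` is the onset latency in seconds
#' relative to CS onset (it may be negative: the fitted response begins its
#' support before CS onset), `k > 0` the shape, `mu > 0` the scale in
#' seconds, and `A` the amplitude; the function integrates to `A` over
#' `t > t0` and, for `k > 1`, peaks at `t0 + (k - 1) * mu`.
#'
#' @param t Numeric vector of times (s, relative to CS onset).
#' @param t0 Onset latency (s).
#' @param k Shape parameter (> 0).
#' @param mu Scale parameter (s, > 0).
#' @param A Amplitude (integral of the response).
#' @return Response values at `t`.
#' @examples
#' t <- seq(-2, 6, by = 0.01)
#' y <- gamma_rf(t, t0 = -1.90203, k = 10.0913, mu = 0.42125, A = 1)
#' t[which.max(y)] # about 1.93 s
#' @export
gamma_rf <- function(t, t0, k, mu, A = 1) {
  if (!is.finite(k) || k <= 0 || !is.finite(mu) || mu <= 0) {
    stop("shape k and scale mu must be finite and strictly positive",
         call. = FALSE)
  }
  A * stats::dgamma(t - t0, shape = k, scale = mu)
}

#' @rdname gamma_rf
#' @return `gamma_rf_mode()` returns the peak time `t0 + (k - 1) * mu`
#'   (for `k > 1`).
#' @export
gamma_rf_mode <- function(t0, k, mu) {
  if (k <= 1) return(t0)
  t0 + (k - 1) * mu
}

#' Fit the gamma response function to a difference time series
#'
#' Fits `(t0, k, mu, A)` by ordinary least squares with the Nelder-Mead
#' simplex, to the (smoothed) difference of grand-mean scan-speed series
#' between CS- and CS+ conditions. The fit is repeated from a fixed coarse
#' grid of starting points (default 8: onsets crossed with
#' fast/slow shape-scale pairs) and the lowest-SSR convergent solution is
#' returned; shape and scale are optimized on the log scale to enforce
#' positivity.
#'
#' @param t Time grid (s, relative to CS onset).
#' @param y Difference series on `t` (same length).
#' @param starts Optional data frame of starting values with columns `t0`,
#'   `k`, `mu`; defaults to the documented 8-point grid.
#' @param reltol Relative SSR convergence tolerance (default 1e-8).
#' @param maxit Maximum simplex iterations per start (default 5000).
#' @return A list with `params` (named: t0, k, mu, A), `ssr`, `converged`,
#'   and `n_starts`.
#' @export
fit_rf <- function(t, y, starts = NULL, reltol = 1e-8, maxit = 5000) {
  stopifnot(length(t) == length(y))
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    stop("time grid and series must be finite", call. = FALSE)
  }
  if (is.null(starts)) {
    starts <- expand.grid(t0 = c(-3, -2, -1, 0),
                          k = c(3, 10), mu = c(1, 0.4))
    starts <- starts[c(1:4, 13:16), ] # pair slow (k=3, mu=1), fast (k=10, mu=0.4)
  }
  a0 <- sum(pmax(y, 0)) * mean(diff(t)) # crude area start for A
  if (a0 <= 0) a0 <- 1
  obj <- function(par) {
    yy <- gamma_rf(t, par[1], exp(par[2]), exp(par[3]), par[4])
    sum((y - yy)^2)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$t0[i], log(starts$k[i]), log(starts$mu[i]), a0)
    fit <- tryCatch(
      stats::optim(p0, obj, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("response-function fit failed from every starting point",
         call. = FALSE)
  }
  # polish the winner
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(reltol = reltol, maxit = maxit))
  list(params = c(t0 = best$par[1], k = exp(best$par[2]),
                  mu = exp(best$par[3]), A = best$par[4]),
       ssr = best$value, converged = best$convergence == 0,
       n_starts = nrow(starts))
}

#' Build a GLM design matrix by stick-function convolution
#'
#' One regressor per modeled condition: a train of unit impulses at that
#' condition's CS onsets convolved with the response function, the latter
#' optionally shifted rightward by `shift_s` (0.5 s for designs whose
#' CS-US interval is 0.5 s longer than the one the response function was
#' fitted on). A constant column is appended. The response-function kernel
#' is truncated where its tail falls below 1e-8 of its peak.
#'
#' @param events Trial-event tibble.
#' @param t_ms Sampling grid of the observed series (ms); regressors are
#'   evaluated on this grid.
#' @param params Named vector/list with `t0`, `k`, `mu` (amplitude is
#'   absorbed by the betas; the kernel has unit area).
#' @param shift_s Rightward shift of the response function in seconds
#'   (>= 0).
#' @param conditions Conditions to model; defaults to all levels present.
#'   Empty conditions are dropped with a warning.
#' @return Numeric matrix with one named column per modeled condition plus
#'   `intercept`.
#' @export
build_design_matrix <- function(events, t_ms, params, shift_s = 0,
                                conditions = NULL) {
  stopifnot(shift_s >= 0)
  if (is.null(conditions)) {
    conditions <- intersect(condition_levels(), unique(events$condition))
  }
  empty <- setdiff(conditions, unique(events$condition))
  if (length(empty) > 0) {
    warning("dropping empty condition regressor(s): ",
            paste(empty, collapse = ", "))
    conditions <- setdiff(conditions, empty)
  }
  t_s <- t_ms / 1000
  cols <- vapply(conditions, function(cond) {
    onsets <- events$cs_onset_ms[events$condition == cond] / 1000
    col <- numeric(length(t_s))
    for (o in onsets) {
      col <- col + rf_kernel_on_grid(t_s - o - shift_s, params)
    }
    col
  }, numeric(length(t_s)))
  X <- cbind(cols, intercept = 1)
  colnames(X) <- c(conditions, "intercept")
  X
}

# evaluate the unit-area RF at lag times, zeroing the sub-threshold tail
rf_kernel_on_grid <- function(lag_s, params) {
  y <- gamma_rf(lag_s, params[["t0"]], params[["k"]], params[["mu"]], A = 1)
  peak <- gamma_rf(gamma_rf_mode(params[["t0"]], params[["k"]],
                                 params[["mu"]]),
                   params[["t0"]], params[["k"]], params[["mu"]], A = 1)
  y[y < 1e-8 * peak] <- 0
  y
}

#' Ordinary-least-squares inversion of the scan-speed GLM
#'
#' Estimates response amplitudes `beta` in `Y = X beta + epsilon` (epsilon
#' i.i.d. noise) by OLS. The condition contrast of interest downstream is
#' `beta[CSplus_USminus] - beta[CSminus]`.
#'
#' @param Y Observed scan-speed series (finite, length `nrow(X)`).
#' @param X Design matrix from [build_design_matrix()].
#' @return Named numeric vector of amplitudes.
#' @export
glm_invert <- function(Y, X) {
  if (length(Y) != nrow(X)) stop("Y and X have different lengths",
                                 call. = FALSE)
  if (any(!is.finite(Y)) || any(!is.finite(X))) {
    stop("Y and X must be finite", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, Y)
  names(beta) <- colnames(X)
  beta
}

#' Per-participant GLM contrast of scan-speed responses
#'
#' Convenience wrapper: builds the design on the recording's grid, inverts
#' the GLM, and returns the non-reinforced CS+ minus CS- amplitude
#' contrast.
#'
#' @param speed A `scan_speed_series`.
#' @param events Trial events for the same recording.
#' @inheritParams build_design_matrix
#' @return A list with `beta` and `contrast`.
#' @export
glm_contrast <- function(speed, events, params, shift_s = 0) {
  X <- build_design_matrix(events, speed$t_ms, params, shift_s)
  beta <- glm_invert(speed$v_deg_s, X)
  contrast <- unname(beta["CSplus_USminus"] - beta["CSminus"])
  list(beta = beta, contrast = contrast)
}
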