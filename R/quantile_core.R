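#' Check (pinball) loss
#'
#' \eqn{\rho_\tau(v) = v(\tau - 1\{v < 0\})}, the loss whose minimizer is
#' the conditional tau-quantile.
#'
#' @param v Numeric vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Numeric vector of losses.
#' @examples
#' check_loss(c(1, -1, 0), 0.3)
#' @export
check_loss <- function(v, tau) {
  check_tau(tau)
  v * (tau - (v < 0))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1)
    stop("tau must be a single number strictly between 0 and 1")
  invisible(tau)
}

#' Smoothing bandwidth for the convolution-smoothed check loss
#'
#' Default bandwidth \eqn{h = \max\{0.05, ((k + \log n)/n)^{2/5}\}} where k
#' is the number of coefficients, as used by smoothed quantile regression.
#'
#' @param n Sample size.
#' @param k Number of design columns.
#' @return Bandwidth h.
#' @export
sqr_bandwidth <- function(n, k) {
  max(0.05, ((k + log(n)) / n)^0.4)
}

#' Fit a quantile regression by smoothed check-loss minimization
#'
#' Minimizes the Gaussian-kernel convolution-smoothed check loss by damped
#' Newton iterations.  The smoothed objective is convex and differentiable;
#' the reported `objective` is the mean *raw* check loss at the solution.
#'
#' @param X Design matrix (must include an intercept column if one is
#'   wanted).
#' @param y Response vector.
#' @param tau Quantile level in (0, 1).
#' @param h Smoothing bandwidth; default [sqr_bandwidth()].
#' @param se Standard-error method: `"kernel"` (Powell sandwich with
#'   Hall--Sheather bandwidth), `"bootstrap"`, or `"none"`.
#' @param tol Relative coefficient-change convergence tolerance.
#' @param maxit Maximum Newton iterations.
#' @param start Optional starting coefficients.
#' @param boot_reps Bootstrap resamples when `se = "bootstrap"`.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `quantile_fit`: list with `coefficients`,
#'   `standard_errors`, `residuals`, `objective` (mean check loss), `tau`,
#'   `n_obs`, `h`, `iterations`, `converged`.
#' @export
fit_quantile <- function(X, y, tau, h = NULL, se = c("kernel", "bootstrap", "none"),
                         tol = 1e-8, maxit = 500L, start = NULL,
                         boot_reps = 200L, seed = NULL) {
  se <- match.arg(se)
  check_tau(tau)
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= k) stop("need more observations than coefficients (n > k)")
  if (qr(X)$rank < k) stop("design matrix is rank deficient")
  if (is.null(h)) h <- sqr_bandwidth(n, k)
  # least-squares warm start keeps the initial residuals on the scale of
  # the smoothing bandwidth
  if (is.null(start)) start <- drop(qr.solve(X, y))
  fit <- cpp_sqr_fit(X, y, tau, h, tol, maxit, start)
  if (!fit$converged)
    stop("quantile regression did not converge in ", fit$iterations,
         " iterations (tau = ", tau, ")")
  b <- drop(fit$coefficients)
  names(b) <- colnames(X)
  out <- structure(
    list(coefficients = b, residuals = drop(fit$residuals),
         objective = fit$objective,
         smoothed_objective = fit$smoothed_objective,
         tau = tau, n_obs = n, h = h,
         iterations = fit$iterations, converged = fit$converged,
         standard_errors = rep(NA_real_, k)),
    class = "quantile_fit")
  if (se == "kernel") {
    out$standard_errors <- quantile_covariance(out, X, y)$se
  } else if (se == "bootstrap") {
    out$standard_errors <- bootstrap_se(X, y, tau, h, tol, maxit,
                                        boot_reps, seed)
  }
  names(out$standard_errors) <- colnames(X)
  out
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat("<quantile_fit> tau =", x$tau, " n =", x$n_obs,
      " mean check loss =", format(x$objective, digits = 6), "\n")
  print(cbind(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Sandwich covariance for a quantile regression fit
#'
#' Powell kernel estimate of the Hessian (conditional density term) with a
#' Hall--Sheather rule for the bandwidth, combined with the
#' \eqn{\tau(1-\tau)} outer matrix:
#' \deqn{\widehat{Cov} = \tau(1-\tau)\, \hat H^{-1} (X'X/n) \hat H^{-1} / n,
#'   \quad \hat H = (2 n c_n)^{-1} \sum 1\{|r_i| \le c_n\} x_i x_i'.}
#'
#' @param fit A `quantile_fit` obtained on `X`, `y`.
#' @param X,y The design and response used for the fit.
#' @return List with `cov` (matrix) and `se` (vector).
#' @export
quantile_covariance <- function(fit, X, y) {
  stopifnot(inherits(fit, "quantile_fit"))
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X); tau <- fit$tau
  r <- fit$residuals
  hs <- hall_sheather(tau, n)
  kappa <- min(stats::sd(r), stats::IQR(r) / 1.349)
  if (!is.finite(kappa) || kappa <= 0) kappa <- stats::sd(r)
  cn <- kappa * (qnorm(min(tau + hs, 1 - 1e-6)) -
                 qnorm(max(tau - hs, 1e-6)))
  if (!is.finite(cn) || cn <= 0)
    stop("degenerate density bandwidth in sandwich covariance")
  inb <- abs(r) <= cn
  if (sum(inb) < k)
    stop("too few residuals inside the density bandwidth")
  H <- crossprod(X[inb, , drop = FALSE]) / (2 * n * cn)
  Hinv <- solve(H)
  J <- crossprod(X) / n
  covm <- tau * (1 - tau) * Hinv %*% J %*% Hinv / n
  list(cov = covm, se = sqrt(pmax(diag(covm), 0)))
}

hall_sheather <- function(tau, n) {
  z <- qnorm(tau)
  n^(-1/3) * qnorm(0.975)^(2/3) *
    ((1.5 * dnorm(z)^2) / (2 * z^2 + 1))^(1/3)
}

bootstrap_se <- function(X, y, tau, h, tol, maxit, reps, seed) {
  n <- nrow(X); k <- ncol(X)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  start <- drop(cpp_sqr_fit(X, y, tau, h, tol, maxit,
                            drop(qr.solve(X, y)))$coefficients)
  B <- matrix(NA_real_, reps, k)
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    B[b, ] <- drop(cpp_sqr_fit(X[idx, , drop = FALSE], y[idx], tau, h,
                               tol, maxit, start)$coefficients)
  }
  apply(B, 2L, stats::sd)
}
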