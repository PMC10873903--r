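#' Minimax concave penalty (MCP)
#'
#' \deqn{p_{\lambda,\delta}(t) = \lambda(|t| - t^2/(2\delta\lambda)) \ for \
#'   |t| < \delta\lambda; \quad \lambda^2\delta/2 \ otherwise.}
#'
#' @param t Numeric vector of coefficients.
#' @param lam Regularization strength lambda > 0.
#' @param delta Concavity parameter delta > 1.
#' @return Penalty values (even in `t`, continuous, saturating).
#' @examples
#' mcp_penalty(c(0, 1, 5), lam = 1, delta = 3)
#' @export
mcp_penalty <- function(t, lam, delta = 3) {
  check_mcp_params(lam, delta)
  a <- abs(t)
  ifelse(a < delta * lam, lam * (a - a^2 / (2 * delta * lam)),
         lam^2 * delta / 2)
}

check_mcp_params <- function(lam, delta) {
  if (!is.numeric(lam) || lam <= 0) stop("lambda must be > 0")
  if (!is.numeric(delta) || delta <= 1)
    stop("delta must be > 1 for a well-defined scalar proximal rule")
  invisible(NULL)
}

#' Scalar MCP proximal operator
#'
#' Solves \eqn{\arg\min_t \ w (z-t)^2/2 + p_{\lambda,\delta}(t)}:
#' soft-threshold-then-inflate for \eqn{|z| < \delta\lambda}, identity
#' outside.  Requires \eqn{\delta w > 1} so the scalar problem is convex.
#'
#' @param z Unpenalized minimizer (scalar or vector).
#' @param w Quadratic weight > 0.
#' @param lam,delta MCP parameters.
#' @return Thresholded value(s).
#' @export
mcp_scalar_update <- function(z, w, lam, delta = 3) {
  check_mcp_params(lam, delta)
  if (w <= 0 || delta * w <= 1)
    stop("require w > 0 and delta * w > 1 (scalar problem convex)")
  vapply(z, cpp_mcp_prox, numeric(1), w = w, lam = lam, delta = delta)
}

#' Lambda path for MCP-penalized quantile regression
#'
#' Log-spaced decreasing grid from lambda_max (the smallest lambda giving an
#' empty survivor set, located analytically from the score of the
#' mediator-free fit and verified by probing) down to `ratio * lambda_max`.
#'
#' @param X Design matrix ordered as (intercept, exposure, covariates,
#'   mediators).
#' @param y Response.
#' @param tau Quantile level.
#' @param penalize Logical vector marking penalized (mediator) columns.
#' @param n_lambda Grid size (>= 2).
#' @param ratio Smallest/largest lambda ratio.
#' @param delta MCP concavity.
#' @param h Smoothing bandwidth.
#' @param tol,maxit Solver controls.
#' @return Decreasing numeric vector of lambdas.
#' @export
lambda_path <- function(X, y, tau, penalize, n_lambda = 20L, ratio = 0.01,
                        delta = 3, h = NULL, tol = 1e-8, maxit = 500L) {
  if (n_lambda < 2L) stop("n_lambda must be >= 2")
  n <- nrow(X)
  if (is.null(h)) h <- sqr_bandwidth(n, ncol(X))
  Xu <- X[, !penalize, drop = FALSE]
  base <- cpp_sqr_fit(Xu, y, tau, h, tol, maxit, drop(qr.solve(Xu, y)))
  r0 <- drop(base$residuals)
  psi <- tau - pnorm(-r0 / h)
  lam_max <- max(abs(crossprod(X[, penalize, drop = FALSE], psi))) / n
  # probe: inflate until the fit at lam_max is actually empty
  start <- numeric(ncol(X))
  start[!penalize] <- drop(base$coefficients)
  for (i in 1:10) {
    f <- cpp_mcp_path(X, y, tau, h, lam_max, delta,
                      as.integer(penalize), tol, maxit, start)
    if (all(abs(f$coefficients[penalize, 1]) <= 1e-8)) break
    lam_max <- lam_max * 1.5
  }
  exp(seq(log(lam_max), log(lam_max * ratio), length.out = n_lambda))
}

#' Step 2: MCP-penalized smoothed quantile regression on screened mediators
#'
#' Minimizes the smoothed check loss plus an MCP penalty on the mediator
#' coefficients (intercept, exposure and covariates unpenalized) by
#' majorize-minimize with inner coordinate descent, warm-starting along a
#' decreasing lambda path, and selects lambda by a high-dimensional BIC
#' \deqn{HBIC(\lambda) = \log(loss) + |S_\tau| \log(k)\log(\log n)/(2n)}
#' with ties resolved toward the sparser (larger lambda) fit.
#'
#' @param dataset `mediation_dataset` with standardized mediators.
#' @param screening A `screening_result` for this dataset/tau.
#' @param tau Quantile level.
#' @param lambda Optional lambda grid; default [lambda_path()].
#' @param delta MCP concavity (> 1).
#' @param n_lambda Grid size when `lambda` is NULL.
#' @param zero_tol Absolute threshold for membership in the survivor set.
#' @param tol,maxit Solver controls.
#' @return Object of class `penalized_fit`: `theta` (named coefficients of
#'   the selected fit), `active_set` (mediator indices into the full p,
#'   the survivor set S_tau), `lambda`, `delta`, `criterion`, `objective`,
#'   `path` (per-lambda summary data frame), `screening`, `tau`.
#' @export
fit_penalized <- function(dataset, screening, tau, lambda = NULL, delta = 3,
                          n_lambda = 20L, zero_tol = 1e-8, tol = 1e-8,
                          maxit = 500L) {
  stopifnot(inherits(dataset, "mediation_dataset"),
            inherits(screening, "screening_result"))
  check_tau(tau)
  idx <- screening$retained
  n <- dataset$n; q <- dataset$q
  if (length(idx) + q + 2L > n)
    stop("screened model has more coefficients than observations")
  X <- cbind(`(Intercept)` = 1, X = dataset$exposure, dataset$covariates,
             dataset$mediators[, idx, drop = FALSE])
  penalize <- c(rep(FALSE, 2L + q), rep(TRUE, length(idx)))
  k <- ncol(X)
  h <- sqr_bandwidth(n, k)
  if (is.null(lambda))
    lambda <- lambda_path(X, dataset$outcome, tau, penalize,
                          n_lambda = n_lambda, delta = delta, h = h,
                          tol = tol, maxit = maxit)
  lambda <- sort(lambda, decreasing = TRUE)
  fit <- cpp_mcp_path(X, dataset$outcome, tau, h, lambda, delta,
                      as.integer(penalize), tol, maxit, numeric(k))
  coefs <- fit$coefficients
  obj <- drop(fit$objective)
  nact <- colSums(abs(coefs[penalize, , drop = FALSE]) > zero_tol)
  crit <- hbic_criterion(obj, nact, n, k)
  best <- select_lambda(crit)
  theta <- coefs[, best]
  names(theta) <- colnames(X)
  active <- idx[abs(theta[penalize]) > zero_tol]
  structure(
    list(theta = theta, active_set = active, lambda = lambda[best],
         delta = delta, criterion = crit[best], objective = obj[best],
         path = data.frame(lambda = lambda, n_active = nact,
                           objective = obj, hbic = crit),
         screening = screening, tau = tau, h = h),
    class = "penalized_fit")
}

#' High-dimensional BIC along a lambda path
#'
#' `hbic_criterion()` computes \eqn{\log(loss) + s\,\log(k)\log(\log n)/(2n)}
#' for each fit on the path; `select_lambda()` returns the index of the
#' minimizing fit, breaking ties toward the first (sparser, larger-lambda)
#' entry of a decreasing path.
#'
#' @param objective Mean check loss per path fit.
#' @param n_active Survivor-set size per path fit.
#' @param n Sample size.
#' @param k Total number of coefficients in the penalized model.
#' @return `hbic_criterion()`: numeric criterion vector; `select_lambda()`:
#'   integer index of the selected fit.
#' @export
hbic_criterion <- function(objective, n_active, n, k) {
  log(pmax(objective, 1e-12)) + n_active * log(k) * log(log(n)) / (2 * n)
}

#' @rdname hbic_criterion
#' @param criterion Criterion vector ordered by decreasing lambda.
#' @export
select_lambda <- function(criterion) {
  if (!length(criterion)) stop("need at least one fit on the path")
  which(criterion <= min(criterion) + 1e-12)[1L]
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat("<penalized_fit> tau =", x$tau, " lambda =",
      format(x$lambda, digits = 4), " |S_tau| =", length(x$active_set), "\n")
  invisible(x)
}
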