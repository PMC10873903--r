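#' Screening dimension
#'
#' Number of mediators retained by marginal screening,
#' \eqn{d = 2\lfloor n/\log n\rfloor} (natural logarithm).
#'
#' @param n Sample size (n >= 3).
#' @return Integer d.
#' @examples
#' screening_dimension(300)  # 104
#' @export
screening_dimension <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 3)
    stop("n must be a single integer >= 3")
  2L * as.integer(floor(n / log(n)))
}

#' Marginal quantile-regression coefficients for all mediators
#'
#' For each mediator k fits the marginal model
#' outcome ~ intercept + exposure + mediator_k + covariates at level tau and
#' returns the mediator coefficient.  Expects mediators already standardized
#' so coefficients are on a common scale.
#'
#' @param dataset A `mediation_dataset` (standardized mediators).
#' @param tau Quantile level.
#' @param se Also compute kernel sandwich standard errors per mediator
#'   (slower; one full fit per mediator in R).
#' @param tol,maxit Solver controls.
#' @return A list with `coefficients` (length p) and, when `se = TRUE`,
#'   `standard_errors`.
#' @export
marginal_effects <- function(dataset, tau, se = FALSE, tol = 1e-8,
                             maxit = 500L) {
  stopifnot(inherits(dataset, "mediation_dataset"))
  check_tau(tau)
  n <- dataset$n
  Xbase <- cbind(`(Intercept)` = 1, X = dataset$exposure, dataset$covariates)
  k <- ncol(Xbase) + 1L
  h <- sqr_bandwidth(n, k)
  beta <- drop(cpp_marginal_qr(Xbase, dataset$mediators, dataset$outcome,
                               tau, h, tol, maxit))
  names(beta) <- dataset$mediator_names
  out <- list(coefficients = beta, tau = tau)
  if (se) {
    ses <- numeric(dataset$p)
    for (j in seq_len(dataset$p)) {
      Xj <- cbind(Xbase, Mk = dataset$mediators[, j])
      f <- fit_quantile(Xj, dataset$outcome, tau, se = "kernel",
                        tol = tol, maxit = maxit)
      ses[j] <- f$standard_errors[ncol(Xj)]
      beta[j] <- f$coefficients[ncol(Xj)]
    }
    names(ses) <- dataset$mediator_names
    out$coefficients <- beta
    out$standard_errors <- ses
  }
  out
}

#' Step 1: marginal quantile screening of mediators
#'
#' Ranks mediators by the absolute marginal quantile-regression coefficient
#' and retains the top \eqn{\min(d, p)} with \eqn{d = 2\lfloor n/\log
#' n\rfloor} (capped so later refits remain overdetermined).  Ties are
#' broken by ascending column index.
#'
#' @param dataset A `mediation_dataset` with standardized mediators.
#' @param tau Quantile level.
#' @param d Screening dimension override; default [screening_dimension()].
#' @param tol,maxit Solver controls.
#' @return Object of class `screening_result`: list with
#'   `marginal_coefficients`, `retained` (sorted index set I_tau), `d`,
#'   `tau`.
#' @export
screen_mediators <- function(dataset, tau, d = NULL, tol = 1e-8,
                             maxit = 500L) {
  stopifnot(inherits(dataset, "mediation_dataset"))
  check_tau(tau)
  if (is.null(d)) d <- screening_dimension(dataset$n)
  d <- min(d, dataset$p, dataset$n - dataset$q - 3L)
  if (d < 1L) stop("screening dimension is < 1; sample too small")
  beta <- marginal_effects(dataset, tau, se = FALSE, tol = tol,
                           maxit = maxit)$coefficients
  ord <- order(-abs(beta), seq_along(beta))  # ties -> lower index first
  retained <- sort(ord[seq_len(d)])
  structure(list(marginal_coefficients = beta, retained = retained,
                 d = d, tau = tau),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> tau =", x$tau, " retained", length(x$retained),
      "of", length(x$marginal_coefficients), "mediators (d =", x$d, ")\n")
  invisible(x)
}
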