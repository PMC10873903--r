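#' OLS mediator model
#'
#' Fits mediator k on intercept + exposure + covariates by ordinary least
#' squares and returns the exposure coefficient (the alpha path) with its
#' classical standard error and a two-sided normal p-value
#' \eqn{P_\alpha = 2\{1 - \Phi(|\hat\alpha|/\hat\sigma_\alpha)\}}.
#'
#' @param dataset A `mediation_dataset`.
#' @param k Mediator column index.
#' @return List with `alpha_hat`, `se_alpha`, `p_alpha`.
#' @export
ols_mediator_model <- function(dataset, k) {
  stopifnot(inherits(dataset, "mediation_dataset"))
  n <- dataset$n; q <- dataset$q
  if (n <= q + 2L) stop("need n > q + 2 for the mediator model")
  X <- cbind(1, dataset$exposure, dataset$covariates)
  fit <- lm.fit(X, dataset$mediators[, k])
  if (fit$rank < ncol(X)) stop("rank-deficient mediator-model design")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  a <- unname(fit$coefficients[2L])
  list(alpha_hat = a, se_alpha = se,
       p_alpha = 2 * (1 - pnorm(abs(a) / se)))
}

#' Step 3 refit of the survivor sub-model
#'
#' Unpenalized quantile regression of the outcome on intercept + exposure +
#' covariates + the surviving mediators.  The survivor model is small, so
#' the smoothed solver is driven toward the exact check-loss minimizer by
#' bandwidth continuation (halving the bandwidth with warm starts down to
#' `h_min`), matching the standard exact refit; set `sharpen = FALSE` to
#' stop at the default bandwidth.  With an empty survivor set the
#' direct-effect-only model is fit.
#'
#' @param dataset `mediation_dataset` (standardized mediators).
#' @param s_tau Integer vector of surviving mediator indices.
#' @param tau Quantile level.
#' @param sharpen Continue the bandwidth toward 0 (default TRUE).
#' @param h_min Final bandwidth of the continuation.
#' @param ... Passed to [fit_quantile()].
#' @return A `quantile_fit`; mediator coefficients are the entries named
#'   after the mediators.
#' @export
refit_submodel <- function(dataset, s_tau, tau, sharpen = TRUE,
                           h_min = 1e-4, ...) {
  stopifnot(inherits(dataset, "mediation_dataset"))
  if (length(s_tau) + dataset$q + 2L >= dataset$n)
    stop("survivor set too large to refit (|S| + q + 2 >= n)")
  X <- cbind(`(Intercept)` = 1, X = dataset$exposure, dataset$covariates)
  if (length(s_tau))
    X <- cbind(X, dataset$mediators[, s_tau, drop = FALSE])
  if (!sharpen)
    return(fit_quantile(X, dataset$outcome, tau, ...))
  args <- list(...)
  se <- args$se %||% "kernel"
  args$se <- NULL
  h <- sqr_bandwidth(nrow(X), ncol(X))
  fit <- do.call(fit_quantile, c(list(X, dataset$outcome, tau, h = h,
                                      se = "none"), args))
  while (h > h_min) {
    h <- max(h / 2, h_min)
    fit <- do.call(fit_quantile,
                   c(list(X, dataset$outcome, tau, h = h, se = "none",
                          start = fit$coefficients), args))
  }
  if (identical(se, "kernel")) {
    sw <- quantile_covariance(fit, X, dataset$outcome)
    fit$standard_errors <- sw$se
    names(fit$standard_errors) <- colnames(X)
  } else if (identical(se, "bootstrap")) {
    fit$standard_errors <- bootstrap_se(X, dataset$outcome, tau, fit$h,
                                        1e-8, 500L, 200L, NULL)
    names(fit$standard_errors) <- colnames(X)
  }
  fit
}

#' Joint-significance decision statistic
#'
#' Combines the two path p-values as \eqn{P^{JS} = \max(P_\alpha, P_\beta)}
#' and scales by the survivor count:
#' \eqn{D^{JS} = \min(d_\tau P^{JS}, 1)} with \eqn{d_\tau = |S_\tau|}.
#'
#' @param p_alpha,p_beta P-values in [0, 1] (vectorized).
#' @param d_tau Cardinality of the survivor set (integer >= 1).
#' @return List with `p_js` and `d_js`.
#' @examples
#' js_statistic(0.001, 0.02, 5)  # p_js 0.02, d_js 0.1
#' @export
js_statistic <- function(p_alpha, p_beta, d_tau) {
  if (any(d_tau < 1)) stop("d_tau must be >= 1")
  if (any(p_alpha < 0 | p_alpha > 1 | p_beta < 0 | p_beta > 1))
    stop("p-values must lie in [0, 1]")
  p_js <- pmax(p_alpha, p_beta)
  list(p_js = p_js, d_js = pmin(d_tau * p_js, 1))
}

#' Select significant mediators
#'
#' Applies the strict decision rule \eqn{D^{JS} < } `level` to a mediator
#' test table and returns the sorted selected indices.
#'
#' @param tests Data frame with columns `index` and `d_js` (as produced by
#'   [qmediate()]).
#' @param level Significance level (default 0.05).
#' @return Sorted integer vector of selected mediator indices.
#' @export
select_mediators <- function(tests, level = 0.05) {
  if (!nrow(tests)) return(integer(0))
  sort(tests$index[tests$d_js < level])
}

#' Controlled direct and indirect effects
#'
#' \eqn{CDE = \hat\gamma_\tau (x - x^*)} and
#' \eqn{CIE = \sum_{k \in \hat\Omega} \hat\alpha_k \hat\beta_{k,\tau}
#' (x - x^*)}; the products \eqn{\alpha_k \beta_{k,\tau}} are invariant to
#' mediator standardization, so either coefficient scale may be supplied.
#'
#' @param gamma_hat Direct-effect coefficient.
#' @param effects Per-mediator products \eqn{\hat\alpha_k\hat\beta_{k,\tau}}
#'   of the selected mediators.
#' @param x,x_star Exposure levels being contrasted.
#' @return List with `cde` and `cie`.
#' @export
controlled_effects <- function(gamma_hat, effects, x, x_star) {
  dx <- x - x_star
  list(cde = gamma_hat * dx, cie = sum(effects) * dx)
}

#' Analysis controls
#'
#' @param level Joint-significance level (default 0.05 as in the decision
#'   rule \eqn{D^{JS} < 0.05}).
#' @param delta MCP concavity (> 1; default 3).
#' @param n_lambda Size of the lambda grid.
#' @param d Screening-dimension override (default
#'   \eqn{2\lfloor n/\log n\rfloor}).
#' @param tol Solver convergence tolerance.
#' @param maxit Maximum solver iterations.
#' @param se Standard-error method for the refit.
#' @return List of class `qmed_control`.
#' @export
qmed_control <- function(level = 0.05, delta = 3, n_lambda = 20L, d = NULL,
                         tol = 1e-8, maxit = 500L, se = "kernel") {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  structure(list(level = level, delta = delta, n_lambda = n_lambda, d = d,
                 tol = tol, maxit = maxit, se = se),
            class = "qmed_control")
}

#' High-dimensional quantile mediation analysis
#'
#' Runs the full three-step procedure at quantile level tau:
#' standardize mediators, screen to \eqn{d = 2\lfloor n/\log n\rfloor},
#' MCP-penalized smoothed quantile regression with HBIC-tuned lambda,
#' unpenalized refit of the survivors, per-survivor joint-significance
#' tests, and selection at `control$level`.
#'
#' @param dataset A `mediation_dataset` (raw mediator scale).
#' @param tau Quantile level in (0, 1).
#' @param control A [qmed_control()] list.
#' @return Object of class `mediation_result` with elements `tau`,
#'   `gamma_hat` (direct effect), `tests` (one row per survivor: index,
#'   name, alpha_hat, se_alpha, beta_hat, se_beta — raw mediator scale —
#'   alpha_std, beta_std, p_alpha, p_beta, p_js, d_js, effect, selected),
#'   `selected` (indices), `total_cie`, `screening`, `penalized`, `refit`,
#'   `record` (standardization record), `n`, `p`.
#' @examples
#' cfg <- sim_config(n = 120, p = 30, case = "I", seed = 7)
#' ds <- sim_generate(cfg)$dataset
#' res <- qmediate(ds, tau = 0.5)
#' res$selected
#' @export
qmediate <- function(dataset, tau, control = qmed_control()) {
  stopifnot(inherits(dataset, "mediation_dataset"))
  check_tau(tau)
  std <- standardize_mediators(dataset)
  sds <- std$dataset
  scr <- screen_mediators(sds, tau, d = control$d, tol = control$tol,
                          maxit = control$maxit)
  pen <- fit_penalized(sds, scr, tau, delta = control$delta,
                       n_lambda = control$n_lambda, tol = control$tol,
                       maxit = control$maxit)
  s_tau <- pen$active_set
  refit <- refit_submodel(sds, s_tau, tau, se = control$se,
                          tol = control$tol, maxit = control$maxit)
  gamma_hat <- unname(refit$coefficients["X"])
  d_tau <- length(s_tau)
  if (d_tau > 0L) {
    off <- 2L + dataset$q
    beta_std <- unname(refit$coefficients[off + seq_len(d_tau)])
    se_beta_std <- unname(refit$standard_errors[off + seq_len(d_tau)])
    ols <- lapply(s_tau, function(k) ols_mediator_model(sds, k))
    alpha_std <- vapply(ols, `[[`, numeric(1), "alpha_hat")
    se_alpha_std <- vapply(ols, `[[`, numeric(1), "se_alpha")
    p_alpha <- vapply(ols, `[[`, numeric(1), "p_alpha")
    p_beta <- 2 * (1 - pnorm(abs(beta_std) / se_beta_std))
    js <- js_statistic(p_alpha, p_beta, d_tau)
    scale_k <- std$record$scale[s_tau]
    tests <- data.frame(
      index = s_tau,
      name = dataset$mediator_names[s_tau],
      alpha_hat = alpha_std * scale_k,
      se_alpha = se_alpha_std * scale_k,
      beta_hat = beta_std / scale_k,
      se_beta = se_beta_std / scale_k,
      alpha_std = alpha_std, beta_std = beta_std,
      p_alpha = p_alpha, p_beta = p_beta,
      p_js = js$p_js, d_js = js$d_js,
      effect = alpha_std * beta_std,
      stringsAsFactors = FALSE)
    tests$selected <- tests$d_js < control$level
    selected <- select_mediators(tests, control$level)
  } else {
    tests <- data.frame(index = integer(0), name = character(0),
                        alpha_hat = numeric(0), se_alpha = numeric(0),
                        beta_hat = numeric(0), se_beta = numeric(0),
                        alpha_std = numeric(0), beta_std = numeric(0),
                        p_alpha = numeric(0), p_beta = numeric(0),
                        p_js = numeric(0), d_js = numeric(0),
                        effect = numeric(0), selected = logical(0),
                        stringsAsFactors = FALSE)
    selected <- integer(0)
  }
  structure(
    list(tau = tau, gamma_hat = gamma_hat, tests = tests,
         selected = selected,
         total_cie = sum(tests$effect[tests$selected]),
         screening = scr, penalized = pen, refit = refit,
         record = std$record, control = control,
         n = dataset$n, p = dataset$p),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("High-dimensional quantile mediation analysis (tau =", x$tau, ")\n")
  cat("  n =", x$n, " p =", x$p, " screened d =", x$screening$d,
      " survivors |S_tau| =", nrow(x$tests),
      " selected |Omega_hat| =", length(x$selected), "\n")
  cat("  direct effect gamma_hat =", format(x$gamma_hat, digits = 6),
      "  total CIE =", format(x$total_cie, digits = 6), "\n")
  if (nrow(x$tests)) {
    cols <- c("index", "name", "alpha_hat", "beta_hat", "p_alpha",
              "p_beta", "d_js", "effect", "selected")
    print(x$tests[cols], digits = 6, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a mediation result as flat tables
#'
#' @param result A `mediation_result`.
#' @return List with `tests` (per-mediator table) and `summary` (one-row
#'   data frame: tau, n, p, d, n_survivors, n_selected, gamma_hat,
#'   total_cie).
#' @export
result_tables <- function(result) {
  stopifnot(inherits(result, "mediation_result"))
  list(tests = result$tests,
       summary = data.frame(
         tau = result$tau, n = result$n, p = result$p,
         d = result$screening$d, n_survivors = nrow(result$tests),
         n_selected = length(result$selected),
         gamma_hat = result$gamma_hat, total_cie = result$total_cie))
}
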