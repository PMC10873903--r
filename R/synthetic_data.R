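#' Simulation design configuration
#'
#' Defines the data-generating process used throughout the simulation
#' studies.  Mediators follow \eqn{M_k = \alpha_k X + \zeta' Z + e_k} with
#' AR-correlated errors \eqn{Cov(e_i, e_j) = \rho^{|i-j|}} (unit variances);
#' the outcome is
#' \deqn{Case\ I:\quad Y = \gamma X + \beta' M + \eta' Z + \epsilon}
#' \deqn{Case\ II:\quad Y = \gamma X + \beta' M + \eta' Z +
#'   \epsilon(\theta X + \phi' M)}
#' with \eqn{\epsilon \sim N(0,1)}, so under Case II the quantile-specific
#' mediator effect is \eqn{\beta_k + Q_\tau(\epsilon)\phi_k}.
#'
#' Default true coefficient vectors (first entries, rest zero):
#' alpha = (0.85, 1.2, 1, 0.15, -0.25, 0.65, -0.50),
#' beta = (0.85, 1.2, 1, 0.25, -0.15, 0, 0, 0.75, -0.5),
#' phi = (0.1, 0.1, 0.1); gamma = 0.5, theta = 0.1, zeta_k = (0.3, 0.3),
#' eta = (0.5, 0.5); exposure and covariates N(0, 4) (variance 4, sd 2).
#' Truly active mediation paths: k in {1, 2, 3, 4, 5}.
#'
#' @param n Sample size (>= 50).
#' @param p Number of mediators (>= 9; default 3000).
#' @param case `"I"` (additive error) or `"II"` (heteroscedastic
#'   multiplier).
#' @param seed Integer seed driving all randomness of [sim_generate()].
#' @param gamma,theta,rho,exposure_sd,covariate_sd Scalar design knobs.
#' @param zeta,eta Length-2 covariate coefficient vectors.
#' @param alpha,beta,phi Optional length-p overrides of the truth vectors.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n, p = 3000L, case = c("I", "II"), seed = 1L,
                       gamma = 0.5, theta = 0.1, rho = 0.25,
                       exposure_sd = 2, covariate_sd = 2,
                       zeta = c(0.3, 0.3), eta = c(0.5, 0.5),
                       alpha = NULL, beta = NULL, phi = NULL) {
  case <- match.arg(case)
  if (n < 50) stop("n must be >= 50")
  if (p < 9) stop("p must be >= 9 (the truth vectors occupy 9 slots)")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  fill <- function(head, p) c(head, numeric(p - length(head)))
  if (is.null(alpha)) alpha <- fill(c(0.85, 1.2, 1, 0.15, -0.25, 0.65, -0.50), p)
  if (is.null(beta))  beta  <- fill(c(0.85, 1.2, 1, 0.25, -0.15, 0, 0, 0.75, -0.5), p)
  if (is.null(phi))   phi   <- fill(c(0.1, 0.1, 0.1), p)
  stopifnot(length(alpha) == p, length(beta) == p, length(phi) == p,
            length(zeta) == 2L, length(eta) == 2L)
  structure(list(n = as.integer(n), p = as.integer(p), case = case,
                 seed = as.integer(seed), gamma = gamma, theta = theta,
                 rho = rho, exposure_sd = exposure_sd,
                 covariate_sd = covariate_sd, zeta = zeta, eta = eta,
                 alpha = alpha, beta = beta, phi = phi),
            class = "sim_config")
}

#' Generate a simulated mediation dataset
#'
#' Pure function of the configuration: the same config (including seed)
#' always yields the same dataset.  Mediator errors use a stationary AR(1)
#' recursion across the mediator index (coefficient rho, innovation sd
#' \eqn{\sqrt{1-\rho^2}}), equivalent in distribution to drawing from the
#' full AR covariance matrix.  Case I and Case II share all random draws,
#' differing only in how the outcome noise enters.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a [mediation_dataset()]), `config`, and
#'   `components` (the latent draws `eps`, `signal` = noise-free outcome,
#'   `multiplier` for Case II), useful for diagnostics.
#' @export
sim_generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n; p <- config$p
  X <- rnorm(n, 0, config$exposure_sd)
  Z <- matrix(rnorm(n * 2L, 0, config$covariate_sd), n, 2L,
              dimnames = list(NULL, c("Z1", "Z2")))
  e <- matrix(rnorm(n * p), n, p)
  if (config$rho > 0 && p > 1L) {
    innov_sd <- sqrt(1 - config$rho^2)
    for (j in 2:p) e[, j] <- config$rho * e[, j - 1L] + innov_sd * e[, j]
  }
  eps <- rnorm(n)
  # mediators: alpha_k X + zeta'Z + e_k  (zeta common to all mediators)
  M <- tcrossprod(X, config$alpha) +
    matrix(drop(Z %*% config$zeta), n, p) + e
  colnames(M) <- paste0("M", seq_len(p))
  signal <- config$gamma * X + drop(M %*% config$beta) +
    drop(Z %*% config$eta)
  if (config$case == "I") {
    Y <- signal + eps
    multiplier <- NULL
  } else {
    multiplier <- config$theta * X + drop(M %*% config$phi)
    Y <- signal + eps * multiplier
  }
  ds <- mediation_dataset(exposure = X, mediators = M, outcome = Y,
                          covariates = Z)
  list(dataset = ds, config = config,
       components = list(eps = eps, signal = signal,
                         multiplier = multiplier, errors = e))
}

#' Ground-truth mediation effects at a quantile level
#'
#' Case I: effects \eqn{\alpha_k \beta_k} for every tau.  Case II: effects
#' \eqn{\alpha_k(\beta_k + Q_\tau(\epsilon)\phi_k)} with
#' \eqn{Q_\tau(\epsilon) = \Phi^{-1}(\tau)}.  The active set collects the
#' nonzero effects.
#'
#' @param config A [sim_config()].
#' @param tau Quantile level in (0, 1).
#' @return List with `effects` (length p), `active_set` (indices of nonzero
#'   effects), `gamma_tau` (direct effect \eqn{\gamma + \theta\Phi^{-1}(\tau)}
#'   under Case II, \eqn{\gamma} under Case I).
#' @export
sim_truth <- function(config, tau) {
  stopifnot(inherits(config, "sim_config"))
  check_tau(tau)
  if (config$case == "I") {
    beta_tau <- config$beta
    gamma_tau <- config$gamma
  } else {
    qe <- qnorm(tau)
    beta_tau <- config$beta + qe * config$phi
    gamma_tau <- config$gamma + qe * config$theta
  }
  effects <- config$alpha * beta_tau
  list(effects = effects, active_set = which(effects != 0),
       gamma_tau = gamma_tau)
}

#' Write a simulated dataset and its ground truth to delimited files
#'
#' @param config A [sim_config()].
#' @param path Output CSV path for the dataset (columns X, M1..Mp, Z1, Z2,
#'   Y).
#' @param truth_path Optional path for a ground-truth sidecar (per-mediator
#'   alpha, beta, phi, and the tau = 0.5 effect/active flag).
#' @return Invisibly, the generated dataset.
#' @export
write_simulation <- function(config, path, truth_path = NULL) {
  g <- sim_generate(config)
  ds <- g$dataset
  tab <- data.frame(X = ds$exposure, ds$mediators, ds$covariates,
                    Y = ds$outcome, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(truth_path)) {
    tr <- sim_truth(config, 0.5)
    utils::write.csv(
      data.frame(mediator = colnames(ds$mediators),
                 alpha = config$alpha, beta = config$beta,
                 phi = config$phi, effect_tau50 = tr$effects,
                 active = seq_len(config$p) %in% tr$active_set),
      truth_path, row.names = FALSE)
  }
  invisible(ds)
}
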