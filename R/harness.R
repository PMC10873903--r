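#' Run one simulation repetition of the three-step procedure
#'
#' Generates one dataset from the design (with the repetition's own seed),
#' runs [qmediate()], and returns the per-mediator mediation-effect
#' estimates \eqn{\hat\alpha_k\hat\beta_{k,\tau}} (exactly 0 for mediators
#' that do not survive Step 2) together with the selected set.
#'
#' @param config A [sim_config()]; its seed is replaced by `rep_seed`.
#' @param tau Quantile level.
#' @param rep_seed Seed for this repetition.
#' @param control A [qmed_control()].
#' @return List with `estimates` (length p), `selected`, `survivors`,
#'   `result` (the full `mediation_result`).
#' @export
run_repetition <- function(config, tau, rep_seed,
                           control = qmed_control()) {
  stopifnot(inherits(config, "sim_config"))
  config$seed <- as.integer(rep_seed)
  ds <- sim_generate(config)$dataset
  res <- qmediate(ds, tau, control)
  est <- numeric(config$p)
  if (nrow(res$tests)) est[res$tests$index] <- res$tests$effect
  list(estimates = est, selected = res$selected,
       survivors = res$tests$index, result = res)
}

#' Aggregate repetition results into evaluation metrics
#'
#' Computes, across repetitions: per-mediator bias (mean estimate minus
#' truth) and SSE (sampling standard deviation of the estimates), and the
#' selection metrics MS (mean selected-set size),
#' TPP \eqn{= |\hat\Omega \cap \Omega_0|/|\Omega_0|} and
#' FDP \eqn{= |\hat\Omega \setminus \Omega_0|/|\hat\Omega|} (0 for an empty
#' selection), averaged over repetitions, each with its Monte-Carlo
#' standard error.
#'
#' @param estimates Matrix (repetitions x p) of per-mediator effect
#'   estimates.
#' @param selections List of selected index vectors, one per repetition.
#' @param truth A [sim_truth()] list (provides `effects` and `active_set`).
#' @return Object of class `sim_metrics`: list with `bias`, `sse`
#'   (length-p vectors), `ms`, `tpp`, `fdp`, `ms_se`, `tpp_se`, `fdp_se`,
#'   `n_reps`, and the per-repetition vectors `ms_reps`, `tpp_reps`,
#'   `fdp_reps`.
#' @export
aggregate_metrics <- function(estimates, selections, truth) {
  estimates <- as.matrix(estimates)
  R <- nrow(estimates)
  if (R < 1L || length(selections) != R)
    stop("need >= 1 repetition with matching selections")
  omega0 <- truth$active_set
  ms <- vapply(selections, length, numeric(1))
  tpp <- vapply(selections, function(s)
    length(intersect(s, omega0)) / length(omega0), numeric(1))
  fdp <- vapply(selections, function(s)
    if (length(s)) length(setdiff(s, omega0)) / length(s) else 0,
    numeric(1))
  mc_se <- function(v) if (R > 1L) stats::sd(v) / sqrt(R) else NA_real_
  structure(
    list(bias = colMeans(estimates) - truth$effects,
         sse = apply(estimates, 2L, stats::sd),
         ms = mean(ms), tpp = mean(tpp), fdp = mean(fdp),
         ms_se = mc_se(ms), tpp_se = mc_se(tpp), fdp_se = mc_se(fdp),
         ms_reps = ms, tpp_reps = tpp, fdp_reps = fdp,
         n_reps = R),
    class = "sim_metrics")
}

#' @export
print.sim_metrics <- function(x, ...) {
  cat("<sim_metrics> reps =", x$n_reps,
      sprintf(" MS = %.4f (se %.4f)  TPP = %.4f (se %.4f)  FDP = %.4f (se %.4f)\n",
              x$ms, x$ms_se, x$tpp, x$tpp_se, x$fdp, x$fdp_se))
  invisible(x)
}

#' Deterministic per-repetition seed
#'
#' Repetition r of cell c uses seed
#' `base_seed + (c - 1) * 100000 + r`, so any repetition can be re-run in
#' isolation; keep `base_seed` below ~2e9 / number of cells.
#'
#' @param base_seed Study-level seed.
#' @param cell Cell index (1-based).
#' @param rep Repetition index (1-based).
#' @return Integer seed.
#' @export
rep_seed_for <- function(base_seed, cell, rep) {
  as.integer(base_seed + (cell - 1L) * 100000L + rep)
}

#' Run a simulation study over a grid of designs
#'
#' One [aggregate_metrics()] per grid cell; repetitions are seeded
#' deterministically via [rep_seed_for()].  Repetitions whose solver fails
#' are recorded and excluded from aggregation (never silently dropped).
#'
#' @param grid Data frame with columns `n`, `case`, `tau` (one row per
#'   cell); an optional `p` column overrides `p`.
#' @param reps Repetitions per cell.
#' @param base_seed Study seed.
#' @param p Number of mediators.
#' @param control A [qmed_control()].
#' @param track Mediator indices whose bias/SSE are reported in the table
#'   (default 1:6).
#' @param verbose Print per-cell progress.
#' @return List with `metrics` (list of `sim_metrics` per cell), `table`
#'   (data frame: one row per cell with MS/TPP/FDP, their MC SEs, tracked
#'   bias/SSE columns, failure count), and `manifest` (seeds and settings).
#' @export
run_study <- function(grid, reps, base_seed = 1L, p = 3000L,
                      control = qmed_control(), track = 1:6,
                      verbose = FALSE) {
  grid <- as.data.frame(grid)
  stopifnot(all(c("n", "case", "tau") %in% names(grid)))
  metrics <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  seeds_used <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    n <- grid$n[ci]; case <- as.character(grid$case[ci]); tau <- grid$tau[ci]
    pc <- if ("p" %in% names(grid)) grid$p[ci] else p
    cfg <- sim_config(n = n, p = pc, case = case)
    est <- matrix(NA_real_, reps, pc)
    sel <- vector("list", reps)
    ok <- logical(reps)
    seeds <- integer(reps)
    for (r in seq_len(reps)) {
      seeds[r] <- rep_seed_for(base_seed, ci, r)
      rep_out <- tryCatch(run_repetition(cfg, tau, seeds[r], control),
                          error = function(e) e)
      if (inherits(rep_out, "error")) {
        warning("cell ", ci, " repetition ", r, " failed: ",
                conditionMessage(rep_out))
        next
      }
      est[r, ] <- rep_out$estimates
      sel[[r]] <- rep_out$selected
      ok[r] <- TRUE
    }
    if (!any(ok)) stop("all repetitions failed in cell ", ci)
    truth <- sim_truth(cfg, tau)
    m <- aggregate_metrics(est[ok, , drop = FALSE], sel[ok], truth)
    metrics[[ci]] <- m
    seeds_used[[ci]] <- seeds
    row <- data.frame(n = n, case = case, tau = tau, p = pc,
                      reps = sum(ok), failed = sum(!ok),
                      ms = m$ms, ms_se = m$ms_se,
                      tpp = m$tpp, tpp_se = m$tpp_se,
                      fdp = m$fdp, fdp_se = m$fdp_se)
    for (k in track) {
      row[[paste0("bias", k)]] <- m$bias[k]
      row[[paste0("sse", k)]] <- m$sse[k]
    }
    rows[[ci]] <- row
    if (verbose)
      cat(sprintf("cell %d (n=%d, case %s, tau=%.2f): MS=%.3f TPP=%.3f FDP=%.4f\n",
                  ci, n, case, tau, m$ms, m$tpp, m$fdp))
  }
  list(metrics = metrics, table = do.call(rbind, rows),
       manifest = list(base_seed = base_seed, reps = reps, p = p,
                       seeds = seeds_used, control = control,
                       version = as.character(utils::packageVersion("qmediate"))))
}

#' One-mediator comparator scan (reduced fidelity)
#'
#' For each mediator separately, fits the marginal outcome quantile model
#' (intercept + exposure + mediator_k + covariates) and a mediator model on
#' exposure + covariates — OLS for `variant = "ols"`, median regression for
#' `variant = "median"` — then applies a joint-significance test with
#' Bonferroni correction over the p mediators.
#'
#' @param dataset A `mediation_dataset` (raw scale; standardized
#'   internally).
#' @param tau Outcome quantile level.
#' @param variant Mediator-model family.
#' @param level Significance level (default 0.05).
#' @param tol,maxit Solver controls.
#' @return List with `effects` (length p, \eqn{\hat\alpha_k
#'   \hat\beta_{k,\tau}}), `p_adjusted`, `selected` (indices with adjusted
#'   p < level).
#' @export
single_mediator_scan <- function(dataset, tau, variant = c("ols", "median"),
                                 level = 0.05, tol = 1e-8, maxit = 500L) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "mediation_dataset"))
  check_tau(tau)
  std <- standardize_mediators(dataset)
  sds <- std$dataset
  p <- sds$p; n <- sds$n
  marg <- marginal_effects(sds, tau, se = TRUE, tol = tol, maxit = maxit)
  beta <- marg$coefficients
  p_beta <- 2 * (1 - pnorm(abs(beta) / marg$standard_errors))
  alpha <- numeric(p); p_alpha <- numeric(p)
  Xmed <- cbind(1, sds$exposure, sds$covariates)
  for (k in seq_len(p)) {
    if (variant == "ols") {
      o <- ols_mediator_model(sds, k)
      alpha[k] <- o$alpha_hat; p_alpha[k] <- o$p_alpha
    } else {
      f <- fit_quantile(Xmed, sds$mediators[, k], 0.5, se = "kernel",
                        tol = tol, maxit = maxit)
      alpha[k] <- f$coefficients[2L]
      p_alpha[k] <- 2 * (1 - pnorm(abs(alpha[k]) / f$standard_errors[2L]))
    }
  }
  p_js <- pmax(p_alpha, p_beta)
  p_adj <- pmin(p * p_js, 1)
  list(effects = alpha * beta, p_adjusted = p_adj,
       selected = which(p_adj < level))
}
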