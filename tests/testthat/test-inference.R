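test_that("OLS mediator model matches lm and uses normal p-values", {
  set.seed(41)
  n <- 100
  X <- rnorm(n)
  Z <- matrix(rnorm(2 * n), n, 2)
  M <- cbind(m1 = 0.7 * X + 0.2 * Z[, 1] + rnorm(n))
  ds <- mediation_dataset(X, M, rnorm(n), Z)
  o <- ols_mediator_model(ds, 1)
  ref <- summary(lm(M[, 1] ~ X + Z))$coefficients
  expect_equal(o$alpha_hat, ref["X", "Estimate"], tolerance = 1e-10)
  expect_equal(o$se_alpha, ref["X", "Std. Error"], tolerance = 1e-10)
  expect_equal(o$p_alpha, 2 * (1 - pnorm(abs(o$alpha_hat) / o$se_alpha)))
})

test_that("noiseless mediator gives the exact alpha and p ~ 0", {
  X <- seq(-2, 2, length.out = 40)
  ds <- mediation_dataset(X, cbind(m = 0.5 * X + 1e-9 * sin(X)), rnorm(40))
  o <- ols_mediator_model(ds, 1)
  expect_equal(o$alpha_hat, 0.5, tolerance = 1e-6)
  expect_lt(o$p_alpha, 1e-12)
})

test_that("a z-score at the 97.5% normal quantile gives p = 0.05", {
  expect_equal(2 * (1 - pnorm(1.959964)), 0.05, tolerance = 1e-6)
})

test_that("alpha p-values are uniform under the null", {
  set.seed(42)
  reps <- 200
  pv <- numeric(reps)
  for (r in seq_len(reps)) {
    X <- rnorm(400)
    ds <- mediation_dataset(X, cbind(m = rnorm(400)), rnorm(400))
    pv[r] <- ols_mediator_model(ds, 1)$p_alpha
  }
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("JS statistic arithmetic, capping and monotonicity", {
  js <- js_statistic(0.001, 0.02, 5)
  expect_equal(js$p_js, 0.02)
  expect_equal(js$d_js, 0.1)
  expect_equal(js_statistic(0.5, 0.4, 3)$d_js, 1)
  expect_equal(js_statistic(0, 0, 7)$d_js, 0)
  expect_error(js_statistic(0.1, 0.1, 0), "d_tau")
  expect_error(js_statistic(-0.1, 0.5, 2), "p-values")
  # monotone in each argument
  set.seed(43)
  for (i in 1:50) {
    pa <- runif(1); pb <- runif(1); d <- sample(1:20, 1)
    base <- js_statistic(pa, pb, d)$d_js
    expect_gte(js_statistic(min(pa * 1.5, 1), pb, d)$d_js, base)
    expect_gte(js_statistic(pa, min(pb * 1.5, 1), d)$d_js, base)
    expect_gte(js_statistic(pa, pb, d + 3)$d_js, base)
  }
})

test_that("selection uses a strict threshold", {
  tests <- data.frame(index = 1:3, d_js = c(0.05, 0.049999, 1))
  expect_identical(select_mediators(tests), 2L)
  expect_identical(select_mediators(data.frame(index = 1:2, d_js = c(1, 1))),
                   integer(0))
})

test_that("controlled effects scale with the exposure contrast", {
  ce <- controlled_effects(0.5, c(0.2, 0.3), x = 1, x_star = 1)
  expect_equal(unlist(ce), c(cde = 0, cie = 0))
  expect_equal(controlled_effects(0.5, numeric(0), 1, 0)$cde, 0.5)
  # true per-unit CIE of the default design's first three mediators
  expect_equal(0.85 * 0.85 + 1.2 * 1.2 + 1 * 1, 3.1625)
  cfg <- sim_config(n = 50, p = 9, seed = 1)
  tr <- sim_truth(cfg, 0.5)
  expect_equal(sum(tr$effects[1:3]), 3.1625)
})

test_that("refit reduces to the plain fit and handles an empty survivor
           set", {
  set.seed(44)
  w <- toy_dataset(n = 80, p = 4)
  sds <- standardize_mediators(w)$dataset
  f0 <- refit_submodel(sds, integer(0), 0.5, se = "none")
  base <- fit_quantile_sharp(cbind(1, sds$exposure, sds$covariates),
                             sds$outcome, 0.5)
  expect_equal(unname(f0$coefficients), unname(base$coefficients),
               tolerance = 1e-4)
  f2 <- refit_submodel(sds, c(1L, 3L), 0.5, se = "none")
  expect_length(f2$coefficients, 2 + sds$q + 2)
  rows <- 1:24
  oracle <- exact_rq(cbind(1, sds$exposure[rows], sds$covariates[rows, ],
                           sds$mediators[rows, c(1, 3)]),
                     sds$outcome[rows], 0.5)
  f2small <- refit_submodel(
    mediation_dataset(sds$exposure[rows],
                      sds$mediators[rows, , drop = FALSE],
                      sds$outcome[rows], sds$covariates[rows, ]),
    c(1L, 3L), 0.5, se = "none", h_min = 1e-6)
  expect_equal(unname(f2small$coefficients), unname(oracle$coefficients),
               tolerance = 1e-5)
})

test_that("an overwhelming single mediation path is found", {
  set.seed(45)
  n <- 500
  X <- rnorm(n)
  M <- matrix(rnorm(n * 5), n, 5)
  M[, 1] <- 2 * X + rnorm(n, sd = 0.5)
  Y <- 2 * M[, 1] + rnorm(n, sd = 0.1)
  ds <- mediation_dataset(X, M, Y)
  res <- qmediate(ds, 0.5)
  expect_identical(res$selected, 1L)
  expect_equal(res$tests$effect[res$tests$index == 1], 4, tolerance = 0.3)
})

test_that("selection funnel is nested and the pipeline is deterministic", {
  w <- toy_dataset(n = 150, p = 25, seed = 46)
  r1 <- qmediate(w, 0.5)
  r2 <- qmediate(w, 0.5)
  expect_identical(r1$tests, r2$tests)
  expect_identical(r1$selected, r2$selected)
  s_tau <- r1$tests$index
  i_tau <- r1$screening$retained
  expect_true(all(r1$selected %in% s_tau))
  expect_true(all(s_tau %in% i_tau))
})

test_that("effect products are invariant to mediator rescaling", {
  w <- toy_dataset(n = 150, p = 10, seed = 47)
  M2 <- w$mediators
  M2[, 1] <- M2[, 1] * 7
  M2[, 2] <- M2[, 2] / 13
  w2 <- mediation_dataset(w$exposure, M2, w$outcome, w$covariates)
  r1 <- qmediate(w, 0.5)
  r2 <- qmediate(w2, 0.5)
  expect_identical(r1$tests$index, r2$tests$index)
  expect_equal(r1$tests$effect, r2$tests$effect, tolerance = 1e-8)
  expect_equal(r1$tests$alpha_std * r1$tests$beta_std,
               r1$tests$alpha_hat * r1$tests$beta_hat, tolerance = 1e-10)
})

test_that("result tables expose the documented schema", {
  w <- toy_dataset(n = 120, p = 8, seed = 48)
  res <- qmediate(w, 0.5)
  tabs <- result_tables(res)
  expect_named(tabs$summary,
               c("tau", "n", "p", "d", "n_survivors", "n_selected",
                 "gamma_hat", "total_cie"))
  expect_true(all(c("index", "name", "alpha_hat", "se_alpha", "beta_hat",
                    "se_beta", "p_alpha", "p_beta", "p_js", "d_js",
                    "effect", "selected") %in% names(tabs$tests)))
})
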