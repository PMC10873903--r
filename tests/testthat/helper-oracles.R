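# Independent oracles used across the suite.

# Exact check-loss minimizer by basis enumeration: some optimal quantile
# regression interpolates k observations, so enumerate all size-k subsets,
# solve the interpolation system, and keep the subset with smallest total
# check loss.  Only viable for small n.
exact_rq <- function(X, y, tau) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(n <= 40)
  best <- NULL
  best_loss <- Inf
  for (S in utils::combn(n, k, simplify = FALSE)) {
    XS <- X[S, , drop = FALSE]
    d <- determinant(XS, logarithm = FALSE)
    if (abs(as.numeric(d$modulus)) < 1e-10) next
    b <- solve(XS, y[S])
    loss <- sum(check_loss(y - X %*% b, tau))
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best <- drop(b)
    }
  }
  list(coefficients = best, loss = best_loss)
}

# Drive the smoothed solver toward the exact solution by shrinking the
# bandwidth with warm starts (continuation).
fit_quantile_sharp <- function(X, y, tau, h_final = 1e-6) {
  hs <- 2^-(1:30)
  hs <- c(hs[hs > h_final], h_final)
  start <- NULL
  fit <- NULL
  for (h in hs) {
    fit <- fit_quantile(X, y, tau, h = h, se = "none", start = start)
    start <- fit$coefficients
  }
  fit
}

# Brute-force scalar MCP proximal oracle on a fine grid containing the
# optimum (which always lies between 0 and z, or at z).
mcp_prox_grid <- function(z, w, lam, delta, step = 1e-5) {
  hi <- max(abs(z), delta * lam) + 2 * step
  grid <- seq(-hi, hi, by = step)
  obj <- w * (z - grid)^2 / 2 + mcp_penalty(grid, lam, delta)
  grid[which.min(obj)]
}

# Gaussian-kernel smoothed check loss (mirrors the solver's objective).
smoothed_check_loss <- function(r, tau, h) {
  u <- r / h
  mean((tau - 0.5) * r +
         0.5 * (r * (1 - 2 * pnorm(-u)) + 2 * h * dnorm(u)))
}

# Small dense mediation dataset with known single strong path, built by
# hand (not via sim_config) so tests do not depend on the generator.
toy_dataset <- function(n = 150, p = 10, seed = 42, strong = 1,
                        a = 1.5, b = 1.5, noise = 0.5) {
  set.seed(seed)
  X <- rnorm(n)
  M <- matrix(rnorm(n * p), n, p)
  M[, strong] <- a * X + rnorm(n, sd = 0.5)
  Z <- matrix(rnorm(n * 2), n, 2)
  Y <- 0.5 * X + b * M[, strong] + 0.3 * Z[, 1] + rnorm(n, sd = noise)
  mediation_dataset(X, M, Y, Z)
}
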