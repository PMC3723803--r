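# Independent oracles and fixture builders shared across test files.

# Normal-equation OLS oracle: coefficients, SEs, RSS computed directly from
# the design matrix, independently of the fitting code under test.
oracle_ols <- function(X, y) {
  XtX_inv <- solve(crossprod(X))
  beta <- drop(XtX_inv %*% crossprod(X, y))
  resid <- drop(y - X %*% beta)
  rss <- sum(resid^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  list(beta = beta, se = sqrt(diag(XtX_inv) * sigma2), rss = rss,
       resid = resid, sigma2 = sigma2, XtX_inv = XtX_inv)
}

# design matrices mirroring the package's model definitions
design_simple <- function(aoa, center) cbind(1, aoa - center)
design_breakpoint <- function(aoa, bp) {
  xc <- aoa - bp
  cbind(1, xc, xc * (aoa <= bp))
}

# small random dataset with a linear + noise structure, valid as aoa_data
random_dataset <- function(n, seed, slope = -1, intercept = 170,
                           noise_sd = 8, aoa_range = c(5, 60)) {
  withr::with_seed(seed, {
    aoa <- sample(seq(aoa_range[1], aoa_range[2]), n, replace = TRUE)
    # ensure at least 2 distinct ages
    if (length(unique(aoa)) < 2) aoa[1:2] <- aoa_range
    gjt <- pmin(pmax(intercept + slope * (aoa - 18) + rnorm(n, 0, noise_sd),
                     0), 204)
    aoa_data(aoa, gjt, study_label = sprintf("random_%d", seed))
  })
}

# exact piecewise-linear (noiseless) dataset with a kink
kinked_dataset <- function(bp = 10, s1 = 0, s2 = -1.5, intercept = 180,
                           aoa = 5:40) {
  gjt <- ifelse(aoa <= bp, intercept + s1 * (aoa - bp),
                intercept + s2 * (aoa - bp))
  aoa_data(aoa, gjt, study_label = "kinked")
}

expect_rel_equal <- function(actual, expected, tol) {
  denom <- pmax(abs(expected), 1)
  expect_lt(max(abs(actual - expected) / denom), tol)
}
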