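#' Huber M-estimation of the simple or breakpoint model
#'
#' Robust refit of the same mean structure as [fit_ols()] /
#' [fit_breakpoint()], downweighting large residuals so that conclusions do
#' not hinge on a handful of extreme scores — the standard first response
#' to the heteroscedasticity endemic in age-effect data (attainment
#' variance tends to grow with AOA). Estimation is iteratively reweighted
#' least squares with Huber's psi (tuning constant 1.345, 95% efficiency
#' under Gaussian errors) and MAD residual scale, via [MASS::rlm()].
#'
#' @param data an [aoa_data] object.
#' @param breakpoint breakpoint age, or `NULL` for the simple model.
#' @param center_at intercept evaluation age for the simple model (ignored
#'   for breakpoint fits, which centre at the breakpoint).
#' @param k Huber tuning constant.
#' @param maxit,acc IRLS iteration cap and coefficient-change convergence
#'   tolerance.
#' @return An `aoa_fit` with `estimator = "huber"`; `$converged` is `FALSE`
#'   (with a warning) if IRLS did not converge.
#' @export
fit_robust <- function(data, breakpoint = NULL, center_at = 18, k = 1.345,
                       maxit = 100, acc = 1e-8) {
  stopifnot(inherits(data, "aoa_data"))
  if (!is.null(breakpoint)) {
    check_segments(data, breakpoint)
    center_at <- breakpoint
  } else if (length(unique(data$aoa)) < 2L) {
    stop("degenerate design: all `aoa` values are identical", call. = FALSE)
  }
  fr <- build_frame(data, center_at, breakpoint)
  m <- MASS::rlm(fit_formula(breakpoint), data = fr, psi = MASS::psi.huber,
                 k = k, scale.est = "MAD", maxit = maxit, acc = acc)
  if (!m$converged) {
    warning("Huber IRLS did not converge within `maxit` iterations")
  }
  new_aoa_fit(m, data, center_at, breakpoint, estimator = "huber",
              converged = m$converged)
}

#' Generalised least squares with variance increasing linearly in AOA
#'
#' Fits the same mean structure as [fit_ols()] / [fit_breakpoint()] under
#' the heteroscedastic error model Var(e_i) = sigma^2 * (1 + gamma * aoa_i),
#' by profile maximum likelihood: for each gamma the coefficients are the
#' weighted least-squares solution and sigma^2 its ML estimate, and gamma
#' maximises the resulting profile log-likelihood over
#' (-1/max(aoa) + eps, upper). gamma = 0 recovers OLS exactly, and the
#' returned optimum is never worse than gamma = 0. ML (not REML) is used so
#' likelihoods of nested mean structures remain comparable.
#'
#' @inheritParams fit_robust
#' @param gamma_upper upper search bound for the variance slope.
#' @return An `aoa_fit` with `estimator = "gls"` and an extra element
#'   `variance_model = list(sigma2, gamma, loglik)`. A warning flags an
#'   optimum on the search boundary.
#' @export
fit_gls_linear_variance <- function(data, breakpoint = NULL, center_at = 18,
                                    gamma_upper = 100) {
  stopifnot(inherits(data, "aoa_data"))
  if (!is.null(breakpoint)) {
    check_segments(data, breakpoint)
    center_at <- breakpoint
  } else if (length(unique(data$aoa)) < 2L) {
    stop("degenerate design: all `aoa` values are identical", call. = FALSE)
  }
  fr <- build_frame(data, center_at, breakpoint)
  fml <- fit_formula(breakpoint)
  n <- nrow(fr)
  aoa <- data$aoa

  profile_fit <- function(gamma) {
    fr$w <- 1 / (1 + gamma * aoa)
    m <- lm(fml, data = fr, weights = w)
    w <- fr$w
    sigma2 <- sum(w * residuals(m)^2) / n
    ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) -
      sum(log(1 + gamma * aoa)) / 2
    list(model = m, sigma2 = sigma2, loglik = ll)
  }

  lower <- -1 / max(aoa) + 1e-6
  opt <- optimize(function(g) -profile_fit(g)$loglik,
                  interval = c(lower, gamma_upper), tol = 1e-8)
  gamma <- opt$minimum
  best <- profile_fit(gamma)
  null_fit <- profile_fit(0)
  if (null_fit$loglik >= best$loglik) {  # guard against optimiser misses
    gamma <- 0
    best <- null_fit
  }
  if (gamma < lower + 1e-4 || gamma > gamma_upper - 1e-4) {
    warning("variance-slope estimate lies on the search boundary")
  }
  out <- new_aoa_fit(best$model, data, center_at, breakpoint,
                     estimator = "gls")
  out$variance_model <- list(sigma2 = best$sigma2, gamma = gamma,
                             loglik = best$loglik)
  out
}

#' Refit after excluding records that are outliers under both models
#'
#' Flags records whose internally studentized residual exceeds `threshold`
#' in absolute value in *both* the simple model and the breakpoint model,
#' removes them, and refits both models — the sensitivity check for
#' conclusions driven by individual participants.
#'
#' @param data an [aoa_data] object.
#' @param breakpoint breakpoint age for the piecewise model.
#' @param threshold absolute studentized-residual cut-off.
#' @param center_at intercept evaluation age for the simple fits.
#' @return list with elements `excluded` (data frame of flagged records,
#'   possibly empty), `original` and `refit` (each a list with `simple` and
#'   `breakpoint` fits; `refit` equals `original` when nothing is flagged).
#' @export
refit_without_outliers <- function(data, breakpoint = 18, threshold = 2.5,
                                   center_at = 18) {
  stopifnot(inherits(data, "aoa_data"), threshold > 0)
  simple <- fit_ols(data, center_at = center_at)
  bp <- fit_breakpoint(data, breakpoint)
  flag <- abs(standardized_residuals(simple)) > threshold &
    abs(standardized_residuals(bp)) > threshold
  excluded <- as.data.frame(data)[flag, , drop = FALSE]
  if (!any(flag)) {
    return(list(excluded = excluded,
                original = list(simple = simple, breakpoint = bp),
                refit = list(simple = simple, breakpoint = bp)))
  }
  kept <- aoa_data(data$aoa[!flag], data$gjt[!flag],
                   study_label = study_label(data), check_scale = FALSE)
  list(excluded = excluded,
       original = list(simple = simple, breakpoint = bp),
       refit = list(simple = fit_ols(kept, center_at = center_at),
                    breakpoint = fit_breakpoint(kept, breakpoint)))
}
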