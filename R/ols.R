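# Shared fit infrastructure: every mean model in the package is a linear
# model in a small design built from (possibly breakpoint-centred) aoa.

# Build the model frame for a simple or breakpoint design. `center_at` is
# the age at which the intercept is evaluated; for breakpoint designs the
# centring age *is* the breakpoint, which is what joins the two segments.
build_frame <- function(data, center_at, breakpoint = NULL) {
  if (is.null(breakpoint)) {
    data.frame(gjt = data$gjt, xc = data$aoa - center_at)
  } else {
    xc <- data$aoa - breakpoint
    before <- as.numeric(data$aoa <= breakpoint)  # segment membership: aoa <= bp
    data.frame(gjt = data$gjt, xc = xc, xc_before = xc * before)
  }
}

fit_formula <- function(breakpoint = NULL) {
  if (is.null(breakpoint)) gjt ~ xc else gjt ~ xc + xc_before
}

new_aoa_fit <- function(model, data, center_at, breakpoint, estimator,
                        converged = TRUE) {
  structure(
    list(model = model, data = data, center_at = center_at,
         breakpoint = breakpoint, estimator = estimator,
         converged = converged),
    class = c(if (!is.null(breakpoint)) "aoa_breakpoint_fit", "aoa_fit")
  )
}

#' Fit a simple linear regression of attainment on age of onset
#'
#' Ordinary least squares fit of the GJT score on AOA, with the predictor
#' centred at `center_at` so that the reported intercept is the predicted
#' score at that age (centring changes only the intercept, never the slope
#' or the fit).
#'
#' @param data an [aoa_data] object.
#' @param center_at age (years) at which the intercept is evaluated.
#' @return An object of class `"aoa_fit"`; see [coef_table()],
#'   [information_criteria()], [standardized_residuals()],
#'   [confidence_band()].
#' @examples
#' d <- generate_aoa_data("linear", slopes = -1.2, intercept = 168,
#'                        n = 60, seed = 1)
#' fit_ols(d, center_at = 18)
#' @export
fit_ols <- function(data, center_at = 18) {
  stopifnot(inherits(data, "aoa_data"))
  if (length(unique(data$aoa)) < 2L) {
    stop("degenerate design: all `aoa` values are identical", call. = FALSE)
  }
  fr <- build_frame(data, center_at)
  new_aoa_fit(lm(fit_formula(), data = fr), data, center_at,
              breakpoint = NULL, estimator = "ols")
}

# number of identified mean-model parameters (aliased terms not counted)
n_mean_params <- function(fit) sum(!is.na(coef(fit$model)))

#' @export
deviance.aoa_fit <- function(object, ...) sum(residuals(object$model)^2)

#' @export
residuals.aoa_fit <- function(object, ...) residuals(object$model)

#' @export
logLik.aoa_fit <- function(object, ...) {
  n <- nrow(object$data)
  dev <- deviance(object)
  if (dev <= .Machine$double.eps * max(1, sum(object$data$gjt^2))) {
    stop("undefined likelihood: the fit is exact (deviance 0)", call. = FALSE)
  }
  # full Gaussian log-likelihood at the ML variance estimate dev/n
  ll <- -n / 2 * (log(2 * pi) + log(dev / n) + 1)
  structure(ll, df = n_mean_params(fit = object) + 1, nobs = n,
            class = "logLik")
}

#' Akaike and Bayesian information criteria of a fit
#'
#' Both criteria are computed from the full Gaussian log-likelihood
#' (including the 2*pi constant) and count the residual-variance parameter
#' in addition to the mean-model terms, i.e. the convention of
#' [stats::AIC()] for `lm` fits. An exact fit (deviance 0) has no defined
#' likelihood and raises an error.
#'
#' @param fit an `aoa_fit`.
#' @return named numeric vector `c(aic = ..., bic = ...)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "aoa_fit"))
  ll <- logLik(fit)  # errors on deviance 0
  c(aic = AIC(ll), bic = BIC(ll))
}

#' R-squared of a fit
#' @param fit an `aoa_fit`.
#' @return fraction of GJT variance accounted for.
#' @export
r_squared <- function(fit) {
  tss <- sum((fit$data$gjt - mean(fit$data$gjt))^2)
  1 - deviance(fit) / tss
}

#' Overall F-test of model fit
#' @param fit an `aoa_fit` estimated by OLS.
#' @return named vector `c(f, df1, df2, p)` testing all slope terms jointly
#'   against the intercept-only model.
#' @export
fit_ftest <- function(fit) {
  stopifnot(inherits(fit, "aoa_fit"))
  if (fit$estimator != "ols") {
    stop("the overall F-test is defined for OLS fits only", call. = FALSE)
  }
  n <- nrow(fit$data)
  k <- n_mean_params(fit)
  df1 <- k - 1
  df2 <- n - k
  tss <- sum((fit$data$gjt - mean(fit$data$gjt))^2)
  f <- ((tss - deviance(fit)) / df1) / (deviance(fit) / df2)
  c(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Coefficient table on the per-segment reporting scale
#'
#' For a simple fit: intercept (predicted score at the centring age) and
#' slope. For a breakpoint fit: intercept (predicted score at the
#' breakpoint) and the two per-segment slopes, `slope (aoa <= bp)` and
#' `slope (aoa > bp)`. Internally the breakpoint model is parameterised as
#' intercept + global slope + (indicator x centred-aoa) difference term;
#' the table converts to per-segment slopes, with the before-segment
#' standard error obtained from the coefficient covariance.
#'
#' @param fit an `aoa_fit`.
#' @return data frame with columns `term`, `estimate`, `se`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "aoa_fit"))
  b <- coef(fit$model)
  V <- vcov(fit$model)
  if (is.null(fit$breakpoint)) {
    data.frame(term = c("intercept", "slope"),
               estimate = unname(b[c("(Intercept)", "xc")]),
               se = sqrt(diag(V)[c("(Intercept)", "xc")]),
               row.names = NULL)
  } else {
    bp <- fit$breakpoint
    slope_after <- unname(b["xc"])
    if (is.na(b["xc_before"])) {
      # aliased slope-change term (single distinct age in the segment)
      slope_before <- NA_real_
      se_before <- NA_real_
    } else {
      slope_before <- unname(b["xc"] + b["xc_before"])
      se_before <- sqrt(V["xc", "xc"] + V["xc_before", "xc_before"] +
                          2 * V["xc", "xc_before"])
    }
    data.frame(term = c("intercept",
                        sprintf("slope (aoa <= %g)", bp),
                        sprintf("slope (aoa > %g)", bp)),
               estimate = c(unname(b["(Intercept)"]), slope_before,
                            slope_after),
               se = c(sqrt(V["(Intercept)", "(Intercept)"]), se_before,
                      sqrt(V["xc", "xc"])),
               row.names = NULL)
  }
}

#' @export
print.aoa_fit <- function(x, digits = 2, ...) {
  kind <- if (is.null(x$breakpoint)) "simple linear model"
          else sprintf("breakpoint model (breakpoint at aoa %g)", x$breakpoint)
  cat(sprintf("%s fit [%s], study '%s'\n", kind, x$estimator,
              study_label(x$data)))
  ct <- coef_table(x)
  ct$estimate <- round(ct$estimate, digits)
  ct$se <- round(ct$se, digits)
  print(ct, row.names = FALSE)
  if (x$estimator == "ols") {
    ft <- fit_ftest(x)
    cat(sprintf("R2 = %.2f, F(%d,%d) = %.1f, p = %.3g, deviance = %.1f\n",
                r_squared(x), ft["df1"], ft["df2"], ft["f"], ft["p"],
                deviance(x)))
  } else {
    cat(sprintf("deviance (RSS) = %.1f%s\n", deviance(x),
                if (!x$converged) " [NOT CONVERGED]" else ""))
  }
  invisible(x)
}

#' Internally studentized residuals
#'
#' Residuals divided by their estimated standard deviation
#' `s * sqrt(1 - h_i)` with `h_i` the leverage — the influence-measure
#' convention used to flag outlying records (conventional cut-off:
#' absolute value above 2.5).
#'
#' @param fit an OLS `aoa_fit`.
#' @return numeric vector, one value per record.
#' @export
standardized_residuals <- function(fit) {
  stopifnot(inherits(fit, "aoa_fit"))
  if (fit$estimator != "ols") {
    stop("standardized residuals are computed for OLS fits", call. = FALSE)
  }
  if (deviance(fit) <= .Machine$double.eps * sum(fit$data$gjt^2)) {
    return(rep(0, nrow(fit$data)))  # exact fit: residuals are identically 0
  }
  unname(rstandard(fit$model))
}

# mean prediction and its standard error at arbitrary ages
predict_mean <- function(fit, aoa, se = FALSE) {
  nd <- build_frame(aoa_data_stub(aoa), fit$center_at, fit$breakpoint)
  nd$gjt <- NULL
  pr <- predict(fit$model, newdata = nd, se.fit = se)
  if (se) list(fit = unname(pr$fit), se = unname(pr$se.fit))
  else unname(pr)
}

# minimal frame carrying aoa for prediction (bypasses aoa_data validation,
# since prediction grids may extend beyond the observed range)
aoa_data_stub <- function(aoa) data.frame(aoa = aoa, gjt = NA_real_)
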