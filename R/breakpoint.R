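#' Fit a joined piecewise (breakpoint) regression
#'
#' Linear model in which the AOA slope is allowed to change at a known
#' breakpoint age. The predictor is centred at the breakpoint and the slope
#' change enters through a binary segment indicator multiplied by the
#' centred predictor, so the two segments are constrained to meet at the
#' breakpoint (no jump). The "before" segment contains records with
#' `aoa <= breakpoint`.
#'
#' @param data an [aoa_data] object.
#' @param breakpoint breakpoint age in years.
#' @return An object of class `c("aoa_breakpoint_fit", "aoa_fit")`.
#' @examples
#' d <- generate_aoa_data("flat_then_decline", slopes = c(0, -1.5),
#'                        breakpoints = 18, intercept = 170, n = 80,
#'                        noise_sd = 5, seed = 1)
#' fit_breakpoint(d, breakpoint = 18)
#' @export
fit_breakpoint <- function(data, breakpoint) {
  stopifnot(inherits(data, "aoa_data"), is.numeric(breakpoint),
            length(breakpoint) == 1L)
  check_segments(data, breakpoint)
  fr <- build_frame(data, center_at = breakpoint, breakpoint = breakpoint)
  new_aoa_fit(lm(fit_formula(breakpoint), data = fr), data,
              center_at = breakpoint, breakpoint = breakpoint,
              estimator = "ols")
}

# each segment must hold >= 2 records; a segment whose records all share
# one age leaves that segment's slope unidentified (aliased coefficient),
# which is tolerated -- the fitted mean and deviance are still defined
check_segments <- function(data, breakpoint) {
  n_before <- sum(data$aoa <= breakpoint)
  n_after <- sum(data$aoa > breakpoint)
  if (n_before < 2L || n_after < 2L) {
    stop(sprintf(paste0("segment underflow: breakpoint %g leaves fewer than ",
                        "2 observations on one side"), breakpoint),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Deviance profile over a grid of candidate breakpoints
#'
#' Fits one joined piecewise model per candidate breakpoint on an integer
#' age grid and records each model's deviance (residual sum of squares).
#' The optimal breakpoint is the deviance minimiser; exact ties are broken
#' towards the smallest candidate age, and the result does not depend on
#' the order in which the grid is supplied. Candidates that leave fewer
#' than two distinct ages in a segment are dropped with a warning.
#'
#' @param data an [aoa_data] object.
#' @param grid_min,grid_max inclusive bounds of the integer candidate grid;
#'   the default 5-19 covers breakpoints compatible with a critical period
#'   ending before maturity.
#' @return An object of class `"deviance_profile"`: a data frame with
#'   columns `breakpoint` and `deviance`, attribute `optimum`.
#' @export
scan_breakpoints <- function(data, grid_min = 5, grid_max = 19) {
  stopifnot(inherits(data, "aoa_data"), grid_min <= grid_max)
  grid <- sort(unique(as.integer(seq(ceiling(grid_min), floor(grid_max)))))
  ok <- vapply(grid, function(bp) {
    sum(data$aoa <= bp) >= 2L && sum(data$aoa > bp) >= 2L
  }, logical(1))
  if (!any(ok)) {
    stop("no candidate breakpoint on the grid is fittable", call. = FALSE)
  }
  if (any(!ok)) {
    warning(sprintf("dropping unfittable candidate breakpoints: %s",
                    paste(grid[!ok], collapse = ", ")))
  }
  grid <- grid[ok]
  dev <- vapply(grid, function(bp) deviance(fit_breakpoint(data, bp)),
                numeric(1))
  out <- data.frame(breakpoint = grid, deviance = dev)
  attr(out, "optimum") <- grid[which.min(dev)]  # first minimum = smallest bp
  class(out) <- c("deviance_profile", "data.frame")
  out
}

#' @rdname scan_breakpoints
#' @param profile a `deviance_profile`.
#' @export
optimal_breakpoint <- function(profile) {
  stopifnot(inherits(profile, "deviance_profile"))
  attr(profile, "optimum")
}

#' @export
print.deviance_profile <- function(x, ...) {
  cat(sprintf("Deviance profile over %d candidate breakpoints (optimum: aoa %g)\n",
              nrow(x), attr(x, "optimum")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Compare a simple fit against a breakpoint fit on the same data
#'
#' Nested-model F-test: F = ((D_simple - D_full) / dk) / (D_full / df_full),
#' referred to its upper tail (the test asks only whether the richer model
#' reduces the residual sum of squares, so it is one-tailed by
#' construction). AIC and BIC differences are reported alongside. The
#' breakpoint model is preferred only when p < alpha.
#'
#' Note that when the breakpoint was itself chosen by minimising deviance
#' over a grid, the nominal p-value of this test is optimistic: the
#' selection step inflates the type-I error, and a "borderline" result for
#' a scanned optimum should be read accordingly.
#'
#' @param simple an `aoa_fit` without breakpoint.
#' @param breakpoint_model an `aoa_breakpoint_fit` on the same data.
#' @param alpha significance level for the preference rule.
#' @return An object of class `"model_comparison"` with fields `f_stat`,
#'   `df1`, `df2`, `p_one_tailed`, `delta_aic`, `delta_bic` (breakpoint
#'   minus simple), `preferred`.
#' @export
compare_nested <- function(simple, breakpoint_model, alpha = 0.05) {
  stopifnot(inherits(simple, "aoa_fit"),
            inherits(breakpoint_model, "aoa_breakpoint_fit"))
  if (!is.null(simple$breakpoint)) {
    stop("`simple` must be a fit without breakpoint", call. = FALSE)
  }
  if (nrow(simple$data) != nrow(breakpoint_model$data) ||
      !isTRUE(all.equal(simple$data$gjt, breakpoint_model$data$gjt)) ||
      !isTRUE(all.equal(simple$data$aoa, breakpoint_model$data$aoa))) {
    stop("model mismatch: the two fits are not on the same dataset",
         call. = FALSE)
  }
  d_s <- deviance(simple)
  d_f <- deviance(breakpoint_model)
  dk <- n_mean_params(breakpoint_model) - n_mean_params(simple)
  df2 <- nrow(breakpoint_model$data) - n_mean_params(breakpoint_model)
  f <- ((d_s - d_f) / dk) / (d_f / df2)
  p <- pf(f, dk, df2, lower.tail = FALSE)
  ic_s <- information_criteria(simple)
  ic_f <- information_criteria(breakpoint_model)
  structure(
    list(f_stat = f, df1 = dk, df2 = df2, p_one_tailed = p,
         delta_aic = unname(ic_f["aic"] - ic_s["aic"]),
         delta_bic = unname(ic_f["bic"] - ic_s["bic"]),
         alpha = alpha,
         preferred = if (p < alpha) "breakpoint" else "simple",
         breakpoint = breakpoint_model$breakpoint),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "Simple vs breakpoint (aoa %g): F(%d,%d) = %.2f, one-tailed p = %.3g\n",
    x$breakpoint, x$df1, x$df2, x$f_stat, x$p_one_tailed))
  cat(sprintf("delta AIC = %.1f, delta BIC = %.1f (breakpoint - simple)\n",
              x$delta_aic, x$delta_bic))
  cat(sprintf("preferred at alpha = %g: %s model\n", x$alpha, x$preferred))
  invisible(x)
}

#' Pointwise confidence band for the fitted mean response
#'
#' Classical t-based band for the conditional mean at each grid age:
#' fitted value plus/minus the t quantile times the prediction standard
#' error derived from the coefficient covariance.
#'
#' @param fit an OLS `aoa_fit` (simple or breakpoint).
#' @param grid ages at which to evaluate the band; defaults to the observed
#'   ages. Ages outside the observed range trigger a warning but are still
#'   computed.
#' @param level confidence level in (0, 1).
#' @return data frame with columns `aoa`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "aoa_fit"), level > 0, level < 1)
  if (is.null(grid)) grid <- sort(unique(fit$data$aoa))
  if (any(grid < min(fit$data$aoa) | grid > max(fit$data$aoa))) {
    warning("confidence band requested outside the observed aoa range")
  }
  pr <- predict_mean(fit, grid, se = TRUE)
  tq <- qt((1 + level) / 2, df.residual(fit$model))
  data.frame(aoa = grid, fit = pr$fit,
             lower = pr$fit - tq * pr$se, upper = pr$fit + tq * pr$se)
}
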