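#' Exact power of a two-sample t-test with unequal group sizes
#'
#' Power is computed from the noncentral t distribution with
#' noncentrality d * sqrt(n1 * n2 / (n1 + n2)) and n1 + n2 - 2 degrees of
#' freedom, with both rejection tails counted in the two-tailed case — no
#' normal approximation. This is what determines whether a non-significant
#' group comparison can be read as evidence of "no difference": with the
#' group sizes typical of critical-period studies, power for a medium
#' effect (d = 0.5) can be as low as 0.20.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d standardized effect size (Cohen's d).
#' @param alpha significance level in (0, 1).
#' @param tails 1 or 2.
#' @return the power, a probability.
#' @examples
#' t2n_power(7, 23, d = 0.5)               # ~0.20
#' t2n_power(105, 105, d = 0.5)            # ~0.95
#' @export
t2n_power <- function(n1, n2, d, alpha = 0.05, tails = 2) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n1 + n2 - 2
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 2) {
    crit <- qt(1 - alpha / 2, df)
    pt(-crit, df, ncp) + pt(crit, df, ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - alpha, df)
    pt(crit, df, ncp, lower.tail = FALSE)
  }
}

#' Smallest equal per-group n reaching a target power
#'
#' Finds the smallest n such that [t2n_power()] with n per group reaches
#' `target_power`, by doubling to bracket the target and then integer
#' bisection (power is strictly increasing in n for d != 0).
#'
#' @param d standardized effect size, non-zero.
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @param target_power required power, in (alpha, 1).
#' @param n_max largest per-group n considered before declaring the target
#'   unreachable.
#' @return integer per-group sample size.
#' @examples
#' solve_n_for_power(d = 0.5, target_power = 0.95)  # 105
#' @export
solve_n_for_power <- function(d, alpha = 0.05, tails = 2, target_power = 0.95,
                              n_max = 1e7) {
  stopifnot(target_power > alpha, target_power < 1)
  if (d == 0) {
    stop("no solution: power equals alpha for every n when d = 0",
         call. = FALSE)
  }
  lo <- 2L
  if (t2n_power(lo, lo, d, alpha, tails) >= target_power) return(lo)
  hi <- 4L
  while (t2n_power(hi, hi, d, alpha, tails) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) {
      stop("no solution: target power unreachable within `n_max`",
           call. = FALSE)
    }
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (t2n_power(mid, mid, d, alpha, tails) >= target_power) hi <- mid
    else lo <- mid
  }
  hi
}
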