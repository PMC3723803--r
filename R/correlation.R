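#' Fisher's r-to-z transformation
#'
#' z = atanh(r) = 0.5 * log((1 + r) / (1 - r)), the variance-stabilising
#' transform under which an independent sample correlation has approximate
#' variance 1 / (n - 3).
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("`r` must lie strictly inside (-1, 1)", call. = FALSE)
  }
  atanh(r)
}

#' Significance test for a correlation coefficient
#'
#' t = r * sqrt(n - 2) / sqrt(1 - r^2), referred to a t distribution with
#' n - 2 degrees of freedom. Note the cliff this creates near conventional
#' thresholds: at n = 50, r = 0.28 is significant at the two-tailed 0.05
#' level while r = 0.27 is not — which is why a significant r in one group
#' and a non-significant r in another never shows the two correlations
#' differ (see [compare_correlations()]).
#'
#' @param r correlation, |r| < 1.
#' @param n number of pairs, at least 4.
#' @param tails 1 or 2.
#' @return named vector `c(t_stat, df, p)`.
#' @export
r_significance <- function(r, n, tails = 2) {
  stopifnot(length(r) == 1L, length(n) == 1L, n >= 4, tails %in% c(1, 2))
  if (abs(r) >= 1) {
    stop("|r| = 1 gives an infinite test statistic", call. = FALSE)
  }
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- if (tails == 2) 2 * pt(-abs(t_stat), n - 2)
       else pt(abs(t_stat), n - 2, lower.tail = FALSE)
  c(t_stat = t_stat, df = n - 2, p = p)
}

#' Compare two independent correlation coefficients
#'
#' The correct procedure for asking whether two correlations from
#' independent samples differ: transform both with [fisher_z()] and refer
#' z_stat = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3)) to the standard
#' normal distribution.
#'
#' @param r1,n1 correlation and number of pairs in the first sample.
#' @param r2,n2 correlation and number of pairs in the second sample.
#' @return An object of class `"correlation_comparison"`: list with `r1`,
#'   `n1`, `r2`, `n2`, `z1`, `z2`, `z_stat`, `p_one_tailed`, `p_two_tailed`.
#' @examples
#' compare_correlations(-0.37, 17, 0.45, 32)
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  stopifnot(length(r1) == 1L, length(r2) == 1L)
  if (n1 <= 3 || n2 <= 3) {
    stop("the z variance 1/(n - 3) requires n >= 4 in both samples",
         call. = FALSE)
  }
  z1 <- fisher_z(r1)
  z2 <- fisher_z(r2)
  z_stat <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(
    list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z1 = z1, z2 = z2,
         z_stat = z_stat,
         p_one_tailed = pnorm(abs(z_stat), lower.tail = FALSE),
         p_two_tailed = 2 * pnorm(abs(z_stat), lower.tail = FALSE)),
    class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("r1 = %.2f (n = %d) vs r2 = %.2f (n = %d)\n",
              x$r1, x$n1, x$r2, x$n2))
  cat(sprintf("Fisher z difference: z = %.2f, one-tailed p = %.4f, two-tailed p = %.4f\n",
              x$z_stat, x$p_one_tailed, x$p_two_tailed))
  invisible(x)
}

#' First-order partial correlation from zero-order correlations
#'
#' r_xy.z = (r_xy - r_xz * r_yz) / (sqrt(1 - r_xz^2) * sqrt(1 - r_yz^2)).
#' The three inputs must form a positive semidefinite correlation matrix.
#' The formula makes explicit why partial correlations shrink as the
#' correlation between the "independent" variables (r_xz) grows even when
#' nothing about the x-y relationship changes — the sampling-imbalance
#' artefact that undermines comparing partial correlations across
#' differently-sampled age groups.
#'
#' @param r_xy,r_xz,r_yz zero-order correlations.
#' @return the partial correlation of x and y given z.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  stopifnot(length(r_xy) == 1L, length(r_xz) == 1L, length(r_yz) == 1L)
  if (abs(r_xz) >= 1 || abs(r_yz) >= 1) {
    stop("perfect confounding: |r_xz| or |r_yz| equals 1", call. = FALSE)
  }
  if (abs(r_xy) > 1) stop("|r_xy| must not exceed 1", call. = FALSE)
  R <- matrix(c(1, r_xy, r_xz,
                r_xy, 1, r_yz,
                r_xz, r_yz, 1), 3, 3)
  if (det(R) < -1e-12 || min(eigen(R, symmetric = TRUE,
                                   only.values = TRUE)$values) < -1e-12) {
    stop("the three correlations do not form a valid (PSD) correlation matrix",
         call. = FALSE)
  }
  (r_xy - r_xz * r_yz) / (sqrt(1 - r_xz^2) * sqrt(1 - r_yz^2))
}

#' Pearson correlations per age-of-arrival subgroup
#'
#' Splits the dataset into the young / middle / old arrival bins (see
#' [age_group()]) and reports the AOA-GJT Pearson correlation and n per
#' bin plus the overall values. Bins with fewer than 4 records are flagged
#' (their r, if computable at all, has no usable z variance); empty bins
#' get `NA` rather than an error.
#'
#' @param data an [aoa_data] object.
#' @param edges bin cut ages, default `c(18, 40)`.
#' @return data frame with columns `group`, `r`, `n`, `flagged`.
#' @export
subgroup_correlations <- function(data, edges = c(18, 40)) {
  stopifnot(inherits(data, "aoa_data"))
  grp <- age_group(data$aoa, edges)
  one <- function(idx) {
    n <- sum(idx)
    r <- if (n >= 2 && sd(data$aoa[idx]) > 0 && sd(data$gjt[idx]) > 0) {
      cor(data$aoa[idx], data$gjt[idx])
    } else NA_real_
    c(r = r, n = n)
  }
  rows <- rbind(overall = one(rep(TRUE, nrow(data))),
                young = one(grp == "young"),
                middle = one(grp == "middle"),
                old = one(grp == "old"))
  data.frame(group = rownames(rows), r = rows[, "r"], n = rows[, "n"],
             flagged = rows[, "n"] < 4, row.names = NULL)
}

#' Aptitude-GJT correlations reported by DeKeyser et al. (2010)
#'
#' The published correlation coefficients between verbal aptitude and GJT
#' score, with group sizes, for the North America and Israel studies —
#' overall and within the young (< 18), middle (18-40) and old (> 40)
#' arrival groups. These printed values are the input for Fisher r-to-z
#' comparisons of the aptitude-attainment correlation across age groups;
#' the underlying raw aptitude data were never published.
#'
#' @format A data frame with 8 rows and 4 columns: `study`, `group`, `r`,
#'   `n`.
#' @source DeKeyser, Alfi-Shabtay & Ravid (2010), *Applied
#'   Psycholinguistics* 31, pp. 425 and 429.
#' @export
dekeyser2010_aptitude <- data.frame(
  study = rep(c("north_america", "israel"), each = 4),
  group = rep(c("overall", "young", "middle", "old"), 2),
  r = c(0.21, 0.11, 0.44, 0.33,
        0.00, -0.37, 0.45, 0.14),
  n = c(76, 20, 26, 30,
        62, 17, 32, 13),
  stringsAsFactors = FALSE
)

#' All pairwise within-study age-group comparisons of printed correlations
#'
#' Convenience wrapper running [compare_correlations()] for every pair of
#' age groups (young/middle/old) within each study of a printed
#' correlation table shaped like [dekeyser2010_aptitude].
#'
#' @param table data frame with columns `study`, `group`, `r`, `n`.
#' @param alpha one-tailed significance level used for the `significant`
#'   flag.
#' @return data frame with one row per comparison: `study`, `group1`,
#'   `group2`, `z_stat`, `p_one_tailed`, `significant`.
#' @export
pairwise_group_comparisons <- function(table = dekeyser2010_aptitude,
                                       alpha = 0.05) {
  stopifnot(all(c("study", "group", "r", "n") %in% names(table)))
  groups <- c("young", "middle", "old")
  out <- list()
  for (st in unique(table$study)) {
    sub <- table[table$study == st & table$group %in% groups, ]
    pairs <- utils::combn(seq_len(nrow(sub)), 2)
    for (j in seq_len(ncol(pairs))) {
      a <- sub[pairs[1, j], ]
      b <- sub[pairs[2, j], ]
      cc <- compare_correlations(a$r, a$n, b$r, b$n)
      out[[length(out) + 1L]] <- data.frame(
        study = st, group1 = a$group, group2 = b$group,
        z_stat = cc$z_stat, p_one_tailed = cc$p_one_tailed,
        significant = cc$p_one_tailed < alpha)
    }
  }
  do.call(rbind, out)
}
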