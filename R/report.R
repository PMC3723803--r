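#' Run the full reanalysis pipeline on one or more AOA-UA datasets
#'
#' For each dataset: descriptive statistics; subgroup correlations;
#' the simple linear fit and the breakpoint fit at the conventional cut-off
#' (default age 18) with their nested comparison; the deviance scan over
#' the candidate grid; simple and breakpoint fits at the scanned optimum
#' with their nested comparison; and the robustness battery (Huber refits,
#' linear-variance GLS, outlier-excluded refits). The pipeline is fully
#' deterministic: identical inputs give identical reports.
#'
#' @param datasets a named list of [aoa_data] objects, or a character
#'   vector of CSV paths readable by [read_aoa_csv()].
#' @param center age at which simple-model intercepts are evaluated and at
#'   which the fixed breakpoint is placed.
#' @param grid_min,grid_max candidate breakpoint grid bounds.
#' @param alpha significance level for model preference.
#' @param edges age-group bin cut ages.
#' @param outlier_threshold absolute studentized-residual cut-off.
#' @param verbose log pipeline stages to standard error?
#' @return An object of class `"reanalysis_report"`: a named list with one
#'   element per dataset, each holding `descriptives`,
#'   `subgroup_correlations`, `simple`, `breakpoint_fixed`,
#'   `comparison_fixed`, `profile`, `optimum`, `simple_opt`,
#'   `breakpoint_opt`, `comparison_opt`, `robust`, `gls`, `outliers`.
#' @export
run_reanalysis <- function(datasets, center = 18, grid_min = 5,
                           grid_max = 19, alpha = 0.05, edges = c(18, 40),
                           outlier_threshold = 2.5, verbose = FALSE) {
  if (is.character(datasets)) {
    paths <- datasets
    datasets <- lapply(paths, read_aoa_csv)
    names(datasets) <- vapply(datasets, study_label, character(1))
  }
  if (length(datasets) == 0L) {
    stop("no input datasets supplied", call. = FALSE)
  }
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- vapply(datasets, study_label, character(1))
  }
  log_msg <- function(...) if (verbose) message(sprintf(...))

  report <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    stopifnot(inherits(d, "aoa_data"))
    log_msg("[%s] n = %d: descriptives and subgroup correlations", nm, nrow(d))
    simple <- fit_ols(d, center_at = center)
    bp_fixed <- fit_breakpoint(d, breakpoint = center)
    log_msg("[%s] deviance scan over aoa %g-%g", nm, grid_min, grid_max)
    profile <- scan_breakpoints(d, grid_min, grid_max)
    opt <- optimal_breakpoint(profile)
    simple_opt <- fit_ols(d, center_at = opt)
    bp_opt <- fit_breakpoint(d, breakpoint = opt)
    log_msg("[%s] optimum breakpoint aoa %g; robustness checks", nm, opt)
    list(descriptives = descriptives(d),
         subgroup_correlations = subgroup_correlations(d, edges),
         simple = simple,
         breakpoint_fixed = bp_fixed,
         comparison_fixed = compare_nested(simple, bp_fixed, alpha),
         profile = profile,
         optimum = opt,
         simple_opt = simple_opt,
         breakpoint_opt = bp_opt,
         comparison_opt = compare_nested(simple_opt, bp_opt, alpha),
         robust = list(simple = fit_robust(d, center_at = center),
                       breakpoint = fit_robust(d, breakpoint = center)),
         gls = list(simple = fit_gls_linear_variance(d, center_at = center),
                    breakpoint = fit_gls_linear_variance(d, breakpoint = center)),
         outliers = refit_without_outliers(d, breakpoint = center,
                                           threshold = outlier_threshold,
                                           center_at = center))
  })
  names(report) <- names(datasets)
  structure(report, class = "reanalysis_report",
            params = list(center = center, grid = c(grid_min, grid_max),
                          alpha = alpha, edges = edges,
                          outlier_threshold = outlier_threshold))
}

#' @export
print.reanalysis_report <- function(x, ...) {
  p <- attr(x, "params")
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("== %s ==\n", nm))
    print(s$descriptives)
    cat("\nSubgroup correlations (aoa-gjt):\n")
    sc <- s$subgroup_correlations
    sc$r <- round(sc$r, 2)
    print(sc, row.names = FALSE)
    cat("\n")
    print(s$simple)
    cat("\n")
    print(s$breakpoint_fixed)
    cat("\n")
    print(s$comparison_fixed)
    cat(sprintf("\nScanned optimum: aoa %g\n", s$optimum))
    print(s$comparison_opt)
    if (nrow(s$outliers$excluded)) {
      cat("\nOutliers excluded (|studentized residual| > threshold in both models):\n")
      print(s$outliers$excluded, row.names = FALSE)
    } else {
      cat("\nNo outliers flagged.\n")
    }
    cat("\n")
  }
  invisible(x)
}

# round half-even to `digits`, the rounding used at the rendering layer
render_num <- function(x, digits = 2) {
  formatC(round(x, digits), format = "f", digits = digits)
}

#' Render a reanalysis report to Markdown and per-table TSV files
#'
#' @param report a `reanalysis_report`.
#' @param dir output directory (created if absent).
#' @return invisibly, the path of the Markdown file written.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "reanalysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- c("# AOA-UA reanalysis report", "")
  write_tsv <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, open = "wb")
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
    close(con)
  }
  fit_row <- function(fit) {
    ct <- coef_table(fit)
    vals <- sprintf("%s = %s +/- %s", ct$term, render_num(ct$estimate),
                    render_num(ct$se))
    extra <- if (fit$estimator == "ols") {
      ft <- fit_ftest(fit)
      sprintf("R2 = %s, F(%d,%d) = %s", render_num(r_squared(fit)),
              ft["df1"], ft["df2"], render_num(ft["f"], 1))
    } else sprintf("deviance = %s", render_num(deviance(fit), 1))
    paste(c(vals, extra), collapse = ", ")
  }
  for (nm in names(report)) {
    s <- report[[nm]]
    slug <- gsub("[^A-Za-z0-9]+", "_", nm)
    md <- c(md, sprintf("## %s", nm), "",
            "### Descriptives", "",
            sprintf("- %s: range %s-%s, mean %s, SD %s",
                    s$descriptives$variable,
                    render_num(s$descriptives$min, 0),
                    render_num(s$descriptives$max, 0),
                    render_num(s$descriptives$mean),
                    render_num(s$descriptives$sd)), "",
            "### Subgroup correlations", "",
            sprintf("- %s: r = %s (n = %d)%s",
                    s$subgroup_correlations$group,
                    render_num(s$subgroup_correlations$r),
                    s$subgroup_correlations$n,
                    ifelse(s$subgroup_correlations$flagged, " [flagged: n < 4]", "")), "",
            "### Models", "",
            sprintf("- Simple: %s", fit_row(s$simple)),
            sprintf("- Breakpoint at aoa %g: %s",
                    s$breakpoint_fixed$breakpoint, fit_row(s$breakpoint_fixed)),
            sprintf("- Comparison at aoa %g: F(%d,%d) = %s, one-tailed p = %s -> prefer %s",
                    s$breakpoint_fixed$breakpoint, s$comparison_fixed$df1,
                    s$comparison_fixed$df2, render_num(s$comparison_fixed$f_stat),
                    render_num(s$comparison_fixed$p_one_tailed, 3),
                    s$comparison_fixed$preferred),
            sprintf("- Scanned optimum: aoa %g", s$optimum),
            sprintf("- Breakpoint at optimum: %s", fit_row(s$breakpoint_opt)),
            sprintf("- Comparison at optimum: F(%d,%d) = %s, one-tailed p = %s -> prefer %s",
                    s$comparison_opt$df1, s$comparison_opt$df2,
                    render_num(s$comparison_opt$f_stat),
                    render_num(s$comparison_opt$p_one_tailed, 3),
                    s$comparison_opt$preferred),
            sprintf("- AIC (breakpoint, simple at optimum): %s, %s; BIC: %s, %s",
                    render_num(information_criteria(s$breakpoint_opt)["aic"], 1),
                    render_num(information_criteria(s$simple_opt)["aic"], 1),
                    render_num(information_criteria(s$breakpoint_opt)["bic"], 1),
                    render_num(information_criteria(s$simple_opt)["bic"], 1)),
            "",
            "### Robustness", "",
            sprintf("- Huber simple: %s", fit_row(s$robust$simple)),
            sprintf("- Huber breakpoint: %s", fit_row(s$robust$breakpoint)),
            sprintf("- GLS gamma (simple): %s; gamma (breakpoint): %s",
                    render_num(s$gls$simple$variance_model$gamma, 4),
                    render_num(s$gls$breakpoint$variance_model$gamma, 4)),
            if (nrow(s$outliers$excluded)) {
              sprintf("- Outliers excluded: %s",
                      paste(sprintf("(aoa %g, gjt %g)", s$outliers$excluded$aoa,
                                    s$outliers$excluded$gjt), collapse = ", "))
            } else "- Outliers excluded: none",
            "")
    write_tsv(s$descriptives, paste0(slug, "_descriptives"))
    write_tsv(s$subgroup_correlations, paste0(slug, "_subgroup_correlations"))
    write_tsv(as.data.frame(s$profile), paste0(slug, "_deviance_profile"))
  }
  path <- file.path(dir, "report.md")
  con <- file(path, open = "wb")
  writeLines(md, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Path to an extracted source-study CSV, if installed
#'
#' The extracted DeKeyser et al. (2010) datasets (supplementary files of
#' the original reanalysis, schema `aoa,gjt`) are not redistributed with
#' the package. If you obtain them, place them in the package's
#' `extdata` directory (or pass their paths straight to [read_aoa_csv()]).
#' A synthetic stand-in with the same schema is always available as
#' `synthetic_north_america.csv`.
#'
#' @param name file name under `extdata`, e.g. `"north_america.csv"`.
#' @return the full path.
#' @export
aoa_example_file <- function(name) {
  path <- system.file("extdata", name, package = "aoabreak")
  if (!nzchar(path)) {
    stop(sprintf(paste0("'%s' is not installed with the package; the ",
                        "extracted source-study data must be obtained from ",
                        "the original study's supplementary materials"),
                 name), call. = FALSE)
  }
  path
}
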