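#' Construct an AOA-UA dataset
#'
#' Bundles paired observations of age of onset of acquisition (AOA, in
#' years) and an ultimate-attainment score (here a grammaticality-judgement
#' task score on a 0-204 scale) into a validated data frame with a study
#' label. Every fitting and reporting function in the package consumes this
#' class.
#'
#' @param aoa integer-valued ages of onset of acquisition, in years.
#' @param gjt attainment scores (points on the 204-item GJT scale).
#' @param study_label short identifier for the study the data come from.
#' @param check_scale enforce the 0-204 score bounds? Real GJT data always
#'   satisfy them; [generate_aoa_data()] disables the check when asked for
#'   unclipped (uncensored) scores so estimator studies are not biased by
#'   truncation.
#' @return A data frame of class `"aoa_data"` with columns `aoa` and `gjt`
#'   and attribute `study_label`.
#' @examples
#' d <- aoa_data(aoa = c(5, 10, 20, 40), gjt = c(190, 180, 160, 140))
#' d
#' @export
aoa_data <- function(aoa, gjt, study_label = "unlabelled",
                     check_scale = TRUE) {
  aoa <- as.numeric(aoa)
  gjt <- as.numeric(gjt)
  if (length(aoa) != length(gjt)) {
    stop("`aoa` and `gjt` must have the same length", call. = FALSE)
  }
  if (length(aoa) < 3L) {
    stop("insufficient data: an AOA-UA dataset needs at least 3 records",
         call. = FALSE)
  }
  if (anyNA(aoa) || anyNA(gjt)) {
    stop("missing values are not allowed in an AOA-UA dataset", call. = FALSE)
  }
  if (any(aoa < 1 | aoa > 100)) {
    stop("`aoa` values must lie in [1, 100] years", call. = FALSE)
  }
  if (check_scale && any(gjt < 0 | gjt > 204)) {
    stop("`gjt` values must lie on the 0-204 score scale", call. = FALSE)
  }
  out <- data.frame(aoa = aoa, gjt = gjt)
  attr(out, "study_label") <- as.character(study_label)[1L]
  class(out) <- c("aoa_data", "data.frame")
  out
}

#' @export
print.aoa_data <- function(x, ...) {
  cat(sprintf("AOA-UA dataset '%s': %d records, aoa %g-%g, gjt %g-%g\n",
              study_label(x), nrow(x), min(x$aoa), max(x$aoa),
              min(x$gjt), max(x$gjt)))
  print(as.data.frame(head(x, 6L)))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @rdname aoa_data
#' @param x an object to coerce / query.
#' @export
study_label <- function(x) {
  lbl <- attr(x, "study_label")
  if (is.null(lbl)) "unlabelled" else lbl
}

#' @rdname aoa_data
#' @param df a data frame with columns `aoa` and `gjt`.
#' @export
as_aoa_data <- function(df, study_label = "unlabelled") {
  if (!all(c("aoa", "gjt") %in% names(df))) {
    stop("data frame must have columns `aoa` and `gjt`", call. = FALSE)
  }
  aoa_data(df$aoa, df$gjt, study_label = study_label)
}

#' Read / write the two-column AOA-UA CSV schema
#'
#' The on-disk schema is the one used by the extracted supplementary
#' datasets of DeKeyser et al. (2010): a header row `aoa,gjt` followed by
#' one integer pair per line. [write_aoa_csv()] emits the same schema
#' byte-stably: LF line endings, no quoting, no row names.
#'
#' @param path file path.
#' @param study_label label attached to the resulting dataset; defaults to
#'   the file name without extension.
#' @return [read_aoa_csv()] returns an [aoa_data] object; [write_aoa_csv()]
#'   returns `path` invisibly.
#' @export
read_aoa_csv <- function(path, study_label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  }
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("aoa", "gjt") %in% names(df))) {
    stop(sprintf("'%s' lacks the required header columns `aoa` and `gjt`",
                 path), call. = FALSE)
  }
  bad <- which(!complete.cases(df[, c("aoa", "gjt")]) |
                 !is.finite(suppressWarnings(as.numeric(df$aoa))) |
                 !is.finite(suppressWarnings(as.numeric(df$gjt))))
  if (length(bad)) {
    stop(sprintf("malformed record in '%s' at data row %d", path, bad[1L]),
         call. = FALSE)
  }
  if (is.null(study_label)) {
    study_label <- sub("\\.[^.]*$", "", basename(path))
  }
  aoa_data(df$aoa, df$gjt, study_label = study_label)
}

#' @rdname read_aoa_csv
#' @param data an [aoa_data] object (or data frame with `aoa`, `gjt`).
#' @export
write_aoa_csv <- function(data, path) {
  con <- file(path, open = "wb")  # binary mode => LF endings on any platform
  on.exit(close(con))
  writeLines(c("aoa,gjt",
               sprintf("%s,%s", format(data$aoa, trim = TRUE, scientific = FALSE),
                       format(data$gjt, trim = TRUE, scientific = FALSE))),
             con, sep = "\n")
  invisible(path)
}

#' Descriptive statistics for an AOA-UA dataset
#'
#' Range, mean and sample standard deviation (n - 1 denominator) for both
#' variables, the summary used to validate extracted data against the
#' source study's published descriptives.
#'
#' @param data an [aoa_data] object.
#' @return A data frame with one row per variable (`aoa`, `gjt`) and columns
#'   `min`, `max`, `mean`, `sd`, plus attribute `n`.
#' @export
descriptives <- function(data) {
  stopifnot(inherits(data, "aoa_data"))
  one <- function(v) {
    data.frame(min = min(v), max = max(v), mean = mean(v), sd = sd(v))
  }
  out <- rbind(aoa = one(data$aoa), gjt = one(data$gjt))
  out <- cbind(variable = rownames(out), out)
  rownames(out) <- NULL
  attr(out, "n") <- nrow(data)
  out
}

#' Bin ages into the conventional young / middle / old arrival groups
#'
#' Arrivals before `edges[1]` are "young", arrivals between `edges[1]` and
#' `edges[2]` inclusive are "middle", later arrivals are "old" — the
#' grouping DeKeyser et al. (2010) used (young < 18, middle 18-40,
#' old > 40).
#'
#' @param aoa numeric ages.
#' @param edges two cut ages, default `c(18, 40)`.
#' @return factor with levels `young`, `middle`, `old`.
#' @export
age_group <- function(aoa, edges = c(18, 40)) {
  stopifnot(length(edges) == 2L, edges[1] < edges[2])
  factor(ifelse(aoa < edges[1], "young",
                ifelse(aoa <= edges[2], "middle", "old")),
         levels = c("young", "middle", "old"))
}
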