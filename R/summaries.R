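#' Cohort-level summary statistics
#'
#' A `cohort_summary` object is a data frame with one row per cohort-level
#' association result, carrying columns `cohort`, `ancestry` (`"SOUTH_ASIAN"`,
#' `"EUROPEAN"`, or `"COMBINED"` for pooled rows), `n`, `outcome` (`"T2D"` or
#' `"VITD"`), `scale` (`"BETA"` or `"LN_OR"`), `estimate`, `se`, `ci_low`,
#' `ci_high`, `p`, `direction` (`"+"`/`"-"`) and `subtotal` (logical; pooled
#' rows that must not be mixed into an all-cohort combination). Odds ratios
#' read from disk (`scale == "OR"`) are converted to the ln-OR scale
#' (`estimate := ln OR`, `scale := "LN_OR"`, flag column `converted_from_or`);
#' their confidence bounds stay on the OR scale, which is what
#' [se_from_ci()] expects for `scale = "LN_OR"`.
#'
#' Each row must carry exactly one source of precision: either `se` or the
#' pair `ci_low`/`ci_high`.
#'
#' @param x A data frame with the columns above.
#' @return A validated `cohort_summary` data frame.
#' @export
as_cohort_summary_table <- function(x) {
  needed <- c("cohort", "ancestry", "n", "outcome", "scale", "estimate",
              "se", "ci_low", "ci_high", "p", "direction", "subtotal")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("summary table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)
  for (col in c("n", "estimate", "se", "ci_low", "ci_high", "p")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  x$subtotal <- as.logical(x$subtotal)
  x$direction <- as.character(x$direction)
  # ln-transform rows still on the OR scale
  is_or <- x$scale == "OR"
  if (any(is_or)) {
    bad <- is_or & (is.na(x$estimate) | x$estimate <= 0)
    if (any(bad)) {
      stop("non-positive OR in row(s): ", paste(which(bad), collapse = ", "),
           call. = FALSE)
    }
    if (is.null(x$converted_from_or)) {
      x$converted_from_or <- rep(FALSE, nrow(x))
    }
    x$estimate[is_or] <- log(x$estimate[is_or])
    x$scale[is_or] <- "LN_OR"
    x$converted_from_or[is_or] <- TRUE
  }
  if (is.null(x$converted_from_or)) {
    x$converted_from_or <- rep(FALSE, nrow(x))
  }
  validate_summaries(x)
  class(x) <- unique(c("cohort_summary", class(x)))
  x
}

validate_summaries <- function(x) {
  bad_p <- is.na(x$p) | x$p <= 0 | x$p > 1
  if (any(bad_p)) {
    stop("p must lie in (0, 1]; offending row(s): ",
         paste(which(bad_p), collapse = ", "), call. = FALSE)
  }
  if (!all(x$scale %in% c("BETA", "LN_OR"))) {
    stop("scale must be 'BETA', 'LN_OR' (or 'OR' on disk)", call. = FALSE)
  }
  if (!all(x$outcome %in% c("T2D", "VITD"))) {
    stop("outcome must be 'T2D' or 'VITD'", call. = FALSE)
  }
  if (!all(x$direction %in% c("+", "-"))) {
    stop("direction must be '+' or '-'", call. = FALSE)
  }
  has_se <- !is.na(x$se)
  has_ci <- !is.na(x$ci_low) & !is.na(x$ci_high)
  neither <- !has_se & !has_ci
  both <- has_se & has_ci
  if (any(neither)) {
    stop("row(s) without se or CI: ", paste(which(neither), collapse = ", "),
         call. = FALSE)
  }
  if (any(both)) {
    stop("row(s) with both se and CI (exactly one is allowed): ",
         paste(which(both), collapse = ", "), call. = FALSE)
  }
  # direction must agree with the sign of the (additive-scale) estimate
  sgn <- sign(x$estimate)
  mismatch <- !is.na(x$estimate) & sgn != 0 &
    ((sgn > 0) != (x$direction == "+"))
  if (any(mismatch)) {
    stop("direction disagrees with estimate sign in row(s): ",
         paste(which(mismatch), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read and write cohort-level summary tables
#'
#' Tab-delimited with a header; mandatory columns
#' `cohort ancestry n outcome scale estimate se ci_low ci_high p direction
#' subtotal`; extra columns are carried through. Scientific notation (e.g.
#' `6.09E-13`) is accepted. Rows with `scale == "OR"` are converted to the
#' ln-OR scale on read and written back as odds ratios, so a read/write
#' round trip reproduces the numeric fields.
#'
#' @param path Path to a tab-delimited summary file.
#' @return `read_summaries()` returns a `cohort_summary` data frame with rows
#'   in file order; `write_summaries()` returns `path` invisibly.
#' @export
read_summaries <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  as_cohort_summary_table(x)
}

#' @rdname read_summaries
#' @param x A `cohort_summary` data frame.
#' @export
write_summaries <- function(x, path) {
  x <- as.data.frame(x)
  conv <- x$converted_from_or %||% rep(FALSE, nrow(x))
  if (any(conv)) {
    x$estimate[conv] <- exp(x$estimate[conv])
    x$scale[conv] <- "OR"
  }
  x$converted_from_or <- NULL
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Reconstruct a standard error from a 95% confidence interval
#'
#' For `scale = "LN_OR"` the bounds are odds ratios and the SE is computed on
#' the ln scale; for `scale = "BETA"` the bounds are used as printed. The
#' normal quantile is fixed at 1.959964.
#'
#' @param ci_low,ci_high Confidence bounds (vectorised).
#' @param scale `"BETA"` or `"LN_OR"`.
#' @return Positive standard error(s).
#' @examples
#' se_from_ci(1.22, 1.26, "LN_OR") # 0.00823
#' se_from_ci(-1.96, 1.96, "BETA") # 1.0
#' @export
se_from_ci <- function(ci_low, ci_high, scale = c("BETA", "LN_OR")) {
  scale <- match.arg(scale)
  if (any(ci_high <= ci_low, na.rm = TRUE)) {
    stop("ci_high must exceed ci_low", call. = FALSE)
  }
  if (scale == "LN_OR") {
    if (any(ci_low <= 0 | ci_high <= 0, na.rm = TRUE)) {
      stop("OR-scale confidence bounds must be positive", call. = FALSE)
    }
    (log(ci_high) - log(ci_low)) / (2 * Z_CRIT)
  } else {
    (ci_high - ci_low) / (2 * Z_CRIT)
  }
}

# Fill missing SEs in a cohort_summary from the CI columns.
ensure_se <- function(x) {
  need <- is.na(x$se)
  if (any(need)) {
    x$se[need] <- mapply(function(lo, hi, sc) se_from_ci(lo, hi, sc),
                         x$ci_low[need], x$ci_high[need], x$scale[need])
  }
  if (any(is.na(x$se) | x$se <= 0)) {
    stop("could not obtain a positive SE for every row", call. = FALSE)
  }
  x
}

fixture_files <- c(
  T2D_SCORE_ON_T2D  = "table_t2d_score_on_t2d.tsv",
  T2D_SCORE_ON_VITD = "table_t2d_score_on_vitd.tsv",
  VITD_SCORE_ON_VITD = "table_vitd_score_on_vitd.tsv",
  VITD_SCORE_ON_T2D = "table_vitd_score_on_t2d.tsv"
)

#' Packaged score-association tables
#'
#' Verbatim transcriptions of the four published per-cohort score-association
#' tables: the T2D allele score against T2D and against 25(OH)D, and the
#' vitamin-D allele score against 25(OH)D and against T2D. Each fixture
#' separates plain cohort rows from ancestry subtotal rows and from the
#' table's printed meta-analysis row (kept verbatim even where internally
#' inconsistent; see [check_fixture_consistency()]).
#'
#' @param table_id One of `fixture_ids()`.
#' @return `load_fixture()` returns a `fixture_table`: a list with elements
#'   `table_id`, `rows` (cohort rows), `subtotals` and `printed_meta`
#'   (one-row `cohort_summary` data frames; these carry the printed meta `z`
#'   in column `z`).
#' @examples
#' fx <- load_fixture("VITD_SCORE_ON_VITD")
#' nrow(fx$rows)          # 6 cohorts
#' fx$printed_meta$estimate
#' @export
load_fixture <- function(table_id) {
  if (!table_id %in% names(fixture_files)) {
    stop("unknown table_id '", table_id, "'; valid ids: ",
         paste(names(fixture_files), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", fixture_files[[table_id]],
                      package = "vitdmr", mustWork = TRUE)
  x <- read_summaries(path)
  out <- list(
    table_id = table_id,
    rows = x[x$row_type == "cohort", , drop = FALSE],
    subtotals = x[x$row_type == "subtotal", , drop = FALSE],
    printed_meta = x[x$row_type == "printed_meta", , drop = FALSE]
  )
  rownames(out$rows) <- NULL
  class(out) <- "fixture_table"
  out
}

#' @rdname load_fixture
#' @export
fixture_ids <- function() names(fixture_files)

#' @export
print.fixture_table <- function(x, ...) {
  cat("Fixture table ", x$table_id, ": ", nrow(x$rows), " cohort rows, ",
      nrow(x$subtotals), " subtotal row(s)\n", sep = "")
  print.data.frame(x$rows, row.names = FALSE, digits = 4)
  cat("printed meta row:\n")
  print.data.frame(x$printed_meta, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Diagnose transcription consistency of a fixture table
#'
#' For every cohort row that carries both an estimate and a confidence
#' interval, compares the (transformed-scale) estimate against the CI
#' midpoint and flags discrepancies larger than two units in the last printed
#' digit of the estimate. This is a report, not a rejection: published tables
#' round estimates and bounds independently, and a few rows (notably in the
#' vitamin-D-score-on-T2D table, where ORs are printed as 1.00) sit just
#' outside the band.
#'
#' @param table_id One of `fixture_ids()`.
#' @return A data frame with columns `cohort`, `estimate` (transformed
#'   scale), `ci_mid`, `discrepancy`, `allowance` and `flag`.
#' @export
check_fixture_consistency <- function(table_id) {
  if (!table_id %in% names(fixture_files)) {
    stop("unknown table_id '", table_id, "'", call. = FALSE)
  }
  path <- system.file("extdata", fixture_files[[table_id]],
                      package = "vitdmr", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = character(0))
  raw <- raw[raw$row_type == "cohort", , drop = FALSE]
  has_ci <- raw$ci_low != "NA" & raw$ci_high != "NA"
  raw <- raw[has_ci, , drop = FALSE]
  if (nrow(raw) == 0L) {
    return(data.frame(cohort = character(), estimate = numeric(),
                      ci_mid = numeric(), discrepancy = numeric(),
                      allowance = numeric(), flag = logical()))
  }
  tr <- function(v, sc) ifelse(sc == "OR", log(as.numeric(v)), as.numeric(v))
  est <- tr(raw$estimate, raw$scale)
  mid <- (tr(raw$ci_low, raw$scale) + tr(raw$ci_high, raw$scale)) / 2
  n_dec <- vapply(raw$estimate, function(s) {
    dot <- regexpr(".", s, fixed = TRUE)
    if (dot < 0) 0L else nchar(s) - dot
  }, integer(1))
  allowance <- 2 * 10^(-n_dec)
  disc <- abs(est - mid)
  data.frame(cohort = raw$cohort, estimate = est, ci_mid = mid,
             discrepancy = disc, allowance = allowance,
             flag = disc > allowance, row.names = NULL)
}
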