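#' Extreme-tail-safe p/Z transforms
#'
#' `z_from_p()` maps a two-sided p-value and a direction sign to a signed Z
#' statistic, `sign * qnorm(1 - p/2)`, evaluated through the upper-tail
#' parameterisation so it stays accurate far into the tail (p down to about
#' 1e-300, i.e. the `3.00E-39`-class p-values that occur in large cohorts).
#' `p_from_z()` is the inverse, `2 * pnorm(|z|, lower.tail = FALSE)`, which
#' uses the complementary tail directly (never `1 - CDF`) and therefore does
#' not underflow to 0 until |z| is far beyond 38; the result is floored at
#' the smallest positive double so p always lies in (0, 1].
#'
#' @param p Two-sided p-value(s) in (0, 1].
#' @param direction `"+"`/`"-"` (or +1/-1), recycled.
#' @param z Signed Z statistic(s).
#' @return Signed Z values, or two-sided p-values.
#' @examples
#' z_from_p(0.05, "+")       # 1.959964
#' z_from_p(6.09e-13, "+")   # 7.198
#' p_from_z(1.959964)        # 0.05
#' @export
z_from_p <- function(p, direction = "+") {
  if (any(is.na(p) | p <= 0 | p > 1)) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  s <- direction_sign(direction)
  # log-p parameterisation: p/2 underflows to a subnormal (where qnorm
  # fails) long before log(p) - log(2) loses accuracy
  s * stats::qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
}

#' @rdname z_from_p
#' @export
p_from_z <- function(z) {
  # go through the log tail: the plain upper-tail pnorm underflows to 0
  # around |z| ~ 37.6, while its log stays exact far beyond; floor at the
  # smallest positive (subnormal) double so p always lies in (0, 1]
  lt <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  pmax(2 * exp(lt), 4.94e-324)
}

direction_sign <- function(direction) {
  if (is.character(direction)) {
    if (!all(direction %in% c("+", "-"))) {
      stop("direction must be '+' or '-'", call. = FALSE)
    }
    ifelse(direction == "+", 1, -1)
  } else {
    sign(direction) + (direction == 0)  # 0 treated as "+"
  }
}

meta_rows <- function(rows, exclude_subtotals) {
  rows <- as.data.frame(rows)
  if (exclude_subtotals && !is.null(rows$subtotal)) {
    rows <- rows[!rows$subtotal, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("no cohort rows to combine", call. = FALSE)
  rows
}

new_meta_result <- function(rows, scheme, estimate = NA_real_, se = NA_real_,
                            z, het = list(q_stat = NA_real_, i2 = NA_real_,
                                          p_het = NA_real_)) {
  structure(list(
    k = nrow(rows), n_total = sum(rows$n),
    estimate = estimate, se = se, z = unname(z), p = p_from_z(z),
    scheme = scheme,
    q_stat = het$q_stat, i2 = het$i2, p_het = het$p_het,
    direction_string = paste(rows$direction, collapse = " "),
    cohorts = rows$cohort),
    class = "meta_result")
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-cohort estimates with weights `1/SE^2`:
#' `estimate = sum(b_i/SE_i^2) / sum(1/SE_i^2)`,
#' `SE = sqrt(1/sum(1/SE_i^2))`, Wald z and p, plus Cochran's Q, I-squared
#' and the heterogeneity p-value from a chi-squared on k-1 df. Rows whose SE
#' is missing have it reconstructed from their confidence interval
#' ([se_from_ci()]); subtotal rows are excluded by default so pooled rows
#' are never double-counted.
#'
#' @param rows A `cohort_summary` data frame sharing one outcome and scale.
#' @param exclude_subtotals Drop rows flagged `subtotal` (default `TRUE`).
#' @return A `meta_result` with `scheme = "IVW"`.
#' @examples
#' fx <- load_fixture("VITD_SCORE_ON_VITD")
#' meta_ivw(fx$rows)   # pooled beta -0.021
#' @export
meta_ivw <- function(rows, exclude_subtotals = TRUE) {
  rows <- meta_rows(rows, exclude_subtotals)
  if (length(unique(rows$scale)) != 1L || length(unique(rows$outcome)) != 1L) {
    stop("rows must share one outcome and one estimate scale", call. = FALSE)
  }
  rows <- ensure_se(rows)
  if (any(rows$se <= 0)) stop("all SEs must be positive", call. = FALSE)
  w <- 1 / rows$se^2
  est <- sum(w * rows$estimate) / sum(w)
  se <- sqrt(1 / sum(w))
  new_meta_result(rows, "IVW", estimate = est, se = se, z = est / se,
                  het = heterogeneity_wb(rows$estimate, w))
}

#' Stouffer Z combination
#'
#' Combines per-cohort signed Z statistics derived from the printed two-sided
#' p-values and direction signs. Unweighted: `Z = sum(z_i)/sqrt(k)` — the
#' scheme that reproduces the printed meta Z columns of the packaged tables.
#' Sample-size weighted: `Z = sum(sqrt(n_i) z_i)/sqrt(sum(n_i))`. No pooled
#' estimate is produced; heterogeneity statistics are attached when every
#' row carries an estimate and SE.
#'
#' @param rows A `cohort_summary` data frame with `p` and `direction` (and
#'   `n` for the weighted scheme).
#' @param weights `"none"` (default) or `"sample_size"`.
#' @param exclude_subtotals Drop rows flagged `subtotal` (default `TRUE`).
#' @return A `meta_result` with `scheme` `"STOUFFER"` or
#'   `"SAMPLE_WEIGHTED_Z"`.
#' @examples
#' fx <- load_fixture("T2D_SCORE_ON_T2D")
#' meta_stouffer(fx$rows)   # Z = 11.86
#' @export
meta_stouffer <- function(rows, weights = c("none", "sample_size"),
                          exclude_subtotals = TRUE) {
  weights <- match.arg(weights)
  rows <- meta_rows(rows, exclude_subtotals)
  zi <- z_from_p(rows$p, rows$direction)
  if (weights == "none") {
    z <- sum(zi) / sqrt(length(zi))
    scheme <- "STOUFFER"
  } else {
    if (any(is.na(rows$n))) {
      stop("sample-size weighting needs n for every row", call. = FALSE)
    }
    z <- sum(sqrt(rows$n) * zi) / sqrt(sum(rows$n))
    scheme <- "SAMPLE_WEIGHTED_Z"
  }
  het <- list(q_stat = NA_real_, i2 = NA_real_, p_het = NA_real_)
  can_het <- all(!is.na(rows$estimate)) &&
    (all(!is.na(rows$se)) || all(!is.na(rows$ci_low) & !is.na(rows$ci_high)))
  if (can_het && nrow(rows) >= 2L) {
    r2 <- ensure_se(rows)
    het <- heterogeneity_wb(r2$estimate, 1 / r2$se^2)
  }
  new_meta_result(rows, scheme, z = z, het = het)
}

heterogeneity_wb <- function(b, w) {
  k <- length(b)
  if (k < 2L) {
    return(list(q_stat = NA_real_, i2 = NA_real_, p_het = NA_real_))
  }
  est <- sum(w * b) / sum(w)
  q <- sum(w * (b - est)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  list(q_stat = q, i2 = i2,
       p_het = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' Cochran's Q, I-squared and heterogeneity p-value
#'
#' Diagnostic heterogeneity statistics for a set of cohort rows, computed
#' about the fixed-effect pooled estimate. With fewer than two rows the
#' statistics are undefined and returned as `NA`.
#'
#' @inheritParams meta_ivw
#' @return A list with `q_stat`, `i2` and `p_het`.
#' @export
heterogeneity <- function(rows, exclude_subtotals = TRUE) {
  rows <- meta_rows(rows, exclude_subtotals)
  if (nrow(rows) < 2L) {
    return(list(q_stat = NA_real_, i2 = NA_real_, p_het = NA_real_))
  }
  rows <- ensure_se(rows)
  heterogeneity_wb(rows$estimate, 1 / rows$se^2)
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Meta-analysis (", x$scheme, "): k = ", x$k,
      ", N = ", format(x$n_total, big.mark = ","), "\n", sep = "")
  if (!is.na(x$estimate)) {
    cat(sprintf("  pooled estimate = %.4g (SE %.3g)\n", x$estimate, x$se))
  }
  cat(sprintf("  Z = %.3f, p = %.3g\n", x$z, x$p))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  heterogeneity: Q = %.2f (df %d), I2 = %.1f%%, p = %.3g\n",
                x$q_stat, x$k - 1L, 100 * x$i2, x$p_het))
  }
  cat("  directions:", x$direction_string, "\n")
  invisible(x)
}

#' @export
coef.meta_result <- function(object, ...) {
  c(estimate = object$estimate, se = object$se)
}

#' @export
confint.meta_result <- function(object, parm, level = 0.95, ...) {
  if (is.na(object$estimate)) {
    stop("no pooled estimate under scheme ", object$scheme, call. = FALSE)
  }
  q <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$estimate - q * object$se,
                object$estimate + q * object$se), nrow = 1)
  dimnames(m) <- list("estimate",
                      sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                 1 - (1 - level) / 2)))
  m
}

#' Forest-plot data and minimal text rendering
#'
#' Emits the rows of an IVW meta-analysis in plotting order (`label`,
#' `estimate`, `ci_low`, `ci_high`, `weight_pct`, all on the combination
#' scale), with the pooled row last. The print method draws a minimal
#' text forest; `plot()` draws a base-graphics version.
#'
#' @inheritParams meta_ivw
#' @return A `forest_data` data frame.
#' @export
forest_data <- function(rows, exclude_subtotals = TRUE) {
  rows <- meta_rows(rows, exclude_subtotals)
  rows <- ensure_se(rows)
  mv <- meta_ivw(rows, exclude_subtotals = FALSE)
  w <- 1 / rows$se^2
  out <- data.frame(
    label = c(rows$cohort, "Pooled (IVW)"),
    estimate = c(rows$estimate, mv$estimate),
    ci_low = c(rows$estimate - Z_CRIT * rows$se,
               mv$estimate - Z_CRIT * mv$se),
    ci_high = c(rows$estimate + Z_CRIT * rows$se,
                mv$estimate + Z_CRIT * mv$se),
    weight_pct = c(100 * w / sum(w), 100),
    stringsAsFactors = FALSE)
  class(out) <- c("forest_data", "data.frame")
  out
}

#' @export
print.forest_data <- function(x, width = 40L, ...) {
  rng <- range(c(x$ci_low, x$ci_high))
  pos <- function(v) {
    1L + as.integer(round((v - rng[1]) / diff(rng) * (width - 1L)))
  }
  lw <- max(nchar(x$label))
  for (i in seq_len(nrow(x))) {
    bar <- rep(" ", width)
    bar[seq(pos(x$ci_low[i]), pos(x$ci_high[i]))] <- "-"
    bar[pos(x$estimate[i])] <- if (i == nrow(x)) "#" else "o"
    cat(sprintf("%-*s |%s| %8.4f [%8.4f, %8.4f] %5.1f%%\n",
                lw, x$label[i], paste(bar, collapse = ""),
                x$estimate[i], x$ci_low[i], x$ci_high[i], x$weight_pct[i]))
  }
  invisible(x)
}

#' @export
plot.forest_data <- function(x, xlab = "estimate", ...) {
  k <- nrow(x)
  ys <- rev(seq_len(k))
  graphics::plot(x$estimate, ys, xlim = range(c(x$ci_low, x$ci_high)),
                 ylim = c(0.5, k + 0.5), yaxt = "n", ylab = "",
                 xlab = xlab, pch = c(rep(15, k - 1), 18),
                 cex = c(0.5 + x$weight_pct[-k] / 50, 1.5), ...)
  graphics::segments(x$ci_low, ys, x$ci_high, ys)
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = ys, labels = x$label, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Recompute a packaged table's meta row under all schemes
#'
#' Loads a fixture, recombines its cohort rows by IVW, unweighted Stouffer
#' and sample-size-weighted Stouffer, and lines the results up against the
#' table's printed meta row. This is the quickest way to see that the
#' printed Z columns follow the unweighted Stouffer scheme — and that one
#' printed meta row (T2D score on 25(OH)D) is internally inconsistent with
#' its own cohort rows.
#'
#' @param table_id One of `fixture_ids()`.
#' @return A `table_reproduction` list with the fixture and the three
#'   `meta_result`s.
#' @export
reproduce_table <- function(table_id) {
  fx <- load_fixture(table_id)
  structure(list(
    fixture = fx,
    ivw = meta_ivw(fx$rows),
    stouffer = meta_stouffer(fx$rows),
    weighted = meta_stouffer(fx$rows, weights = "sample_size")),
    class = "table_reproduction")
}

#' @export
print.table_reproduction <- function(x, ...) {
  fx <- x$fixture
  cat("Reproduction of table ", fx$table_id, " (", nrow(fx$rows),
      " cohort rows)\n", sep = "")
  pm <- fx$printed_meta
  on_or <- isTRUE(pm$converted_from_or[1])
  est <- if (on_or) exp(x$ivw$estimate) else x$ivw$estimate
  printed_est <- if (on_or) exp(pm$estimate[1]) else pm$estimate[1]
  cat(sprintf("  printed meta:    estimate %s, Z %s\n",
              format(printed_est, digits = 4),
              format(pm$z[1], digits = 4)))
  cat(sprintf("  IVW:             estimate %s (SE %.3g), Z %.3f\n",
              format(est, digits = 4), x$ivw$se, x$ivw$z))
  cat(sprintf("  Stouffer:        Z %.3f\n", x$stouffer$z))
  cat(sprintf("  sqrt(N)-weighted Z %.3f\n", x$weighted$z))
  invisible(x)
}
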