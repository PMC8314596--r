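#' Additive-model association fits
#'
#' `fit_linear_vitd()` regresses ln 25(OH)D on a per-sample term (a SNP
#' dosage or an allele score) plus covariates by ordinary least squares;
#' `fit_logistic_t2d()` fits the analogous maximum-likelihood logistic model
#' for T2D status. Both use an additive genetic model: the term enters the
#' linear predictor untransformed, so for a dosage the estimate is a
#' per-effect-allele effect.
#'
#' Samples with a missing outcome or a missing term are excluded (missing
#' dosages are dropped, not mean-imputed), and `n` in the result counts
#' analysed samples only. Inference is Wald-normal throughout: `z =
#' estimate/se`, `p = 2 * pnorm(-|z|)`, `direction = sign(z)` (with "+" for
#' z = 0), so the three fields are mutually consistent.
#'
#' @param term A column name of `cohort$dosages`, or a numeric per-sample
#'   vector (e.g. an allele score).
#' @param cohort A `vd_cohort` (or any list with a `dosages` matrix and a
#'   `phenotypes` data frame).
#' @param covariates Character vector of phenotype columns to adjust for.
#'   Defaults to age, sex and BMI; add `"t2d"` for score-on-25(OH)D fits and
#'   `"uv_index"` where measured.
#' @param term_label Label stored in the result (defaults to the column name
#'   or `"term"`).
#' @return An `assoc_result`: list with `term`, `outcome`, `n`, `estimate`,
#'   `se`, `z`, `p`, `direction`, `eaf` (when the term is a 0/1/2 dosage),
#'   `covariates_used`, `estimable` and `notes`.
#' @examples
#' ch <- simulate_cohort(default_presets("INDEPENDENT", n = 2000, seed = 1))
#' fit_linear_vitd("rs2282679", ch)
#' fit_logistic_t2d("rs7903146", ch)
#' @export
fit_linear_vitd <- function(term, cohort,
                            covariates = c("age", "sex", "bmi"),
                            term_label = NULL) {
  d <- assoc_frame(term, cohort, covariates, term_label,
                   outcome = log(cohort$phenotypes$vitd_nmol_l))
  if (nrow(d$data) < 30L) {
    stop("fewer than 30 samples with a non-missing outcome", call. = FALSE)
  }
  if (stats::sd(d$data$.term) == 0) {
    stop("degenerate design: term '", d$label, "' is constant", call. = FALSE)
  }
  fit <- stats::lm(.y ~ ., data = d$data)
  assoc_from_fit(fit, d, outcome = "VITD")
}

#' @rdname fit_linear_vitd
#' @export
fit_logistic_t2d <- function(term, cohort,
                             covariates = c("age", "sex", "bmi"),
                             term_label = NULL) {
  d <- assoc_frame(term, cohort, covariates, term_label,
                   outcome = cohort$phenotypes$t2d)
  if (length(unique(d$data$.y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (stats::sd(d$data$.term) == 0) {
    stop("degenerate design: term '", d$label, "' is constant", call. = FALSE)
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = d$data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("logistic fit did not converge in 50 iterations (deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }
  res <- assoc_from_fit(fit, d, outcome = "T2D")
  # perfect or quasi-separation: the Wald SE explodes and the ln-OR runs
  # away; report non-estimable rather than crash (the glm warning is not
  # raised reliably, so detect on magnitude too)
  if (sep_warn || is.na(res$se) || res$se > 20 || abs(res$estimate) > 10) {
    res$estimable <- FALSE
    res$notes <- c(res$notes, "separation detected: term effect non-estimable")
    res$estimate <- res$se <- res$z <- NA_real_
    res$p <- NA_real_
  }
  res
}

# Assemble the model frame: outcome, term and covariates, complete cases only.
assoc_frame <- function(term, cohort, covariates, term_label, outcome) {
  ph <- cohort$phenotypes
  if (is.character(term) && length(term) == 1L) {
    if (!term %in% colnames(cohort$dosages)) {
      stop("term '", term, "' is not a dosage column", call. = FALSE)
    }
    label <- term_label %||% term
    tv <- as.numeric(cohort$dosages[, term])
  } else {
    label <- term_label %||% "term"
    tv <- as.numeric(term)
    if (length(tv) != nrow(ph)) {
      stop("term vector length does not match the cohort", call. = FALSE)
    }
  }
  missing_cov <- setdiff(covariates, names(ph))
  if (length(missing_cov) > 0L) {
    stop("covariate(s) absent from the phenotype table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(.y = outcome, .term = tv)
  for (cv in covariates) d[[cv]] <- ph[[cv]]
  keep <- stats::complete.cases(d) & is.finite(d$.y)
  list(data = d[keep, , drop = FALSE], label = label,
       covariates = covariates,
       is_dosage = all(tv[!is.na(tv)] %in% 0:2))
}

assoc_from_fit <- function(fit, d, outcome) {
  cf <- summary(fit)$coefficients
  notes <- character()
  aliased <- setdiff(names(coef(fit)), rownames(cf))
  if (".term" %in% aliased || is.na(coef(fit)[".term"])) {
    stop("degenerate design: term is collinear with covariates", call. = FALSE)
  }
  if (length(aliased) > 0L) {
    notes <- c(notes, paste("aliased covariate(s):",
                            paste(aliased, collapse = ", ")))
  }
  kappa_x <- kappa(stats::model.matrix(fit))
  if (kappa_x > 1e8) {
    notes <- c(notes, sprintf("ill-conditioned design (kappa = %.3g)", kappa_x))
  }
  est <- cf[".term", 1]
  se <- cf[".term", 2]
  z <- est / se
  res <- list(term = d$label, outcome = outcome, n = nrow(d$data),
              estimate = unname(est), se = unname(se), z = unname(z),
              p = p_from_z(z),
              direction = if (z >= 0) "+" else "-",
              eaf = if (d$is_dosage) mean(d$data$.term) / 2 else NA_real_,
              covariates_used = d$covariates,
              estimable = TRUE, notes = notes)
  class(res) <- "assoc_result"
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Association fit (", if (x$outcome == "VITD") "linear, ln 25(OH)D"
      else "logistic, T2D", ")\n", sep = "")
  cat("  term: ", x$term, "   n = ", x$n, "\n", sep = "")
  if (!x$estimable) {
    cat("  non-estimable:", paste(x$notes, collapse = "; "), "\n")
    return(invisible(x))
  }
  lab <- if (x$outcome == "T2D") "ln-OR" else "beta"
  cat(sprintf("  %s = %.4g (SE %.3g), z = %.3f, p = %.3g [%s]\n",
              lab, x$estimate, x$se, x$z, x$p, x$direction))
  if (x$outcome == "T2D") {
    cat(sprintf("  OR = %.3f (95%% CI %.3f, %.3f)\n", exp(x$estimate),
                exp(x$estimate - Z_CRIT * x$se),
                exp(x$estimate + Z_CRIT * x$se)))
  }
  if (length(x$covariates_used)) {
    cat("  adjusted for:", paste(x$covariates_used, collapse = ", "), "\n")
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @export
coef.assoc_result <- function(object, ...) {
  c(estimate = object$estimate, se = object$se)
}

#' Convert an association fit to a cohort-summary row
#'
#' Lossless field mapping into the [read_summaries()] row format. For T2D
#' outcomes the estimate stays on the ln-OR scale with its SE, and the
#' OR-scale 95% CI `exp(estimate +/- 1.959964 se)` is carried in extra
#' columns `or_ci_low`/`or_ci_high`.
#'
#' @param result An `assoc_result`.
#' @param cohort_label Cohort name for the `cohort` column.
#' @param ancestry `"SOUTH_ASIAN"`, `"EUROPEAN"` or `"COMBINED"`.
#' @return A one-row `cohort_summary` data frame.
#' @export
as_cohort_summary <- function(result, cohort_label, ancestry = "EUROPEAN") {
  stopifnot(inherits(result, "assoc_result"))
  if (!result$estimable) {
    stop("cannot summarise a non-estimable fit", call. = FALSE)
  }
  row <- data.frame(
    cohort = cohort_label, ancestry = ancestry, n = result$n,
    outcome = result$outcome,
    scale = if (result$outcome == "T2D") "LN_OR" else "BETA",
    estimate = result$estimate, se = result$se,
    ci_low = NA_real_, ci_high = NA_real_,
    p = result$p, direction = result$direction, subtotal = FALSE,
    stringsAsFactors = FALSE)
  if (result$outcome == "T2D") {
    row$or_ci_low <- exp(result$estimate - Z_CRIT * result$se)
    row$or_ci_high <- exp(result$estimate + Z_CRIT * result$se)
  }
  as_cohort_summary_table(row)
}
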