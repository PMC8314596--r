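# Pull (estimate, se, p) out of the objects the pipeline produces.
est_se_p <- function(x) {
  if (inherits(x, c("assoc_result", "meta_result"))) {
    if (inherits(x, "meta_result") && is.na(x$estimate)) {
      stop("meta_result under scheme ", x$scheme,
           " carries no pooled estimate; use an IVW result", call. = FALSE)
    }
    c(estimate = x$estimate, se = x$se, p = x$p)
  } else if (is.numeric(x) && length(x) >= 2L) {
    est <- unname(x[1]); se <- unname(x[2])
    p <- if (length(x) >= 3L) unname(x[3]) else p_from_z(est / se)
    c(estimate = est, se = se, p = p)
  } else {
    stop("expected an assoc_result, meta_result, or c(estimate, se[, p])",
         call. = FALSE)
  }
}

#' Wald-ratio instrumental-variable estimate
#'
#' The ratio estimator `beta_iv = beta_outcome / beta_exposure` — the causal
#' effect of the exposure on the outcome per exposure unit — with its
#' first-order delta-method standard error
#' `|beta_iv| * sqrt(se_out^2/b_out^2 + se_exp^2/b_exp^2)`; when the
#' instrument-outcome estimate is exactly zero the SE falls back to
#' `se_out / |b_exp|`.
#'
#' @param exposure Instrument-exposure association: an `assoc_result`, an IVW
#'   `meta_result`, or `c(estimate, se[, p])`.
#' @param outcome Instrument-outcome association, same forms.
#' @param instrument Label for the instrument (SNP or score name).
#' @return An `mr_estimate`: list with `beta_iv`, `se_iv`, `z`, `p`,
#'   `instrument` and the two input associations.
#' @examples
#' # DHCR7: -0.042 ln-nmol/L per allele on 25(OH)D; ln(1.05) per allele on T2D
#' wald_ratio(c(-0.042, 0.0032), c(log(1.05), 0.017), "rs12785878")
#' @export
wald_ratio <- function(exposure, outcome, instrument = "score") {
  ex <- est_se_p(exposure)
  ou <- est_se_p(outcome)
  if (ex["estimate"] == 0) {
    stop("weak instrument: instrument-exposure estimate is zero",
         call. = FALSE)
  }
  if (ex["se"] <= 0 || ou["se"] <= 0) {
    stop("both standard errors must be positive", call. = FALSE)
  }
  beta_iv <- unname(ou["estimate"] / ex["estimate"])
  se_iv <- if (ou["estimate"] == 0) {
    unname(ou["se"] / abs(ex["estimate"]))
  } else {
    abs(beta_iv) * sqrt(unname(ou["se"])^2 / unname(ou["estimate"])^2 +
                        unname(ex["se"])^2 / unname(ex["estimate"])^2)
  }
  z <- beta_iv / se_iv
  structure(list(beta_iv = beta_iv, se_iv = se_iv, z = z, p = p_from_z(z),
                 instrument = instrument,
                 exposure_assoc = ex, outcome_assoc = ou),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("Wald-ratio IV estimate [", x$instrument, "]\n", sep = "")
  cat(sprintf("  beta_iv = %.4g (SE %.3g), z = %.3f, p = %.3g\n",
              x$beta_iv, x$se_iv, x$z, x$p))
  cat(sprintf("  instrument-exposure: %.4g (SE %.3g, p %.3g)\n",
              x$exposure_assoc["estimate"], x$exposure_assoc["se"],
              x$exposure_assoc["p"]))
  cat(sprintf("  instrument-outcome:  %.4g (SE %.3g, p %.3g)\n",
              x$outcome_assoc["estimate"], x$outcome_assoc["se"],
              x$outcome_assoc["p"]))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  c(beta_iv = object$beta_iv, se_iv = object$se_iv)
}

verdict_one <- function(ex_p, ou_p, alpha) {
  if (is.na(ex_p) || ex_p >= alpha) "INCONCLUSIVE"
  else if (!is.na(ou_p) && ou_p < alpha) "SUPPORTED"
  else "NOT_SUPPORTED"
}

direction_block <- function(exposure, outcome, alpha, label) {
  nm <- names(exposure)
  if (is.null(nm) || is.null(names(outcome)) ||
      !setequal(nm, names(outcome))) {
    stop(label, ": exposure and outcome lists must share instrument names",
         call. = FALSE)
  }
  ests <- lapply(nm, function(k) {
    wald_ratio(exposure[[k]], outcome[[k]], instrument = k)
  })
  names(ests) <- nm
  comp_name <- intersect(c("composite", "score"), nm)
  per <- vapply(ests, function(e) {
    verdict_one(e$exposure_assoc["p"], e$outcome_assoc["p"], alpha)
  }, character(1))
  verdict <- if (length(comp_name) >= 1L) {
    per[[comp_name[1]]]
  } else {
    "INCONCLUSIVE"
  }
  notes <- character()
  supp <- nm[per == "SUPPORTED"]
  if (length(supp) > 0L) {
    notes <- c(notes, paste0(label, ": instrument(s) individually supported: ",
                             paste(supp, collapse = ", ")))
  }
  if (length(comp_name) == 0L) {
    notes <- c(notes, paste0(label, ": no composite instrument supplied; ",
                             "direction verdict left INCONCLUSIVE"))
  }
  list(estimates = ests, per_instrument = per, verdict = verdict,
       notes = notes)
}

#' Bidirectional Mendelian-randomization report
#'
#' Assembles the forward (25(OH)D to T2D) and reverse (T2D to 25(OH)D)
#' instrument analyses into one causal report. Each of the four arguments is
#' a named list of association results — one per instrument, matched by name
#' across exposure and outcome within a direction; the element named
#' `"composite"` (or `"score"`) is the composite allele-score instrument
#' that decides the direction's verdict. Per-instrument Wald ratios are
#' always computed, because a finding can be instrument-specific (in the
#' source analysis only the synthesis-gene instrument DHCR7 passed).
#'
#' A direction is `SUPPORTED` when the composite instrument associates with
#' its exposure at `p < alpha` and with the outcome at `p < alpha`;
#' `NOT_SUPPORTED` when the instrument is strong but the outcome association
#' is not; `INCONCLUSIVE` when the instrument-exposure association itself
#' fails `alpha` (weak instrument) or no composite is supplied. The default
#' threshold is the Bonferroni-corrected 0.05/8 = 0.00625 (printed 0.0063):
#' eight tests — six SNPs plus the two composite scores.
#'
#' @param forward_exposure,forward_outcome Named lists for the vitamin-D
#'   instruments: their associations with 25(OH)D (exposure) and with T2D
#'   (outcome). Elements may be `assoc_result`s, IVW `meta_result`s or
#'   `c(estimate, se, p)` vectors.
#' @param reverse_exposure,reverse_outcome Same for the T2D instruments
#'   against T2D (exposure) and 25(OH)D (outcome).
#' @param alpha Significance threshold in (0, 1); default `0.05/8`.
#' @return An `mr_report` with elements `forward`, `reverse` (each holding
#'   per-instrument `mr_estimate`s, per-instrument verdicts and the
#'   direction verdict), `alpha`, `verdicts` and `notes`.
#' @export
mr_bidirectional <- function(forward_exposure, forward_outcome,
                             reverse_exposure, reverse_outcome,
                             alpha = 0.05 / 8) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  fwd <- direction_block(forward_exposure, forward_outcome, alpha,
                         "forward (25(OH)D -> T2D)")
  rev <- direction_block(reverse_exposure, reverse_outcome, alpha,
                         "reverse (T2D -> 25(OH)D)")
  structure(list(forward = fwd, reverse = rev, alpha = alpha,
                 verdicts = c(forward = fwd$verdict, reverse = rev$verdict),
                 notes = c(fwd$notes, rev$notes)),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Bidirectional Mendelian-randomization report",
      sprintf("(alpha = %.4f)\n", x$alpha))
  for (dir in c("forward", "reverse")) {
    blk <- x[[dir]]
    lab <- if (dir == "forward") "25(OH)D -> T2D" else "T2D -> 25(OH)D"
    cat(sprintf("%s [%s]: %s\n", dir, lab, blk$verdict))
    for (k in names(blk$estimates)) {
      e <- blk$estimates[[k]]
      cat(sprintf("  %-12s beta_iv %8.4g (SE %.3g)  p_exp %.2e  p_out %.2e  %s\n",
                  k, e$beta_iv, e$se_iv, e$exposure_assoc["p"],
                  e$outcome_assoc["p"], blk$per_instrument[[k]]))
    }
  }
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' @export
summary.mr_report <- function(object, ...) {
  rows <- do.call(rbind, lapply(c("forward", "reverse"), function(dir) {
    blk <- object[[dir]]
    do.call(rbind, lapply(names(blk$estimates), function(k) {
      e <- blk$estimates[[k]]
      data.frame(direction = dir, instrument = k, beta_iv = e$beta_iv,
                 se_iv = e$se_iv, z = e$z, p = e$p,
                 p_exposure = unname(e$exposure_assoc["p"]),
                 p_outcome = unname(e$outcome_assoc["p"]),
                 verdict = blk$per_instrument[[k]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Reporting scale for ln-scale 25(OH)D effects
#'
#' Headline numbers quote ln-scale 25(OH)D betas multiplied by 100 and
#' labelled nmol/L (so a score beta of -0.021 is quoted as "-2.1 nmol/L").
#' This returns that conventional value together with the exact percent
#' change in 25(OH)D, `100 * (exp(beta) - 1)`.
#'
#' @param beta_ln Effect(s) on ln 25(OH)D (ln-nmol/L).
#' @return A data frame with columns `beta_ln`, `reported` (100 * beta) and
#'   `percent` (exact percent change).
#' @examples
#' beta_ln_reported(c(-0.021, -0.042))
#' @export
beta_ln_reported <- function(beta_ln) {
  data.frame(beta_ln = beta_ln,
             reported = 100 * beta_ln,
             percent = 100 * expm1(beta_ln))
}
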