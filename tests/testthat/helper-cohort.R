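# Shared test builders: tiny instrument tables, hand-made cohorts, and a
# writer for ad hoc summary files.

toy_instruments <- function(weights = c(0.1, 0.2, 0.3),
                            eaf = c(0.5, 0.25, 0.5),
                            exposure = "T2D") {
  as_snp_instruments(data.frame(
    rsid = paste0("rs", seq_along(weights)), gene = "toy",
    effect_allele = "A", other_allele = "B",
    eaf = eaf, weight = weights, exposure = exposure,
    stringsAsFactors = FALSE))
}

# A bare cohort from explicit vectors; covariates optional.
manual_cohort <- function(t2d = NULL, vitd = NULL, dosage = NULL,
                          rsid = "rs1") {
  n <- max(length(t2d), length(vitd), length(dosage))
  g <- matrix(if (is.null(dosage)) NA_integer_ else as.integer(dosage),
              ncol = 1, dimnames = list(NULL, rsid))
  ph <- data.frame(sample_id = sprintf("S%04d", seq_len(n)))
  ph$t2d <- if (is.null(t2d)) rep(NA_integer_, n) else t2d
  ph$vitd_nmol_l <- if (is.null(vitd)) rep(NA_real_, n) else vitd
  structure(list(dosages = g, phenotypes = ph, params = NULL),
            class = "vd_cohort")
}

write_summary_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

summary_row <- function(cohort = "A", ancestry = "EUROPEAN", n = 1000,
                        outcome = "VITD", scale = "BETA", estimate = 0.1,
                        se = 0.05, ci_low = NA, ci_high = NA, p = 0.04,
                        direction = "+", subtotal = FALSE) {
  data.frame(cohort = cohort, ancestry = ancestry, n = n, outcome = outcome,
             scale = scale, estimate = estimate, se = se, ci_low = ci_low,
             ci_high = ci_high, p = p, direction = direction,
             subtotal = subtotal, stringsAsFactors = FALSE)
}
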