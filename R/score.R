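#' Specify a weighted allele score
#'
#' A score spec names the instruments (all for the same exposure), the
#' combination mode and the missing-genotype rule. `SUM` accumulates
#' `weight_j * dosage_j`; `AVERAGE` divides the sum by the number of alleles
#' counted (2 x the number of SNPs entering the sum). With
#' `no_mean_imputation = TRUE` (the default, matching PLINK's
#' `--score-no-mean-imputation`) a missing genotype contributes nothing;
#' otherwise it is replaced by its frequency-expected dosage `2 * eaf`.
#'
#' @param name Score label.
#' @param instruments A [as_snp_instruments()] table (>= 1 row, one exposure).
#' @param mode `"SUM"` or `"AVERAGE"`.
#' @param no_mean_imputation Logical; see above.
#' @param standardize Logical; if `TRUE`, [build_score()] returns the score
#'   normalised to mean 0, SD 1.
#' @return A `score_spec` object.
#' @export
score_spec <- function(name, instruments, mode = c("SUM", "AVERAGE"),
                       no_mean_imputation = TRUE, standardize = TRUE) {
  mode <- match.arg(mode)
  instruments <- as_snp_instruments(instruments)
  if (nrow(instruments) < 1L) {
    stop("a score needs at least one instrument", call. = FALSE)
  }
  if (length(unique(instruments$exposure)) != 1L) {
    stop("all instruments in one score must share an exposure trait",
         call. = FALSE)
  }
  structure(list(name = name, instruments = instruments, mode = mode,
                 no_mean_imputation = no_mean_imputation,
                 standardize = standardize),
            class = "score_spec")
}

#' Build a weighted allele score
#'
#' Computes the per-sample weighted score defined by a [score_spec()] from a
#' dosage matrix. Samples whose genotypes are all missing get a missing
#' score.
#'
#' @param dosages Samples x SNPs matrix with 0/1/2/`NA` entries and rsID
#'   column names.
#' @param spec A [score_spec()].
#' @return Numeric per-sample score vector (standardised when
#'   `spec$standardize`).
#' @examples
#' g <- rbind(c(2, 1, 0), c(2, NA, 0))
#' colnames(g) <- c("rs1", "rs2", "rs3")
#' ins <- as_snp_instruments(data.frame(
#'   rsid = c("rs1", "rs2", "rs3"), gene = "g",
#'   effect_allele = "A", other_allele = "B",
#'   eaf = c(0.5, 0.25, 0.5), weight = c(0.1, 0.2, 0.3), exposure = "T2D"))
#' build_score(g, score_spec("s", ins, standardize = FALSE)) # 0.4, 0.2
#' @export
build_score <- function(dosages, spec) {
  stopifnot(inherits(spec, "score_spec"))
  ins <- spec$instruments
  absent <- setdiff(ins$rsid, colnames(dosages))
  if (length(absent) > 0L) {
    stop("dosage matrix lacks instrument column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  g <- dosages[, ins$rsid, drop = FALSE]
  obs <- !is.na(g)
  if (spec$no_mean_imputation) {
    g[!obs] <- 0
    counted <- rowSums(obs)      # SNPs entering each sample's sum
  } else {
    for (j in seq_len(ncol(g))) {
      g[!obs[, j], j] <- 2 * ins$eaf[j]
    }
    counted <- rep(ncol(g), nrow(g))
  }
  raw <- as.numeric(g %*% ins$weight)
  if (spec$mode == "AVERAGE") raw <- raw / (2 * counted)
  raw[rowSums(obs) == 0L] <- NA_real_
  if (spec$standardize) raw <- standardize_score(raw)
  raw
}

#' Standardise a score to mean 0, SD 1
#'
#' Normalisation over the non-missing entries (sample SD, denominator
#' `n - 1`); missing entries stay missing.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return The standardised vector.
#' @export
standardize_score <- function(x) {
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 2L) {
    stop("degenerate score: fewer than two distinct non-missing values",
         call. = FALSE)
  }
  (x - mean(obs)) / stats::sd(obs)
}

#' Derive instrument weights from association results
#'
#' Sets each instrument's weight to the per-allele estimate of the matching
#' association fit (ln-OR for T2D, ln-scale slope for 25(OH)D), preserving
#' effect-allele orientation. Intended for in-sample sensitivity runs; the
#' default pipeline uses fixed published weights
#' ([default_instruments()]) to avoid winner's-curse circularity.
#'
#' @param results List of `assoc_result` objects for single SNPs, all with
#'   the same outcome.
#' @param template Optional `snp_instruments` table supplying alleles and
#'   frequencies for the fitted rsIDs; without it, allele labels are `NA`.
#' @return A `snp_instruments` table with `weight` set to the estimates.
#' @export
score_weights_from_results <- function(results, template = NULL) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "assoc_result")))
  outs <- unique(vapply(results, `[[`, character(1), "outcome"))
  if (length(outs) != 1L) {
    stop("mixed outcomes: all results must instrument the same exposure",
         call. = FALSE)
  }
  rsids <- vapply(results, `[[`, character(1), "term")
  wts <- vapply(results, `[[`, numeric(1), "estimate")
  eafs <- vapply(results, `[[`, numeric(1), "eaf")
  if (!is.null(template)) {
    template <- as_snp_instruments(template)
    idx <- match(rsids, template$rsid)
    if (anyNA(idx)) {
      stop("template lacks rsid(s): ",
           paste(rsids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    out <- template[idx, , drop = FALSE]
    out$weight <- wts
    out$exposure <- outs
    return(as_snp_instruments(out))
  }
  as_snp_instruments(data.frame(
    rsid = rsids, gene = NA_character_,
    effect_allele = NA_character_, other_allele = NA_character_,
    eaf = eafs, weight = wts, exposure = outs,
    stringsAsFactors = FALSE))
}
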