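#' SNP instrument definitions
#'
#' A `snp_instruments` object is a data frame with one row per instrument SNP
#' and columns `rsid`, `gene`, `effect_allele`, `other_allele`, `eaf`
#' (effect-allele frequency), `weight` (per-allele effect: ln-OR when the
#' instrumented exposure is T2D, ln-nmol/L slope when it is 25(OH)D) and
#' `exposure` (`"T2D"` or `"VITD"`).
#'
#' @param x A data frame with the columns above.
#' @return `as_snp_instruments()` returns a validated `snp_instruments` object.
#' @examples
#' default_instruments("VITD")
#' @export
as_snp_instruments <- function(x) {
  needed <- c("rsid", "gene", "effect_allele", "other_allele",
              "eaf", "weight", "exposure")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("instrument table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[needed]
  x$rsid <- as.character(x$rsid)
  x$gene <- as.character(x$gene)
  x$effect_allele <- as.character(x$effect_allele)
  x$other_allele <- as.character(x$other_allele)
  x$eaf <- as.numeric(x$eaf)
  x$weight <- as.numeric(x$weight)
  x$exposure <- as.character(x$exposure)
  validate_instruments(x)
  class(x) <- c("snp_instruments", "data.frame")
  x
}

validate_instruments <- function(x) {
  if (!all(x$exposure %in% c("T2D", "VITD"))) {
    stop("exposure must be 'T2D' or 'VITD'", call. = FALSE)
  }
  bad_af <- !is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1)
  if (any(bad_af)) {
    stop("eaf must lie strictly in (0, 1); offending rsid(s): ",
         paste(x$rsid[bad_af], collapse = ", "), call. = FALSE)
  }
  same <- !is.na(x$effect_allele) & !is.na(x$other_allele) &
    x$effect_allele == x$other_allele
  if (any(same)) {
    stop("effect_allele must differ from other_allele; offending rsid(s): ",
         paste(x$rsid[same], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$rsid)) {
    stop("duplicated rsid in instrument table", call. = FALSE)
  }
  invisible(x)
}

#' Read or write an instrument table
#'
#' Tab-delimited with header columns
#' `rsid  gene  effect_allele  other_allele  eaf  weight  exposure`.
#'
#' @param path Path to a tab-delimited instrument file.
#' @return `read_instruments()` returns a [as_snp_instruments()] object;
#'   `write_instruments()` returns `path` invisibly.
#' @export
read_instruments <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_snp_instruments(x)
}

#' @rdname read_instruments
#' @param x A `snp_instruments` object.
#' @export
write_instruments <- function(x, path) {
  x <- as_snp_instruments(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged instrument set
#'
#' The six instruments used throughout: three vitamin-D pathway SNPs weighted
#' by their per-allele effects on ln 25(OH)D (GC rs2282679 -0.091, DHCR7
#' rs12785878 -0.042, CYP2R1 rs12794714 -0.039 ln-nmol/L) and three T2D SNPs
#' weighted by their per-allele ln-odds-ratios (IGF2BP2 rs1470579 ln 1.12,
#' TCF7L2 rs7903146 ln 1.25, KCNQ1 rs2237896 ln 1.49). Allele labels are
#' nominal simulation labels (the source tables print no allele codes);
#' orientation is fixed by the sign of the weight.
#'
#' @param exposure `"VITD"`, `"T2D"`, or `"both"`.
#' @return A `snp_instruments` data frame.
#' @export
default_instruments <- function(exposure = c("both", "VITD", "T2D")) {
  exposure <- match.arg(exposure)
  path <- system.file("extdata", "instruments.tsv", package = "vitdmr",
                      mustWork = TRUE)
  x <- read_instruments(path)
  if (exposure != "both") x <- x[x$exposure == exposure, , drop = FALSE]
  as_snp_instruments(x)
}

#' @export
print.snp_instruments <- function(x, ...) {
  cat("SNP instruments (", nrow(x), " variants)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
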