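#' Simulation parameters for a synthetic genotype-phenotype cohort
#'
#' Bundles everything the generator needs: Hardy-Weinberg allele frequencies,
#' per-allele genetic effects on ln 25(OH)D and on the T2D log-odds, covariate
#' effects, and the optional causal (25(OH)D to T2D), reverse-causal (T2D to
#' 25(OH)D) and pleiotropic paths. At most one of the two directional paths
#' may be active in a single run, so the simulated causal direction is always
#' unambiguous.
#'
#' Covariates enter every linear predictor centred at their generative means
#' (age 52 y, sex 0.5, BMI 26.5 kg/m2), so `baseline_ln_vitd` and
#' `t2d_intercept` are the outcome levels of a reference individual.
#'
#' @param n Cohort size (positive integer).
#' @param ancestry `"EUROPEAN"` or `"SOUTH_ASIAN"` (label only; frequencies
#'   live in `maf_by_snp`).
#' @param maf_by_snp Named numeric vector of effect-allele frequencies, one
#'   per SNP, each strictly in (0, 1).
#' @param vitd_effects Named vector of per-allele slopes on ln 25(OH)D
#'   (ln-nmol/L); names must be a subset of `names(maf_by_snp)`.
#' @param t2d_log_ors Named vector of per-allele ln-odds-ratios on T2D.
#' @param baseline_ln_vitd Intercept of the ln 25(OH)D model (ln nmol/L).
#' @param vitd_sd Residual SD of ln 25(OH)D (> 0).
#' @param t2d_intercept Intercept of the T2D logit model.
#' @param covariate_effects List with numeric vectors `vitd` and `t2d`, each
#'   with elements `age`, `sex`, `bmi`: covariate slopes on the two outcomes.
#' @param causal_vitd_to_t2d Causal effect of ln 25(OH)D on the T2D log-odds
#'   (ln-OR per ln-nmol/L; default 0).
#' @param reverse_t2d_to_vitd Shift in ln 25(OH)D for T2D cases
#'   (ln-nmol/L; default 0).
#' @param pleiotropy Named vector of direct per-allele ln-ORs on T2D that
#'   bypass 25(OH)D (default none).
#' @param missing_rate Probability that a dosage entry is missing, in [0, 1).
#' @param uv_index `NULL`, or `list(mean=, sd=, effect=)` adding a normal UV
#'   covariate to the ln 25(OH)D predictor.
#' @param seed Integer seed driving a single random stream.
#' @return A validated `sim_params` object (a list).
#' @seealso [default_presets()] for ready-made scenario parameterisations.
#' @export
sim_params <- function(n,
                       ancestry = "EUROPEAN",
                       maf_by_snp,
                       vitd_effects = numeric(),
                       t2d_log_ors = numeric(),
                       baseline_ln_vitd = log(50),
                       vitd_sd = 0.45,
                       t2d_intercept = qlogis(0.10),
                       covariate_effects = default_covariate_effects(),
                       causal_vitd_to_t2d = 0,
                       reverse_t2d_to_vitd = 0,
                       pleiotropy = numeric(),
                       missing_rate = 0,
                       uv_index = NULL,
                       seed = 1L) {
  p <- list(n = as.integer(n), ancestry = ancestry,
            maf_by_snp = maf_by_snp, vitd_effects = vitd_effects,
            t2d_log_ors = t2d_log_ors,
            baseline_ln_vitd = baseline_ln_vitd, vitd_sd = vitd_sd,
            t2d_intercept = t2d_intercept,
            covariate_effects = covariate_effects,
            causal_vitd_to_t2d = causal_vitd_to_t2d,
            reverse_t2d_to_vitd = reverse_t2d_to_vitd,
            pleiotropy = pleiotropy, missing_rate = missing_rate,
            uv_index = uv_index, seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

default_covariate_effects <- function() {
  list(vitd = c(age = -0.002, sex = 0.05, bmi = -0.010),
       t2d  = c(age = 0.040, sex = 0.20, bmi = 0.080))
}

# Generative covariate distributions (shared by the intercept calibration).
COVARIATE_DIST <- list(age = c(mean = 52, sd = 13),
                       sex = c(mean = 0.5, sd = 0.5),
                       bmi = c(mean = 26.5, sd = 4.8))

validate_sim_params <- function(p) {
  if (is.na(p$n) || p$n <= 0L) stop("n must be a positive integer", call. = FALSE)
  if (length(p$maf_by_snp) == 0L || is.null(names(p$maf_by_snp))) {
    stop("maf_by_snp must be a named vector of allele frequencies", call. = FALSE)
  }
  if (any(p$maf_by_snp <= 0 | p$maf_by_snp >= 1)) {
    stop("all allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  for (fld in c("vitd_effects", "t2d_log_ors", "pleiotropy")) {
    v <- p[[fld]]
    if (length(v) > 0L && !all(names(v) %in% names(p$maf_by_snp))) {
      stop(fld, " names must be a subset of names(maf_by_snp)", call. = FALSE)
    }
  }
  if (p$vitd_sd <= 0) stop("vitd_sd must be positive", call. = FALSE)
  if (p$missing_rate < 0 || p$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (p$causal_vitd_to_t2d != 0 && p$reverse_t2d_to_vitd != 0) {
    stop("causal_vitd_to_t2d and reverse_t2d_to_vitd cannot both be active: ",
         "the simulated causal direction must be unambiguous", call. = FALSE)
  }
  invisible(p)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each SNP is drawn independently with genotype probabilities
#' ((1-q)^2, 2q(1-q), q^2) for effect-allele frequency q, then entries are
#' set missing independently with probability `missing_rate`.
#'
#' @param n Number of samples.
#' @param maf_by_snp Named vector of effect-allele frequencies.
#' @param missing_rate Per-entry missingness probability in [0, 1).
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @return An `n` x SNPs integer matrix with entries 0/1/2 or `NA`, columns
#'   named by rsID.
#' @examples
#' g <- simulate_genotypes(1000, c(rs1 = 0.3), seed = 1)
#' mean(g) # ~ 0.6
#' @export
simulate_genotypes <- function(n, maf_by_snp, missing_rate = 0, seed = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (any(maf_by_snp <= 0 | maf_by_snp >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- length(maf_by_snp)
  g <- matrix(NA_integer_, nrow = n, ncol = m,
              dimnames = list(NULL, names(maf_by_snp)))
  for (j in seq_len(m)) {
    q <- maf_by_snp[[j]]
    g[, j] <- sample(0:2, n, replace = TRUE,
                     prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }
  if (missing_rate > 0) {
    g[matrix(runif(n * m) < missing_rate, nrow = n)] <- NA_integer_
  }
  g
}

# Dosage contribution to a linear predictor: missing dosages contribute 0.
dosage_term <- function(dosages, effects) {
  out <- numeric(nrow(dosages))
  if (length(effects) == 0L) return(out)
  for (rs in names(effects)) {
    d <- dosages[, rs]
    d[is.na(d)] <- 0
    out <- out + effects[[rs]] * d
  }
  out
}

#' Simulate phenotypes on top of a dosage matrix
#'
#' Generates age, sex and BMI, then 25(OH)D and T2D according to the model
#' \deqn{\ln vitd = baseline + \sum_j \beta_j g_j + covariates +
#'       reverse \cdot t2d + N(0, vitd\_sd)}
#' \deqn{logit P(t2d) = intercept + \sum_j \gamma_j g_j + \sum_j
#'       pleiotropy_j g_j + causal \cdot \ln vitd + covariates.}
#' T2D is generated before 25(OH)D when the reverse path is active and after
#' it when the causal path is active; the two paths are mutually exclusive.
#' Missing dosages contribute 0 to linear predictors. 25(OH)D is stored on
#' the measurement scale (nmol/L).
#'
#' @param dosages A dosage matrix from [simulate_genotypes()] with columns
#'   covering all SNPs named in `params`.
#' @param params A [sim_params()] object.
#' @return A `vd_cohort`: list with `dosages` and a `phenotypes` data frame
#'   (`sample_id`, `age`, `sex`, `bmi`, `t2d`, `vitd_nmol_l`, and `uv_index`
#'   when enabled).
#' @export
simulate_phenotypes <- function(dosages, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!all(names(params$maf_by_snp) %in% colnames(dosages))) {
    stop("dosage matrix lacks column(s) named in params", call. = FALSE)
  }
  n <- nrow(dosages)
  ce <- params$covariate_effects
  age <- rnorm(n, COVARIATE_DIST$age["mean"], COVARIATE_DIST$age["sd"])
  sex <- rbinom(n, 1, 0.5)
  bmi <- rnorm(n, COVARIATE_DIST$bmi["mean"], COVARIATE_DIST$bmi["sd"])
  cov_vitd <- ce$vitd["age"] * (age - 52) + ce$vitd["sex"] * (sex - 0.5) +
    ce$vitd["bmi"] * (bmi - 26.5)
  cov_t2d <- ce$t2d["age"] * (age - 52) + ce$t2d["sex"] * (sex - 0.5) +
    ce$t2d["bmi"] * (bmi - 26.5)

  uv <- NULL
  if (!is.null(params$uv_index)) {
    uv <- rnorm(n, params$uv_index$mean, params$uv_index$sd)
    cov_vitd <- cov_vitd + params$uv_index$effect * (uv - params$uv_index$mean)
  }

  gen_vitd <- dosage_term(dosages, params$vitd_effects)
  gen_t2d <- dosage_term(dosages, params$t2d_log_ors) +
    dosage_term(dosages, params$pleiotropy)

  if (params$reverse_t2d_to_vitd != 0) {
    # disease first, then its downstream shift on 25(OH)D
    lp_t2d <- params$t2d_intercept + gen_t2d + cov_t2d
    t2d <- rbinom(n, 1, plogis(lp_t2d))
    ln_vitd <- params$baseline_ln_vitd + gen_vitd + cov_vitd +
      params$reverse_t2d_to_vitd * t2d + rnorm(n, 0, params$vitd_sd)
  } else {
    ln_vitd <- params$baseline_ln_vitd + gen_vitd + cov_vitd +
      rnorm(n, 0, params$vitd_sd)
    lp_t2d <- params$t2d_intercept + gen_t2d + cov_t2d +
      params$causal_vitd_to_t2d * ln_vitd
    t2d <- rbinom(n, 1, plogis(lp_t2d))
  }

  phen <- data.frame(sample_id = sprintf("S%06d", seq_len(n)),
                     age = age, sex = sex, bmi = bmi, t2d = t2d,
                     vitd_nmol_l = exp(ln_vitd),
                     stringsAsFactors = FALSE)
  if (!is.null(uv)) phen$uv_index <- uv
  structure(list(dosages = dosages, phenotypes = phen, params = params),
            class = "vd_cohort")
}

#' Simulate a complete cohort
#'
#' Seeds one random stream from `params$seed`, then draws genotypes and
#' phenotypes sequentially, so identical parameters give bit-identical
#' cohorts.
#'
#' @param params A [sim_params()] object.
#' @return A `vd_cohort` (see [simulate_phenotypes()]).
#' @examples
#' ch <- simulate_cohort(default_presets("INDEPENDENT", n = 500, seed = 7))
#' ch
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  g <- simulate_genotypes(params$n, params$maf_by_snp, params$missing_rate,
                          seed = NULL)
  simulate_phenotypes(g, params)
}

#' @export
print.vd_cohort <- function(x, ...) {
  ph <- x$phenotypes
  cat("Synthetic cohort: ", nrow(ph), " samples, ",
      ncol(x$dosages), " SNPs\n", sep = "")
  cat(sprintf("  T2D cases: %d (%.1f%%); median 25(OH)D: %.1f nmol/L\n",
              sum(ph$t2d), 100 * mean(ph$t2d),
              stats::median(ph$vitd_nmol_l, na.rm = TRUE)))
  invisible(x)
}

# Mean/variance of the non-intercept part of the T2D linear predictor under
# the generative model; used to calibrate the intercept to a target
# prevalence by Gauss-quadrature over a normal approximation.
lp_moments <- function(maf, t2d_effects, cov_t2d, causal, baseline_ln_vitd,
                       vitd_effects, vitd_sd) {
  mu <- 0; v <- 0
  for (rs in names(t2d_effects)) {
    q <- maf[[rs]]
    mu <- mu + t2d_effects[[rs]] * 2 * q
    v <- v + t2d_effects[[rs]]^2 * 2 * q * (1 - q)
  }
  for (nm in names(COVARIATE_DIST)) {
    v <- v + (cov_t2d[[nm]] * COVARIATE_DIST[[nm]]["sd"])^2
  }
  if (causal != 0) {
    m_lv <- baseline_ln_vitd
    v_lv <- vitd_sd^2
    for (rs in names(vitd_effects)) {
      q <- maf[[rs]]
      m_lv <- m_lv + vitd_effects[[rs]] * 2 * q
      v_lv <- v_lv + vitd_effects[[rs]]^2 * 2 * q * (1 - q)
    }
    mu <- mu + causal * m_lv
    v <- v + causal^2 * v_lv
  }
  c(mean = unname(mu), var = unname(v))
}

calibrate_t2d_intercept <- function(target_prev, mom) {
  f <- function(a) {
    stats::integrate(function(z) plogis(a + mom["mean"] + sqrt(mom["var"]) * z) *
                       stats::dnorm(z), -8, 8)$value - target_prev
  }
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

#' Scenario presets for the synthetic cohort generator
#'
#' Ready-made parameterisations of the four study scenarios:
#' \describe{
#'   \item{INDEPENDENT}{The concluded world: the six per-allele effects are
#'     set to their published values (GC -0.091, DHCR7 -0.042, CYP2R1 -0.039
#'     ln-nmol/L; IGF2BP2 ln 1.12, TCF7L2 ln 1.25, KCNQ1 ln 1.49) with no
#'     causal, reverse or pleiotropic path.}
#'   \item{FORWARD_CAUSAL}{As INDEPENDENT plus a causal effect of ln 25(OH)D
#'     on the T2D log-odds. The default, ln(1.05)/(-0.042) = -1.162 ln-OR per
#'     ln-nmol/L, is the value under which the DHCR7 allele raises T2D odds
#'     by 5% per allele through its -0.042 effect on ln 25(OH)D.}
#'   \item{REVERSE_CAUSAL}{As INDEPENDENT plus a -0.10 ln-nmol/L shift of
#'     25(OH)D in T2D cases.}
#'   \item{NULL}{All genetic effects exactly zero (covariate structure kept).}
#' }
#' Effect-allele frequencies default to the European range (0.22-0.32), or to
#' the South Asian GC frequency 0.73 when `ancestry = "SOUTH_ASIAN"`. The
#' T2D intercept is calibrated so that marginal prevalence is close to
#' `target_prevalence` under the scenario's genetic and covariate structure.
#'
#' @param scenario One of `"INDEPENDENT"`, `"FORWARD_CAUSAL"`,
#'   `"REVERSE_CAUSAL"`, `"NULL"`.
#' @param ancestry `"EUROPEAN"` or `"SOUTH_ASIAN"`.
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param causal_vitd_to_t2d Override for the FORWARD_CAUSAL path strength.
#' @param reverse_t2d_to_vitd Override for the REVERSE_CAUSAL shift.
#' @param target_prevalence Marginal T2D prevalence the intercept is
#'   calibrated to (default 0.10).
#' @param missing_rate Dosage missingness rate.
#' @return A [sim_params()] object.
#' @export
default_presets <- function(scenario = c("INDEPENDENT", "FORWARD_CAUSAL",
                                         "REVERSE_CAUSAL", "NULL"),
                            ancestry = c("EUROPEAN", "SOUTH_ASIAN"),
                            n = 50000, seed = 1L,
                            causal_vitd_to_t2d = log(1.05) / (-0.042),
                            reverse_t2d_to_vitd = -0.10,
                            target_prevalence = 0.10,
                            missing_rate = 0) {
  scenario <- match.arg(scenario)
  ancestry <- match.arg(ancestry)
  ins <- default_instruments("both")
  maf <- stats::setNames(ins$eaf, ins$rsid)
  if (ancestry == "SOUTH_ASIAN") maf[["rs2282679"]] <- 0.73
  vitd_eff <- stats::setNames(ins$weight[ins$exposure == "VITD"],
                              ins$rsid[ins$exposure == "VITD"])
  t2d_eff <- stats::setNames(ins$weight[ins$exposure == "T2D"],
                             ins$rsid[ins$exposure == "T2D"])
  causal <- 0; reverse <- 0
  if (scenario == "NULL") {
    vitd_eff[] <- 0
    t2d_eff[] <- 0
  } else if (scenario == "FORWARD_CAUSAL") {
    causal <- causal_vitd_to_t2d
  } else if (scenario == "REVERSE_CAUSAL") {
    reverse <- reverse_t2d_to_vitd
  }
  ce <- default_covariate_effects()
  mom <- lp_moments(maf, t2d_eff, ce$t2d, causal, log(50), vitd_eff, 0.45)
  intercept <- calibrate_t2d_intercept(target_prevalence, mom)
  sim_params(n = n, ancestry = ancestry, maf_by_snp = maf,
             vitd_effects = vitd_eff, t2d_log_ors = t2d_eff,
             baseline_ln_vitd = log(50), vitd_sd = 0.45,
             t2d_intercept = intercept, covariate_effects = ce,
             causal_vitd_to_t2d = causal, reverse_t2d_to_vitd = reverse,
             missing_rate = missing_rate, seed = seed)
}

#' Write or read a cohort as a pair of tab-delimited files
#'
#' `<prefix>_dosages.tsv` has `sample_id` plus one 0/1/2/`NA` column per
#' rsID; `<prefix>_phenotypes.tsv` has the phenotype table.
#'
#' @param cohort A `vd_cohort`.
#' @param prefix Output path prefix.
#' @return `write_cohort()` returns the two paths invisibly; `read_cohort()`
#'   returns a `vd_cohort` (without generative parameters).
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "vd_cohort"))
  dpath <- paste0(prefix, "_dosages.tsv")
  ppath <- paste0(prefix, "_phenotypes.tsv")
  dd <- data.frame(sample_id = cohort$phenotypes$sample_id,
                   cohort$dosages, check.names = FALSE)
  utils::write.table(dd, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$phenotypes, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(dosages = dpath, phenotypes = ppath))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(prefix) {
  dd <- utils::read.delim(paste0(prefix, "_dosages.tsv"),
                          check.names = FALSE)
  ph <- utils::read.delim(paste0(prefix, "_phenotypes.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(dd[, setdiff(names(dd), "sample_id"), drop = FALSE])
  storage.mode(g) <- "integer"
  if (!identical(nrow(g), nrow(ph))) {
    stop("dosage and phenotype files disagree on sample count", call. = FALSE)
  }
  structure(list(dosages = g, phenotypes = ph, params = NULL),
            class = "vd_cohort")
}
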