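test_that("wald_ratio follows the ratio estimator and its delta-method SE", {
  # DHCR7-style inputs: -0.042 ln-nmol/L per allele, ln(1.05) per allele
  w <- wald_ratio(c(-0.042, 0.0032), c(log(1.05), 0.017), "rs12785878")
  expect_equal(w$beta_iv, -1.16167057546267, tolerance = 1e-9)
  expect_equal(w$se_iv,
               abs(w$beta_iv) * sqrt(0.017^2 / log(1.05)^2 +
                                     0.0032^2 / 0.042^2),
               tolerance = 1e-12)

  zero_out <- wald_ratio(c(0.5, 0.02), c(0, 0.1))
  expect_equal(zero_out$beta_iv, 0)
  expect_equal(zero_out$se_iv, 0.1 / 0.5)

  # a near-exact instrument passes the outcome SE through the ratio
  lim <- wald_ratio(c(1, 1e-12), c(0.5, 0.1))
  expect_equal(lim$se_iv, 0.1, tolerance = 1e-6)

  expect_error(wald_ratio(c(0, 0.1), c(0.2, 0.1)), "weak instrument")
  expect_error(wald_ratio(c(0.5, 0), c(0.2, 0.1)), "positive")
})

test_that("the delta-method SE respects its first-order lower bound", {
  set.seed(71)
  for (i in 1:50) {
    bx <- runif(1, 0.01, 1) * sample(c(-1, 1), 1)
    by <- runif(1, -1, 1)
    sx <- runif(1, 0.001, 0.5); sy <- runif(1, 0.001, 0.5)
    w <- wald_ratio(c(bx, sx), c(by, sy))
    expect_gte(w$se_iv + 1e-12, abs(sy / bx))
  }
})

test_that("wald_ratio accepts association and meta objects directly", {
  ch <- simulate_cohort(default_presets("INDEPENDENT", n = 5000, seed = 23))
  sc <- build_score(ch$dosages, score_spec("vd", default_instruments("VITD")))
  fx <- fit_linear_vitd(sc, ch, term_label = "vd_score")
  fo <- fit_logistic_t2d(sc, ch, term_label = "vd_score")
  w <- wald_ratio(fx, fo, "vd_score")
  expect_equal(w$beta_iv, fo$estimate / fx$estimate, tolerance = 1e-12)

  m <- meta_ivw(load_fixture("VITD_SCORE_ON_VITD")$rows)
  w2 <- wald_ratio(m, fo, "vd_score_meta")
  expect_equal(w2$beta_iv, fo$estimate / m$estimate, tolerance = 1e-12)
  stf <- meta_stouffer(load_fixture("VITD_SCORE_ON_T2D")$rows)
  expect_error(wald_ratio(m, stf), "no pooled estimate")
})

test_that("the headline association pattern yields the published verdicts", {
  # composite scores: strong on their exposures, null on the cross outcomes;
  # DHCR7 alone clears the corrected threshold on both sides
  report <- mr_bidirectional(
    forward_exposure = list(composite = c(-0.021, 0.001, 7.92e-78),
                            rs12785878 = c(-0.042, 0.0032, 9.0e-32),
                            rs2282679 = c(-0.091, 0.005, 2.87e-61)),
    forward_outcome = list(composite = c(0.002, 0.0013, 0.12),
                           rs12785878 = c(log(1.05), 0.017, 0.004),
                           rs2282679 = c(log(1.03), 0.024, 0.207)),
    reverse_exposure = list(composite = c(log(1.24), 0.00823, 1.82e-32)),
    reverse_outcome = list(composite = c(-0.0002, 0.0001, 0.829)))
  expect_equal(unname(report$verdicts["forward"]), "NOT_SUPPORTED")
  expect_equal(unname(report$verdicts["reverse"]), "NOT_SUPPORTED")
  expect_equal(unname(report$forward$per_instrument["rs12785878"]),
               "SUPPORTED")
  expect_equal(unname(report$forward$per_instrument["rs2282679"]),
               "NOT_SUPPORTED")
  expect_true(any(grepl("rs12785878", report$notes)))
  expect_output(print(report), "NOT_SUPPORTED")
  smry <- summary(report)
  expect_equal(nrow(smry), 4)
  expect_true(all(c("beta_iv", "verdict") %in% names(smry)))
})

test_that("the default threshold is Bonferroni 0.05/8 printing as 0.0063", {
  report <- mr_bidirectional(
    forward_exposure = list(composite = c(-0.02, 0.001, 1e-20)),
    forward_outcome = list(composite = c(0.001, 0.01, 0.9)),
    reverse_exposure = list(composite = c(0.2, 0.01, 1e-20)),
    reverse_outcome = list(composite = c(0.001, 0.01, 0.9)))
  expect_equal(report$alpha, 0.05 / 8)
  expect_equal(sprintf("%.4f", report$alpha), "0.0063")
  expect_output(print(report), "0.0063")
  expect_error(mr_bidirectional(list(composite = c(1, 1)),
                                list(composite = c(1, 1)),
                                list(composite = c(1, 1)),
                                list(composite = c(1, 1)), alpha = 1.2),
               "alpha")
})

test_that("verdicts are invariant to relabelling effect alleles", {
  fe <- list(composite = c(-0.021, 0.001, 7.92e-78))
  fo <- list(composite = c(0.002, 0.0013, 0.12))
  re <- list(composite = c(0.215, 0.008, 1.82e-32))
  ro <- list(composite = c(-0.0002, 0.0001, 0.829))
  base <- mr_bidirectional(fe, fo, re, ro)
  flip <- function(l) lapply(l, function(v) c(-v[1], v[2], v[3]))
  flipped <- mr_bidirectional(flip(fe), flip(fo), flip(re), flip(ro))
  expect_equal(flipped$verdicts, base$verdicts)
  expect_equal(abs(flipped$forward$estimates$composite$beta_iv),
               abs(base$forward$estimates$composite$beta_iv))
})

test_that("weak or absent composite instruments give INCONCLUSIVE", {
  rep1 <- mr_bidirectional(
    forward_exposure = list(composite = c(0.01, 0.02, 0.6)),
    forward_outcome = list(composite = c(0.2, 0.05, 1e-5)),
    reverse_exposure = list(rs1 = c(0.2, 0.01, 1e-20)),
    reverse_outcome = list(rs1 = c(0.3, 0.01, 1e-20)))
  expect_equal(unname(rep1$verdicts["forward"]), "INCONCLUSIVE")
  expect_equal(unname(rep1$verdicts["reverse"]), "INCONCLUSIVE")
  expect_true(any(grepl("no composite", rep1$notes)))
})

test_that("simulated scenarios recover the planted causal structure", {
  run_direction <- function(scenario, seed, n = 30000) {
    ch <- simulate_cohort(default_presets(scenario, n = n, seed = seed,
                                          causal_vitd_to_t2d = -0.5))
    vd <- build_score(ch$dosages, score_spec("vd", default_instruments("VITD")))
    td <- build_score(ch$dosages, score_spec("td", default_instruments("T2D")))
    mr_bidirectional(
      forward_exposure = list(composite = fit_linear_vitd(vd, ch,
                                                          term_label = "vd")),
      forward_outcome = list(composite = fit_logistic_t2d(vd, ch,
                                                          term_label = "vd")),
      reverse_exposure = list(composite = fit_logistic_t2d(td, ch,
                                                           term_label = "td")),
      reverse_outcome = list(composite = fit_linear_vitd(
        td, ch, covariates = c("age", "sex", "bmi", "t2d"),
        term_label = "td")))
  }

  # independence: both directions null
  ind <- lapply(1:3, function(s) run_direction("INDEPENDENT", 300 + s))
  expect_true(all(vapply(ind, function(r) r$verdicts["forward"],
                         character(1)) == "NOT_SUPPORTED"))
  expect_true(all(vapply(ind, function(r) r$verdicts["reverse"],
                         character(1)) == "NOT_SUPPORTED"))

  # forward causation: the composite forward Wald ratio covers the planted
  # effect, and no spurious reverse signal appears
  fwd <- lapply(1:3, function(s) run_direction("FORWARD_CAUSAL", 400 + s))
  covers <- vapply(fwd, function(r) {
    e <- r$forward$estimates$composite
    abs(e$beta_iv - (-0.5)) < 1.959964 * e$se_iv
  }, logical(1))
  expect_gte(sum(covers), 2)
  expect_true(all(vapply(fwd, function(r) r$verdicts["reverse"],
                         character(1)) == "NOT_SUPPORTED"))

  # reverse causation: no spurious forward signal; the reverse ratio leans
  # negative (cases sit lower in 25(OH)D)
  rev <- lapply(1:4, function(s) run_direction("REVERSE_CAUSAL", 500 + s))
  expect_true(all(vapply(rev, function(r) r$verdicts["forward"],
                         character(1)) == "NOT_SUPPORTED"))
  mean_rev <- mean(vapply(rev, function(r)
    r$reverse$estimates$composite$beta_iv, numeric(1)))
  expect_lt(mean_rev, 0)
})

test_that("ln-scale betas convert to the reporting scale", {
  rs <- beta_ln_reported(c(-0.021, -0.042, 0))
  expect_equal(rs$reported, c(-2.1, -4.2, 0))
  expect_equal(rs$percent, 100 * (exp(c(-0.021, -0.042, 0)) - 1))
})
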