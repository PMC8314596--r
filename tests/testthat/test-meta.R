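# Expected Z values below were frozen from a 50-digit-precision
# inverse-normal reference computation.

test_that("z_from_p is accurate from p = 1 down to extreme tails", {
  expect_equal(z_from_p(1.0, "+"), 0.0)
  expect_equal(z_from_p(0.05, "+"), 1.959964, tolerance = 1e-6)
  expect_equal(z_from_p(6.09e-13, "+"), 7.19845194796348, tolerance = 1e-9)
  expect_equal(z_from_p(2.70e-04, "-"), -3.64250283822469, tolerance = 1e-9)
  expect_equal(z_from_p(1e-300, "+"), 37.0471, tolerance = 1e-3)
  expect_error(z_from_p(0, "+"), "\\(0, 1\\]")
  expect_error(z_from_p(-0.1, "+"), "\\(0, 1\\]")
  expect_error(z_from_p(1.0000001, "+"), "\\(0, 1\\]")
})

test_that("p_from_z and z_from_p invert each other across the usable range", {
  zs <- c(seq(-38, 38, by = 2.5), 0, 0.5, -0.5)
  back <- z_from_p(p_from_z(zs), ifelse(zs >= 0, "+", "-"))
  expect_equal(back, zs, tolerance = 1e-6)
  expect_true(all(p_from_z(c(0, 5, 40, 1000)) > 0))
})

test_that("IVW pooling matches hand-computed and degenerate cases", {
  fx <- load_fixture("VITD_SCORE_ON_VITD")
  sa <- fx$rows[fx$rows$ancestry == "SOUTH_ASIAN", ]
  m <- meta_ivw(sa)
  expect_equal(m$estimate, -0.03112, tolerance = 1e-5)
  expect_equal(m$se, 0.0072, tolerance = 1e-4)

  one <- meta_ivw(fx$rows[1, ])
  expect_equal(one$estimate, fx$rows$estimate[1])
  expect_equal(one$se, fx$rows$se[1])

  eq <- rbind(summary_row(cohort = "A", estimate = 0.2, se = 0.1),
              summary_row(cohort = "B", estimate = 0.4, se = 0.1))
  expect_equal(meta_ivw(as_cohort_summary_table(eq))$estimate, 0.3)
})

test_that("IVW agrees with an independent fixed-effect implementation", {
  skip_if_not_installed("metafor")
  fx <- load_fixture("VITD_SCORE_ON_VITD")
  m <- meta_ivw(fx$rows)
  rma <- metafor::rma(yi = fx$rows$estimate, sei = fx$rows$se, method = "FE")
  expect_equal(m$estimate, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$se, rma$se, tolerance = 1e-10)
  expect_equal(m$q_stat, rma$QE, tolerance = 1e-8)

  fx2 <- load_fixture("T2D_SCORE_ON_T2D")
  r2 <- vitdmr:::ensure_se(fx2$rows)
  m2 <- meta_ivw(fx2$rows)
  rma2 <- metafor::rma(yi = r2$estimate, sei = r2$se, method = "FE")
  expect_equal(m2$estimate, as.numeric(rma2$beta), tolerance = 1e-10)
})

test_that("Stouffer combination matches the high-precision reference", {
  r3 <- as_cohort_summary_table(rbind(
    summary_row(cohort = "A", estimate = 0.1, p = 0.5, direction = "+"),
    summary_row(cohort = "B", estimate = -0.1, p = 0.1, direction = "-"),
    summary_row(cohort = "C", estimate = 0.1, p = 0.01, direction = "+")))
  expect_equal(meta_stouffer(r3)$z, 0.92691589633387, tolerance = 1e-9)

  r2 <- as_cohort_summary_table(rbind(
    summary_row(cohort = "A", p = 0.02), summary_row(cohort = "B", p = 0.3)))
  expect_equal(meta_stouffer(r2)$z, 2.37784543509240, tolerance = 1e-9)

  r1 <- as_cohort_summary_table(summary_row(estimate = -0.1, p = 0.001,
                                            direction = "-"))
  expect_equal(meta_stouffer(r1)$z, -3.29052673149189, tolerance = 1e-9)
  expect_equal(meta_stouffer(r1)$z, z_from_p(0.001, "-"), tolerance = 1e-12)
})

test_that("sample-size weighting reduces to unweighted under equal n", {
  rows <- as_cohort_summary_table(rbind(
    summary_row(cohort = "A", n = 4000, p = 0.03),
    summary_row(cohort = "B", n = 4000, p = 0.2),
    summary_row(cohort = "C", n = 4000, p = 0.6)))
  expect_equal(meta_stouffer(rows, weights = "sample_size")$z,
               meta_stouffer(rows)$z, tolerance = 1e-12)

  # with the published cohort sizes the two schemes separate: the printed
  # combined Z follows the unweighted scheme
  fx <- load_fixture("T2D_SCORE_ON_T2D")
  expect_equal(meta_stouffer(fx$rows)$z, 11.8641588661375, tolerance = 1e-9)
  expect_equal(meta_stouffer(fx$rows, weights = "sample_size")$z,
               12.1311813222658, tolerance = 1e-9)
  rows_no_n <- fx$rows
  rows_no_n$n <- NA
  expect_error(meta_stouffer(rows_no_n, weights = "sample_size"), "n")
})

test_that("heterogeneity statistics follow their closed forms", {
  same <- as_cohort_summary_table(rbind(
    summary_row(cohort = "A", estimate = 0.2, se = 0.1),
    summary_row(cohort = "B", estimate = 0.2, se = 0.1)))
  h <- heterogeneity(same)
  expect_equal(h$q_stat, 0)
  expect_equal(h$i2, 0)

  pm <- as_cohort_summary_table(rbind(
    summary_row(cohort = "A", estimate = 1, se = 1),
    summary_row(cohort = "B", estimate = -1, se = 1, direction = "-")))
  expect_equal(heterogeneity(pm)$q_stat, 2)

  single <- as_cohort_summary_table(summary_row())
  expect_true(is.na(heterogeneity(single)$q_stat))
  m <- meta_ivw(load_fixture("VITD_SCORE_ON_VITD")$rows)
  expect_equal(m$i2, max(0, (m$q_stat - (m$k - 1)) / m$q_stat))
})

test_that("meta invariants hold: SE bound, sign agreement, permutation", {
  fx <- load_fixture("VITD_SCORE_ON_VITD")
  rows <- vitdmr:::ensure_se(fx$rows)
  m <- meta_ivw(rows)
  expect_lt(m$se, min(rows$se))

  # all three schemes agree in sign when every cohort direction agrees
  set.seed(55)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    r <- do.call(rbind, lapply(seq_len(k), function(i) {
      summary_row(cohort = paste0("C", i), n = sample(500:5000, 1),
                  estimate = -runif(1, 0.01, 0.5), se = runif(1, 0.01, 0.2),
                  p = runif(1, 1e-6, 0.9), direction = "-")
    }))
    r <- as_cohort_summary_table(r)
    signs <- c(sign(meta_ivw(r)$z), sign(meta_stouffer(r)$z),
               sign(meta_stouffer(r, weights = "sample_size")$z))
    expect_true(all(signs == -1))
  }

  shuf <- fx$rows[sample(nrow(fx$rows)), ]
  expect_equal(meta_stouffer(shuf)$z, meta_stouffer(fx$rows)$z,
               tolerance = 1e-12)
  expect_equal(meta_ivw(shuf)$estimate, meta_ivw(fx$rows)$estimate,
               tolerance = 1e-12)
})

test_that("subtotal rows are excluded from combination by default", {
  fx <- load_fixture("T2D_SCORE_ON_T2D")
  all_rows <- rbind(fx$rows, fx$subtotals)
  expect_equal(meta_stouffer(all_rows)$k, 8)
  expect_equal(meta_stouffer(all_rows, exclude_subtotals = FALSE)$k, 9)
  expect_error(meta_ivw(fx$rows[0, ]), "no cohort rows")
})

test_that("forest data carries IVW weights with the pooled row last", {
  fx <- load_fixture("VITD_SCORE_ON_VITD")
  fd <- forest_data(fx$rows)
  expect_equal(nrow(fd), 7)
  expect_equal(fd$label[7], "Pooled (IVW)")
  expect_equal(fd$label[1:6], fx$rows$cohort)
  expect_equal(sum(fd$weight_pct[1:6]), 100, tolerance = 1e-9)
  expect_true(all(fd$ci_low < fd$estimate & fd$estimate < fd$ci_high))
  expect_output(print(fd), "Pooled")
})

test_that("table reproduction contrasts all schemes with the printed row", {
  rp <- reproduce_table("T2D_SCORE_ON_VITD")
  # the printed meta row of this table is internally inconsistent: its own
  # cohort rows recombine to +0.21, the printed Z is -0.212
  expect_equal(rp$stouffer$z, 0.212, tolerance = 0.005)
  expect_equal(rp$fixture$printed_meta$z, -0.212)
  expect_output(print(rp), "Stouffer")
})
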