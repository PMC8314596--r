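---
title: "Bidirectional Mendelian randomization between 25(OH)D and type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional Mendelian randomization between 25(OH)D and type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The question and the design

Observational studies consistently find that people with low circulating
25-hydroxyvitamin D (25(OH)D) have more type 2 diabetes (T2D), but
supplementation trials have been equivocal, and both confounding (sun
exposure, adiposity, lifestyle) and reverse causation (disease changing
behaviour and 25(OH)D) can manufacture the observational signal.
Mendelian randomization (MR) sidesteps both: genotypes are fixed at
conception, so a variant that robustly shifts 25(OH)D acts as a randomized
"dose assignment" for the exposure. Running MR in *both* directions — vitamin-D
variants against T2D, and T2D variants against 25(OH)D — additionally
identifies which causal arrow, if any, the data support.

`vitdmr` implements this bidirectional design end to end with two composite
instruments of three SNPs each:

* vitamin-D pathway: GC rs2282679 (transport), DHCR7 rs12785878 (synthesis),
  CYP2R1 rs12794714 (25-hydroxylation), weighted by their per-allele effects
  on ln 25(OH)D (−0.091, −0.042, −0.039 ln-nmol/L);
* T2D susceptibility: IGF2BP2 rs1470579, TCF7L2 rs7903146, KCNQ1 rs2237896,
  weighted by their per-allele ln-odds-ratios (ln 1.12, ln 1.25, ln 1.49).

25(OH)D is analysed throughout on the natural-log scale; T2D on the
log-odds scale. The six instruments are treated as pre-harmonized and in
linkage equilibrium.

## The statistical pipeline

**Association layer.** Per-SNP and per-score effects come from additive-model
fits: ordinary least squares for ln 25(OH)D and maximum-likelihood logistic
regression for T2D (`fit_linear_vitd()`, `fit_logistic_t2d()`), adjusted for
age, sex and BMI (plus T2D status in score-on-25(OH)D fits, and UV index
where measured). Inference is Wald-normal — $z = \hat\beta/\mathrm{SE}$,
$p = 2\Phi(-|z|)$ — so estimate, Z, p and direction are mutually consistent,
as in the published summary tables. Samples with a missing outcome or a
missing genotype are excluded from the fit (genotypes are never
mean-imputed); perfect separation in the logistic fit is reported as a
non-estimable result rather than an error.

**Allele scores.** `build_score()` reproduces PLINK `--score` semantics with
the `--score-no-mean-imputation` rule: the raw score is
$\sum_j w_j g_j$ over non-missing genotypes, a missing genotype contributing
zero (or $2\,\mathrm{EAF}_j$ when imputation is requested), with an
`AVERAGE` mode dividing by the number of alleles counted. Scores are then
standardised to mean 0, SD 1 (`standardize_score()`), so score-on-outcome
effects are per SD of score — which is how the published table magnitudes
read. The source analysis does not say whether SUM or AVERAGE preceded
normalisation; with complete data the two are identical after
standardisation, so both are exposed and SUM is the default. Weights are
fixed external constants by default; `score_weights_from_results()` exists
for in-sample sensitivity runs but re-estimating weights in the analysis
cohort invites winner's-curse bias.

**Meta-analysis.** Three combination schemes, all authored here and
cross-checked in the tests against an independent fixed-effect
implementation and a 50-digit-precision reference:

* inverse-variance fixed-effect (`meta_ivw()`): weights $1/\mathrm{SE}^2$,
  with SEs reconstructed from 95% CIs where tables print only intervals,
  $\mathrm{SE} = (t(u) - t(l))/(2 \times 1.959964)$, $t = \ln$ on the OR
  scale. The quantile is pinned at 1.959964 for determinism; the difference
  from 1.96 is below printed precision.
* unweighted Stouffer (`meta_stouffer()`): $Z = \sum z_i/\sqrt{k}$ with
  $z_i = \mathrm{sign}_i\,\Phi^{-1}(1-p_i/2)$.
* sample-size-weighted Stouffer: $Z = \sum \sqrt{n_i}\,z_i / \sqrt{\sum n_i}$.

Recomputing the packaged tables identifies the scheme behind every printed
combined Z as the *unweighted* Stouffer: 11.86 (T2D score on T2D, 8
cohorts), −18.67 vs printed −18.68 (vitamin-D score on 25(OH)D), −4.61 and
1.54 exactly (South Asian subset; vitamin-D score on T2D). The
$\sqrt{N}$-weighted scheme gives 12.13 on the first table and is retained
because the accompanying text describes sample-size weighting. Cochran's Q,
$I^2 = \max(0, (Q-(k-1))/Q)$ and the heterogeneity p-value are always
reported; random-effects pooling is deliberately not offered, matching the
fixed-effect design. p↔Z transforms go through R's log-parameterised
normal quantile/tail so they stay accurate for p down to $10^{-300}$
(combined p-values such as $3\times10^{-39}$ occur in the large cohorts);
the plain tail underflows near $|z| = 37.6$.

Subtotal rows (ancestry-level pooled rows inside the tables) carry a
`subtotal` flag and are excluded from combination by default, so a pooled
row can never be mixed into an all-cohort meta-analysis.

**MR layer.** `wald_ratio()` computes the instrumental-variable ratio
$\hat\beta_{IV} = \hat\beta_{GY}/\hat\beta_{GX}$ with the first-order
delta-method SE
$|\hat\beta_{IV}|\sqrt{\mathrm{SE}_{GY}^2/\hat\beta_{GY}^2 +
\mathrm{SE}_{GX}^2/\hat\beta_{GX}^2}$ (falling back to
$\mathrm{SE}_{GY}/|\hat\beta_{GX}|$ at $\hat\beta_{GY}=0$). The source
analysis reports its causal conclusion qualitatively; the numeric Wald ratio
is this package's minimal formalisation of it and is labelled as such in
reports. `mr_bidirectional()` assembles both directions: a direction is
SUPPORTED only when the composite instrument passes the corrected threshold
$\alpha = 0.05/8 = 0.00625$ (printed 0.0063; six SNPs plus two traits) on
both the exposure and the outcome side, NOT_SUPPORTED when the instrument
is strong but the outcome association is not, INCONCLUSIVE when the
instrument itself is weak. Per-instrument ratios are always reported
because the key published finding is instrument-specific: only the
synthesis-gene instrument (DHCR7) clears the threshold against T2D. With
three instruments per direction, MR-Egger or median estimators are not
identifiable and are intentionally omitted; pleiotropy robustness is
explored through simulation scenarios instead.

## What the synthetic cohorts emulate

No individual-level data accompany the published tables, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes:

* genotypes under Hardy-Weinberg equilibrium at the six SNPs, with
  European effect-allele frequencies in the published 0.22–0.32 range
  (GC 0.28, DHCR7 0.25, CYP2R1 0.32, IGF2BP2 0.30, TCF7L2 0.30,
  KCNQ1 0.25) and the South Asian GC frequency 0.73; per-cohort frequencies
  for the other SNPs were not published, so the European values are presets,
  not claims;
* $\ln(\mathrm{25(OH)D}) = \mu + \sum_j \beta_j g_j + \text{covariates} +
  \text{reverse}\cdot \mathrm{T2D} + N(0, \sigma)$ with $\mu = \ln 50$ and
  $\sigma = 0.45$, chosen to match the ~50 nmol/L level and ~50% coefficient
  of variation of the published cohort descriptives;
* $\mathrm{logit}\,P(\mathrm{T2D}) = \alpha + \sum_j \gamma_j g_j +
  \sum_j \delta_j g_j + \text{causal}\cdot\ln(\mathrm{25(OH)D}) +
  \text{covariates}$, a logistic (not threshold-liability) disease model,
  simpler and already on the OR scale the instruments are defined on;
* covariates age ~ N(52, 13) years, sex ~ Bernoulli(0.5),
  BMI ~ N(26.5, 4.8) kg/m², centred in the linear predictors so the
  intercepts are reference-individual values; loose calibration to the
  published cohort demographics, again presets rather than claims;
* an optional UV-index covariate entering the 25(OH)D predictor as a normal
  per-sample variable (its three-month-average derivation from weather data
  is out of scope).

Four scenario presets (`default_presets()`) pin the study conditions.
`INDEPENDENT` is the concluded world: the six published per-allele effects
with no cross-trait path. `FORWARD_CAUSAL` adds a causal effect of
ln 25(OH)D on the T2D log-odds, defaulting to
$\ln(1.05)/(-0.042) \approx -1.162$ — the strength at which the DHCR7 allele
raises T2D odds by the published 5% per allele through its −0.042 effect on
ln 25(OH)D. `REVERSE_CAUSAL` shifts cases' ln 25(OH)D by −0.10, a
deficiency-sized effect consistent with the case-control 25(OH)D gaps in
the cohort descriptives. `NULL` zeroes all genetic effects. The causal and
reverse paths are mutually exclusive in one run, so the generative causal
direction is always unambiguous; generation order follows the active arrow
(disease before 25(OH)D under reverse causation, after it otherwise). The
T2D intercept is calibrated by deterministic quadrature so marginal
prevalence is ~10% under each scenario's genetic and covariate structure.
One seed drives a single random stream, making cohorts bit-reproducible.

What the generator deliberately does **not** emulate: linkage
disequilibrium between instruments (the published instruments are in
linkage equilibrium, $r^2 = 0.001$), population-structure confounding,
genotyping error, relatedness (one contributing cohort is sib-pairs; no
mixed models here), or assay differences between cohorts. Passing tests
therefore show that the pipeline recovers known effects from data meeting
the analysis assumptions — not that those assumptions hold in any real
cohort.

## Numerical choices and degenerate inputs

* Wald-normal p-values (not likelihood-ratio) keep Z, p and direction
  mutually consistent with the printed tables; direction for $z = 0$ is "+"
  by documented tie-break.
* The logistic fit converges on relative log-likelihood change $<10^{-8}$
  within 50 iterations; non-convergence is an error, separation a flagged
  non-estimable result (detected by SE/estimate magnitude as well as by
  glm's warning, which is not raised reliably).
* Constant terms, term-covariate collinearity and constant scores are
  degenerate-design errors; an aliased *covariate* is recorded as a note on
  an otherwise valid fit, as is an ill-conditioned design matrix.
* ORs printed as 1.00 get SEs only from their CIs, never from p, avoiding
  division by $\ln(1.00) = 0$.
* Fixture transcription checking (`check_fixture_consistency()`) is a
  diagnostic report, not a gate: published rounding puts a few rows of the
  vitamin-D-score-on-T2D table just outside the two-last-digit-units band,
  and one printed meta row (T2D score on 25(OH)D: estimate −0.0002,
  SE 0.0001, Z −0.212) is internally inconsistent — its own cohort rows
  recombine to +0.212 under every scheme considered. The fixture keeps the
  printed values verbatim and `reproduce_table()` shows both.
* Per-SNP 25(OH)D fits default to adjusting for BMI (one results passage
  omits it); the covariate list is an argument, so either convention is one
  call away.

## Problem sizes

Deterministic table recomputation runs in milliseconds. The simulation
checks use cohorts of 50,000 samples and 20 seeds for parameter-recovery
summaries (matching the published per-cohort scale), 100 seeded replicates
for Hardy-Weinberg goodness of fit, 1,000 small-cohort replicates for the
null p-value uniformity check, and reduced cohorts (12,000–30,000 samples,
3–4 seeds) for scenario-verdict recovery, where coverage rather than power
is the assertion — power at the published effect sizes needs the full
~50,000-sample scale that the parameter-recovery checks exercise.

## Worked example

```{r example}
# 1. recompute a published table
rp <- reproduce_table("VITD_SCORE_ON_VITD")
print(rp)

# 2. simulate the concluded world and run the full bidirectional analysis
ch <- simulate_cohort(default_presets("INDEPENDENT", n = 20000, seed = 7))
vd <- build_score(ch$dosages, score_spec("vd", default_instruments("VITD")))
td <- build_score(ch$dosages, score_spec("td", default_instruments("T2D")))

report <- mr_bidirectional(
  forward_exposure = list(composite = fit_linear_vitd(vd, ch)),
  forward_outcome  = list(composite = fit_logistic_t2d(vd, ch)),
  reverse_exposure = list(composite = fit_logistic_t2d(td, ch)),
  reverse_outcome  = list(composite = fit_linear_vitd(
    td, ch, covariates = c("age", "sex", "bmi", "t2d"))))
print(report)
```

## Known limitations

The pipeline analyses summary tables exactly as printed, including their
rounding; pooled-OR recomputation therefore differs from the published
pooled OR in the third digit (1.249 vs 1.24), inside the tolerance that
2–3-significant-digit inputs imply. The exact weighting behind the
published pooled OR CI cannot be recovered (it coincides with the largest
cohort's CI). Strand/allele harmonisation across files, proxy-SNP lookup,
genomic control, meta-regression and two-sample MR against external GWAS
are all out of scope.
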