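---
title: "Two-sample Mendelian randomization with neuromr: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with neuromr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromr)
```

## The problem

Mendelian randomization (MR) uses genetic variants as natural instruments to
ask whether an exposure causes an outcome when randomized trials are
impossible — for instance, whether facets of neuroticism (depressed affect,
worry, sensitivity to environmental stress and adversity) causally raise the
risk of psychiatric disorders such as PTSD. In the *two-sample* design the
SNP–exposure and SNP–outcome associations come from separate,
non-overlapping GWAS, so the entire analysis runs on published summary
statistics: per-SNP effect sizes, standard errors, alleles, frequencies,
p-values and sample sizes.

The design rests on three instrument assumptions: each variant is robustly
associated with the exposure (relevance), shares no confounder with the
outcome (independence), and affects the outcome only through the exposure
(exclusion restriction). The package operationalizes relevance through its
selection filters and probes exclusion through its sensitivity battery;
independence is not testable from summary data and remains an assumption.

## Instrument selection

`build_instruments()` applies, in order:

1. **Association screen.** Strictly `p < 5e-8` (genome-wide significance).
   For mediator traits that would otherwise retain fewer than three
   instruments, the study driver relaxes to `5e-6` — except for traits
   listed in `no_relax` (by default SCZ, which has ample genome-wide
   signal). Strict inequality matters at the boundary and is tested.
2. **LD clumping.** Greedy pruning: rank by ascending p (ties broken by
   `snp_id`, so results are independent of row order), take the best SNP,
   drop every remaining SNP on the same chromosome within ±10,000 kb with
   `r² ≥ 0.001` against it, repeat. SNPs missing from the LD panel are
   treated as uncorrelated with a warning, mirroring reference-panel
   dropout.
3. **Strength filter.** Per-SNP `F = beta²/se²`, keeping `F > 10`
   (strictly). The variance explained is recovered from the one-parameter
   relation `R² = F/(F + N − 2)`, the algebraic inverse of
   `F = R²(N−2)/(1−R²)`; this is the standard identity linking the two and
   is monotone in `F` at fixed `N`, which the tests assert.

## Harmonization

Effects must refer to the same allele in both datasets. Matching pairs are
kept; swapped pairs negate the outcome beta and reflect its allele
frequency; pairs that agree only after A↔T/C↔G complementation are
strand-flipped first. Palindromic SNPs (A/T, C/G) are the hard case: their
strand cannot be read off the alleles, so orientation must come from allele
frequency. The ambiguity band is `(0.42, 0.58)` — the de-facto convention in
two-sample MR tooling; the publication record this package is patterned on
says only "intermediate allele frequencies", so the band is exposed as a
parameter (`c(0, 1)` drops every palindrome). Outside the band, a
palindrome is oriented by whether the two frequencies sit on the same side
of 0.5; inside it, or with a missing frequency, it is dropped. Every
decision is tagged per SNP in a harmonization log, and irreconcilable
allele pairs are dropped loudly, never kept.

## Estimators

With aligned effects \((\hat\beta_{Xj}, \hat\beta_{Yj})\) and weights
\(w_j = 1/\mathrm{se}^2_{Yj}\):

* **IVW (multiplicative random effects)** — the primary estimator. The
  through-origin weighted slope
  \(\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2\), fixed-effect standard error
  \((\sum w_j \hat\beta_{Xj}^2)^{-1/2}\), inflated by
  \(\max(1, \sqrt{Q/(J-1)})\) with \(Q\) Cochran's statistic at the
  estimate. Truncation at 1 means balanced heterogeneity widens the
  interval but underdispersion never narrows it — the conservative
  convention. P-values are two-sided normal. One SNP degrades to the Wald
  ratio \(\hat\beta_Y/\hat\beta_X\).
* **MR-Egger** adds an intercept after orienting every SNP to a
  non-negative exposure effect. The slope is a pleiotropy-robust estimate
  under the InSIDE assumption; an intercept away from zero indicates
  *directional* horizontal pleiotropy. Standard errors are inflated by
  \(\max(1, \hat\sigma)\) and referred to a t distribution with \(J-2\)
  degrees of freedom. The truncation makes the intercept test mildly
  conservative under the null (about 3–5% rejection at nominal 5% in the
  package's own calibration runs) — it never exceeds its nominal level,
  which is the property the sensitivity screen relies on.
* **Weighted median** — the interpolated weighted median of per-SNP Wald
  ratios with inverse-variance weights on the ratio scale (first-order
  ratio SE `se_Y/|beta_X|`; a second-order option adds the exposure term).
  It is consistent while valid instruments carry more than half the
  weight. Its SE comes from a parametric bootstrap with a recorded seed.

Confidence intervals are Wald-normal for IVW and the weighted median and
t-based for Egger. All three are reported per pair by `run_uvmr()`, with a
consistency flag when the betas share a sign.

## Sensitivity battery

`sensitivity_report()` bundles Cochran's Q for both the IVW and Egger fits
(df \(J-1\) and \(J-2\)), the Egger intercept test, leave-one-out IVW
estimates with a sign-stability flag, funnel-plot data (ratio vs precision),
and MR-PRESSO. MR-PRESSO simulates the null distribution of the
inverse-variance-weighted residual sum of squares around leave-one-out IVW
predictions: the global p-value uses the add-one empirical tail (so it is
never exactly zero and is floored at `1/(n_sim+1)`), while the per-SNP
outlier test uses the plain empirical proportion, Bonferroni-multiplied by
the SNP count — with an add-one numerator the smallest attainable adjusted
p would be `J/(n_sim+1)`, which already exceeds 0.05 for typical instrument
counts at moderate `n_sim`, and no outlier could ever be declared. When
outliers are found the IVW estimate is recomputed without them and reported
alongside the uncorrected one; the distortion test is not part of this
battery. `n_sim` defaults to 1000.

## Multiplicity, dismissal, MVMR and mediation

The study driver assigns each exposure–outcome pair a tier: `bonferroni`
when the IVW p-value beats `0.05/m` (with `m` the grid size, e.g.
`0.05/30 ≈ 0.0017` for 3 exposures × 10 outcomes), `nominal` below 0.05,
`null` otherwise — and `dismissed` when MR-PRESSO's global test flags
pleiotropy (p < 0.05) on an otherwise significant pair. The Egger intercept
p is carried as a secondary flag but does not by itself dismiss, since the
global residual test is the battery's designated gatekeeper.

Outcomes with at least two nominally significant exposures get a
multivariable IVW fit: the per-exposure instrument sets are merged (union,
re-clumped jointly with each SNP ranked by its best p across exposures),
harmonized to a common allele across all datasets, and the outcome is
regressed on the SNPs × exposures effect matrix without intercept, weights
`1/se_Y²`, SEs inflated by the same truncated dispersion factor. A
rank-deficient effect matrix (collinear exposures) is a hard error.

Two-step mediation multiplies the exposure→mediator and mediator→outcome
IVW estimates into an indirect effect, with the delta-method SE
\(\sqrt{\hat\beta_{EM}^2 se_{MO}^2 + \hat\beta_{MO}^2 se_{EM}^2}\), and
reports the proportion mediated `indirect/total`. Because that ratio is
skewed when the total effect is imprecise, its interval comes from seeded
Monte-Carlo propagation rather than a second delta step. The direct effect
is reported as `total − indirect`, labelled difference-derived. Step-2
instruments are drawn from the mediator's own summary statistics after
excluding SNPs that already instrument the exposure, so the two steps use
non-overlapping variants; step 2 is univariable IVW (an MVMR-adjusted
variant can be run by hand with `harmonize_multi()` + `mvmr_ivw()`).
Eligibility requires all three links nominally significant and none
dismissed.

## The synthetic-data generator

`generate_dataset()` draws summary statistics with known causal structure
so every stage is testable without external downloads. Per instrument:
allele frequency `p ~ U(0.05, 0.95)`; standard errors from the standard
per-allele form `1/sqrt(2 N p (1−p))` in each (non-overlapping) sample;
true effect magnitude uniform within ±10% of `se_X sqrt(F*−1)` so the
expected instrument F matches the target (default 100, inside the 20–174
range typical of the motivating GWAS) and every planted instrument stays
genome-wide detectable; observed effects drawn around their truth;
horizontal pleiotropy added to a configurable fraction of instruments
(`N(mean, sd²)`, mean 0 balanced, nonzero directional); optional LD blocks
realized as clusters of near-duplicate SNPs with full within-block pairwise
r²; optional palindromic variants with frequencies near 0.5; and, in
mediation scenarios, a mediator with its own instruments plus the induced
`direct + em×mo` total path.

Two generator design choices deserve explanation. First, effects are
*oriented to the exposure-increasing allele* (positive magnitudes), the
convention of standard MR method simulations: every estimator here is
invariant to joint allele re-orientation, but with sign-symmetric true
effects and pleiotropy independent of them, directional pleiotropy would
average out of the IVW numerator and no estimator contrast could be
demonstrated. Second, the magnitude jitter is deliberately narrow (±10%):
a heavy-tailed magnitude distribution leaves a sizeable share of "true"
instruments below the genome-wide screen, breaking the generator's
contract that planted instruments are selectable. Binary outcomes reuse
the same sampling-variance form on the log-odds scale — adequate for
testing the estimators, not a case–control likelihood simulation; winner's
curse and genome-wide LD structure are likewise not modelled, so passing
tests certify the estimators and pipeline logic, not the vagaries of real
GWAS data.

`generate_paper_shaped_study()` assembles a full 3-exposure × 10-outcome
study over a shared SNP universe (40 instruments per exposure, 30 per
mediator, 60 null SNPs by default; exposures n = 350,000, outcomes
n = 200,000), with eight non-null total effects and two planted mediation
chains whose effect sizes are the log odds ratios such studies report
(totals around OR 2.6–2.9 per exposure SD; mediator→outcome links at
OR 1.04 and 1.11). The OR 1.11 chain is comfortably detectable
(z ≈ 6 on step 2); the OR 1.04 chain is as marginal as it is in practice
and may miss the eligibility screen at some seeds — by design.

## Numerical and reproducibility choices

Every stochastic routine (weighted-median bootstrap, MR-PRESSO, mediation
Monte-Carlo, the generators) takes an explicit seed, records it in its
output, and restores the caller's RNG state, so study runs are
byte-reproducible and seeded internals never perturb user-level streams.
Empirical p-values use the add-one rule where a zero p would be
misleading (the MR-PRESSO global test). Ties in clumping break
lexicographically. Degenerate inputs fail loudly: zero exposure effect in
a Wald ratio, fewer than 3 instruments for Egger/weighted median, fewer
than 4 for MR-PRESSO, rank-deficient MVMR matrices, zero total effect in
a mediation proportion.

Default problem sizes in the test and acceptance runs — 1000 replicates
for calibration, 500 for pleiotropy robustness, 200 for MR-PRESSO power
and mediation recovery, MR-PRESSO at 500 simulated datasets there — were
chosen to give stable operating-characteristic estimates (Monte-Carlo
standard errors well under the decision margins) while keeping a full run
in the low tens of seconds on one core.

## Known limitations

Summary statistics only (no individual-level likelihoods); no proxy-SNP
lookup or imputation of missing outcome associations; no Steiger
direction filtering, MR-RAPS, mode-based or contamination-mixture
estimators, MVMR-Egger or conditional F statistics; the MR-PRESSO
distortion test is deliberately omitted. LD handling assumes the supplied
r² table is on the analysis ancestry; computing LD from genotypes is out
of scope.
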