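---
title: "Methods: immune-signature screening and rule-out diagnostics for sepsis in very preterm infants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-signature screening and rule-out diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosepsig)
```

# The problem

Late-onset sepsis — bacterial infection more than 72 hours after birth — is a
leading cause of death in very preterm babies (born before 32 weeks
gestation). Because no bedside test reliably rules sepsis out at the moment a
baby first shows clinical signs, most suspected episodes trigger empirical
antibiotics, and many courses continue even when cultures come back negative.
This package implements, as tested and reusable code, an analysis pipeline
for longitudinal immune-profiling studies of this population:

1. rule-based classification of each blood draw into five clinical
   categories (MCS, ClinSep, NSC, Stable, NEC) and composite
   Sepsis / No-Sepsis groups;
2. a multi-parameter rank-based screen for a cellular immune signature of
   sepsis, with age-bracket, age-strata and CRP-stratified follow-ups and a
   mixed-model confounder adjustment;
3. temporal pre/sepsis/post paired analysis of episode dynamics;
4. evaluation of a combined C-reactive protein (CRP) / amphiregulin (AREG)
   rule-out test, including ROC/Youden threshold selection and
   prevalence-adjusted predictive values; and
5. post-processing of externally produced per-gene differential-expression
   tables (fixed haemoglobin filter, thresholding, multi-condition set
   partition).

Because the per-sample clinical tables of any real cohort are not
redistributable, the package is exercised end to end on a synthetic
longitudinal cohort generator whose defaults encode the study conditions the
pipeline was designed for. The generator is first-class, tested code — not a
throwaway fixture — and every downstream stage is validated against the
ground truth it records.

# The synthetic cohort generator

`cohort_config()` fixes the study conditions; `simulate_cohort()` is fully
deterministic given a configuration (including its seed).

**Cohort shape.** Nineteen babies, gestational age 23–29 weeks, sampled at
weekly intervals with ±2-day jitter, targeting a median of nine draws per
baby. Sepsis episodes arrive as a Poisson process (mean 1.7 per baby,
matching 32 episodes over 19 babies), each microbiologically confirmed with
probability 0.55 and otherwise culture-negative clinical sepsis; unconfirmed
suspicion events (antibiotics stopped within 72 h) arrive at mean 1.2 per
baby, and a baby develops necrotising enterocolitis with probability 0.1.
Every episode contributes a draw at onset (the suspicion draw substitutes
for that week's routine draw, so routine draws within three days of an event
are suppressed and events are kept at least four days apart); 30% of sepsis
episodes contribute a second draw two to three days later sharing the same
episode identifier, which the deduplication stage later removes.

**Immune parameters.** Each sample carries 105 flow-derived parameters.
Baselines are log-normal per parameter (counts, frequencies and median
fluorescence intensities are positive and right-skewed, and positivity
guarantees a well-defined log2 fold change), spanning roughly 20–5000 in
raw units. On the log2 scale each measurement adds: a per-baby random
intercept (SD 0.25 log2 units — repeated draws from one baby are
correlated; no published within-baby correlation structure exists for this
setting, so a random intercept of plausible magnitude is our choice),
a developmental age trend, an episode effect, and multiplicative assay
noise with a 20% coefficient of variation (no noise model is published; a
20% CV is typical of derived flow parameters).

**The planted signature.** Ten named parameters (CD4 and CD8 T-cell counts,
T-cell count and frequency, mDC count and frequency, pDC frequency, and
HLA-DR MFI on DC, classical and intermediate monocytes) are suppressed
2^(-1)-fold at episode onset, recovering linearly to baseline over seven
days — the acute-suppression-with-rebound kinetics of sepsis-induced
immunoparalysis. The remaining 95 parameters carry no episode effect.

**Developmental age trend.** Every parameter rises by 0.5 log2 units from
day 1 and plateaus at `age_plateau_day` (default 15). The plateau sits at
the first 15-day bracket boundary deliberately: with 15-day brackets, a
trend that kept rising to day 30 would make bracket 2 (days 16–30)
straddle the rise, creating a real bracket-2-vs-3 difference; saturating at
the boundary gives the intended structure in which only the first
neighbouring-bracket transition carries a genuine difference, while the
increase is still confined to the first month of life.

**Plasma analytes.** Baseline AREG is log-normal with `meanlog = log(19)`
and `sdlog = log(27.9/14) / (2 qnorm(0.75))`, i.e. the median is exactly
the 19 pg/mL stable-baby reference and the quartiles are the symmetric
log-scale fit to the reference IQR of 14–27.9 pg/mL (they land at
13.5/26.8, within 4%; we prioritise the median, the primary location
statistic, over an exact IQR). At sepsis onset AREG is multiplied by 4
(decaying linearly over the rebound window), so a minority of episodes
remain below typical rule-out thresholds purely through baseline
variability. CRP has a low log-normal baseline (median 2 mg/L) and rises
above 10 mg/L in only 75% of sepsis episodes (`crp_low_fraction = 0.25`,
the reported fraction of culture-proven neonatal infections with CRP at or
below 10 mg/L). Unconfirmed suspicion draws are test-positive at modest
rates (CRP rise 0.25, AREG spike 0.25), which reproduces the realistically
poor specificity of any inflammation-based rule in babies with
non-infectious instability. IL-6 and IL-10 rise with CRP-positive sepsis;
CXCL8, TNF-α and IFN-γ carry no effect.

**What the generator does not emulate.** No raw FCS events, gating,
bead-count calibration or single-cell count matrices; no mechanistic
immunology (effects are phenomenological multiplicative shifts); no
gestational-age dependence of immune traits; no informative missingness
(QC dropout is random at rate 0.02). Passing tests therefore demonstrate
that the pipeline recovers the structures it assumes, at realistic effect
and noise magnitudes — not that those structures exhaust real data.

# Classification rules

`classify_samples()` applies, in precedence order: NEC (Bell stage II/III),
MCS (contemporaneous positive culture), ClinSep (suspicion +
culture-negative + ≥3 clinical criteria for invasive infection + antibiotic
course/intent ≥5 days), NSC (suspicion + culture-negative + antibiotics
stopped within 72 h), Stable (routine draw). Three choices the rules do not
pin down by themselves:

* **Unsupported CoNS isolates.** A coagulase-negative staphylococcus
  culture without supporting clinical evidence does not qualify as MCS; we
  additionally treat the isolate as a contaminant, i.e. the culture as
  effectively negative, so the sample can still satisfy ClinSep or NSC.
* **Contemporaneity** of culture and draw is encoded by the generator
  (positive cultures are only stamped on onset draws), so the classifier
  takes the flag at face value rather than re-deriving it from timestamps.
* **Residual combinations** (suspected, culture-negative, antibiotics
  continued beyond 72 h but ClinSep thresholds unmet) match no rule. In
  strict mode (default) they raise an error naming the rows; with
  `strict = FALSE` they are returned unclassified with a warning. We do not
  silently coerce them into a category.

Group membership is per-sample: a baby septic in week 3 and stable in week
8 legitimately contributes to both composite groups, and
`composite_groups()` reports which babies do.

# Statistical choices

**Effect size.** The volcano fold change is the log2 ratio of group
medians — robust, consistent with median-centric reporting of skewed flow
parameters. A pseudocount (half the smallest positive observed value) is
added only when a median is exactly zero.

**Tests.** Two-group comparisons use the two-sided Mann–Whitney test:
exact when the combined sample is ≤20 and tie-free, otherwise the
tie-corrected normal approximation (average ranks, continuity correction).
Paired comparisons use the Wilcoxon matched-pairs signed-rank test with
zero differences dropped; the exact distribution is used for ≤25 tie-free
non-zero differences, and for small samples with tied absolute differences
(n ≤ 14) the null distribution is enumerated over all 2^n sign assignments
directly. Three-plus-group plasma comparisons use Kruskal–Wallis with
Dunn's post-hoc z-tests (tie-corrected pooled variance; Bonferroni family
correction by default, the classical Dunn procedure). The test suite pins
all of these to independent brute-force oracles (full labeling and sign
enumeration, step-up BH by definition, exhaustive Youden search).

**Multiplicity.** Benjamini–Hochberg step-up control, applied within each
analysis family (one screen, one bracket grid), mirroring per-figure
correction practice. Non-evaluable tests stay `NA` and do not count
towards the family size. Screen significance needs both the adjusted
p-value (<0.01) and the fold-change gate (|log2FC| > 0.6); the DEG
thresholds (<0.05, >0.95) are strict inequalities.

**Confounder adjustment.** `adjust_confounders()` fits a linear
mixed-effects model by REML with a per-baby random intercept, reporting
the sepsis fixed effect with Satterthwaite degrees of freedom. The
contract is the model formula; the optimiser is `lmerTest::lmer`.
Non-convergence is reported, never silently dropped; a single baby is an
explicit error.

**Pairing.** Each deduplicated sepsis sample is matched to the nearest
prior and subsequent sample from the same baby within 14 days ("about one
week" either side, with slack for jittered schedules). Same-episode
samples are never their own neighbours; equidistant candidates (possible
only with same-day duplicates) resolve to the earlier in input order and
are flagged; one sample may serve as post for one episode and pre for the
next, flagged as shared. A parameter is called *sepsis-transient* when
pre-vs-sepsis and sepsis-vs-post are significant while pre-vs-post is not,
each comparison requiring at least five complete pairs.

**Diagnostics.** ROC candidate thresholds are the observed unique values
with strict ">" positivity; the Youden-maximal threshold breaks ties
toward the lowest candidate (maximising sensitivity — the test's purpose
is to rule sepsis *out*). The combined rule is negative iff CRP ≤ 10 mg/L
*and* AREG ≤ 38.7 pg/mL; a missing analyte yields a not-evaluable call,
excluded from the 2×2 with its count reported, never a silent negative.
Confusion metrics are exact fractions; presentation rounds to two
decimals, half away from zero. `adjust_prevalence()` re-expresses PPV/NPV
at an external prior by Bayes' rule and reproduces the count-based values
exactly at the empirical prevalence (an algebraic identity the tests
check on random confusion matrices). The 48-hour window is measured from
the blood culture draw (not antibiotic start), configurable.

# Problem sizes and numerical conventions

The test suite exercises the full 19-baby, 105-parameter cohort across 50
seeds for signature recovery and null control (about a minute of
computation), 60 mixed-model fits for coverage and 100 for size, and
brute-force oracle comparisons at the sizes where enumeration is exact
(Mann–Whitney totals ≤12, signed-rank n ≤12, Youden instances up to 1000
points, BH vectors up to length 200). The acceptance script draws 10^5
baseline AREG values. Unit-level fixtures use a reduced 8-baby,
20-parameter configuration for speed. All tables are UTF-8 delimited text;
every artifact is reproducible from the saved configuration and seed
alone.

# Known limitations

* The generator's episode effects are uniform across affected parameters
  and babies; real signatures vary in magnitude and direction (HLA-DR MFI
  falls, but some acute-phase parameters rise).
* The classifier consumes structured flags; it does not parse clinical
  notes, infer antibiotic intent, or adjudicate disagreements between
  assessors.
* The combined-test evaluation treats the cut-offs as fixed inputs;
  selecting the AREG threshold and evaluating the rule on the same samples
  (as the reference analysis does) is optimistic, and the package makes
  that choice explicit rather than hiding it.
* Exact signed-rank enumeration with ties is limited to n ≤ 14; larger
  tied samples use the normal approximation.
* Sensitivity/specificity confidence intervals are not reported (exact
  binomial intervals could be added; the reference analysis reports point
  estimates only).
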