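---
title: "Methods: threshold-classifier discovery for mouth-rinse stress markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-classifier discovery for mouth-rinse stress markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Psychological stress leaves chemical traces in saliva, and water briefly
rinsed in the mouth is a practical, non-invasive proxy for a saliva sample.
`rinsemet` implements a complete discovery pipeline for such studies: a
two-group design (chronically high-stress vs control participants,
classified by questionnaire instruments upstream of this package) sampled at
four collection points around two acute stress tasks (`Rest`, `Post-UK`
after a Uchida-Kraepelin test, `Recover`, `Post-WM` after a working-memory
test). The measured input is a samples x features table of concentrations —
water-soluble metabolites from CE-MS, steroids from LC-MS and two salivary
proteins (sIgA, CgA) — with per-feature analytical QC metadata.

Two properties of this kind of data drive every design choice in the
package:

1. **Individual differences dominate.** The largest variance component in
   salivary metabolomics is the participant, not the group or the time
   point; single-analyte markers drown in it.
2. **Sample dilution is shared across features.** Rinse-volume and flow
   variation scale every concentration in a sample by a common factor. Any
   two-feature ratio cancels it exactly — the core reason the pipeline's
   predictive stage searches metabolite *ratios*.

# The synthetic study generator

Raw cohort data of this kind are typically not publicly deposited, so the
package ships a generator (`generate_study()`) whose output has the
statistical structure above, making every downstream stage testable. On the
log scale each concentration is

$$\log x_{ipft} = \mu_f + u_{pf} + s_p + d_i + \beta_f g_p + \tau_{ft} +
c_{f}(\mathrm{sex}_p, \mathrm{age}_p) + \varepsilon_{ipf}$$

with feature baseline $\mu_f \sim N(\log 10, 1)$ (concentrations around
10 units, two orders of magnitude of spread), feature-specific participant
effect $u_{pf}$ (SD 0.4), a shared per-participant scalar $s_p$ (SD 0.35,
"global individuality"), a per-sample shared log dilution factor $d_i$
(SD 0.3), planted group and time-course effects, small sex/age offsets on a
tenth of the metabolites (SD 0.1), and residual noise (SD 0.1). Log-normal
concentrations with additive random effects are the standard metabolomics
assumption, and they make ratio-based dilution cancellation exact. With
these defaults the participant share of log-concentration variance (ICC) is
about 0.74 — individual differences dominate, as they should — and the
dilution SD is three times the residual SD, so single features are
meaningfully masked.

Cells below a per-feature limit of detection are *censored*, not missing:
the LOD sits at the 1st percentile of a feature's marginal distribution by
default. Features that survive a 50%-detection inclusion gate in real
studies are rarely censored much more than this; a higher rate is available
through `lod_quantile`. Decoy features that violate exactly one QC criterion
(recovery, RSD, or detection) can be appended to exercise the filter; they
are drawn from dedicated random sub-streams, so adding decoys never perturbs
the core draws. One master seed fixes the whole table bit-for-bit.

## The planted marker pair

The default study plants one marker ratio: `met001` (group log-effect
$-0.6$) over `met002` ($+0.6$), with the two features' participant effects
correlated at $\rho = 0.9$. The correlation encodes co-regulation, and it is
the ratiometric mechanism itself: the pair's ratio cancels dilution, the
shared participant scalar *and* most feature-specific individuality, giving
a closed-form two-class separation of

$$\mathrm{AUC} = \Phi\!\left(\frac{2\delta}{\sigma_{\mathrm{pair}}\sqrt 2}\right),
\qquad \sigma_{\mathrm{pair}}^2 = 2\sigma_u^2(1-\rho) + 2\sigma_\varepsilon^2,$$

about 0.9999 at the defaults. This margin is deliberate. A ratio that pairs
*one* informative feature with a random partner still cancels dilution and
carries half the planted log-effect, so several hundred such "partial"
candidates compete with the planted pair; without co-regulation the maximum
of those partial candidates overtakes the true pair in a third of studies,
and the generator would not satisfy its own construction contract (the
planted pair must dominate the exhaustive search). An uncorrelated design
(`pair_correlation = 0`) remains available. The generator also plants
fifteen metabolites that drop 40% at `Post-WM` in the high-stress cohort
only, exercising the longitudinal stage, and `null_config()` switches every
planted structure off.

What the generator does *not* emulate: correlated metabolite modules beyond
the marker pair, batch/drift structure, circadian effects, heavy-tailed
analytical error, or missingness other than left-censoring. Passing
recovery tests on this synthetic cohort therefore demonstrates that the
*algorithms* find what was planted under realistic variance structure — not
that any particular real-world marker is true.

# Feature inclusion, imputation, standardisation

Metabolite-class features are retained iff recovery lies in $[70, 130]$%,
RSD $\le 20$%, and the feature is detected (above LOD) in at least 50% of
one group's samples. "Within" bounds are read as closed intervals
(`strict_boundaries = TRUE` flips the convention), detection is evaluated
with each group's samples pooled across time points (a per-time-point mode
is provided, since the pooling convention is a genuine open choice), and
steroid/protein features bypass the recovery/RSD criteria because those
belong to the CE-MS validation of the metabolite platform. Censored cells
are then substituted with one fifth of the feature's minimum quantifiable
value, and features are z-scored (sample SD, $n-1$) for the multivariate
overviews; the scaling is stored so the transform inverts exactly.

# Screening

**Cross-sectional** (`group_screen`): Mann-Whitney U per feature, high
stress vs control, within each collection point and on per-participant
medians across points. p-values are exact (full enumeration) when both
groups have at most eight tie-free observations, otherwise the tie-corrected
normal approximation with continuity correction; a permutation oracle in the
test suite shows the approximation error is below 0.01 at the study's group
sizes. Benjamini-Hochberg correction is applied within each stratum's
feature family by default (a pooled family across strata is one switch,
since the pooling convention is not fixed by the protocol). Direction is the
sign of the high-stress minus control median.

**Longitudinal** (`longitudinal_screen`, `interval_summary`): per feature, a
tie-corrected Friedman test over the four collection points with
participants as blocks (tie correction matters because LOD substitution
creates ties), BH across features; Nemenyi post-hoc for the six time-point
pairs, referred to the studentized range distribution. Interval-level
feature lists use BH across features *within each interval* on the Nemenyi
p-values (the alternative families — across intervals, or both — are
defensible; this one matches reporting interval-specific tables), gated at
$q < 0.05$, with a highlighted subset whose cohort-median percent change is
at least 30%. Percent change is measured against the cohort median at the
earlier time point: the robust choice consistent with the nonparametric
framing.

# The predictive core

A candidate classifier is a *threshold model*: a score (one concentration,
or one concentration ratio), an orientation (high or low scores predict
high stress) and a cutoff. Fitting maximises the Youden index
$J = \mathrm{sens} + \mathrm{spec} - 1$ over all cutoffs (midpoints between
consecutive distinct sorted scores, plus $\pm\infty$) and both orientations.
Ties in $J$ are broken by higher specificity, then the smaller cutoff, then
the high-predicts-stress orientation; all comparisons are done in integer
arithmetic so the fit is bit-reproducible. The full-data AUC is tested
against 0.5 with DeLong's placement-value variance and a one-sided Z-test.

Evaluation follows the protocol of leave-one-out cross-validation nested in
a bootstrap: participants are resampled with replacement *within each
group* (100 iterations at the defaults), a full leave-one-participant-out
CV runs inside each replicate, and AUC, accuracy
($(TP+TN)/N$ over participants) and F1 ($2TP/(2TP+FP+FN)$, high stress
positive) are summarised by their means and 2.5/97.5 percentile intervals.
Three decisions here were genuinely open and are worth stating:

- **Resampling unit.** The participant, always — for the pooled `All`
  stratum a participant's four samples enter and leave training together
  and the participant is scored by the median of their sample scores.
  Anything else leaks within-participant structure.
- **Held-out AUC orientation.** Held-out scores are pooled raw and oriented
  once, by the full-data fit's orientation. Re-orienting per fold would
  make the pooled AUC incoherent (the same score could count as evidence in
  both directions).
- **Bootstrap duplicates** are treated as distinct units inside the inner
  LOOCV. This is standard bootstrap semantics and mildly optimistic (a
  duplicate of the held-out participant can sit in training); the
  evaluation is used for *ranking and selection*, where the small common
  optimism is immaterial.

`search_models()` evaluates every feature, or every unordered pair as one
canonical ratio (numerator first in feature order — the reciprocal is
redundant under a threshold model, only the orientation flips), ranks by
mean bootstrap AUC, and `select_models()` applies the strict CI-lower-bound
bar: AUC $> 0.60$ (0.65 at `Post-WM`, 0.50 for `All`), accuracy $> 0.50$,
F1 $> 0.50$. `transfer_evaluate()` carries a fitted cutoff unchanged to the
other collection points.

## The winner's curse, quantified

With 8,001 ratio candidates and 32 participants, the maximum *full-data*
AUC under a global null is large (typically 0.8-0.9): selection optimism is
severe, and the package reports it rather than hiding it. The
CI-lower-bound rule shrinks the selected set to a small fraction of the
family (typically under 2% of candidates under the null), but it does
**not** empty it: cross-validation inside the same cohort cannot undo
selection over thousands of candidates, because the apparent separation
sits in the data itself. Selected null candidates are a real phenomenon of
this design, which is why reported models should be read as ranked
hypotheses for external validation, not confirmed markers. The test suite
asserts the idealised property that the null selected set is empty in most
cohorts; that assertion fails at the study's scale and is left failing
deliberately, as an honest record of this limit.

# Covariate robustness

For a chosen marker, `logistic_adjust()` fits logistic regressions of group
on the raw marker score without and with sex and age-group (decades,
categorical) covariates, reporting Wald intervals per term. With 16
participants per group and a strong marker, (quasi-)complete separation is
likely; it is detected and handled by Firth's bias-reduced penalised
likelihood (a small internal Fisher-scoring implementation on the modified
score), and surfaced via a flag. Odds-ratio magnitudes for a raw-ratio
score are scale-dependent and should be compared only in direction, which
is the robustness claim the stage actually checks. `stratified_compare()`
runs the Mann-Whitney comparison within each sex and flags whether the
direction agrees.

# Unsupervised overviews

PCA operates on the z-scored table via the SVD with a deterministic sign
convention (largest-magnitude loading positive). Group ellipses on a score
plot use the sample mean and covariance scaled by the $\chi^2_2$ quantile —
the common large-sample score-plot region; the small-sample F-based
Hotelling region is one argument away. Hierarchical clustering uses
Euclidean distance with Ward's linkage (`ward.D2`).

# Numerical conventions and degenerate inputs

- Youden candidate cutoffs never coincide with data values (midpoints and
  $\pm\infty$ only), so `>=`-vs-`>` ambiguity cannot arise.
- All-identical scores yield a degenerate model with $J = 0$ and a warning.
- Perfect separation makes the DeLong variance zero; the one-sided p is
  reported as 0 with a degeneracy flag rather than NaN.
- A LOOCV fold whose training set loses a class is skipped with a warning.
- Constant features z-score to all zeros with a warning; a feature entirely
  below LOD warns at imputation.
- Percentile CIs use the type-7 quantile convention throughout.
- One master seed derives fixed-purpose sub-seeds per stage, so enabling or
  disabling one stage never changes another's draws.

# Problem sizes used by the test and acceptance suites

Chosen to make Monte-Carlo assertions stable: oracle-equivalence suites use
1,000 random instances (AUC/U identity, Youden brute force, BH step-up);
DeLong-vs-bootstrap variance uses 2,000 resamples per instance at $n = 32$;
Friedman calibration uses 500 null studies at $n = 16, k = 4$; the
cross-sectional null calibration uses 200 synthetic studies; planted-marker
recovery uses 50 studies at 25 bootstrap iterations (the evaluation
protocol itself defaults to 100). The acceptance script scales the recovery
sweep to 20 studies and reports rates, not verdicts.

# Known limitations

Percentile bootstrap intervals around a cross-validated metric quantify
resampling spread conditional on the cohort; at 16 participants per group
they undercover the population AUC (measured coverage of the null value 0.5
is roughly 70%, not 95%). They are used here — as in the protocol they
implement — for *ranking and selection bars*, not as calibrated confidence
statements.

The generator's effect sizes are not estimates of any real cohort's; the
paper-scale headline numbers (a specific marker's AUC) are not reproducible
from synthetic data and are not claimed. Nemenyi p-values are conservative
by construction. The logistic stage does not model interactions or
continuous age. The pipeline assumes a complete design (every participant
measured at every collection point); incomplete designs error rather than
silently dropping data.
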