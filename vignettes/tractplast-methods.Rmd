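---
title: "Detecting behaviorally relevant white-matter plasticity from along-tract qMRI profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting behaviorally relevant white-matter plasticity from along-tract qMRI profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractplast)
```

## The problem

Motor learning reshapes white matter, but single MRI contrasts are poorly
specific to the underlying tissue processes (myelin, neurites, glia, iron,
water). `tractplast` implements a multivariate along-tract analysis for
longitudinal multi-contrast quantitative MRI (qMRI): tract profiles of eight
metrics — NODDI volume fractions (FISO, FICVF) and orientation dispersion
(ODI), multi-parameter-mapping MT, R1, R2\* and PD, and the aggregate
g-ratio — observed at three sessions in a within-subject design with a
no-intervention control interval (session 1 to 2) followed by a training
interval (session 2 to 3). The package asks, per tract segment: did the
metric profile change multivariately after training but not during the
control interval, and does the size of that latent change track each
subject's learning?

The package consumes precomputed tract profiles (long tables keyed by
subject, session, tract, segment, metric). Tractography, registration and
map fitting are upstream concerns.

## Segment-wise multivariate longitudinal model (RM-ASCA+)

For one tract segment, each metric is z-scored over all (subject, session)
observations and modeled by a linear mixed model

\[ \text{outcome} \sim \text{time} + (1 \mid \text{ID}), \]

with the baseline session as reference and a subject random intercept. The
fixed time effects of all metrics form an observations-by-metrics *effect
matrix* (baseline rows are zero under reference coding), which is decomposed
by singular value decomposition **without further centering**, so the origin
anchors the baseline and component scores read directly as change
trajectories. PC1 scores per session summarize the dominant multivariate
trajectory; unit-norm loadings say which metrics carry it. On balanced
complete data the mixed-model fixed effects equal session-mean differences
exactly (generalized least squares coincides with ordinary least squares),
and `fit_segment_asca()` uses that closed form; unbalanced data fall back to
`lme4`. The equality is itself a test in the suite.

Two conventions resolve the inherent sign/rotation arbitrariness: each
component's largest-magnitude loading is made positive, and every bootstrap
replicate is sign-aligned to the point estimate by loading dot product.

### Uncertainty: cluster bootstrap with BCa intervals

`bootstrap_asca()` resamples subjects with replacement (B = 1000 for
reporting) and reruns the *entire* pipeline — standardization, model,
decomposition — per replicate, so intervals reflect all estimated
quantities. Intervals are bias-corrected and accelerated (BCa), with the
acceleration constant from a leave-one-subject-out jackknife. A segment is
called *plastic* when the baseline and control-session score intervals
overlap (stable control period) while the post-training interval overlaps
neither.

Because the baseline is anchored at the origin, its interval is degenerate
at zero; the post-training comparison against baseline therefore reduces to
"does the session-3 interval exclude zero". The suite calibrates this rule
two ways: on null cohorts the plastic rate over 100 bootstrapped segment
fits is at most 1% (observed: 0), and on cohorts with a known injected
effect the BCa intervals cover the analytically derived population session
scores at close to the nominal rate over 200 replicate cohorts at B = 400
(the suite asserts 95% ± 4% over all session scores; control-session
intervals run conservative while the post-training score — a norm-like PCA
projection — is covered slightly below nominal).

### Individual scores and the behavior link

`predict_subject_scores()` projects each subject's standardized metric
vector onto the PC1 loadings. Predicted scores are grand-mean anchored while
the model trajectory is baseline-anchored; the offset cancels in the
interval changes the analysis uses (session 3 minus 1, session 3 minus 2).
Neighboring plastic segments whose loading vectors agree (absolute cosine at
least 0.9) are averaged into one section and refitted
(`merge_adjacent_segments()`), emphasizing spatially consistent effects.

Spearman correlations between each interval's change score and the
learning exponent are pooled by the first-order Olkin–Pratt correction
\(G_i = r_i\,(1 + (1 - r_i^2)/(2(n_i - 3)))\) with fixed-effect weights
\(w_i = n_i\); the pooled variance is
\(V = \sum w_i^2 v_i / (\sum w_i)^2\) with \(v_i = (1 - G^2)^2/(n_i - 1)\),
giving normal-approximation intervals and one-sided p-values in the
direction hypothesized from the group trajectory (set before computing p).
This exact variance rule reproduces, to the printed two decimals, the
published interval bounds for pooled estimates of −0.38 and −0.31 at
n = (24, 24) — an acceptance test. Two caveats are worth stating plainly:
evaluating \(1 - G^2\) at the observed estimate makes the interval
moderately anti-conservative at n = 24 (the suite pins observed coverage
for two independent correlations inside [0.88, 0.97] rather than the
nominal 95%), and the two intervals share the post-training session, which
lowers coverage further (roughly 80% when the intervals are fully
dependent). The pooling is applied as published, with the caveats
documented rather than repaired.

## Motor learning quantification

Per subject, within-session mean balance times over eight training sessions
are fitted with a power law \(y = a\,s^{b}\) by nonlinear least squares,
initialized from the log–log linear fit (deterministic given the data; the
two agree exactly on noise-free data). An optional three-parameter form
\(c + a\,s^b\) is available. The group-level test is a one-sample t test of
the exponents against zero with df = n − 1; the one-sided p (improvement
direction) and the two-sided p are both reported, since the published
phrasing ("greater than zero") implies but does not state sidedness.

## Aggregate g-ratio calibration

With myelin volume fraction \(\mathrm{MVF} = \alpha\,\mathrm{MT}\) and
axonal volume fraction
\(\mathrm{AVF} = (1 - \mathrm{MVF})(1 - \mathrm{FISO})\,\mathrm{FICVF}\),
the aggregate g-ratio is

\[ g = \sqrt{1 - \mathrm{MVF}/\mathrm{FVF}}
     = \sqrt{\mathrm{AVF}/(\mathrm{MVF} + \mathrm{AVF})},
   \qquad \mathrm{FVF} = \mathrm{MVF} + \mathrm{AVF}. \]

A published variant of this expression omits MVF from the fiber-volume
denominator (equivalent to \(\sqrt{1 - \mathrm{MVF}/\mathrm{AVF}}\)), which
is inconsistent with the left identity; `compute_g(literal = TRUE)`
evaluates it for comparability, but the default is the standard form above,
which also lands the calibration at the expected cohort scale
(\(\alpha \approx 0.103\) at splenium means MT = 3.5, FICVF = 0.6,
FISO = 0.1 — matching the published cohort median of 0.10). Calibration is
closed-form: with \(A_0 = (1 - \mathrm{FISO})\,\mathrm{FICVF}\) and
reference \(g^\*\) (default 0.70, electron-microscopy anchored),
\(m = A_0 (1 - g^{*2})/(A_0(1 - g^{*2}) + g^{*2})\) and
\(\alpha = m/\mathrm{MT}\); the round trip is exact to machine precision.
The cohort factor is the **median** of per-subject values. Invalid voxels
(\(\alpha\,\mathrm{MT} \ge 1\), zero fiber volume) become `NA`, never
clamped values. `sensitivity_scan()` recalibrates over a reference grid
(default 0.68–0.72) and confirms near-perfect correlations between the
resulting maps.

## Monte Carlo multiplicity null

p-value-based corrections are unavailable for the interval-overlap rule, so
familywise error is assessed by simulation: each of 2,320 segments (29
tracts × 80 retained segments) receives four equicorrelated standard-normal
z-scores (one-factor construction, pairwise ρ = 0.5, unit marginals); the
least extreme z is retained — all four criteria must hold simultaneously —
and counted against |z| > 1.96. The p-value is the share of 10,000
iterations with at least the observed nine false positives, with no
continuity correction. Treating the control-interval *non*-significance
requirement as a fourth significance criterion is deliberate and
conservative, and is modeled as stated. An independent semi-analytic oracle
(per-segment pass probability by 1-D integration over the shared factor,
then an exact binomial tail; the spec's Poisson approximation is replaced
by the exact binomial since segments are independent) agrees with the
simulation and both land at p ≈ 0.01.

## Network-level stage

The subjects-by-sections matrix of latent change scores (default interval:
session 3 minus session 2, the training interval; configurable to 3 minus
1 — the source is ambiguous on this point) enters an unrotated PCA on the
correlation matrix, with loadings reported as component–variable
correlations and signs fixed so the mean loading is positive. Factorability
is screened by KMO from anti-image partial correlations, Bartlett's
sphericity test, and the determinant of the correlation matrix against
1e-5; component retention uses Horn's parallel analysis (mean criterion by
default; note that on pure noise the sequential mean-criterion count can
retain more than one component by chance — the stricter 95th-percentile
criterion rarely does, and both are available).

Cortical neurite-dispersion change is regressed on the latent score by MM
estimation (S-start, bisquare M-step at 95% Gaussian efficiency,
c = 4.685), with case-resampling bootstrap BCa intervals for coefficients.
Model significance uses a robust deviance comparison against the
intercept-only fit: with \(D = \sum \rho_c(r_i/s)\) at the full-model MM
scale \(s\), the pseudo-F is \(((D_0 - D_1)/q)\,/\,(D_1/(n - q - 1))\) and
the robust \(R^2 = 1 - D_1/D_0\). Published \(R^2\) values are
data-dependent and are not reproduction targets; this deviance-based
definition is the package's documented choice. A condition number of the
predictor matrix is always reported, and for collinear multiple-predictor
models the omnibus test, not individual coefficients, is the headline.
Exactly collinear (zero-residual) data short-circuit before the
S-estimator, which cannot subsample them, and return the degenerate report
(R² = 1, infinite pseudo-F). LOOCV refits the model leaving each subject
out and reports MSE, RMSE and \(1 - SSE_\text{model}/SSE_\text{null}\)
against per-fold training-mean predictions; negative ratios flag
overfitting.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults encode the study conditions: 24 subjects, three
sessions four weeks apart, 29 motor-network bundles × 98 segments, eight
metrics with plausible white-matter baselines, and five localized effect
templates (a free-water-driven decrease in the right anterior thalamic
radiation; g-ratio-driven decreases in right frontopontine,
thalamo-premotor and corticospinal sections; an R2*/PD increase in an
inferior left corticospinal section). Values are generated as
baseline + scale × (subject intercept + effect + AR(1) noise along
segments), with:

- `sigma_subject = 1.0`, `sigma_resid = 0.4` z-units: between-subject
  differences dominate session-to-session noise, reflecting the high
  test–retest reliability of qMRI metrics (intraclass correlation near
  0.85);
- `ar_phi = 0.7`: tract profiles are spatially smooth;
- effect magnitude 0.8 z at the post-training session with subject SD
  0.4, and a zero control-interval effect (the stable-control design);
- learning exponents coupled to the subjects' latent effect magnitudes by
  a Gaussian copula (the normal-score correlation \(2\sin(\pi\rho_s/6)\)
  hits a target Spearman exactly in population). The default target is
  **−0.5**: with negative-going group effects, stronger learners show
  larger (more negative) change, so pooled brain-behavior correlations
  carry the sign of the group trajectory, as the expected-direction
  convention requires. Power-law scales of ~10 s, exponents ~0.3 with
  ~35% log-scale spread, and 1.5-s trial noise give group exponent tests
  in the published t ≈ 14 regime;
- cortical change `odi_change = −1.82 × magnitude + N(0, 1.5)`, a slope
  echoing the published cross-tissue regression and noise giving a
  moderate R².

One master seed derives per-component child seeds deterministically, so
panels, behavior and cortical responses are individually and jointly
reproducible.

The generator makes no attempt to emulate voxel-level imaging physics,
tractography failure modes, registration error, spatially varying
reliability, or non-Gaussian artifacts. Passing tests on synthetic cohorts
therefore demonstrate statistical correctness and calibration of the
pipeline under its own assumptions — not robustness to the full messiness
of real acquisitions.

## Numerical choices and degenerate inputs

- Trimming 98 → 80 segments is centered (drop 9 per side, keeping
  segments 10–89); asymmetric trims are refused, and only "middle 80" is
  fixed by the source, so other centered windows are configurable.
- Zero-variance metrics are excluded from standardization with a warning;
  inside bootstrap replicates they contribute zero signal instead, keeping
  replicate dimensions aligned.
- Bootstrap replicates that fail to fit are dropped and counted; more than
  10% failures is a hard error.
- BCa bias proportions are clamped away from 0/1; degenerate bootstrap
  distributions collapse the interval to the point value.
- Spearman requires n ≥ 4 and positive variance; pooling requires
  n > 4 per correlation and passes |r| = 1 through with a flag.
- Singular mixed-model fits (subject variance at the zero boundary) are
  flagged, not errors.

## Problem sizes in the test suite

Simulation-based tests use one-tract cohorts of 24 subjects with 2–4
metrics so that the full suite (including 200 replicate-cohort coverage
calibration at B = 400, 100 null-cohort segment bootstraps at B = 300, and
the 10,000-iteration Monte Carlo null) completes in roughly seven minutes
on one core. These sizes are the package's calibration choices; the
reported properties are stable well below them.

## Known limitations

- The pooled-correlation interval inherits the anti-conservativeness
  discussed above; treat one-sided p-values near the threshold with care.
- The baseline-anchored decomposition makes the session-1 interval
  degenerate; studies wanting uncertainty on the baseline itself should
  augment the effect matrix with the intercept, which this package
  deliberately does not do.
- PC2 and beyond are reported descriptively; no inference is offered for
  them.
- The mixed model contains time only — no covariates or interactions.
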