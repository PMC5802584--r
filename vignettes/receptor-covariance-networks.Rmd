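---
title: "Receptor covariance networks from regional PET binding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor covariance networks from regional PET binding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcovnet)
```

petcovnet implements the statistical core of a two-group regional PET
neuroreceptor study — the kind of design that compares receptor availability
between a patient group and matched controls, region by region, and then asks
whether the *covariance structure* of regional binding differs between the
groups. This vignette explains the models and procedures, the parameters that
matter, what the synthetic cohort generator does and does not emulate, and the
design choices made where the methodology was genuinely open.

## Equilibrium DVR quantification

Under a bolus/infusion tracer administration, tissue activity reaches a flat
plateau once infusion balances clearance. At that equilibrium the distribution
volume ratio (DVR) of a target region reduces to a ratio of steady-state
activity concentrations:

$$\mathrm{DVR}_{\text{region}} =
\frac{\bar{C}_{\text{region}}(t \in W)}{\bar{C}_{\text{ref}}(t \in W)},$$

where $W$ is the late equilibrium window (default 45–60 min) and the
reference is a region assumed devoid of specific binding (default
cerebellum). `equilibrium_dvr()` implements this with two declared
conventions, since framing conventions are not standardised:

* **Frame inclusion**: a frame belongs to the window iff its *midpoint* lies
  in $[start, end)$. The half-open rule makes boundary-straddling frames
  unambiguous.
* **Duration weighting**: in-window frame activities are averaged weighted by
  frame duration, which matches integrating activity over the window when
  frames have unequal lengths. For equal-length frames it coincides with the
  plain mean.

Equilibrium is *assumed*, never enforced: `check_equilibrium()` reports the
OLS slope of activity against frame midpoint within the window, relative to
the mean in-window activity (units: fraction per minute; default tolerance
0.005/min), and flags drifting curves without altering any DVR. Cells with
fewer than two in-window frames are marked indeterminate rather than failing,
mirroring how a quality-control step should degrade.

## Per-region group comparison

`welch_test()` is the package's own implementation of Welch's unequal-variance
t test with Welch–Satterthwaite degrees of freedom. It accepts raw samples or
summary statistics (mean, SD, n) interchangeably — the two paths are
algebraically identical, which lets printed summary tables from the literature
be re-tested without raw data.

`ancova_region()` fits $\mathrm{DVR} \sim \text{group} + \text{covariates}$ by
least squares and tests the group factor by partial F (model comparison
against the group-dropped model), with the SPSS-style effect size
$\eta_p^2 = SS_{\text{group}} / (SS_{\text{group}} + SS_{\text{resid}})$.
With no covariates this is one-way ANOVA and $F = t^2$ of the pooled t test —
an identity the test suite checks numerically.

`compare_all_regions()` always reports **both arms** — covariate-adjusted and
unadjusted — side by side. Published per-region tables in this design family
sometimes print F statistics whose degrees of freedom are consistent with a
plain ANOVA even when the narrative describes covariates; emitting both arms,
clearly labelled, avoids guessing which model produced a given printed value.
P-values are uncorrected by default (matching common practice in this
literature), with Benjamini–Hochberg and Bonferroni columns behind a flag.

`mancova()` is deliberately honest about its own limits: with $R$ regions as
dependent variables the multivariate test requires residual degrees of
freedom greater than $R$, so a 36-region design with 28 subjects is singular
by construction. The function raises an explicit error recommending
dimension reduction instead of silently producing a degenerate statistic;
with one region it collapses to the univariate F.

`normality_screen()` applies Shapiro–Wilk per (group, region) cell at an
uncorrected 0.05 threshold — an explorative screen, reported rather than used
to gate anything, consistent with how such checks are used in practice.

## The three-step correlation-network comparison

The central procedure treats the across-subject correlation structure of
regional binding as a *receptor covariance network* and compares it between
groups in three steps:

1. **Per-group Pearson matrices** (`corr_matrix()`): for $R = 36$ regions,
   $R(R-1)/2 = 630$ unique inter-regional correlations per group.
2. **Global comparison** (`global_comparison()`): the 630 values per group
   are Fisher z-transformed ($z = \operatorname{atanh} r$) and compared with
   Welch's t test (a raw-correlation arm is available as a sensitivity
   analysis). The statistic is oriented controls − patients, so globally
   stronger patient coupling appears as $t < 0$.
3. **Per-pair tests** (`compare_all_pairs()`): each unique pair is tested
   with the independent-groups Fisher z statistic
   $(z_1 - z_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}$ at a one-tailed,
   uncorrected threshold of $p < 0.001$, plus the entrywise difference map
   $r_{\text{controls}} - r_{\text{patients}}$ for visualisation
   (`difference_map()`, `render_heatmap()`; red = stronger in controls,
   blue = stronger in patients).

Two caveats are inherent to the procedure and deliberately preserved:

* The global Welch test treats 630 mutually dependent correlations (they
  share subjects and regions) as independent observations. The test is
  reproduced faithfully because it is part of the procedure being
  implemented, and `simulate_null()` exists precisely to quantify what that
  assumption does to its operating characteristics — under the null the
  empirical SD of the global t is an order of magnitude larger than 1, so
  its nominal p-values should be read as descriptive. `permutation_global()`
  provides a label-permutation alternative whose validity does not rest on
  the independence assumption.
* The one-tailed direction of the per-pair test is configurable and recorded
  in the output (`attr(x, "tail")`). The default alternative is
  patients-greater, the direction of the coupling findings this design
  family reports; leaving the direction implicit invites silent sign errors.

### What the null simulation shows — including a known miscalibration

`simulate_null()` draws both groups from the *control* configuration
(identical means, SDs and baseline correlation; coupling overrides stripped —
the minimal faithful null), runs the full three-step procedure on each of $K$
cohorts, and reports the per-pair flag rate with the exact binomial 99%
interval for the flag count at the nominal level.

At the study's own sample size this exposes a real, if small, miscalibration
of the per-pair test: the normal reference distribution for
$(z_1 - z_2)/\sqrt{2/(n-3)}$ has lighter tails than the statistic's actual
distribution at $n = 14$. Monte-Carlo on isolated bivariate-normal pairs
($\rho = 0.5$) puts the true one-tailed rejection rate at the 0.001 level
near 0.0012–0.0013 — roughly a 25% relative inflation, i.e. about 0.16
spurious flags per 630 pairs in absolute terms. Consequently the aggregated
flag count over many null cohorts typically falls *above* the exact binomial
interval around 0.001, and the package's own strictest calibration test is
expected to fail for most seeds. We report this as a property of the
procedure at small n rather than "fixing" it, because the test's definition
(variance $1/(n-3)$, normal reference) is the field-standard one; users who
need exact finite-sample control should prefer `permutation_global()` or a
per-pair permutation approach.

## The synthetic cohort generator

`make_default_config()` encodes the study conditions the pipeline is designed
around: two groups of 14; 36 Hammers-style regions in which the ten
temporal-lobe structures carry published group means and SDs (amygdala
1.91 ± 0.20 in patients vs 1.69 ± 0.14 in controls, etc.) and the remaining
26 regions default to 1.80 ± 0.15 in both groups; a baseline inter-regional
correlation of 0.5; patient-specific anterior-cingulate couplings to the
middle and posterior orbitofrontal cortex and the straight gyrus (0.85 vs
0.10 in controls); clinical scores with published group moments; and a
−0.8 target correlation between patient amygdala DVR and the AASE craving
subscores.

Defaults that are free choices, made once and documented here:

* **base_corr = 0.5.** Only the qualitative fact of a globally positive
  correlation pattern is available; 0.5 is a mid-range value typical of
  reported structural/receptor covariance matrices and keeps the implied
  matrices comfortably positive definite before coupling injection.
* **AASE items on a 1–5 scale**, generated as continuous ratings within the
  scale range (patients: item mean 2.4, SD 0.8). Continuous items keep the
  injected subscore–DVR correlation exact; integer Likert rounding would
  attenuate it by a few percent without changing anything the pipeline
  tests. The scale range is configurable.
* **Control AUDIT mean 2 (SD 1.5)** — healthy-range screening scores, since
  only the patient-group value is published.
* **Medication, dose and relapse structure** are injected by *conditioning
  on* the drawn DVRs rather than shifting them: antidepressant use is
  assigned with probability decreasing in standardised amygdala DVR
  (log-odds −1.5 per SD around a rate of 0.5), imipramine equivalents are
  drawn as a floored normal (139.4 ± 97.8 mg) for medicated patients, and
  relapse probability (base rate 8/14) increases with the standardised dose
  (log-odds +0.8). Conditioning keeps the configured DVR moments exactly
  intact — an additive "medication effect" on DVR would corrupt the
  generator's calibration contract.

### Coupling injection and positive definiteness

Setting three ACC couplings to 0.85 (patients) or 0.10 (controls) on top of a
0.5 equicorrelation base makes both matrices indefinite (smallest eigenvalues
≈ −0.10 and −0.12). A one-shot eigenvalue-clip followed by re-normalisation
to unit diagonal would repair definiteness but drag the coupled entries to
≈ 0.79 and ≈ 0.13 — violating the generator's contract that configured
couplings are recovered within ±0.02 at large n. The generator therefore uses
**alternating projections** between the PSD cone (eigenvalues clipped at
1e−8) and the affine set {unit diagonal, coupled entries fixed at their
targets}. Both sets are convex and their intersection is non-empty for the
default targets, so the iteration converges; the coupled entries are honoured
*exactly* and only uncoupled baseline entries drift (by up to ≈ 0.06 in rows
adjacent to the coupled star). When the targets are jointly infeasible (no
correlation matrix exists with those fixed entries) the iteration fails to
reach the intersection and configuration validation raises an error naming
the group and pairs.

Other generator mechanics: DVR vectors are multivariate normal
(`MASS::mvrnorm`); any subject vector containing a non-positive DVR is
rejected and redrawn with a warning (vanishingly rare at realistic SDs, so
configured moments are preserved); clinical scores are inverse-CDF truncated
normals at their legal floors (truncation slightly inflates means relative to
the configured location when the floor is within ~1 SD — accepted, since the
floor is a hard validity constraint).

Synthetic TACs (`generate_tacs()`) emulate only what quantification needs:
an exponential-approach rise reaching an *exact* plateau at 40 min, target
plateaus equal to `ref_level ×` the subject's DVR, frame values at frame
midpoints, and multiplicative Gaussian frame noise. They do not emulate
bolus overshoot, decay correction, motion, scatter, or regionally varying
kinetics — so the noiseless round-trip test (generator → TACs →
`equilibrium_dvr()` → exact recovery) validates the quantification
arithmetic, not PET physics.

### What passing tests do and do not show

The generator produces multivariate-normal DVRs with exactly the configured
first and second moments and clean equilibrium TACs. Real regional PET data
have skewed cells (the normality screen exists for a reason), atlas
segmentation error, partial-volume effects and kinetic deviations from
equilibrium. Tests passing on synthetic cohorts therefore demonstrate that
the *statistical machinery* is correct and calibrated under its stated
assumptions — not that those assumptions hold for any particular scanner,
tracer or cohort.

## Numerical choices and degenerate inputs

* Fisher z at $|r| = 1$ (duplicated or anti-duplicated regions): clamped to
  $\pm(1 - 10^{-12})$ with a warning rather than returning ±Inf.
* Welch test with both SDs zero: error ("degenerate samples") — the df is
  undefined. One SD zero is allowed.
* Correlation matrices require ≥ 4 subjects per group ($n - 3 > 0$) and
  nonzero variance in every region; violations error with the region named.
* Pair ordering is lexicographic by region-set index everywhere; ranking
  ties inherit this order, so outputs are deterministic.
* Spearman p-values use the t approximation on mid-ranks at the typical
  n ≈ 14; an exact-distribution arm (`exact = TRUE`) exists for n ≤ 10
  without ties.
* Permutation p-values use the add-one estimator $(1 + \#\{|t_b| \ge
  |t_{obs}|\})/(B + 1)$, which cannot return 0 and is valid at finite B.
* All randomised functions take an explicit seed and restore the caller's
  RNG state; identical (config, seed) pairs produce byte-identical CSV
  output.

## Problem sizes used in the shipped checks

The package's own test suite exercises the generator-recovery contracts at
n = 10,000 per group (moments within ±0.01, couplings within ±0.02), the
craving association at n = 5,000 patients (±0.05), the null calibration at
K = 500 cohorts of 14 + 14 (315,000 pair tests), and the coupling-detection
power claim over 100 seeds at the study's own n = 14 per group. These sizes
make the Monte-Carlo standard errors comfortably smaller than the asserted
tolerances while keeping a full run in the tens of seconds.

## Known limitations

* No kinetic modelling: DVR is a pure equilibrium ratio; data that never
  reach equilibrium are flagged, not corrected.
* No dependent-correlation tests (overlapping-variable comparisons); only
  the independent-groups case is implemented.
* No graph-theoretic network summaries (hubs, modularity); the unit of
  inference is the region pair and the global pooled comparison.
* The MANCOVA front-end cannot overcome a singular design; it refuses.
* The per-pair Fisher z test's mild tail inflation at n = 14 (above) is
  inherent to the normal approximation; the permutation alternative is the
  remedy offered.
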