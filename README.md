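# petcovnet

Receptor covariance network analysis for two-group regional PET binding
studies.

## The problem

PET neuroreceptor studies of psychiatric and addiction disorders typically
compare a patient group against matched controls on regional tracer binding —
for example, metabotropic glutamate receptor 5 (mGluR5) availability in
recently abstinent alcohol use disorder versus healthy non-smokers, two
groups of 14 male subjects each. Beyond per-region mean differences, such
studies increasingly ask whether the *covariance structure* of binding across
regions differs between groups: across-subject inter-regional correlations of
binding form a "receptor covariance network", analogous to structural
covariance in morphometry.

petcovnet implements that full analysis chain as tested, reusable R
functions, for analysts who work at the regional level (after atlas
segmentation, which is out of scope):

1. **Quantification.** With a bolus/infusion protocol, tissue activity
   plateaus and the distribution volume ratio reduces to an activity ratio:
   DVR = C̄_region(45–60 min) / C̄_cerebellum(45–60 min), computed from
   time-activity curves with duration-weighted in-window frame means and an
   equilibrium diagnostic (`equilibrium_dvr()`, `check_equilibrium()`).
2. **Per-region comparison.** Welch's t (t = (m₁−m₂)/√(s₁²/n₁+s₂²/n₂),
   Welch–Satterthwaite df), covariate-adjusted GLM per region with partial F
   and SPSS-style partial η², a MANCOVA front-end, and a Shapiro–Wilk screen
   (`welch_test()`, `ancova_region()`, `compare_all_regions()`, `mancova()`,
   `normality_screen()`).
3. **Network comparison**, the three-step procedure: per-group Pearson
   matrices over all R(R−1)/2 = 630 unique region pairs; a global Welch test
   on the Fisher z-transformed (z = atanh r) correlation sets; per-pair
   independent-groups Fisher z tests, (z₁−z₂)/√(1/(n₁−3)+1/(n₂−3)), at a
   one-tailed p < 0.001 uncorrected threshold; and the r_controls −
   r_patients difference map with heatmap rendering (`corr_matrix()`,
   `global_comparison()`, `compare_all_pairs()`, `difference_map()`).
4. **Calibration.** A null-simulation harness measuring the procedure's
   actual type-I behaviour, plus a label-permutation alternative to the
   (dependence-ignoring) global test (`simulate_null()`,
   `permutation_global()`).
5. **Clinical layer.** AASE craving subscores (reward = items 4, 8, 15, 17,
   20; relief = items 3, 6, 12, 16, 18), region–clinical correlations
   (Pearson/Spearman), imipramine dose equivalents, and subgroup Welch
   comparisons (`aase_scores()`, `correlate_region_clinical()`,
   `imipramine_equivalent()`, `subgroup_welch()`).
6. **Synthetic cohorts.** A generator calibrated to the published summary
   statistics (amygdala DVR 1.91 ± 0.20 patients vs 1.69 ± 0.14 controls,
   n = 14/14, globally positive correlations, patient-specific ACC–OFC
   coupling, negative amygdala–craving association), so every stage is
   testable without patient data (`make_default_config()`,
   `generate_cohort()`, `generate_tacs()`).

The methods vignette (`vignettes/receptor-covariance-networks.Rmd`) documents
the models, default parameters, generator assumptions and known limitations.

## Worked example

```r
library(petcovnet)

# a printed clinical summary re-tested from its summary statistics
welch_test(list(mean = 3.5, sd = 3.2, n = 14),
           list(mean = 1.1, sd = 1.7, n = 14))
#> Welch two-sample t test (two_sided)
#>   t = 2.478, df = 19.8, p = 0.02234

# synthetic study-sized cohort, covariate-adjusted amygdala comparison
coh <- generate_cohort(make_default_config(), seed = 1)
ancova_region(coh, "amygdala", covariates = c("BDI", "BAI"))
#> amygdala: F(1, 24) = 4.311, p = 0.04873, partial eta^2 = 0.1523 (covariate-adjusted)

# three-step network comparison
m_ctl <- corr_matrix(coh, "control")
m_pat <- corr_matrix(coh, "patient")
global_comparison(m_ctl, m_pat)
#> Global correlation comparison (fisher_z, controls - patients):
#>   t = 1.148, df = 1257, p = 0.2511 over 630 pairs/group

pc <- compare_all_pairs(m_ctl, m_pat, alpha = 0.001)
head(pc[order(pc$p_one_tailed), ], 1)
#>                     region_a                       region_b  r_ctl r_pat  stat p_one_tailed flagged
#> 311 anterior_cingulate_gyrus posterior_orbitofrontal_cortex -0.106 0.926 -4.07     2.36e-05    TRUE
```

At the study's own n = 14 per group, a single simulated cohort behaves like a
single real one: the amygdala group effect is significant but modest
(F(1, 24) = 4.31 here; its size varies seed to seed around the configured
0.22-DVR mean difference), the top-ranked pair test recovers one of the
injected anterior-cingulate–orbitofrontal couplings (r = 0.93 in patients vs
−0.11 in controls, one-tailed p = 2.4e−05, the only pair flagged at 0.001),
and the global controls−patients t is small — per-pair coupling differences
barely move the pooled mean of 630 correlations. Direction conventions:
negative per-pair `stat` and negative difference-map entries both mean
stronger coupling in patients.

An end-to-end run (`run_pipeline(pipeline_config(out_dir = "out", seed = 1))`)
writes the cohort table, per-region TSV (both adjusted and unadjusted arms),
per-group correlation matrices, the 630-row pair table, the difference map,
global-test JSON, clinical associations, heatmap PNGs and a reproducibility
manifest. A thin command-line dispatcher over the same functions ships in
`inst/cli/petcovnet.R` with verbs `simulate`, `quantify`, `compare`,
`covnet`, `nullsim`, `clinical` and `run`.

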