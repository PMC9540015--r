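# ebmstage

Event-based modelling and staging of disease progression from
cross-sectional brain morphometry.

## What this package is for

In mesial temporal lobe epilepsy with hippocampal sclerosis (MTLE-HS),
regional gray-matter measures differ from controls in a way that suggests
progressive change, but longitudinal cohorts able to resolve the *order* of
those changes are scarce. The event-based model (EBM) infers that order from
a single cross-sectional case-control dataset: each biomarker's transition
from its normal to its abnormal distribution is an "event", and if patients
traverse a common sequence, early events are abnormal in many patients and
late events in few. A fitted model also assigns every subject a disease
stage (0 = no events, N = all events) from one scan.

`ebmstage` is aimed at imaging researchers working with multicenter regional
morphometry (Desikan–Killiany cortical thickness and surface area plus
subcortical volumes; 156 measures, 78 left/right pairs). It provides the
complete pipeline — missingness filtering, within-center SVD imputation,
empirical-Bayes ComBat harmonization, covariate residualization,
ipsilateral/contralateral relabeling with a seeded control split, brain
asymmetry indices, robust effect-size feature selection, the KDE-mixture
EBM with greedy-ascent + MCMC sequence estimation, bootstrap positional
variance diagrams, per-subject staging, and stage–clinical association
statistics — plus a synthetic multicenter cohort generator with a known
ground-truth event sequence, so the whole path is testable end to end.

## The model in brief

For biomarkers with ordering *S* and a uniform prior over stages 0..N, the
likelihood of subject *j* is

    P(X_j | S) = 1/(N+1) * sum_k  prod_{i<=k} p(x_{j,S(i)} | E)
                                * prod_{i>k}  p(x_{j,S(i)} | not E)

with per-biomarker normal/abnormal densities fitted as constrained
two-component KDE mixtures against the control distribution. The
maximum-likelihood ordering is found by greedy ascent (10 × 10 000
transpositions by default) followed by Metropolis MCMC over permutations
(500 000 samples); ordering uncertainty comes from 100 within-group
bootstrap refits summarized as a positional variance diagram. Robust
Cohen's *d* (medians and mean absolute deviations in place of means and
SDs) with threshold |d| ≥ 0.5 selects the biomarkers; the brain asymmetry
index is BASI = (ipsi − contra) / ((ipsi + contra)/2).

## Worked example

```r
library(ebmstage)

cfg <- sim_config(n_controls = 300, n_cases_left = 150, n_cases_right = 150,
                  n_centers = 4, seed = 42)
cohort <- simulate_cohort(cfg)
#> Synthetic cohort: 600 subjects ( 300 controls, 300 cases ), 4 centers,
#> 7 ground-truth events

res <- run_pipeline(
  default_config(
    split = list(seed = 42),
    ebm = list(greedy_iter = 1000, greedy_init = 4, mcmc_samples = 10000,
               bootstrap_repeats = 10, bootstrap_mcmc = 1000,
               bootstrap_greedy_iter = 300, bootstrap_greedy_init = 2,
               seed = 42),
    out = list(dir = "readme_run")),
  cohort = cohort$data, clinical = cohort$clinical)

res$ebm
#> Event-based model fit: 11 events
#>   ML sequence: ipsi_hippocampus_vol -> basi_hippocampus_vol ->
#>     ipsi_superiorparietal_thick -> basi_superiorparietal_thick ->
#>     ipsi_precuneus_thick -> basi_precuneus_thick ->
#>     ipsi_supramarginal_thick -> basi_supramarginal_thick ->
#>     ipsi_superiorfrontal_thick -> ipsi_thalamus_vol -> ipsi_fusiform_thick
#>   log-likelihood: -3943.55
```

Eleven of the 234 candidate features pass |d| ≥ 0.5 — the strongest being
ipsilateral hippocampal volume (d = −1.79) — and the fitted sequence opens
with hippocampal volume loss followed immediately by hippocampal asymmetry,
then neocortical thinning and thalamic volume: the asymmetry indices of the
affected pairs earn sequence positions of their own because the
contralateral side acts as a within-subject reference.

```r
head(res$selected[, c("feature", "d")], 3)
#>                       feature         d
#> 75       ipsi_hippocampus_vol -1.793824
#> 28 ipsi_superiorparietal_thick -1.621256
#> 24        ipsi_precuneus_thick -1.417891

res$associations$correlations[1, ]
#>                    test       rho            p   n
#> 1 stage_vs_duration_all 0.5321408 2.463305e-23 300

res$associations$resistance$auc
#> [1] 0.5913602
```

Assigned stage correlates with duration of illness (Spearman ρ = 0.53 here;
the generator links duration to the latent stage at 2 years/stage) and
discriminates drug-resistant from responsive cases (AUC = 0.59). 234 of 300
controls sit at stage 0. All artifacts (`sequence.json`, `pvd.csv`,
`stages.csv`, `mixtures.csv`, `effect_table.csv`, `associations.csv`, run
log, manifest) are written to the output directory;
`render_report(dir, clinical)` adds the stage histogram and
duration-by-stage tables.

A thin command-line wrapper is installed at
`inst/scripts/ebm_pipeline.R` (`simulate`, `run`, `report` subcommands).

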