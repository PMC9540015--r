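---
title: "Event-based modelling and staging of disease progression from cross-sectional morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based modelling and staging of disease progression from cross-sectional morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmstage)
```

## The problem

Mesial temporal lobe epilepsy with hippocampal sclerosis (MTLE-HS) is
associated with regional loss of gray matter that appears, from
cross-sectional comparisons, to be progressive. Longitudinal imaging cohorts
large enough to resolve the *order* in which regions become abnormal are
rare. The event-based model (EBM) sidesteps this by treating each biomarker's
transition from its normal to its abnormal distribution as an "event" and
asking which single ordering of events best explains a cross-sectional
case-control dataset: if all patients traverse the same sequence, biomarkers
early in the sequence should be abnormal in many patients and late ones in
few. A fitted model also assigns each subject a stage — the number of events
they have passed — from a single scan.

`ebmstage` implements the full analysis path for multicenter regional
morphometry (cortical thickness, surface area, subcortical volume under the
Desikan–Killiany parcellation; 156 measures, 78 left/right pairs), together
with a synthetic-cohort generator that carries a known ground truth, so
every stage of the pipeline is testable without access to restricted
consortium data.

## The model

For biomarkers $1, \dots, N$ with event ordering $S$, a subject $j$ at stage
$k$ has biomarkers $S(1..k)$ drawn from their abnormal densities $p(x\mid E)$
and the rest from their normal densities $p(x \mid \neg E)$. With a uniform
prior over stages $0..N$,

$$P(X_j \mid S) = \frac{1}{N+1} \sum_{k=0}^{N}
  \prod_{i \le k} p(x_{j,S(i)} \mid E)
  \prod_{i > k} p(x_{j,S(i)} \mid \neg E),$$

and the data log-likelihood is the sum over subjects (cases only by
default; the controls inform the normal components through the mixtures —
`ebm.likelihood_subjects = "all"` switches this). The model assumes events
are monotone (an abnormal biomarker never reverts) and that a single
ordering describes the cohort.

### Component densities: KDE mixtures

Each biomarker's case distribution is a mixture of a normal and an abnormal
component that overlap; neither is assumed Gaussian (ventricular volumes are
right-skewed). `fit_mixture()` fits both components as weighted
Gaussian-kernel KDEs, iterating: controls always belong to the normal
component with weight 1; cases contribute to the two components with their
posterior membership weights; the mixture weight $\theta$ is the case mass
in the abnormal component; and a directionality constraint forbids
abnormality on the healthy side of the normal component's median. The
update uses posterior *weights* rather than a hard 0.5 threshold: with hard
assignment the abnormal component of late-sequence events (truly abnormal
in only ~12% of cases) absorbs a large mass of normal cases and $\theta$
stabilizes far from the generating fraction, which measurably degrades
staging; the weighted update recovers $\theta$ to within a few points in
simulation. $\theta$ is clipped to $[0.01, 0.99]$ and a clipped or anchored
fit is flagged degenerate. Bandwidths follow Silverman's rule on the
effective (weighted) sample, floored at $10^{-3}$ of the biomarker SD so a
shrinking component cannot collapse. For large support/evaluation products
the KDE is evaluated through an FFT-binned density on a 2048-point grid with
linear interpolation (absolute error ~$10^{-4}$, far below the membership
tolerance); small problems use exact kernel sums.

### Sequence estimation and uncertainty

The maximum-likelihood ordering is found by greedy ascent (default 10
random initializations × 10&nbsp;000 transposition proposals, accepting
strict improvements) followed by Metropolis MCMC over permutations (default
500&nbsp;000 samples, symmetric transposition proposals, acceptance
$\min(1, e^{\Delta \log L})$), returning the best sequence visited — which
can never fall below the greedy initialization. Transpositions are the
simplest symmetric proposal; for small $N$ the oracle-equivalence tests
confirm the search attains the exhaustive optimum. Ordering uncertainty is
summarized by a positional variance diagram: subjects are resampled with
replacement *within* case/control strata (preserving the group ratio), the
mixtures refitted and the search rerun (with deliberately shorter chains,
configurable), and entry $(e, p)$ of the PVD is the fraction of bootstrap
maximum-likelihood sequences placing event $e$ at position $p$. Every
replicate contributes a permutation matrix, so rows and columns each sum to
1 exactly. A bootstrap draw in which any biomarker is constant within a
group is redrawn and logged. The MCMC-sample PVD of the primary fit is also
written (`pvd_mcmc.csv`) for comparison; the bootstrap PVD is the canonical
one.

### Staging

`stage_subjects()` assigns every subject — cases *and* controls — the stage
maximizing $\prod_{i\le k} p(x_{S(i)}|E)\prod_{i>k} p(x_{S(i)}|\neg E)$,
with ties broken toward the lower stage ("no abnormality" is the
conservative default, and it makes the stage-0 behavior reproducible). The
per-stage log-likelihood vector is retained in `stages.csv`.

## The pipeline around the model

Stages run in a fixed order, mirroring how multicenter morphometry is
prepared in practice:

1. **Missingness filter** — subjects with more than 10 missing feature
   values are dropped (strictly more: 10 is kept); every drop is logged.
2. **Imputation** — remaining missing cells are completed within each
   center by iterative truncated-SVD completion (default rank 5,
   tolerance $10^{-6}$ on the column-standardized scale, 500 iterations).
   Columns are rescaled to unit observed SD for the iteration — the
   features span four orders of magnitude and a diagonal rescaling
   preserves rank structure exactly — and observed cells are never
   altered.
3. **Harmonization** — parametric empirical-Bayes ComBat (`combat_fit()` /
   `combat_apply()`), removing per-center location and scale biases while
   protecting age, sex, ICV and a three-level diagnosis factor
   (control / left-case / right-case). ICV enters linearly, the named
   tool's convention. Harmonization operates on the original 156
   left/right features, before any relabeling. The fit/apply split keeps
   all center parameters inspectable and serializable; tests verify
   agreement with `sva::ComBat` to $10^{-6}$ on shared inputs.
4. **Residualization** — per feature, OLS on age, sex, ICV; the residual
   plus the fitted intercept replaces the feature, keeping the original
   scale. The model is fitted on all subjects pooled (the literal reading
   of adjustment-after-harmonization; `residualize.fit_on = "controls"`
   switches to control-only estimation).
5. **Ipsi/contra relabeling** — for left-lateralized cases the left
   hemisphere becomes ipsilateral, mirrored for right; controls are split
   in half by a seeded draw (per-cohort, not per-center — no
   stratification is assumed; the seed is a required, logged input), the
   larger half going to the left assignment when the count is odd.
6. **Asymmetry indices** — for each of the 78 pairs,
   $\mathrm{BASI} = (I - C) / \tfrac{I + C}{2}$, computed from the
   harmonized, adjusted side values so the index is free of center and
   covariate structure (the alternative order is not offered a switch;
   computing BASI last is the package's choice and is antisymmetric and
   scale-invariant by construction). The two hemispheric summary measures
   are included among the 78 pairs.
7. **Feature selection** — robust Cohen's $d$ (medians and mean absolute
   deviations about the median in place of means and SDs, pooled with the
   classical $(n-1)$-weighted formula) for all 234 features; features with
   $|d| \ge 0.5$ (lenient alternative 0.4) enter the EBM, each carrying
   its abnormality direction as the sign of $d$. The MAD center is
   configurable (`mad_center`), median being the default since the median
   replaces the mean throughout the robust variant.
8. **EBM fit, bootstrap PVD, staging, associations** — as above;
   associations cover Spearman correlations of stage with duration of
   illness and age at onset (all cases and stages ≥ 1 only), the
   resistant-vs-responsive Mann–Whitney $U$ with
   $\mathrm{AUC} = U/(n_1 n_2)$ (resistant treated as the positive group),
   a Kruskal–Wallis comparison of left vs right stage distributions, and
   stage-0 versus later-stage contrasts (Welch $t$ by default, pooled
   variance switchable) for duration, onset and ipsilateral hippocampal
   volume, plus stratified robust effect sizes of hippocampal volume
   against controls. No multiple-testing correction is applied across
   these tests; they are reported individually.

`run_pipeline()` executes all of this from one configuration list (or YAML
file), writes every artifact (`sequence.json`, `pvd.csv`, `stages.csv`,
`mixtures.csv`, `effect_table.csv`, `associations.csv`), a structured run
log of every filtering decision, and a manifest recording the configuration,
seeds, input hashes and per-stage counts. Two runs with the same inputs,
configuration and seeds are byte-identical in their staged output.

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the structure the pipeline must
remove or recover, with a recorded ground truth. Its defaults are the
package's canonical study conditions and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| cohort | 1625 controls, 446 left + 358 right cases | typical large multicenter epilepsy consortium composition |
| centers | 25, uniform assignment | same |
| events | 7 region pairs, hippocampus first, ventricle last | the qualitative ordering reported for MTLE-HS |
| effect size | 2.0 SD separation, equal-variance Gaussian components | hallmark-level atrophy effect; simplest structure satisfying the EBM assumptions |
| latent stages | uniform over 0..N, including 0 | lets stage-0-driven association findings be exercised |
| center biases | additive SD 0.3, log-scale SD 0.1, drawn once per center per feature | moderate scanner/protocol variation |
| covariates | age −0.3, ICV +0.4, male +0.2 (feature-SD per standardized covariate) | typical directions and magnitudes for morphometry |
| missingness | 0.02% MCAR + 2 subjects forced above the 10-value filter | segmentation QC failure rate plus filter exercise |
| duration | 15 y + 2 y/stage + N(0, 5 y) | matches the observed gap between stage-0 and later-stage cases |
| resistance | logit(1.4 + 0.25·stage) | ~89% resistant overall, rising with stage |

Abnormality is applied to the seizure-focus hemisphere only; the direction
is a decrease for volumes, thickness and surface area and an increase for
the lateral ventricles. Events are defined on region pairs, so the
ipsilateral analysis features inherit the effect after relabeling, and the
asymmetry indices of affected pairs acquire effects of their own — which is
why the full pipeline typically selects a handful of BASI features beyond
the seven generating events.

What the generator does **not** emulate: spatial correlation between
regions, non-Gaussian control distributions, longitudinal trajectories,
center-dependent detectability of sclerosis, and any systematic difference
between left and right cases. Passing tests therefore demonstrate that the
machinery recovers truth under the stated conditions, not that real cohorts
satisfy those conditions. In particular the left-vs-right stage comparison
is a null test here by construction, and the generator treats stage 0 as a
genuine latent state (truly mild disease) rather than modelling
scanner-dependent under-detection.

## Numerical choices

* Sequence likelihoods are accumulated with log-sum-exp; densities are
  floored at $10^{-300}$ before logs.
* The likelihood inner loop (run ~150k times per fit) computes stage
  cumulative sums via one (subjects × N) × (N × N) triangular matrix
  product and avoids generic dispatch; ~125 µs per evaluation at
  n = 500, N = 7.
* Degenerate inputs: identical mixture densities make all orderings
  equally likely (verified); a zero-spread paired-difference vector in the
  effect-size comparisons is reported as degenerate rather than tested;
  `BASI` is `NA` (and logged) when a pair sums to zero.
* All randomness flows through explicit seeds (simulation seed, control
  split seed, EBM seed); derived seeds stay below $2^{31}$.

## Problem sizes used by tests and the acceptance script

The test suite runs the oracle-equivalence check on 20 cohorts of 150+150
subjects with 5 events against exhaustive enumeration of all 120 orderings;
the recovery check on 20 cohorts at the canonical 500+500 / 7-event
conditions with greedy 2500 × 4 and 50&nbsp;000 MCMC samples; and the
pipeline determinism check at reduced search settings. The acceptance
script reruns the canonical recovery once and a full default-scale
multicenter pipeline with greedy 2500 × 4, 50&nbsp;000 MCMC samples and 20
bootstrap repeats. These sizes are the package's validation choices; the
full-scale defaults (10 × 10&nbsp;000 greedy, 500&nbsp;000 MCMC, 100
bootstraps) remain the production configuration.

## Known limitations

* A single ordering is assumed for the whole cohort; subtype mixtures
  (distinct progression patterns) are out of scope, though left-only and
  right-only cohorts can be fitted separately with the same functions.
* Staging is a hard argmax; the per-stage likelihood vector is exported
  but no posterior stage distribution is computed.
* The KDE mixture is identifiable only through the directionality
  constraint and the control anchor; biomarkers whose cases are
  indistinguishable from controls are driven to the $\theta$ clip and
  flagged, and are better excluded by the effect-size threshold upstream.
* ComBat assumes exchangeable per-center effects under normal /
  inverse-gamma priors (the parametric variant only); nonparametric priors
  and nonlinear age trends are not implemented.
* With around 15% of simulated cases at latent stage 0, stage–clinical
  correlations in the synthetic cohort are driven partly by the stage-0
  group, mirroring the qualitative phenomenon the association module is
  designed to dissect.
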