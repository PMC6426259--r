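---
title: "Case-only ascertainment bias and causal-model ranking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only ascertainment bias and causal-model ranking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascbias)
```

## The problem

Cohorts assembled to study a disease usually contain cases only (or cases
plus a handful of controls).  When a secondary trait — here, the relative
abundance of a gut bacterial taxon — is tested for association with a
disease-risk genotype inside such a sample, the conditioning on disease
status can create, destroy, or attenuate associations that do or do not
exist in the source population.  `ascbias` provides the machinery to
quantify this selection bias exactly, to predict its direction under four
parsimonious causal structures, and to use those predictions the other way
around: given an observed pattern of association signs, which causal
structures are still tenable?

Throughout, `g` is a biallelic risk variant (dosage 0/1/2), `b` a bacterial
level, `d` a binary disease status, and `G`, `B`, `D` their standardized
versions (mean 0, variance 1).  The four generative structures are

* **(a) mediation** — `B = βG + ε`, disease risk logistic in `B`:
  the variant acts on disease *through* the bacterium;
* **(b) pleiotropy** — `B = βG + ε`, disease risk logistic in `G`:
  one variant, two independent consequences;
* **(c) independent risk factors** — `B = ε`, disease risk logistic in
  both `B` and `G`: no association in the population;
* **(d) reverse causation** — disease risk logistic in `G`, then
  `b = γD + ε`: the disease alters the bacterium.

`causal_model()` encodes one structure with its parameters (`β`, `γ` on the
per-SD scale; `ω0`, `ωB`, `ωG` in log-odds; allele frequency; target
prevalence; error distribution).  `simulate_population()` draws from it in
the order the structure dictates (disease first only for model d).

## The exact bias formula

Let `Δ = β_case − β_pop` be the difference between the OLS coefficient of
`B` on `G` computed among cases and in the whole population.  Because `d`
is binary, conditional moments expand algebraically: writing
`r = σ_d/μ_d` with `μ_d = E[d]` and `σ_d² = μ_d(1−μ_d)`,

    E[X | d = 1] = E[X] + r·E[XD]

for any `X`.  Applying this to `BG`, `B`, `G` and `G²` gives

    σ²_{G|d=1} = 1 + r·E[G²D] − (r·E[GD])²
    Δ = ( r·E[BGD] − r²·E[GD]·E[BD] ) / σ²_{G|d=1}
        + E[BG]·(1 − σ²_{G|d=1}) / σ²_{G|d=1}

`delta_exact()` evaluates this from a `moment_set` produced by
`standardize()`.  Two numerical conventions make the identity *exact* on
finite samples rather than asymptotic: all standardizations use the
population-variance (divide-by-n) convention, and the case-only OLS slope
is computed on the full-sample standardized views (the slope itself is
location-invariant).  The test suite verifies agreement with the brute-force
two-regression difference to 1e-8 across random parameterizations of all
four models, and the conditional-moment identity to 1e-10.

## Closed-form approximations and their derivation

For a common disease, small effects and near-normal `B` and `G`, a
second-order expansion of the logistic around the prevalence inside the
exact formula yields

    Δ_a ≈ −β̃ (1 − β̃²) ω̃_B² · μ_d(1−μ_d) / σ²_{G|d=1}
    Δ_b ≈ 0         (exact in expectation: ε ⟂ d given G)
    Δ_c ≈ −ω_G ω̃_B · μ_d(1−μ_d) / σ²_{G|d=1}
    Δ_d ≈ −γ̃ ω_G σ_d

where tildes place `β` and `ω_B` on the standardized-bacterium scale
(`β̃ = β/√(1+β²)`, `ω̃_B = ω_B·sd(b)`).  The factor `μ_d(1−μ_d)` is worth a
note: rendering artifacts make published versions of such formulas easy to
misread as `(1−μ_d)²`, and the distinction matters — at a 30% prevalence the
two differ by a factor 2.3.  We rederived the expansion from scratch; the
`μ_d(1−μ_d)` form agrees with `delta_exact()` on large simulations to within
1–13% at moderate effects, while the `(1−μ_d)²` reading is off by a factor
2–3.  Outside the small-effect regime only the *sign* of `delta_approx()`
is contractually guaranteed:

    sign(Δ_a) = −sign(β)        sign(Δ_c) = −sign(ω_G ω_B)
    Δ_b = 0                     sign(Δ_d) = −sign(γ ω_G)

`delta_approx()` defaults `σ²_{G|d=1}` to 1 (its small-effect value) unless
a `moment_set` supplies it.  The rare-disease property follows directly:
`μ_d(1−μ_d) → 0` as `μ_d → 0`, so case-only sampling hurts least exactly
where case-only designs are most needed.

The sign predictions are tabulated by `predict_sign_pattern()`, including
the across-taxa "panel" correlation between case-only genotype effects and
case-control disease effects: positive under mediation/pleiotropy with
concordant effect panels, negative under independent risk factors (the
case-only estimate is then *pure bias*, `≈ −ω_G ω_B`-shaped, anticorrelated
with the disease effect), and null under reverse causation.

## Synthetic cohort generator

The generator exists so that every downstream stage is testable without
clinical data.  What it emulates:

* a 6-rank taxonomy (phylum → species) with 6/12/17/36/63/34 named taxa;
  because there are fewer species than genera, leaves occur at several
  ranks, as in real incompletely-resolved annotations;
* negative-binomial counts at the leaves with per-taxon dispersions solved
  from the NB zero-probability equation `(θ/(θ+μ))^θ = p₀` so each taxon
  hits its target zero fraction (clamped with a warning below the Poisson
  floor `e^{−μ}`; a target of exactly 0 is honored by zero-truncated
  sampling); log-normal baseline means give the heavy-tailed composition of
  real communities;
* upward aggregation of leaf counts, with an "unassigned" pseudo-leaf under
  every internal node and at the top level — this produces the
  parent-child consistency (children never exceed their parent) and the
  grey unassigned mass of real profiles by construction, and induces the
  strong cross-rank correlations observed in practice;
* host covariates at the marginal frequencies of a 182-case/38-control
  IBD cohort (smoking 21.4%, anti-TNF 49.5%, oral 5-ASA 38.5%, ...; age
  normal around 40.6, SD 12, truncated at 18 — the source reports only
  means, so the spread is our choice of a plausible adult IBD age
  distribution); 63% CD among cases with 60% of CD ileal (a typical ileal
  involvement rate; not reported in the source table);
* four risk loci, with the low-frequency locus represented by three
  variants that can be collapsed to carrier (default) or summed-dosage
  coding.

What it deliberately does **not** emulate: the real inter-taxon correlation
matrix beyond what shared ancestry induces; compositional closure effects
beyond the division by total counts; treatment effects on taxa;
read-level sequencing noise, chimeras or contamination.  Tests passing on
synthetic data therefore validate the statistical machinery, not any claim
about a particular real community.

`embed_causal_structure()` grafts a causal model onto a generated cohort:
it re-draws the assigned taxon's leaf counts with a log-link mean shift
(`μ·e^{βG}` or `μ·e^{γD}`) and regenerates disease status from the model's
logistic, re-calibrating the intercept to the target prevalence.  The
monotone log link is invisible to the rank-based analysis downstream.

## Association pipeline

* **Filtering**: taxa detected in fewer than 20% of samples are dropped
  (boundary inclusive: exactly 20% is retained), with a ledger recording
  every dropped taxon and its reason; a lineage-completeness rule
  optionally drops unannotated taxa.
* **Transformation**: rank-based inverse normal transformation with the
  Blom offset, `qnorm((rank − 3/8)/(n + 1/4))`, mid-ranks for ties (the
  zero mass of a sparse taxon forms one tied block).  The output is
  exactly invariant to monotone transforms of the input, which is also why
  the NB log-link choice above is innocuous.
* **Model**: OLS of the unit-variance outcome on the untransformed
  genotype plus confounders (discovery set: sex, age, smoking and four
  treatment classes) and optionally covariates selected within the
  outcome's taxonomic rank.  Coefficients are the change in outcome SD per
  risk allele (or per carrier status); p-values use the t reference.
  Disease type is deliberately *not* adjusted for, because subtype has a
  genetic basis and adjusting for it can invalidate the test.
* **Covariate selection**: `select_level_covariates()` is a deterministic
  greedy stand-in for published multi-phenotype covariate-selection
  methods: it admits up to 5 same-rank taxa that explain residual outcome
  variance (p < 0.05) and are not associated with the genotype (p > 0.05),
  the latter rule preventing collider adjustment.  It reproduces the
  intent (power gain without bias), not the internals, of such methods.
* **Multiplicity**: Bonferroni within each taxonomic rank — taxa across
  ranks are nested and strongly correlated, so a global correction would
  be doubly punitive.
* **Strata**: the genotype model is re-fit in IBD, CD, ileal CD,
  non-ileal CD and UC; strata with constant genotype or fewer than 10
  usable samples yield missing-result records rather than estimates.
* **Case-control stage**: logistic regression of status on the transformed
  taxon plus confounders; perfect separation is flagged with an
  infinite-coefficient sentinel and excluded downstream.

Missing covariate values are handled by listwise deletion with a logged
count.

## Meta-analysis, enrichment, concordance

Two-stage results are pooled by fixed-effect inverse-variance weighting;
when only printed `(β, p)` pairs are available the standard error is
recovered as `|β|/Φ⁻¹(1−p/2)`.  This arithmetic reconstructs published
pooled estimates to two decimals (see `scripts/acceptance.R`), and agrees
with `metafor::rma(method = "FE")` to 1e-10 in the test suite.  Directional
enrichment uses the one-sided exact binomial test (normal approximations
with and without continuity correction are available, since published
enrichment p-values are not always reproducible under a single variant —
the choice is configurable and documented rather than silently matched).
Effect concordance sums per-taxon genotype effects across genes, correlates
them with the case-control disease effects (Pearson), and draws its p-value
from taxon-label permutations.

## Counterfactual model scoring

`collect_observed()` reduces the pipeline outputs to the features the four
models disagree about; `score_models()` compares them with each model's
predicted pattern and returns the set of models no informative feature
contradicts.  The decision thresholds are explicit package choices (the
underlying question has no canonical values):

* a case-only association is **persistent** when discovery and replication
  share a sign and the pooled p-value clears `0.05/n_tests` (the
  meta-stage Bonferroni, with `n_tests` set to the screening width);
* it is **null** when the pooled |z| < 1.28 without a persistent sign;
* a sign that is neither (weak but non-null) is *ambiguous* and rejects no
  model — treating weak evidence as decisive would let 1-in-5 null draws
  overturn a verdict;
* concordance is signed only when its permutation test is significant;
  a non-significant correlation inside |r| < 0.15 is called null, outside
  that band it is ambiguous;
* the subset-vs-full slope (tested against 1 by `slope_vs_unity()`) is
  consulted only when the genetic effect is known to concentrate in the
  subset's subtype, and then only *favors* mediation over pleiotropy —
  it never rejects a model on its own.

Models are not mutually exclusive; the report is a set with an optional
"favored" annotation, never a single winner.

## Simulation experiments and the problem sizes used

All experiments derive replicate seeds from one master seed, so results
are reproducible and independent of execution order.  Intercepts are
calibrated by root-finding on the Monte-Carlo marginal expectation with
common random numbers, making the calibration deterministic given the seed
(closed form checks: all effects zero gives `ω0 = logit(prevalence)`).

* **Bias grids** (`run_bias_experiment`): per replicate, OLS in the whole
  population and in cases; `Δ̂ = β̂_case − β̂_pop` holds exactly per
  replicate.  The sign properties are exercised at 200 replicates of
  n = 20,000 per model and per error distribution (normal, exponential,
  uniform — all standardized to unit variance).
* **Sparsity** (`run_sparsity_experiment`): NB bacterium with a
  replicate-specific zero fraction in [0, 0.95], allele frequency uniform
  in [0.05, 0.95], 200 cases sampled from n = 10,000; the package's
  reference run uses 2,000 replicates per model.  Signed explained
  variance is recorded on the raw and rank-transformed scales; both the
  true effects (models a, b) and the bias (model c) shrink toward the
  null as sparsity grows, with no sign disagreement between scales.
* **Heterogeneity** (`run_heterogeneity_experiment`): CD from the causal
  model (prevalence 0.7%), UC independent (0.7%), IBD their union;
  n = 30,000 with 200 sampled IBD cases, allele frequency in [0.05, 0.2],
  zero fraction in [0, 0.8].  Effect magnitudes are set to the middle of
  the literature ranges for the four loci and their taxa: `ω_G = 0.4`
  (OR ≈ 1.5), `ω_B = −0.4`, and a per-case log-fold change `γ = −0.4` for
  reverse causation.  The per-case parameterization matters: scaling the
  disease→bacterium effect by the *standardized* status would imply a
  ~12 SD shift per case at sub-1% prevalence, which no reported effect
  supports.  Under models c and d these magnitudes leave no detectable
  signal in any stratum (the acceptance suite checks rejection rates
  against the nominal 5% in IBD, CD-only and UC-only strata at 2,000
  replicates).
* **Severity** (`run_severity_experiment`): severity ~ Binomial(5, p) with
  p following the model's logistic; diagnosis is severity ≥ 1.  Under
  reverse causation the case-only genotype-bacterium correlation persists
  (severity still varies within cases) and is cancelled by adjusting the
  bacterium for severity; models a-c keep their primary-experiment
  patterns.  Reference run: 5 replicates of n = 100,000.
* **Panels** (`run_panel_experiment`): 50 taxa per panel, 500 cases/500
  controls drawn from populations of a few thousand; per-taxon effects
  drawn concordantly (risk-allele-depleted bacteria are protective), at
  magnitudes comparable to replicated cohort estimates — except under
  independent risk factors, where larger logistic effects are needed for
  the *bias* to reach the magnitudes reported for real cohorts, mirroring
  the usual illustrative choice of super-real effects.
* **Polynomial surface** (`fit_polynomial_logit_approx`): nested
  least-squares fits of the true disease probability on monomials
  `B^i G^j` up to total order 4; fit quality is the squared correlation
  between fitted and true probabilities (the display this emulates plots
  fitted against true values without naming a metric).  Collinear terms
  are dropped and reported.  Marginal terms suffice at prevalence 0.5 with
  modest effects; higher orders become necessary as prevalence leaves 0.5
  and effects grow.

## Numerical choices and degenerate inputs

* Population-variance convention everywhere a moment identity must be
  exact; `sd()`-based scaling only where a conventional regression scale
  is reported.
* NB dispersion solve uses `log1p` to avoid catastrophic cancellation at
  large size parameters; unattainable zero-fraction targets clamp to the
  Poisson floor with a warning.
* Constant vectors error with the offending variable's name; degenerate
  genotype draws at tiny n are resampled a bounded number of times, then
  error.
* Perfect-fit regressions (zero residual variance) in `slope_vs_unity()`
  return t = 0, p = 1 when the slope is 1 rather than an unstable ratio.
* TSVs are written with 17 significant digits so write/read round trips
  are bit-exact.

## Known limitations

The verdict logic consumes signs and thresholds, not effect sizes; it
cannot quantify *how much* of a genetic effect is mediated.  Mixture
models (several causal structures at once), gene-environment interaction,
and unmeasured-confounder variants of reverse causation are out of scope.
The covariate-selection stand-in shares admission rules, not theory, with
published selection methods.  Estimating Δ from case-only data alone is
impossible without external information — the package's sign logic is the
designed workaround, not a limitation it hides.
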