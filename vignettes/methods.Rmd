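---
title: "Methods: the conformal screening funnel and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the conformal screening funnel and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confunnel)
```

# Overview

`confunnel` implements a multi-stage virtual-screening funnel: lead-like
filtering, docking-score labeling, aggregated Mondrian inductive conformal
prediction (ICP) over fingerprints, Δp-ranked candidate selection, a
conjunctive ADMET cascade, and molecular-dynamics stability analytics.
This vignette records the models, the parameters that matter, the
numerical conventions, and the design decisions taken where the procedure
was genuinely open — in enough detail that every number the package
produces can be re-derived by hand.

# The synthetic test bed

Real campaigns of this kind rest on two external engines — a docking
program scoring hundreds of thousands of conformer ensembles, and a
compound database of hundreds of millions of molecules. Neither belongs in
a desk-scale package, so both are replaced by generators with known ground
truth.

## Library generator

`generate_library()` draws `n_compounds` records with 1024-bit binary
fingerprints. Background bits are i.i.d. Bernoulli(0.05); eight designated
*planted* bits are each present with probability 0.10, so the planted-bit
count per compound is Binomial(8, 0.1) (mean 0.8). Heavy-atom counts are
uniform on 15..30 and cLogP is Normal(2.0, 2.5²), deliberately straddling
the lead-like window (20 ≤ HAC ≤ 25, −5 ≤ cLogP ≤ 3.5, all bounds
inclusive) so the filter removes a realistic majority: the analytic
retention rate is (6/16)·[Φ(0.6) − Φ(−2.8)] ≈ 27%. The planted-bit count
is stored in a sidecar table, never in the fingerprint-facing record, so a
learner can only recover it through the fingerprint itself.

What this emulates — a sparse hashed circular fingerprint in which a small
substructure family drives potency. What it does not emulate — correlated
bits from shared scaffolds, activity cliffs, assay artifacts, or any real
chemistry; passing tests demonstrate that the *procedure* recovers a
recoverable signal, not that any particular chemotype would be found.

## Docking oracle

`docking_oracle()` assigns conformer *c* of a compound carrying *s*
planted bits the score (kcal/mol, lower = better binding):

$$\mathrm{score}_c = \beta_0 + \beta_1 s + e_{\mathrm{compound}} +
e_{\mathrm{conformer},c}$$

with β₀ = −6.0, β₁ = −0.5, e_compound ~ N(0, 0.4²) drawn once per
compound, e_conformer ~ N(0, 0.3²) i.i.d., and the reported optimal score
the minimum over conformers. Separating the two noise scales gives the
conformer-count experiment a known mechanism: only conformer noise makes
larger ensembles help, and with σ_conformer = 0 all ensemble sizes are
exactly equivalent.

Every compound's noise stream is seeded by hashing (oracle seed, compound
id), making scores deterministic and independent of scoring order. Within
a compound the conformer draws form a fixed stream, so the first *k*
draws are shared across ensemble sizes: best scores are *nested* (exactly
paired and monotone non-increasing in *k* by construction), which is what
a paired-design sensitivity analysis assumes.

## ADMET profiles and trajectories

`generate_admet_profiles()` draws the 13 endpoints independently, each
matching its required value with a configurable marginal rate. Two
stringencies are used in the package's own experiments: the study-scale
joint pass probability of ≈ 0.3% (rate 0.003^(1/13) ≈ 0.64 per endpoint,
under which 12,000 profiles yield a few dozen survivors) and a desk-scale
default of 0.75 per endpoint (joint ≈ 2.4%) so that a 200-compound top-k
retains a handful of candidates.

`generate_trajectory()` produces three motion modes with closed-form
expectations: *rigid* (every frame a proper rotation + translation of the
template; fitted RMSD must vanish), *harmonic* (per-atom isotropic
Gaussian displacements of SD *a*; RMSF = a√3), and *drift* (uniform
expansion by 1 + rate·frame; Rg strictly increasing). Frames default to
10 ps spacing, the save interval of the emulated production runs.

# The conformal screen

## Labeling

`label_actives()` marks the top `q` (default 0.01) of compounds by optimal
docking score as computationally active: k = max(1, ⌊q·n⌋), ties at the
threshold broken by ascending compound id. The realized threshold (the
k-th lowest score) is reported alongside.

## Ensemble and p-values

`train_acp()` trains `n_models = 5` independent ICPs. Each member splits
the labeled data stratified-by-class into proper-training (80%) and
calibration (20%) with seed `base_seed + m`, fits the base classifier, and
stores per-class calibration nonconformities α = 1 − P̂(true class). The
base classifier is a pluggable interface; the default is gradient-boosted
trees (xgboost, binary logistic, 60 rounds, depth 4, class-weight
balancing via `scale_pos_weight`, AUC as the evaluation metric, single
thread for reproducibility). Any probabilistic binary classifier works.

For a new fingerprint, each member yields deterministic class-conditional
p-values `(count of calibration α ≥ α_new + 1) / (n_c + 1)`; the ensemble
aggregates by the member-wise **median** (configurable to mean). We use
deterministic rather than tie-smoothed p-values for bit-reproducibility;
the cost is slight extra conservatism. Mondrian (per-class) calibration
makes the validity guarantee hold within each class — essential under the
~99:1 imbalance that top-1% labeling creates.

Four regions at significance ε: active (p₁ > ε ≥ p₀), inactive
(p₀ > ε ≥ p₁), both, null. Ranking uses Δp = p₁ − p₀ computed from the
aggregated p-values (not aggregated member-wise Δp). With small active
calibration sets the attainable p₁ values are coarse (multiples of
1/(n₁+1)); this is a real property of conformal prediction at extreme
imbalance, visible in the desk-scale runs.

## Choosing ε

`select_epsilon()` scans ε over 0.001..0.500 (step 0.001; thresholds
above 0.5 cannot yield single-label predictions) and returns the smallest
ε maximizing the true-positive rate, where TPR counts only the strict
*active* region (the ambiguous *both* region is not a positive — the
configurable, stricter choice). Per-class error curves
P(p_true-class ≤ ε) accompany the selection; validity requires them to
stay at or below the diagonal up to binomial noise.

In `run_pipeline()` ε is selected on a 25% validation split of the
labeled subsample, after which the deployed ensemble is **refit on the
full subsample**: the split exists only to pick a threshold and report
honest metrics, and discarding a quarter of scarce labeled actives from
the deployed model would waste the costliest data in the funnel.

## Metrics

`evaluate_screen()` counts the strict active region as positive (both/null
are non-positive), reports the confusion matrix, recall and precision, and
a rank-based (Mann–Whitney) ROC-AUC using Δp as the score.
`correlation_diagnostics()` reports Pearson r between Δp and the docking
score and between Δp and the ascending-score rank; in the pipeline these
are computed on the *held-out* library compounds against the oracle's own
scores — the desk-scale analogue of test-set validation, where a strong
negative correlation indicates the surrogate's confidence tracks binding
affinity.

# The ADMET cascade and funnel accounting

`apply_admet_filter()` is a conjunction: a compound passes iff all 13
endpoints match their required values ("No" for every toxicity/liability
endpoint, "Yes" for HLM stability). BBB penetration is grouped with the
negatives by default but exposed as configurable, since CNS exposure is
desirable in CNS programs. The rejection tally records each compound's
first failing endpoint (in canonical order) plus total failures per
endpoint. `merge_with_scores()` joins survivors with predictions and
docking scores, dropping (and logging) survivors without a score — the
step at which a filtered set can shrink on integration with docking data.
`funnel_summary()` computes reduction rates as (1 − output/input)·100
rounded **half-up** to 3 decimals, the printed-table convention, and
refuses chains whose counts do not connect unless annotated.

# MD analytics: conventions and numerics

* **Superposition** — Kabsch via SVD with the determinant correction, so
  reflections are never returned; geometry must span a plane (N ≥ 3,
  second singular value > 1e−8) or a degenerate-fit error is raised.
* **RMSF** — frames are fit to frame 1, a mean structure computed, and
  frames refit to that mean (one iteration) before measuring fluctuations.
* **Radius of gyration** — mass-weighted, with *about-axis* components
  (RgX² = Σm(y²+z²)/Σm), the convention of the common MD analysis tools,
  satisfying 2Rg² = RgX²+RgY²+RgZ² to 1e−10 relative; a flag switches to
  along-axis components with identity Rg² = ΣRg_axis².
* **SASA** — Shrake–Rupley with 960 golden-spiral points per atom and a
  1.4 Å water probe; isolated-sphere quadrature error is below 1%. vdW
  radii come from a bundled Bondi table (H 1.20, C 1.70, N 1.55, O 1.52,
  S 1.80, P 1.80 Å); unknown elements get 1.7 Å with a warning, masses
  12 amu likewise.
* **Hydrogen bonds** — distance(D,A) ≤ 3.5 Å and angle(H–D–A) ≤ 30°, both
  configurable; persistence is the bonded-frame fraction per (D,A) pair.
* **DCCM** — C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩) after
  superposition; motionless atoms give NA rows with a warning rather than
  a silent 0/0.
* **Free-energy landscape** — collective variables default to the first
  two principal components of the superposed coordinates (any two user
  series, e.g. RMSD and Rg, may substitute); F = −k_B T ln(P/P_max) with
  k_B T = R·T/1000 kJ/mol, T = 310 K by default (2.577 kJ/mol). The most
  populated bin is exactly 0 and unvisited bins are masked (NA), never 0.
* **Secondary structure** — a deliberately simplified three-state variant
  of DSSP: backbone H-bonds from the Kabsch–Sander energy
  E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with the
  −0.5 kcal/mol cutoff, amide H reconstructed on the bisector from N, CA
  and the previous C when absent; H for residues inside two consecutive
  i→i+4 turns, E for bridge partners at sequence separation ≥ 3
  (antiparallel and parallel ladder patterns), C otherwise. It is not a
  replacement for full 8-state DSSP.

Coordinates are always Å, internal indexing is 1-based R convention with
1-based PDB serials on output, and trajectories are assumed whole (no
periodic-boundary imaging).

# Problem sizes and reproducibility

The package's own experiments run at desk scale, chosen so the full test
suite and the reproduction script each finish in well under a minute of
compute per experiment: 20,000-compound screens with 2,000-compound docked
subsamples for the pipeline (the study-scale counts — hundreds of millions
screened, 200,000 docked, top 12,000 carried to ADMET — enter only as
printed stage counts in the funnel-accounting checks); five independent
20,000-compound screens with 4,000-compound training subsamples for the
validity curves; 1,000 paired compounds at ensemble sizes {1, 10, 50, 100}
for the conformer experiment. All randomness flows from explicit integer
seeds; per-compound streams are derived by hashing (seed, id) so results
do not depend on iteration order.

# Known limitations

* The synthetic fingerprint-score relationship is linear with independent
  bits; real structure-activity landscapes are neither. Validity and
  enrichment results transfer to real data only in so far as
  exchangeability and a learnable signal hold there.
* Aggregating member p-values by the median preserves per-class validity
  only approximately; empirically the aggregate is conservative, and the
  package's validity experiment measures exactly this.
* The ADMET stage filters externally supplied binary endpoint labels; the
  endpoint predictors themselves are out of scope.
* The simplified secondary-structure assignment omits 3-10/π helices,
  bends and turns, and the SASA implementation uses brute-force neighbor
  search — appropriate at desk scale, quadratic in atom count.
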