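---
title: "Methods: insulin phosphoproteome dynamics and kinase-substrate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insulin phosphoproteome dynamics and kinase-substrate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosdyn)
```

`phosdyn` analyses two kinds of SILAC phosphoproteomics screens of insulin
signalling — a two-inhibitor screen and a nine-point stimulation time
course — and predicts kinase-substrate relationships from their combined
features. This vignette documents the models, the tunable parameters, the
numerical conventions, and what the synthetic benchmark does and does not
demonstrate.

## The data model

A site table has one row per phosphosite: identity (`protein_id`,
`position`, `residue` ∈ {S, T, Y}, `multiplicity`), a MaxQuant-style
localization probability, a 13-residue sequence window centred on the
phosphosite (termini padded with `_`), per-replicate log2 ratio columns for
the inhibitor screen (`ins_*`, `mk_*`, `ly_*`: insulin, insulin + Akt
inhibitor, insulin + PI3K/mTOR inhibitor, each versus basal), and
time-course columns `tc<j>_<r>` for timepoint `j` (0, 15 s, 30 s, 1, 2, 5,
10, 20, 60 min) and replicate `r`. Ratios are always stored as log2;
`read_site_table(..., ratio_scale = "linear")` transforms raw ratios on
read. Missing quantification is `NA`, never 0 — a log2 ratio of 0 is a
meaningful "no change". Sites quantified at several multiplicities are kept
as separate records.

## Regulation calling

Insulin regulation is thresholded at `mad_multiplier` (default 2.5) times
the **raw** median absolute deviation of the insulin log2 ratios, with no
1.4826 normal-consistency constant (the constant is exposed as the
`consistency` argument of `mad_threshold()`). Two conventions matter:

- The MAD is computed on the *full pooled distribution of replicate-level
  insulin log2 ratios* of all quantified sites, regulated and unregulated
  together — one global threshold. Pooling replicates, rather than
  per-site medians, keeps the threshold an estimate of the spread of the
  log2 data itself; medians would shrink the scale by roughly the square
  root of the replicate count and inflate the regulated call rate.
- Calls are strict inequalities on the per-site median: `up` if
  median > +threshold, `down` if median < −threshold, otherwise `none`. A
  site with no quantified insulin replicate is "not quantified", a state
  distinct from `none`.

On null log2 data with a raw MAD of 0.40 — the spread typical of such
screens — the 2.5-MAD threshold is 1.0 log2 units, i.e. a 2-fold change.

## Inhibitor dependence

For a regulated site the reversal fraction is
`1 − log2(inhibitor)/log2(insulin)`, computed on replicate medians (median
first, then the ratio, for robustness): 1 is full reversal, 0 none. The
formula is sign-symmetric, so down-regulated sites are handled unchanged;
it is undefined when the insulin response is 0, and such sites are excluded
from dependence calls. Reversal is computed on the log2 scale (whether the
40% rule should act on log2 or linear ratios is a genuine modelling choice;
log2 is used and the threshold is a config parameter).

A site is PI3K/mTOR-dependent when the PI3K/mTOR-inhibitor arm reverses its
response by more than `reversal_threshold` (default 0.40), and
Akt-dependent when it is PI3K-dependent *and* the Akt-inhibitor arm also
exceeds the threshold — Akt acts downstream of PI3K, so the calls are
nested. Before classification, sites are filtered to localization class I
(probability > 0.75), to quantification in at least one replicate of every
arm, and to a consistent response direction. The data model carries one
insulin reference per site, so the direction-consistency filter is
implemented at replicate level: every quantified insulin replicate must
agree in sign with the median. `dependence_summary()` reports the fraction
of regulated sites that are PI3K-dependent and the fraction of those that
are Akt-dependent.

## Temporal features and clustering

Per-timepoint replicate medians are min-max scaled to [0, 1]. Missing
timepoints are linearly interpolated *in real time* (minutes), endpoints
taking the nearest observed value; sites missing more than 3 of the 9
timepoints are excluded from clustering; constant profiles map to all-0.5
and are flagged degenerate. The area under the scaled curve and the
quadratic fit both use real minutes divided by 60 rather than equally
spaced indices — the 15 s–60 min axis is strongly non-uniform, and the
kinetic interpretation (an AUC near 1 means an immediately saturating
response) only holds in real time.

Fuzzy c-means uses the standard Bezdek alternating updates with squared
Euclidean distance, fuzzifier `m = 2` and `c = 18` clusters by default
(both configurable; neither is canonical, and the defaults follow common
practice for phosphoproteome time courses at this scale). Memberships are
initialized uniformly at random with a fixed seed; iteration stops when the
largest centroid change drops below `1e-6` or after 300 iterations. A
profile at zero distance from a centroid takes membership 1 there (shared
if several centroids coincide). The objective `sum(u^m d^2)` is recorded
per iteration and is non-increasing.

Centroid shapes are labeled by rule, in this order: **decreased** (final
value more than 0.3 below the initial value), **sustained increase** (final
value ≥ 60% of the maximum and post-1-min maximum at least 0.3 above the
initial value), **transient** (maximum before 5 min and final ≤ 40% of the
maximum), else **other**. Decreased is evaluated first deliberately: on the
scaled axis a monotone decrease has its maximum at t = 0 and a low final
value, so it would otherwise satisfy the transient predicate.

## Motif statistics

PSSMs are per-position amino-acid frequencies over 13-mers with an additive
pseudocount (default 0.5 per letter; PSSM regularization is not otherwise
constrained), converted to log2 odds against a background frequency vector
— by convention the pooled letter frequencies of the full site cohort
(`background_freqs()`), mirroring the use of the non-regulated
phosphoproteome as reference. Scoring sums the flank log-odds, skipping the
centre (conditioned to be S/T/Y) and `_` padding.

Percent-difference enrichment reports `100 × (p_fg − p_bg)` per (position,
residue) cell with a two-sided pooled two-proportion z-test with continuity
correction at `alpha = 0.01`. The z-test is a declared approximation of the
iceLogo machinery; the continuity correction also handles zero-count cells.

## Kinase-substrate prediction

The feature vector per site, in fixed order: 9 scaled timepoints, AUC,
3 quadratic coefficients (highest order first), the mean log2 ratio across
timepoints, the three inhibitor-screen medians, and one PSSM score per
trained kinase (17 + K features). Sites without a usable time course are
excluded; missing inhibitor medians are imputed as 0 (no response).

Each kinase classifier is an ensemble of 25 RBF-kernel SVMs (`C = 1`,
`gamma = 1/n_features` by default — none of these is canonical and all are
config), each member trained on all curated positives against an
independently subsampled 5:1 negative set. Negatives are drawn from sites
in no kinase's positive set and at least 13 residues away from any positive
on the same protein, to avoid window-overlap leakage. Features are
standardized with location/scale from the training pool. The ensemble mean
decision value is min-max normalized to [0, 1] over the scored cohort (a
single scored site degenerates to 0.5 with a warning). The delta score is
the site's score minus its best score among the other kinases. Candidates
are ranked per kinase by Pareto non-dominated sorting maximizing
(score, delta) — front 1 is non-dominated; within fronts, ranks are by
descending score with stable ties. Ranking per kinase (rather than jointly)
keeps each kinase's candidate list self-contained. Known substrates are
flagged in the output, not removed. `evaluate_cv()` estimates sensitivity
and specificity at the 0.5 operating point and the AUROC by stratified
5-fold cross-validation, with Wilson and Hanley-McNeil intervals.

## Abundance and enrichment statistics

iBAQ divides summed peptide intensity by the count of fully tryptic,
zero-missed-cleavage peptides of length 7–30 (cleavage C-terminal to K/R
except before P). Proteins are ranked by descending iBAQ (ties broken by
id) and split into four equal-count quartiles. Term enrichment uses
Fisher's exact test against a user-supplied background universe with
Benjamini-Hochberg control; the default FDR is 0.02, with 0.01 retained as
a common alternative preset. The abundance rank-shift test is a two-sided
Wilcoxon rank-sum test with normal approximation and tie correction.

## The synthetic benchmark

`simulate_phosphoproteome()` plants a known composition: 15% regulated
sites, two thirds of them increased; 55% of regulated sites
PI3K/mTOR-dependent and 67% of those Akt-dependent; residues 87.8/11.4/0.8%
S/T/Y; 63% class I. Up-regulated sites draw a temporal archetype
(fast-sustained 0.5, transient 0.3, slow ramp 0.2); down-regulated sites
decrease. Effect sizes are Normal(1.5, 0.5) log2 units truncated at 1.0;
replicate noise is Gaussian with sd 0.25 log2 units (no published value
constrains this; 0.25 is a realistic SILAC replicate spread and is
config); missingness is 10% per replicate per condition, completely at
random, which also exercises the "quantified in at least one replicate per
screen" filter. Basal (t = 0) ratios are 0 by construction, noise included.
Akt-dependent sites are reversed in both inhibitor arms by Uniform(0.6, 1),
PI3K-only sites in the PI3K/mTOR arm only, independent sites essentially
unreversed (Uniform(−0.1, 0.2)). Planted kinases follow the pathway:
Akt substrates are fast-sustained and Akt-dependent (R at −5/−3 windows),
mTORC1 substrates slow-ramp and PI3K-only (P at +1), PKA substrates
PI3K-independent increases (R at −3/−2). The inhibitor-screen insulin arm
carries each site's full effect regardless of archetype — the screen is
taken to probe each site at its responsive time; without this convention
transient sites would be structurally invisible to the regulation caller.

What the generator does *not* emulate: correlated replicate noise,
intensity-dependent missingness, abundance-regulation correlation, peptide-
level interference, multi-site peptides shared across records, or realistic
proteome-wide motif composition beyond the planted columns. Passing the
benchmark therefore shows that the pipeline's inference is correct when its
assumptions hold, not that those assumptions hold on any particular real
dataset.

## Problem sizes and determinism

The standard benchmark cohorts are 20,000 sites for regulation, dependence
and residue recovery, 5,000 all-regulated sites for clustering, and
1,500–2,500 sites for classifier checks; these sizes give sampling error
comfortably inside the recovery tolerances (e.g. ±2 percentage points on
the regulated fraction). Every stochastic step — generation, membership
initialization, negative subsampling, fold assignment — is seeded, and
`run_pipeline()` writes a manifest with md5 checksums and no timestamps, so
a fixed seed reproduces outputs byte for byte.

## Known limitations

- The dependence classifier is binary (>40% reversal); no dose-response
  modelling.
- Cluster identities are not stable across seeds (only the shape-level
  summary is); fuzzy c-means finds local optima.
- The SVM ensemble's hyperparameters are defaults, not tuned; the package
  reports cross-validated performance rather than guaranteeing it.
- PSSM and enrichment statistics treat flank positions independently.
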