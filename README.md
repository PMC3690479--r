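# phosdyn

Analysis of insulin-responsive phosphoproteome dynamics from SILAC
phosphoproteomics screens, and machine-learning prediction of
kinase-substrate relationships.

Quantitative phosphoproteomics of insulin signalling typically produces two
complementary screens: a kinase-inhibitor screen (log2 SILAC ratios of
insulin, insulin + Akt inhibitor, and insulin + PI3K/mTOR inhibitor, each
against basal) and a dense stimulation time course (here nine points: 0,
15 s, 30 s, 1, 2, 5, 10, 20 and 60 min). `phosdyn` implements the analysis
chain that turns such site tables into biology, for proteomics
bioinformaticians and signalling labs:

- **Regulation calling.** A site is insulin-regulated when its median log2
  ratio exceeds a global threshold of 2.5 raw median absolute deviations
  (MADs) of the log2 ratio distribution — on typical data roughly a 2-fold
  change.
- **Pathway dependence.** For a regulated site, the reversal fraction
  `1 − log2(inhibitor)/log2(insulin)` measures how much of the insulin
  response an inhibitor abolishes; reversal > 40% calls the site
  PI3K/mTOR-dependent (LY-type inhibitor arm) and, among those,
  Akt-dependent (MK-type arm), after class I localization
  (probability > 0.75), per-arm quantification and direction-consistency
  filters.
- **Temporal structure.** Time courses are min-max scaled to [0, 1],
  summarized by the area under the curve and a quadratic fit in normalized
  time, and soft-clustered by fuzzy c-means (Bezdek updates, c = 18,
  fuzzifier m = 2); cluster centroids are labeled sustained-increase /
  transient / decreased by shape rules.
- **Motifs.** Position-specific scoring matrices (13-residue windows,
  log2 odds with pseudocounts) and iceLogo-style percent-difference
  enrichment with two-proportion z-tests.
- **Kinase-substrate prediction.** Per kinase (Akt, mTORC1, PKA), an
  ensemble of RBF-kernel SVMs trained on curated substrates versus
  subsampled negatives scores every site from its temporal, inhibitor and
  motif features; scores are min-max normalized, a delta score
  (score minus the best competing kinase) measures specificity, and
  candidates are prioritized by Pareto non-dominated sorting over
  (score, delta).
- **Annotation statistics.** iBAQ abundance ranking with quartiles
  (in-silico tryptic digest denominator), Fisher's exact term enrichment
  with Benjamini-Hochberg control, and a Wilcoxon rank-shift test of
  phosphoprotein abundance.

Because the raw mass-spectrometry dataset such analyses start from is not
shippable, the package includes a first-class synthetic-data generator
(`simulate_phosphoproteome()`) that emulates both screens with planted
ground truth — regulated fractions, inhibitor reversal, kinase-specific
temporal archetypes and motif-bearing sequence windows — so every stage is
testable and benchmarkable end to end.

## Worked example

```r
library(phosdyn)

sim <- simulate_phosphoproteome(sim_config(n_sites = 5000), seed = 42)
sim
#> Synthetic phosphoproteome: 5000 sites (773 regulated), seed 42

calls <- classify_dependence(sim$sites)
round(attr(calls, "threshold"), 3)
#> [1] 0.523
dependence_summary(calls)
#> # A tibble: 1 × 6
#>   n_filtered n_regulated n_pi3k_dependent n_akt_dependent frac_pi3k
#>        <int>       <int>            <int>           <int>     <dbl>
#> 1       1389         493              260             178     0.527
#> # ℹ 1 more variable: frac_akt_among_pi3k <dbl>
```

The 2.5-MAD threshold lands at 0.52 log2 units (about 1.4-fold on this
low-noise simulation); 493 of the class-I, fully quantified sites are
insulin-regulated, 52.7% of those are blocked by the PI3K/mTOR inhibitor,
and 178/260 = 68.5% of the PI3K-dependent sites are also Akt-dependent —
recovering the planted pathway structure.

```r
regulated <- calls$site_id[!is.na(calls$direction) &
                           calls$direction != "none"]
cl <- cluster_profiles(sim$sites[sim$sites$site_id %in% regulated, ],
                       centers = 12, seed = 42)
round(100 * prop.table(table(cl$shape)), 1)
#>          decreased sustained_increase          transient
#>               31.3               47.9               20.8
```

About half of the regulated temporal profiles show a sustained increase
with insulin, the remainder being transient or decreased.
`autoplot(attr(cl, "fit"))` draws the cluster centroid curves;
`plot_dependence(calls)` shows the reversal scatter.

`run_pipeline(out_dir, sim_config(n_sites = 2000), seed = 7)` executes the
whole chain — simulation, regulation calls, clustering, motif enrichment,
SVM training and Pareto-ranked predictions — writing stage TSVs and a
deterministic JSON manifest.

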