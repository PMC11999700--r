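# isletscape

Spatial analysis of islet and extra-islet inflammation in multiplexed imaging
of human pancreas, for researchers studying insulitis — the immune
infiltration of islets of Langerhans that defines type 1 diabetes (T1D).
Starting from a per-cell table (coordinates in µm, cell types, marker
intensities), the package reconstructs:

- **Cell types and marker gates** — per-donor z-normalisation, kNN + Leiden
  clustering with signature-based auto-annotation, and marker positivity
  gated at the 99th percentile of a background distribution (cell types known
  not to express the marker); a cell is positive iff its intensity is
  strictly greater.
- **Islet instances** — every cell's *window* (its 20 nearest neighbours) is
  summarised as a cell-type composition with α/β/δ merged to "Endocrine";
  windows are over-clustered by mini-batch k-means (k = 200), endocrine-rich
  clusters define the islet region, and islets are connected components of
  the symmetric k = 5 spatial graph with fewer-than-10-cell components
  dropped. Composition features per islet are `log1p(count / n_endocrine)`
  over non-endocrine types, counting cells inside plus within 20 µm of the
  boundary.
- **Insulitis pseudotime and stages** — diffusion pseudotime from the islet
  nearest the non-T1D centroid on a cosine kNN graph (15 neighbours, Leiden
  clusters, graph-abstraction connectivity), normalised to [0, 1]; stages
  Normal / Inflamed / Insulin-Depleted by a β-presence and immune-enrichment
  rule, with Insulin-Depleted + Immune islets defined as β-free islets with
  > `cd8` CD8⁺T cells and > `mac` macrophage/DCs, thresholds defaulting to
  the 95th percentiles over Normal islets.
- **CD8 sub-states** — per inflamed islet, marker-positivity frequencies of
  CD8⁺T cells (islet + 20 µm band), clustered into sub-states; islet-versus-
  swath enrichment by donor-pooled frequencies and Wilcoxon signed-rank
  tests.
- **Cellular neighbourhoods (CNs)** — over-cluster-and-merge naming (types
  present in > 80% of a cluster's windows; acinar/epithelial excluded from
  names), spatial CN instances, instance adjacency frequencies, and
  abundance (cells per acinar cell) contrasted across donor groups by
  Mann-Whitney tests.
- **Lobular models** — cells assigned to lobules (Voronoi partition or
  GeoJSON masks, interlobular space = "edge"); extra-islet lobular
  abundances per acinar cell; and lme4 mixed models: the intraclass
  correlation ICC = τ²/(τ²+σ²) of islet pseudotime within lobules
  (`pt ~ 1 + (1|lobule)`), per-donor two-level models
  (`pt_z ~ x + (1|lobule)`), and a three-level random-intercept,
  random-slope model (`pt_z ~ x + (1 + x|donor) + (1|donor:lobule)`), all
  with Satterthwaite degrees of freedom.

A ground-truthed synthetic tissue generator (`synthetic_config()`,
`generate_tissue()`) plants islets with a lobule-structured insulitis stage,
staged β-loss and immune infiltration, four CD8 activation profiles, and
B-cell/CD8 aggregates with adjacent vasculature patches — so every stage of
the pipeline is testable against known truth.

## Worked example

```r
library(isletscape)
library(dplyr)

tis   <- generate_tissue(synthetic_config(seed = 1))
cells <- tis$cells

# islets from window composition
w      <- compute_windows(cells, k = 20)
region <- detect_islet_region(w, n_clusters = 200, seed = 7)
islets <- extract_islets(cells, region)
cells  <- add_islet_ids(cells, islets)
feats  <- islet_composition_features(islets, cells)
nrow(islets)
#> [1] 33

# pseudotime and stages
traj   <- build_trajectory(feats, n_neighbors = 15, seed = 3)
pt     <- compute_pseudotime(traj, feats$islet_id[feats$group == "nonT1D"])
stages <- label_stages(pt, feats)
table(stages$stage)
#>
#>        Inflamed InsulinDepleted          Normal
#>              16               2              15

# lobular patterning of one donor
cells <- bind_rows(lapply(split(cells, cells$donor_id), function(cc)
  assign_lobules(cc, tis$partitions[[cc$donor_id[1]]])))
ab <- lobular_abundance(cells, islets, pt)
fit_icc(ab, donor = "D04")
#> <hlm_fit> icc model, n = 4
#>   tau^2 = 0.0090, sigma^2 = 0.0002, ICC = 0.975
```

33 islet instances are detected (32 planted; one detected islet is a split).
The stage table says roughly half the islets are Normal (mostly the non-T1D
donors') while T1D donors contribute Inflamed and Insulin-Depleted islets.
For donor D04 the ICC of 0.97 means nearly all variance in islet pseudotime
is between lobules rather than within them — strong lobular patterning
(though from only 4 islets in 2 qualifying lobules; per-donor ICCs on small
tissues are noisy, which is exactly why the package reports them with their
variance components).
`tidy()` and `glance()` work on every model fit, and `plot_tissue()`,
`plot_pseudotime()`, `plot_adjacency()`, `plot_lobular_slopes()` give the
standard figures.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on the default
synthetic world — generation, typing, gating, islet detection, pseudotime,
staging, sub-states, CNs with adjacency, and the lobular models — logging
each stage's headline numbers, and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
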