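---
title: "Methods: islet and extra-islet spatial analysis with isletscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: islet and extra-islet spatial analysis with isletscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In type 1 diabetes (T1D), immune cells infiltrate and destroy the islets of
Langerhans. Multiplexed tissue imaging of cadaveric pancreas yields a table of
single cells — coordinates in micrometres, a cell-type label, and one
intensity per marker — from which this package reconstructs the anatomy of
insulitis at three scales: the islet (instance detection, composition,
pseudotemporal staging), the peri-islet space (distance swaths, CD8 T cell
activation sub-states), and the lobule (cellular neighbourhoods, hierarchical
models of lobular patterning). A ground-truthed synthetic-tissue generator
makes every stage testable without imaging data.

## Pipeline and models

### Windows and islet instances

Each cell's *window* is its 20 nearest spatial neighbours (index cell
excluded, ties broken by cell order; windows never cross donors), summarised
as counts per cell type with alpha/beta/delta merged into one "Endocrine"
type. Windows are over-clustered with mini-batch k-means (k = 200, batch
1024, 3 restarts keeping the best full-data inertia); clusters whose mean
endocrine window fraction exceeds 0.5 form the islet region. Although one
cluster typically dominates, several clusters may jointly pass the threshold —
a robustness choice for data where over-clustering splits the islet area.
Islet instances are connected components of the symmetric k = 5 kNN graph
over region cells (an edge joins two cells when either is among the other's
five nearest); components with fewer than 10 cells, or without a single
endocrine cell, are discarded.

The islet *boundary* is represented non-parametrically by the member cells
themselves: a cell's distance to an islet is its distance to the nearest
member cell. This is parameter-free and monotone in the intuitive notion of
"distance from the islet edge"; a convex hull would behave almost identically
for the compact islets both real tissue and the generator produce. Band cells
that belong to another islet are excluded, and remaining band cells are
attributed to their nearest islet only, so nothing is double-counted.

### Composition features and pseudotime

For each islet, each non-endocrine type is counted inside the islet plus
within 20 µm of its boundary and divided by the number of endocrine cells
inside; features are `log1p` of these ratios, which implements a log
transform while keeping zero counts finite at exactly 0. The islet trajectory
is a kNN graph (cosine distance, 15 neighbours) over feature rows with Leiden
clustering at resolution 1; cluster connectivity is the observed inter-cluster
edge count divided by its expectation under random edge assignment, the
graph-abstraction statistic.

Pseudotime is diffusion pseudotime from a root on that graph: with transition
matrix T = D^-1 A, the squared distance between cells x and y is the weighted
sum over non-stationary eigenpairs of (lambda/(1-lambda))^2
(psi(x) - psi(y))^2. The root is the single islet nearest (cosine) to the
mean feature vector of non-T1D islets — the distance must start at a graph
node, so the centroid itself cannot serve. Values are min-max normalised to
[0, 1]; the normalisation and units are a package decision, as the upstream
method family reports pseudotime only up to scale. A disconnected graph is
handled per component (each component gets a local root nearest the non-T1D
centroid) with a warning. An explicit omit list supports isolating a path
through the map: omitted islets are removed before the computation and
afterwards inherit the pseudotime of their nearest retained neighbour in
feature space, which by construction never changes retained values.

### Stage labels

Trajectory clusters map to stages by rule rather than manual merging:
clusters with beta-cells (median beta fraction > 0.05) and immune enrichment
(CD8 + macrophage/DC per endocrine cell) at or below the 90th percentile of
non-T1D islets are Normal; beta-present clusters above it are Inflamed;
beta-free islets are Insulin-Depleted regardless of cluster. Within the
Insulin-Depleted group, islets with strictly more than `cd8_thresh` CD8 T
cells *and* strictly more than `mac_thresh` macrophage/DCs form the
Insulin-Depleted + Immune sub-state; by default both thresholds are the 95th
percentiles of those counts over Normal islets (with the canonical reference
values being 2 and 7).

### Marker gating and CD8 sub-states

A marker's background distribution pools cell types known not to express it;
the threshold is the 99th percentile of that background under the type-7
(linear interpolation between order statistics) convention — a concrete,
testable choice where the source procedure names only "the 99th percentile" —
and a cell is positive only if strictly greater. Gating is per donor by
default, consistent with per-donor normalisation elsewhere; a pooled mode is
provided because the original procedure does not say which was used.

For each inflamed islet, CD8 T cells inside the islet and within 20 µm are
combined and the fraction positive per functional marker computed; islets
below a configurable CD8 floor (default 1, as the source's exclusion rule is
unstated) are excluded and listed. Sub-states come from Leiden clustering on
z-normalised frequency rows, replacing interactive embedding gating; the
number of clusters is not forced to four. Islet-versus-swath enrichment pools
cells within donor before computing frequencies, then applies a two-sided
Wilcoxon signed-rank test across donors with zero differences dropped; raw
p-values are reported by default (mirroring the uncorrected convention for
these panels), with a Benjamini–Hochberg option off by default.

### Cellular neighbourhoods

CN identification over-clusters windows with k = 200 and names each raw
cluster by the set of cell types *present* (at least one cell in the window)
in strictly more than 80% of its windows; acinar and epithelial cells
participate in clustering but never in names; same-name clusters merge;
empty names pool into one "(background)" CN so every cell has a label and
abundance accounting stays exact. Instances are connected components of the
k = 5 spatial graph restricted to each CN's cells; the graph is built over
*all* cells first because tissue distances are physical — restricting first
would connect cells across gaps occupied by other neighbourhoods. Two
instances are adjacent when any cell of one is a k = 5 neighbour of any cell
of the other; the adjacency frequency from source to destination CN is the
fraction of source instances adjacent to at least one destination instance.
The cited prior work's exact adjacency criterion is not restated in the
source, so this cell-contact rule is a declared, oracle-testable stand-in.
CN abundance is cells-per-acinar-cell per donor, contrasted across donor
groups with two-sided Mann–Whitney tests and ranked by fold change.

### Lobular models

Cells map to lobules by point-in-polygon against a planar partition (even-odd
ray casting), with cells outside every polygon assigned to the reserved
"edge" pseudo-lobule; "edge" is interlobular space, not a lobule, and is
excluded from modelling (configurable). Lobular abundance uses only
extra-islet cells, divided by extra-islet acinar counts, z-normalised within
donor; islet pseudotime is z-normalised across the entire dataset. Lobules
without islets cannot contribute an outcome and are excluded from the models.

Three mixed models are fitted by REML through lme4 (the same engine the
source analyses used): the intercept-only model `pseudotime ~ 1 + (1 |
lobule)` whose ICC = tau^2/(tau^2 + sigma^2) quantifies lobular patterning;
a per-donor two-level model `pt_z ~ x + (1 | lobule)`; and a three-level
model `pt_z ~ x + (1 + x | donor) + (1 | donor:lobule)` with an unstructured
donor-level intercept–slope covariance, the literal reading of the quoted
random-effects term. Fixed-effect inference uses Satterthwaite degrees of
freedom. Because the usual helper package is not a dependency here, the
Satterthwaite machinery is implemented in-package in the standard way: the
REML criterion is expressed as a function of (theta, sigma), the covariance
of the variance-parameter estimates is approximated by twice the inverse
finite-difference Hessian, the gradient of Var(L'beta) is taken by central
differences, and df = 2 (L'VL)^2 / (g' A g). On balanced designs with a
group-level covariate this reproduces the closed-form J - 2 to within
rounding, which the tests assert. Singular (boundary) fits are flagged, and
a Wald-normal fallback is reported as such when the Hessian is unusable.
lme4's own optimizer replaces the bespoke bounded quasi-Newton scheme that
was sketched at design time; re-implementing an REML optimizer would add risk
and no fidelity, since the source itself used lme4.

## The synthetic world

The generator emits, per donor: a Voronoi lobule partition from uniform seed
points clipped to the tissue rectangle (space-filling and irregular, like
real lobules); islets as near-uniform truncated-Gaussian disks (truncation at
one sigma with sigma equal to the islet radius — real islets are sharply
bounded, encapsulated structures, and a loose Gaussian rim is unrealistically
diffuse and defeats window-based detection); a homogeneous Poisson background
of exocrine and stromal cells, with islet footprints carved out because
islets displace acinar tissue; and planted B-cell/CD8 aggregates with a
vasculature-rich patch placed in contact and distant nerve-rich patches, the
ground truth for neighbourhood naming and adjacency.

Each islet's stage is its lobule's mean stage plus an islet-level deviation;
the two standard deviations (defaults 0.15 and 0.15) set the intraclass
correlation, defaulting to 0.5 — the middle of the range reported for donors
with appreciable lobular patterning (0.17–0.74). Composition follows stage:
the beta fraction among endocrine cells falls linearly from 0.55 to zero at
stage 0.7; immune infiltration rates per endocrine cell are
`intercept + slope * stage^exponent`, with exponents staggering the waves
(macrophage/DCs early at 0.7, CD8 T late at 1.6, B cells last at 2) as
observed along insulitis progression. Peak rates (~0.2 CD8 per endocrine
cell) match the scale of published insulitis counts — tens of T cells against
hundreds of endocrine cells. A beta-free islet retains its peak infiltrate
with probability 0.3 (the Insulin-Depleted + Immune sub-state) and otherwise
reverts to stage-0 rates. Marker intensities are lognormal: background
meanlog 0, sdlog 0.5; positives meanlog 2.5, sdlog 0.4. The distribution
family is a modelling decision — the source does not state one — and the
~12x positive shift reflects the strong bimodality of real lineage markers;
anything much weaker is not typeable by any method in 15 dimensions.
Inflamed-islet CD8 T cells draw functional-marker positivity from one of
four planted profiles (all-low; CD45RA/CD69; CD45RO/PD-1;
LAG-3/ICOS/Granzyme-B/CD57), mirroring the reported sub-states
qualitatively.

What the generator does *not* emulate: segmentation error, lateral bleed,
staining batch structure beyond donor-wise scale, cell-shaped (non-point)
geometry, and realistic islet shape irregularity. A green test therefore
establishes that the implementation is faithful to its stated rules and
recovers planted structure under realistic density, composition, and noise —
not that it would segment real CODEX images end to end.

## Numerical choices and degenerate inputs

- Ties in every kNN query break by cell index, making window composition,
  components, and instances bit-reproducible; tests compare against
  sort-based oracles including duplicated points.
- Percentiles use type-7 interpolation everywhere a percentile is named.
- Mini-batch k-means and Leiden run under fixed seeds; Leiden consumes R's
  RNG, so a `set.seed` before each call pins results. All generator
  randomness flows from one seed, and helpers restore the caller's RNG state.
- Cells with identical marker vectors form a single typing cluster; an
  all-zero cluster annotates to the first vocabulary type with a tie flag.
- Eigenvalues within 1e-8 of 1 (stationary and disconnected directions) are
  excluded from diffusion pseudotime.
- Zero-variance frequency columns z-normalise to 0 rather than NaN.
- Boundary variance estimates (tau^2 = 0) are legal and flagged `singular`;
  ICC is clamped to [0, 1] by construction.

## Known limitations

- Typing accuracy is reported against the generator's own vocabulary; real
  panels with co-expression and bleed would need signature curation.
- Diffusion pseudotime assumes the inflammation gradient is the dominant
  geometry of the feature manifold; a root chosen inside a dense,
  undifferentiated cloud resolves ordering within that cloud poorly.
- The three-level model needs several donors with many lobules each;
  Satterthwaite df for the donor-level slope are approximate at K = 5
  donors, and boundary slope variances are common there.
- Adjacency depends on the declared cell-contact rule; other reasonable
  rules (centroid distance, shared border length) would order pairs
  similarly but not identically.
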