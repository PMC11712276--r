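---
title: "Methods: phylogenetic regionalization, its nulls, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic regionalization, its nulls, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylorealms)
```

This vignette documents the models and procedures implemented in
`phylorealms`, the conventions we pinned where the methods literature leaves
choices open, what the synthetic-data generator does and does not emulate,
and the known limitations. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The regionalization chain

### Turnover

Beta diversity between two cells is measured by the Simpson (turnover-only)
index, $\beta_{sim} = \min(b,c)/(a+\min(b,c))$, which ignores nestedness: a
species-poor cell whose assemblage is a subset of a richer one scores 0.
The phylogenetic version replaces species counts by branch lengths of the
tree spanned by each assemblage: a branch is present in a cell iff at least
one descendant tip occurs there, and $A$, $B$, $C$ are the summed lengths of
shared and unique branches. Two conventions matter:

* **Root edge.** The stem above the root is excluded from all branch sums
  (it is shared by every non-empty cell and its length is undefined),
  the standard convention; the edges descending from the root are included.
* **Reduction.** On a star tree with unit pendant edges, the phylogenetic
  index reduces exactly to the species-level index; this identity is a test.

Pairwise matrices are computed by sparse cross-products (cells x species
times its transpose), never per-pair loops, and verified against a naive
double loop on small instances. When a set of grafted trees is supplied,
per-tree matrices are averaged elementwise in a streaming fashion.

### Tree grafting

Species missing from the backbone are attached within their genus clade —
at a node drawn uniformly from the clade's basal node (the congeners' MRCA)
and all internal nodes below it — or within their family clade when no
congener is present. The methods sources do not state whether binding
targets nodes or edge midpoints; we pin the **node-uniform** reading, attach
by polytomy with pendant length equal to the node's height (which preserves
ultrametricity exactly, no re-dating), and split the pendant edge at its
midpoint when the clade is a single tip. Grafting order is sorted species
ids, so a single seed fixes the whole tree; a tree set uses seeds
`seed + 0 ... seed + n - 1`.

### Linkage, elbow, realms

Eight agglomerative criteria are supported (UPGMA, WPGMA, UPGMC, WPGMC,
single, complete, ward, ward2, via `stats::hclust`); `select_linkage` picks
the one whose cophenetic distances correlate best with the input
dissimilarities, breaking ties in that canonical order. The centroid/median
criteria can invert heights; cuts are defined by cluster count, so
inversions are tolerated and reported.

Explained variance of a partition is defined on **raw** dissimilarity sums,
$ev = 1 - \sum_{\text{within}} d / \sum_{\text{all}} d$ (a squared variant
is available behind a flag). This is the simplest definition with the
required boundary behaviour ($ev(1)=0$, $ev(n)=1$, monotone under
refinement); the source analyses print explained-variance percentages
without a formula, so the convention is ours and all tests pin it.

The number of regions is the **elbow** of the $ev(k)$ curve along dendrogram
cuts: the interior $k$ maximizing the perpendicular distance to the chord
from $(1, ev(1))$ to $(k_{max}, ev(k_{max}))$, ties to the smallest $k$.
Two details are deliberate:

* Endpoints always lie on the chord, so the search is restricted to
  interior $k$; $k_{max} = 2$ forces $k = 2$.
* $k_{max}$ defaults to 30. The chord must extend well past the plausible
  region count: if $k_{max}$ sits just beyond the true $k$, the chord slope
  approaches the per-region variance increment and the selection
  degenerates into a coin flip (we observed exactly this at
  $k_{max} = 20$ on the synthetic defaults).

Realms are the cut of the **same** dendrogram at the smallest $k'$ whose
explained variance reaches the threshold (default 0.60), so realms nest the
regions by construction.

### Diversity, endemism, ordination

Per region we report species richness of the union, Faith's PD of the union
(region-level, not averaged over cells), mean per-cell weighted endemism
($WE = \sum_{sp} 1/\text{range}_{sp}$) and phylogenetic endemism
($PE = \sum_{br} \ell_{br}/\text{range}_{br}$), and evolutionary
distinctiveness, the unweighted mean over other regions of the mean
between-region dissimilarity (a cell-count-weighted variant is a flag).
WE and PE telescope — summing either over all cells returns the species
count and the total branch length — and those identities are tested to
1e-9. The NMDS of the region x region mean-dissimilarity matrix uses
`vegan::monoMDS` (Kruskal stress-1, monotone regression, metric start).

## 2. Scheme comparison and its nulls

The V-measure compares two labelings of the same cells through the
contingency table: homogeneity $h = 1 - H(A|B)/H(A)$, completeness
$c = 1 - H(B|A)/H(B)$ (defined as 1 when the reference entropy is 0), and
$V = 2hc/(h+c)$, natural-log entropies, equal cell weights (on an equal-area
grid, count weighting equals area weighting; sub-cell land fractions are not
modelled). Significance comes from V against random **Voronoi**
regionalizations with the same number of regions as the comparison scheme:
seeds sampled uniformly among land cells, every cell assigned to the nearest
seed (ties to the lowest seed index), p-value by the add-one estimator
$(1 + \#\{V_{null} \ge V_{obs}\})/(n_{null}+1)$, which never returns 0.

Boundary distances are planar centroid distances to the nearest boundary
cell (a cell with a queen neighbour of a different label); the correlation
between two schemes' log distances (offset `log(d + cell_km/2)` keeps
boundary cells finite) is tested with a modified t-test in the spirit of the
Clifford–Richardson distance-class estimator: pairwise distances are binned
into 10 equal-width classes up to half the maximum distance, per-class
moment autocorrelations $\hat\rho_x(k)$, $\hat\rho_y(k)$ estimated, and

$$\widehat{var}(r) = \tfrac1n + \tfrac2{n^2}\sum_k N_k \hat\rho_x(k)\hat\rho_y(k),
\qquad \hat M = 1 + 1/\widehat{var}(r),$$

clamped to $[3, n]$, with $t = r\sqrt{(\hat M - 2)/(1-r^2)}$ on $\hat M - 2$
degrees of freedom. The exact estimator variant in the source literature is
ambiguous; this one is pinned and validated by calibration: on white-noise
fields $\hat M/n \approx 1$ and the type-I error sits in $[0.03, 0.07]$,
while on strongly autocorrelated fields the naive test rejects at over 15%
and the modified test stays near the nominal level (these are acceptance
tests).

## 3. The spatial boundary model

Whether a cell touches a boundary (queen adjacency; computed for all
boundaries, deep between-realm boundaries, and shallow within-realm
boundaries — the first is exactly the OR of the other two) is modelled as a
binomial-logit mixed model with one spatially structured random intercept
per analysis cell. The source names a "SAR/HGLM" without an estimator; we
pin:

* a **proper-CAR** prior with precision $Q = D - 0.95\,W$ on the binary
  adjacency $W$ of cells within `neighbor_km` (default 282.84 km — on a
  100-km grid, twice the diagonal neighbour distance; `"auto"` recomputes
  the smallest radius connecting every analysis cell to at least one other);
* **penalized quasi-likelihood** (Breslow–Clayton working linear mixed
  model), with the random-effect variance re-estimated at every outer
  iteration by profiling the REML criterion of the working model
  (1-D optimization), tolerance 1e-6 on the fixed effects, at most 200
  iterations; non-convergence is flagged, never silently replaced;
* predictors centred and scaled internally, the analysis restricted to
  cells within 200 km of a boundary (avoiding extreme zero inflation far
  from boundaries);
* effect sizes as Fisher's z through the Wald chain
  $z = \operatorname{atanh}\!\big(w/\sqrt{w^2 + (n-p)}\big)$ with $w$ the
  Wald statistic — the source states only that effect sizes are Fisher's z,
  so this chain is our documented convention. It makes effect sizes
  invariant to predictor units (tested).

PQL attenuates binary-data coefficients and smooth predictors compete with
the spatial field (spatial confounding), so absolute coefficient values
should be read cautiously; the model's validated surface is sign recovery
of planted effects and type-I calibration of null predictors, both
acceptance-tested. On responses that are (near-)deterministic functions of
a predictor — e.g. a realm boundary perfectly marked by a terrain step —
quasi-separation can prevent convergence; the fit is returned with its
diagnostics and `converged = FALSE`.

Predictors follow the conventional definitions: focal CV (sample SD over
the focal cell and available queen neighbours divided by the absolute
window mean, `NA` when the mean is 0), TRI (mean absolute difference to
available neighbours; no padding at edges or coasts), and LGM climate
velocity $v = (|\Delta T|/\Delta t)/\max(g, 10^{-9})$ with $g$ the local
gradient magnitude of the present layer by central differences (one-sided
at edges); flat-field cells hit the $\varepsilon$ floor and are reported.

## 4. Node-based indicator clades

The node screening statistics are operational definitions pinned by this
package (the original node-based software defines them only informally):
for an internal node with daughters A and B (a polytomy's extra daughters
pool into B),

* **SOS**: per occupied cell, the standardized deviation of daughter-A
  richness from a null that permutes the A/B membership over the node's
  species, preserving every species' range and the clade sizes
  ($sd_{null}=0 \Rightarrow 0$). The null is always drawn for the canonical
  first daughter (the set holding the smallest species id) and the B side
  is each draw's complement, so swapping the daughters negates every score
  exactly.
* **GND**: with $p_A(s)$ the local share of daughter-A richness and $P_A$
  the global share, $D_{obs} = \overline{|p_A - P_A|}$ over occupied cells,
  rescaled between the permutation-null mean and
  $D_{max} = \overline{\max(P_A, 1-P_A)}$, clipped to $[0,1]$. Disjoint
  daughter ranges score near 1, identically distributed daughters near 0
  (both acceptance-tested); no numerical equivalence with the original
  software is claimed.

Nodes passing the screen (default GND > 0.65) are regressed — OLS of SOS on
realm membership, $R^2$ equal to the squared point-biserial correlation —
for every unordered realm pair; a node is an *indicator* for a pair when its
mean SOS changes sign between the realms. In the desk-scale synthetic world
the widespread and realm-wide occupancy tiers place members of both
daughters in every cell, capping GND near 0.3; the default screen then
retains nothing, which is the correct behaviour, and the analysis script
falls back to an explicitly labelled exploratory threshold.

## 5. The synthetic world

The generator plants a known truth: contiguous regions grown from
farthest-point seeds by balanced competitive growth (smallest region claims
the frontier cell nearest its seed), merged into contiguous realms by the
same balanced growth on the region adjacency graph; a pure-birth (Yule)
phylogeny rescaled to root age 100 (the birth rate is irrelevant after
rescaling); and environmental layers with realm steps.

**Clade-to-region assignment.** The documented design we started from —
recursive bipartition of the tree matched to the realm/region hierarchy,
largest clades first — degenerates on unbalanced Yule topologies (a root
split of 1 vs n-1 tips starves whole realms of species; we observed a
76-cell region with a single endemic). The implemented rule instead
decomposes the tree into *tribes* (maximal clades of at most
$\lceil n/2k \rceil$ tips), packs consecutive tribes into $k$ bins by an
optimal contiguous dynamic programme minimizing the worst deviation from
the even share, and hands bins to regions with same-realm regions adjacent.
No clade is ever split between regions, and endemic counts stay near-even
on any topology.

**Occupancy tiers.** The turnover structure has four tiers: regional
endemics occupy home-region cells with `p_in = 0.6` and all other cells with
`p_out = 0.02`; a *bleed* tier adds `p_realm = 0.08` occupancy in same-realm
cells within one queen ring of the home region (ranges spill over into the
adjacent part of their realm; realm boundaries act as dispersal barriers);
`realm_widespread_frac = 0.10` of species range over their whole realm; and
`widespread_frac = 0.10` are globally widespread. The two realm tiers exist
because Simpson phylogenetic beta on a Yule tree carries almost no
realm-depth signal from clade nesting alone — the deep "spine" branches
shared by sister regions are short, and we measured within-realm vs
between-realm dissimilarities of 0.46 vs 0.49 without the tiers, which
makes a 60%-variance realm cut unrecoverable. Real biotas have nested
turnover mostly because range sizes are hierarchical (regional, realm-wide,
cosmopolitan species); the tiers encode that. When `p_in == p_out` all
tiers collapse to the same rate, so the explicit no-signal world stays
signal-free. Every land cell is guaranteed at least one species by copying
one species in from the nearest occupied cell (deterministic, minimal
distortion); every species is guaranteed at least one cell within its home
range.

**Environment.** Layers carry plausible nonzero baselines (so constant
layers have CV 0, not 0/0). Only temperature (`temp_present`) and
`elevation` carry the realm step — the synthetic realms are climatically
and topographically delimited — while the four seasonality/annual layers
are independent smooth noise (3x3 mean-filtered white noise; a cheap
substitute for a Gaussian-process sampler with adequate autocorrelation at
desk scale). Elevation gets five-fold noise. An earlier design stepping all
layers identically made the focal-CV predictors near-duplicates
(VIF ~ 1000) and the realm response separable; the implemented design keeps
all VIFs below 2, as the boundary models require. `temp_lgm` is
`temp_present` plus a smooth south-to-north cooling offset.

**What a green test does and does not establish.** The generator produces
compact regions of comparable size, balanced endemic counts, and
homogeneous within-region occupancy. Real range data have richness
gradients, range-size skew far beyond three tiers, coastlines and
projection artefacts, and sampling error — none of which are emulated
(realistic geography and fitted diversification models are out of scope).
Recovery of the planted truth therefore validates the *method chain*, not
the difficulty of any real dataset.

## 6. Numerical choices and degenerate inputs

* Dissimilarity matrices are dense; at the desk scales used here
  (hundreds of cells) this is far below memory limits. Averaging over tree
  sets is streaming.
* Ties: linkage ties resolve by `hclust`'s ordering; Voronoi distance ties
  to the lowest seed index; elbow ties to the smallest k; linkage-selection
  ties to the canonical method order.
* Degenerate inputs raise classed errors rather than silent results: empty
  cells in Simpson beta, single-region schemes in boundary distance,
  zero-variance vectors in correlations, all-0/1 responses in the boundary
  model, unplaceable species (family absent from the backbone) in grafting.
  Linkage methods whose cophenetic distances are constant are skipped
  during selection with `NA` coefficients.
* Seeds: every stochastic function takes an explicit seed; the pipeline
  derives per-stage seeds from the master seed by fixed offsets
  (`seed * 1000003 + offset mod 2^31 - 1`) so stages can be rerun in
  isolation.

## 7. Known limitations

* PQL is the only estimator for the boundary model (no INLA-style
  alternative), and its coefficients are attenuated; inference rests on
  signs, relative effect sizes and the calibration tests.
* The V-measure operates on the common grid; polygon-overlay comparison of
  vector regionalizations is out of scope, as is acquiring published
  reference schemes (they can be supplied as cell-label CSVs).
* GND/SOS are this package's operational definitions; scores are not
  numerically comparable to other node-based software.
* The elbow is a heuristic; on worlds with weak hierarchical contrast the
  selected k can drift by one or two, which is why the planted-truth
  acceptance criterion is a success *rate* over seeds rather than a
  per-seed guarantee.
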