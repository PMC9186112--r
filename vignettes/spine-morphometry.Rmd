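---
title: "Methods: automated spine morphometry from light-microscopy meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated spine morphometry from light-microscopy meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinemorph)
```

# The problem and the pipeline

Dendritic spines imaged by confocal microscopy and reconstructed as triangle
meshes arrive in varying states of completeness: the ~200 nm resolution
limit of light microscopy makes thin spine necks invisible or fragments the
reconstruction into pieces. `spinemorph` takes per-spine meshes (coordinates
in micrometers) plus the dendritic-shaft insertion point of each spine and
produces per-spine morphometry and population statistics, via five stages:
classification by completeness, computational neck repair, unsupervised
head/neck separation, measurement, and statistics.

All geometry is carried in micrometers internally; diameters are reported
in nanometers only at the output layer, matching the conventions of the
morphometry literature. Meshes derived from confocal stacks should be
z-corrected (`apply_z_correction`, factor 0.84 for the datasets this
package targets) exactly once, at load time; the correction is a
dataset-level acquisition setting in the manifest, not a per-spine choice,
and the manifest makes it explicit rather than guessing per species.

# Completeness classes and repair

* **A** – one component, separable into head and neck.
* **B** – one component, not separable (sessile or filopodium-like).
* **C** – one component whose nearest vertex lies ≥ 0.2 µm from the
  insertion point: a detached head with an invisible neck.
* **D** – two components.
* **E** – three or more components; discarded (complex shape, little data).

The 0.2 µm anchor threshold is the light-microscopy resolution proxy: a gap
smaller than that is not evidence of a missing neck. Repair adds a cylinder
of radius 0.17 µm (human) or 0.14 µm (mouse) — the median group-A neck
radius of each species, which a two-pass workflow can also recompute from
its own data (`resistance_report` exposes the group medians). Group C gets
a cylinder from the insertion point to the nearest mesh vertex; group D
gets a bridge between the mutually closest vertex pair of its two
components, followed by a neck extension if the bridged mesh still leaves
an anchor gap. Ties in the closest pair are broken toward the lowest vertex
index for determinism. The cylinder is welded to the existing mesh by a
triangle fan onto the nearest vertex: measurement needs a closed head and a
connected surface, not a physically fused neck. Repair only ever *adds*
geometry — original vertices and faces are untouched — which is what makes
head volume invariant under repair (checked to 2% in the test suite).
Because the cylinder radius is an arbitrary constant, neck diameter is
never reported for repaired spines; they contribute head volume and neck
length only.

For group D the insertion point does not identify which component is the
anchor; the implementation bridges the closest pair regardless and records
the operations in the provenance log.

# Head/neck separation

Two per-face features drive the separation:

* **Shape diameter function (SDF)**: rays are cast from each face centroid
  into the mesh interior, spread over a deterministic Fibonacci spiral in a
  120° cone around the inward normal (25 rays per face by default). Each
  chord is normalized by the cosine of its angle to the inward normal —
  on a sphere every normalized chord then equals the diameter exactly — and
  the per-face value is a low quantile (25th percentile) of the normalized
  chords after interquartile outlier rejection, followed by one
  neighbor-averaging pass. The low quantile compensates the upward bias
  that tilted rays acquire on tubes; the residual bias on a cylinder is
  about +3–4%, within the tolerances used for diameters. Holes are capped
  (centroid fans) before casting so chords terminate; faces whose rays all
  miss are imputed from neighbors and flagged.
* **Skeleton distance**: distance from the face centroid to the curve
  skeleton. The skeleton is produced by mean-curvature-flow style
  contraction (iterated sparse least squares with a uniform graph
  Laplacian, contraction weight doubled each of 6 rounds), followed by
  merging vertices along short contracted edges, a minimum spanning tree
  over the merged clusters, and a leaf-extension step that pushes each
  skeleton end back out to the centroid of the extreme vertices of its
  cluster (contraction pulls tube ends inward; the extension restores the
  lost length, keeping total skeleton length of a capped cylinder within a
  few percent of its true length). Sphere-like meshes collapse to a single
  node and are flagged. The insertion point is attached to the skeleton as
  an anchor node so distances and arc lengths reach the spine base.

A two-component bivariate Gaussian mixture is fit to the standardized
features by EM (both features are micrometer-valued but have different
dynamic ranges, hence the standardization; the method description this
follows is silent on scaling). Initialization is deterministic: quantile
splits of the SDF at 0.3–0.7, five restarts, best likelihood kept. The
component with the lower mean SDF is the neck. The GMM is fit per spine,
matching the behavior of per-object segmentation tools.

The soft labels are refined by an exact minimum s–t cut minimizing

```
E = sum_f -log P(label_f) + lambda * sum_{f~g} w(theta) [label_f != label_g]
```

with λ = 0.5 (appropriate for the smooth meshes light microscopy produces)
and a dihedral weight that makes cuts cheap only at sharp concave creases:
for concave edges `w = clamp(-log(alpha/pi), 1e-6, 10)` with `alpha` the
angle between face normals, and `w = 10` for convex edges. (A small
constant on convex edges would let the cut wander freely across the convex
head, defeating the smoothness term; the head–neck junction is precisely a
concave crease, so that is where cuts become cheap.) Posteriors are clamped
to `[1e-3, 1-1e-3]` so a handful of overconfident faces cannot pin the cut.
After the cut, disconnected label patches below 20% of their class are
absorbed into the other class: around features like the basal cap the
crease makes cutting *around* an island nearly free, so the smoothness term
alone cannot remove it. The energy optimality of the raw cut (never worse
than the posterior argmax) is asserted in the tests with the island
post-process disabled.

## The separability decision (group A vs B)

The source methodology never states an operational criterion for "could not
be separated"; the following is this package's documented choice. A spine
is separable when:

1. both regions have at least 5 faces (guards against single-face necks);
2. each region is connected (vertex-wise, so vertex-welded repair
   cylinders count);
3. the face nearest the insertion point carries the neck label;
4. the mixture components do not collapse: the neck cluster's mean SDF must
   be at least 1.3× thinner than the head cluster's — otherwise there is no
   thin compartment at all;
5. the measured neck is at least 0.2 µm long — the same resolution proxy as
   the anchor rule. Without this, the cut can shave the flat basal cap off
   a sessile dome and call it a neck.

# Morphometry

* **Head volume/area**: the head submesh is capped at the label boundary
  with a centroid fan and integrated by the divergence theorem. The cap is
  included in the head area entering sphericity (the closed-surface
  convention; the methods description leaves this open, and the cap
  contribution is second-order for near-planar junctions).
* **Sphericity** `= π^(1/3) (6V)^(2/3) / A`: 1 for a sphere,
  scale-invariant, ≤ 1 by the isoperimetric inequality (up to
  discretization).
* **Neck length**: arc length along the skeleton from the insertion anchor
  to the point of the skeleton closest to the boundary-ring centroid
  (projected onto skeleton edges, so a final node already inside the head
  is not overcounted). Arc length — not the Euclidean chord — is the
  documented choice: it degrades gracefully to the chord for straight
  necks and tracks tortuous necks, which the chord underestimates (a 90°
  bend of arc 0.6 µm has a 0.42 µm chord).
* **Neck diameter**: median SDF over neck faces, ×1000 to nm; group A only.
  Values below the 200 nm resolution proxy are flagged `sub_resolution`,
  not censored — synthetic data can legitimately go below it.
* **Spine length**: distance from the insertion point to its nearest
  skeleton node plus the longest skeleton arc from there; the leaf
  extensions make the arc reach the spine tip. Collapsed skeletons fall
  back to the maximal insertion-to-vertex distance, flagged.
* **Spine volume**: signed volume of the capped mesh, orientation repaired
  once if negative; computed for every group except E, including B.

# Statistics

* **Density histograms**: bin heights are counts divided by total count and
  by bin width *on the original axis*, so the area integrates to 1 for both
  linear and geometric (log-scale) bins; the latter are the right
  representation for the right-skewed, roughly log-normal morphometric
  features.
* **Mann–Whitney U** on midranks; for `n_x + n_y <= 16` the two-sided p is
  exact from the full permutation distribution (computed by subset-sum
  counting over doubled midranks, so ties are handled exactly); larger
  samples use the normal approximation with tie and continuity corrections.
  The exact branch is verified against explicit enumeration over all
  `choose(n, n_x)` assignments in the tests.
* **Hartigan's dip statistic**: the maximum distance between the empirical
  CDF and the nearest unimodal CDF, computed by the classical
  greatest-convex-minorant / least-concave-majorant refinement of the
  modal interval (C++, near-linear per sample). At the modal endpoints the
  fitted CDF may jump (an atom at the mode), so those knots carry no corner
  deviation of their own — omitting this detail breaks heavily tied
  samples. The implementation agrees to 1e-10 with an independent
  brute-force oracle (bisection over band feasibility across all mode
  placements) for n ≤ 8, and was cross-validated during development against
  the reference R implementation on tens of thousands of random samples.
  Note the dip is *not* invariant under monotone transforms (convexity is
  not): only positive affine invariance is asserted.
* **Dip test**: bootstrap p against the uniform(0,1) null, the canonical
  conservative reference; `n_boot` defaults to 2000 (p resolution 5e-4).
* **2D/3D dip tests**: the statistic is the maximum 1D dip over projections
  of the standardized sample onto a fixed grid (36 half-turn angles in 2D;
  64 Fibonacci-hemisphere directions in 3D — the dip varies smoothly with
  direction, so modest grids suffice; both are configurable). The p-value
  is calibrated by applying the identical max-over-directions procedure to
  samples from a multivariate Gaussian with the data's mean and covariance,
  which absorbs the max-induced multiplicity; a rank-deficient covariance
  is ridge-regularized and flagged. Because the null reference here is a
  documented substitute (the original procedure's null is unspecified),
  published multidimensional p-values are not reproduction targets.
  Features are dip-tested on raw values in 1D; projections use
  standardized coordinates so no axis dominates by units.
* **Spearman/Wald**: Spearman's rho on midranks with the two-sided Wald
  t-test for zero slope of the rank–rank regression.

# The resistance model

`R_neck = rho * l / (pi r^2)` with cytosolic resistivity `rho` deliberately
left out: `resistance_index` returns `l/(pi r^2)` (1/µm), ratios are
resistivity-free, and `absolute_resistance` anchors to a published
reference measurement. Population ratios use medians-of-geometry (the
median length and the median radius, radius = diameter/2 rounded to the
nanometer, mirroring how published medians are quoted), not the median of
per-spine ratios; `resistance_report` exposes the per-spine-median
alternative alongside. Only unrepaired group-A spines enter (diameter
required).

# The synthetic generator: what it emulates and what it does not

`make_spine` builds spines as lathed surfaces: an ellipsoidal head
truncated where its cross-section matches the neck, joined to a tube that
is circular at the base and blends into the elliptical truncation ring
(the blend emulates junction flare). The weld ring is the exact
ground-truth head/neck boundary. Degradations mirror the completeness
classes: B is a sessile dome (ellipsoid truncated at 85% of its width,
seated directly on the base — no neck exists by construction), C omits the
neck entirely, D splits it into a detached basal fragment plus the head
with a stub, E adds a floating fragment. Default tessellation (resolution
2) keeps the discretized head volume within ~1.5% of the analytic
ellipsoid volume; resolution 1 (≈ 600 faces) is used for the large test
suites and stays within ~4%.

`sample_population` draws feature tables from log-normal marginals coupled
by a Gaussian copula (latent Pearson correlation `2 sin(pi rho_s / 6)` to
hit Spearman targets). The default medians (head volume 0.32 µm³, neck
length 0.594 µm, neck diameter 339 nm) are published human group-A medians;
the multiplicative spreads (sdlog 0.7, 0.7, 0.33) were chosen once so the
simulated ranges match the published min–max spans, and the default rank
correlations (0.25, 0.4, 0.1) are plausible mid-range values for these
features. `make_bimodal_population` provides the negative control for the
dip tests.

The generator emulates mesh-level degradations only. It does not simulate
the imaging point-spread function, intensity noise, or the systematic
neck-thinning/head-inflation of light microscopy — no quantitative model of
those is available to emulate — so green tests establish that the
*algorithms* recover known geometry, not that the pipeline corrects imaging
bias. Optional vertex jitter (`jitter_sd`, as a fraction of neck radius)
supports robustness checks and is off in oracle tests.

# Numerical choices and limitations

* Degenerate faces are dropped at load with a message; silent NaNs
  downstream are worse than a logged repair.
* Binary PLY is rejected (ASCII PLY and OBJ are supported); manifests are
  JSON (YAML accepted when the `yaml` package is installed).
* All randomness flows from explicit integer seeds; the pipeline derives
  per-spine seeds by a stable hash of the spine id, so results are
  independent of processing order, and reruns are byte-identical.
* Group E is discarded without attempting iterative bridging of ≥ 3
  components; whether that was ever valid upstream is unknown, so it is
  not implemented.
* The separability guards (SDF ratio 1.3×, 0.2 µm minimum neck) are
  package choices where the upstream criterion is undefined; both are
  anchored to interpretable quantities (a neck must be distinctly thinner
  than the head, and longer than the resolution limit) rather than tuned
  constants.
* Published dataset-level numbers (group percentages, dataset medians,
  dip-test p-values on the confocal datasets) depend on data that is not
  deposited; the test suite replaces them with property-based checks
  against generator ground truth, and the acceptance report recomputes
  only the closed-form species comparisons.
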