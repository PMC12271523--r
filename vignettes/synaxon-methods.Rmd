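---
title: "Methods: clustering, synthesis and connectivity of long-range axons"
author: "synaxon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering, synthesis and connectivity of long-range axons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Long-range axons (LRAs) carry most inter-regional connectivity in the
mammalian brain, but reconstructed LRAs are scarce: a few thousand cells
against tens of millions. `synaxon` implements a workflow that generalizes
from a sparse set of reconstructions to whole populations of synthetic
axons embedded in a voxel brain atlas, and derives the resulting
single-cell connectome and region-level projectome. The pipeline has three
stages:

1. **Projection clustering.** Each reconstructed axon $a$ with soma in
   source region $s_a$ is summarized by its projection pattern: the vector
   $t_a \in \mathbb{N}^B$ of terminal counts per target region, or the
   vector $l_a \in (\mathbb{R}^{0+})^B$ of axonal path length per target
   region. Axons of one source region are clustered with a Gaussian
   mixture model (GMM) fitted by expectation–maximization (EM); the number
   of components is chosen by the Bayesian Information Criterion (BIC) or
   imposed.
2. **Synthesis.** For each new soma, a cluster $c$ is drawn with
   probability $p_c$; target regions are drawn from the cluster's
   empirical targeting probabilities; target points are placed uniformly
   inside each region; a trunk is routed with a weighted Steiner tree on an
   in-brain voxel lattice whose edges are discounted inside fiber tracts
   (white matter); the trunk is post-processed (straightening of lattice
   artifacts, then controlled curvature noise); tufts — the terminal
   arbors — are grown at the target points from persistence barcodes of
   reconstructed tufts, selected with probability proportional to their
   representativity scores.
3. **Connectivity.** Axo-dendritic touches are detected by segment
   proximity, filtered by a minimum inter-bouton interval, pruned to a
   physiological synapse density, and aggregated into a neuron adjacency
   matrix and a region projectome.

Every stage is testable without external data: the package ships a
toy-atlas builder and a synthetic-population generator with known ground
truth.

# Data model

Morphologies are rooted trees of 3D points with radii and SWC structure
types (`Morphology`). Pass-through points (exactly one child) are interior
polyline geometry; *sections* are derived as maximal unbranched chains, so
no section boundary is a unifurcation and sanitization never destroys
geometry. Multi-point somata are collapsed to their centroid on read. Only
this minimal sanitization of the upstream repair process is implemented;
cut-branch repair is out of scope.

The atlas (`BrainAtlas`) is an integer annotation raster (0 = outside), an
Allen-style region hierarchy, and a boolean fiber-tract mask. World
coordinates are micrometres; a point belongs to voxel
$\lfloor (x - o)/v \rfloor$ (half-open ownership). Hemispheres split at a
midline plane; a point exactly on the midline is "right" (a documented
tie-break). Region lookups can be lifted to any hierarchy depth, since
regions can be defined at several levels of detail; the level used for
projection features is a configuration parameter.

Projection features of a population are stored as a
`SummarizedExperiment` with assays `terminals` and `lengths` (rows =
regions, columns = axons). Contralateral targets are separate vocabulary
entries suffixed `"_contra"`, so ipsi/contra targeting survives
clustering. Because the same region id annotates both hemispheres, the
hemisphere tag of a terminal is taken from the terminal's own position
relative to the soma's hemisphere.

Two deliberate conventions in the feature computation:

* lengths are restricted to *termination* regions (at least one terminal);
  pass-through cable is discarded by default (`includePassThrough` keeps
  it);
* segment region membership is decided by the segment midpoint, without
  splitting segments at voxel boundaries — the error is bounded by the
  voxel size.

# Gaussian mixture clustering

The mixture density, posterior responsibilities and log-likelihood are the
standard forms; all densities are evaluated in log space and posteriors
are log-sum-exp stabilized. The M-step uses the weighted maximum-likelihood
updates under the covariance constraint. The default covariance is
*spherical* (one scalar variance per component), the structure selected in
practice by BIC on projection data; diagonal covariance is available, and
full covariance is supported for density evaluation but not fitting.

Choices that matter:

* **Initialization.** k-means++-style distance-weighted seeding refined by
  up to 10 Lloyd iterations, 10 restarts, tolerance $10^{-6}$ on the
  log-likelihood, at most 500 iterations. The Lloyd refinement exists for a
  concrete reason: without it, restarts occasionally converge with one
  component collapsed onto a single outlier point.
* **Variance floor.** Components are floored at 1% of the mean
  per-dimension data variance (`varFloorFrac = 1e-2`). A much smaller
  floor (e.g. $10^{-6}$) provably corrupts BIC selection: a component
  collapsed onto one point gains more log-likelihood from its diverging
  density than its BIC parameter cost, so model selection prefers spurious
  spike components. At 1% a singleton component can still form (duplicate
  projection patterns are common in the small-$N$ regime) but cannot buy
  its parameters with a density singularity.
* **BIC convention.** $\mathrm{BIC} = \kappa \ln n - 2\,l(\theta)$ with
  $\kappa$ the free-parameter count (spherical:
  $(C-1) + CB + C$); *lower is better* and selection uses the argmin.
  This is the same criterion as "maximize the BIC score" under the
  opposite sign convention.
* **Cluster-count range.** The operating default searches
  $C \in \lceil N_s/2 \rceil .. N_s$ per source region — the regime used
  when the goal is reproducing rather than describing the data. Recovery
  experiments on separated blobs use an explicit wider range (`cRange`),
  since the default range cannot contain a small true $C$ at large $N$.
  Degenerate populations collapse the range ($N_s = 1 \to C = 1$ with the
  variance at the floor).
* **Empty components** are re-seeded from the point with the lowest
  maximum posterior; the monotone log-likelihood trace restarts there.

Virtual axons are sampled by drawing a component with probability $p_c$
and a vector from its Gaussian; negatives are clipped to zero and entries
in regions unobserved among the component's (hard-assigned) training
members are zeroed — the post-processing that removes values sampled in
regions absent from the biological input.

# Tufts

Axon terminals are agglomerated by single linkage under a dual threshold:
two terminals may merge iff their Euclidean distance **and** their tree
path distance are both within 300 um (the operating clustering radius and
path distance). Clusters are the connected components of this constraint
graph — single linkage is used because it is parameter-free beyond the two
thresholds and brute-force verifiable. Each multi-terminal cluster becomes
a tuft rooted at the lowest common ancestor (LCA) of its terminals. The
tuft subtree is the ancestor plus the nodes below it whose descendant
terminals all belong to the cluster; when the ancestor sits on a
through-going trunk, the downstream cable stays in the trunk. The ancestor
node belongs to the tuft, the trunk ends at it (a duplicate seam point
appears on re-serialization), and node conservation
$|\mathrm{trunk}| + \sum_t |\mathrm{tuft}_t| = |\mathrm{axon}|$ is exact;
in the rare case of two clusters sharing an ancestor only the first owns
the node.

The topology of a tuft is summarized as a persistence barcode of the
path-distance filtration from the tuft root, with the elder rule: at each
bifurcation the child with the larger maximal descendant path distance
survives; every other child is born there. One bar per leaf.

Tufts are grouped by (GMM cluster, ancestor region), with per-group mean
and variance of per-axon tuft counts. The variance is the population
(MLE) variance, matching the mixture module's conventions. Each tuft gets
a *representativity score*: per feature (total length, leaf count, maximal
path distance, mean section length), the absolute deviation from the group
median in units of the group spread (half the 5th–95th percentile range —
the same spread as the MVS machinery); the score is
$\max(0, 1 - \overline{d_f})$, so a group-typical tuft scores near 1 and
singleton groups score exactly 1. This concrete formula is the package's
instantiation of a score whose published definition lives in supplementary
material; it is isolated behind `representativityScores()` for easy
replacement.

# Synthesis

**Graph.** Vertices are in-brain voxel centers on a sublattice (default
stride 2 voxels; the packaged demo uses stride 1 because its toy atlas is
only 16 voxels per hemisphere and a coarser lattice visibly quantizes
trunk geometry), plus the soma and target points snapped to their nearest
lattice vertex. Edges connect 26-neighbours; the weight is the Euclidean
length times the fiber discount $\alpha$ when both endpoints are in the
fiber mask (default $\alpha = 0.5$; no published value exists, and 0.5
makes a white-matter detour of up to twice the direct length preferable).

**Steiner tree.** Two standard constructions are built — iterative
nearest-terminal shortest-path insertion, and the classical metric-closure
MST expanded to shortest paths — each refined by an MST over its vertex
set with non-terminal leaves pruned, followed by a key-path exchange local
search (every tree path between branch/terminal vertices is swapped for
the true shortest path between the components it separates, until no swap
helps). No step increases the weight, so the 2-approximation guarantee of
the base constructions is preserved. On random instances with up to 60
vertices and 6 terminals the result matches the exact Dreyfus–Wagner
optimum in almost nine cases out of ten and is never more than ~12%
heavier (the exact dynamic program ships as `exactSteinerWeight()` and is
exponential only in the terminal count).

**Trunk post-processing.** Each tree path is first straightened by greedy
line-of-sight simplification (a shortcut is kept only when the chord stays
inside annotated brain) — this removes lattice artifacts (zig-zag and
snap-vertex doglegs), which is exactly the kind of non-biological local
geometry the post-processing stage is meant to replace. The path is then
resampled at a fixed step with the emitted direction
$(1 - n - r)\,\hat{u}_{\text{waypoint}} + r\,\hat{u}_{\text{previous}} +
n\,\xi$, $\xi$ a unit Gaussian: noise $n$ roughens local geometry, local
history $r$ smooths curvature, and endpoints (source, targets, branch
points) are preserved exactly. Tortuosity is $\geq 1$ and increases with
$n$ (defaults $n = 0.1$, $r = 0.2$, step 50 um).

**Tuft growth.** A tuft is selected for each target point from the library
group (cluster, region) with probability proportional to representativity
(the simplest monotone choice); a missing group falls back to the nearest
region among the cluster's groups by border distance, logged. Growth is
simplified barcode-driven: one tip starts at the target point along the
incoming trunk direction; when a tip passes the birth distance of an
unassigned bar a sibling spawns there; a tip terminates exactly at its
bar's death distance. Leaf count equals bar count and terminal path
distances land on the death values. Directions persist with Gaussian
noise; growth is constrained to the (hemisphere-resolved) target region —
candidate steps that exit are redrawn, then steered back — which is the
mitigation for tufts extending beyond their intended areas and guarantees
every selected region retains a terminal. Radii are constant (default
0.5 um); diameter synthesis is out of scope.

**Determinism.** One master seed deterministically spawns per-stage,
per-neuron substreams via a hash (`deriveSeed()`), so execution order
cannot change results and identical configuration + seed give
byte-identical SWC output.

# Connectivity

Touches are all (axon segment, dendrite segment) pairs of distinct
neurons with minimal segment–segment distance within the touch distance
(default: sum of radii + 1 um; no published value exists). A uniform
spatial hash over segment midpoints generates candidates with a cell size
that guarantees the result is identical to the all-pairs computation; the
brute-force path ships as `detectTouchesBruteForce()` and the equality is
asserted on every test scene. Touches are then filtered per (axon, branch)
by a greedy minimum inter-bouton interval scan (default 5 um) and pruned
per postsynaptic neuron to a synapse density (default 0.1/um of dendrite)
by uniform random subsampling — the physiological filtering specifics of
the upstream circuit-building pipeline are out of scope. Aggregation
yields the sparse neuron adjacency, the region projectome (pre soma region
to synapse region), out-degrees (distinct partners by default; synapse
count as a variant), and the diagnostic tables connections-vs-border
-distance and connections-vs-axon-length. In the latter, feature rows are
folded onto base acronyms because synapse locations are absolute while
feature rows are soma-relative.

# Validation machinery

Reference normalization is $(\tilde P_r - V(a)) / \sigma(P_r)$ — note the
printed orientation, median **minus** value, so one reference standard
deviation *below* the median maps to $+1$. The Maximum Visible Spread
(MVS) score between two samples is
$|\mathrm{med}(P) - \mathrm{med}(Q)| / \max(\mathrm{spread}(P),
\mathrm{spread}(Q))$ with spread = half the 5th–95th percentile range
(window configurable); $< 0.1$ flags strong significance (`**`), $< 0.5$
non-randomness (`*`). Both spreads zero gives 0 for equal medians and
$+\infty$ otherwise. The concrete formula is isolated behind
`mvsScore()` because its published definition defers to supplementary
material.

# The synthetic-data generator

`demoToyAtlas()` builds a 32 x 16 x 16 voxel volume at 100 um with
mirrored hemispheres, a presubiculum-like source region (PRE), seven
target regions under two mid-level parents, one region split into two
layer-like leaves (to exercise hierarchy lifting), a connected background
region, and fiber corridors from the source towards two targets. Corridor
voxels stop at region borders — white matter lies between gray regions;
letting corridors run to region centroids would pull discounted trunks
deep into target regions, which has no biological counterpart.

`demoPopulationSpec()` defines the standard demo: 59 axons from PRE in 5
clusters with distinct target menus and per-region mean tuft counts
(2–3), echoing the scale of the reference clustering demonstration (five
clusters imposed over 59 presubiculum axons). One cluster targets the
contralateral hemisphere. Per axon, the generator samples a soma and tuft
points, routes a trunk as a greedy nearest-point insertion tree of
straight chords (each point attaches to the nearest node of the existing
cable, as axon collaterals do — deliberately *not* the package's
lattice/Steiner code path, so fixtures stay independent of what they
test), and attaches V-shaped two-terminal tufts whose common ancestor is
the sampled point itself. Tuft placement retries until the leaves land in
the intended region, so at zero count noise the generated terminal counts
match the specification exactly. Trunk points carry 10 um jitter on 60 um
segments (~8% tortuosity, the scale seen in reconstructions; perfectly
straight fixture trunks would bias every in-region length comparison
against the noise-postprocessed synthesized trunks).

What the generator does *not* emulate: reconstruction artifacts (cut
planes, swapped radii), realistic branching statistics inside tufts
(always two terminals), region-specific laminar targeting, and real
fiber-tract geometry. Passing the end-to-end comparisons therefore shows
that the pipeline reproduces the projection structure *it was given*
under controlled conditions — not that it reproduces any particular real
dataset.

`generateScene()` provides postsynaptic material: stellate dendritic
neurons (default rays resampled at 25–40 um) placed uniformly in the
brain, with ray directions redrawn so dendrites stay inside annotated
tissue. The connectivity demonstration uses 100 cells with 8 mm of
dendrite each — the total dendritic length scale of a pyramidal cell; much
shorter dendrites make the dendritic field so sparse that per-region
synapse counts are dominated by clumping noise.

# Problem sizes and numerical choices

The packaged analyses run at deliberately small sizes: 59-axon
populations, a 32 x 16 x 16 voxel atlas, lattice stride 1 (about 4,000
routing vertices), 100-neuron dendritic scenes, 20-seed recovery
experiments at $n = 200$, 50 Steiner oracle instances, 100 random trees
for the tuft oracle. The full test suite runs in about four minutes.
Stochastic end-to-end comparisons are evaluated at fixed seeds; across
seeds the per-region MVS criterion fluctuates (medians of 5–10 values),
and the connectivity linearity sits near its threshold
(dendritic-field clumping at 100 cells), which is the expected behaviour
of these statistics at this scale, not an implementation artifact — the
deterministic oracles (touch detection, tuft partition, Steiner bounds)
hold exactly on every run.

Other numerical details: angles are radians internally; variances floored
as described; `N(mean, sd)` tuft-count draws are rounded to the nearest
integer and clamped to $\geq 1$ (sd 0 gives the mean exactly);
empty-target-selection redraws are bounded at 10 before a deterministic
fallback to the highest-probability region; the barcode grower advances
in exact sub-steps to bar births and deaths, so those path distances are
exact rather than within-a-step.

# Known limitations

* The lattice Steiner construction is a structural approximation of the
  original graph-construction procedure, which is not fully specified in
  the main text of its source.
* Full covariance mixtures are not fitted (density evaluation only).
* Trunk radii are constant; no diameter model.
* The representativity and MVS formulas are concrete instantiations of
  scores whose published definitions live in supplementary material; both
  are isolated behind single functions.
* Local-axon grafting, flat-map projections and 3D rendering are out of
  scope.
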