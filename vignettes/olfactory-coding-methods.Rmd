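---
title: "Methods: from spike trains to higher-brain-center odor maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spike trains to higher-brain-center odor maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfmap)
```

# Scope and model of the data

`olfmap` implements the quantitative analysis chain used to study combinatorial
odor coding in the *Drosophila* olfactory system: odor-evoked spike trains of
identified projection-neuron (PN) and olfactory-sensory-neuron (OSN) classes
are reduced to class × odor response-intensity matrices; those matrices are
analyzed as points in a population "odor space" (distances, Ward clustering,
PCA, ANOSIM); tuning transformations between processing levels are quantified
with per-glomerulus correlations and lifetime sparseness; and axonal
morphologies are converted into voxel density maps that, weighted by response
intensities, reconstruct virtual odor-activity maps in the mushroom-body
calyx and lateral horn (LH).

Each analysis stage is exposed as a plain function; `run_olfactory_analysis()`
orchestrates the full chain on synthetic data.

## Response intensity

A response is the spike count in a 1-s window shifted by the odor-arrival
delay, `[0.05, 1.05)` s after stimulus onset, minus the count for the
solvent-matched control stimulus (mineral oil or water). The window is
half-open so boundary spikes are assigned unambiguously. Negative
control-subtracted values are retained in the matrix: rectification to zero
happens only where the downstream statistic requires non-negative input —
lifetime sparseness, Bray–Curtis dissimilarity, and functional-map weighting.
Per class, trials are reduced first (default: the first stimulation round
only, for comparability across neurons recorded in different animals; a
trial-mean mode exists), then sister neurons are averaged. Because both
reductions are arithmetic means, subtracting the control before or after
averaging is algebraically identical.

## Lifetime sparseness

Selectivity of a tuning vector $r = (r_1,\dots,r_N)$ over the fixed odor
panel ($N = 17$ by default) is

$$S = \frac{1}{1 - 1/N}\left(1 - \frac{\left(\sum_j r_j / N\right)^2}{\sum_j r_j^2 / N}\right),$$

after setting $r_j < 0$ to zero. $S = 0$ for a uniform responder, $S = 1$ for
a single-odor responder. An all-zero rectified vector leaves $S$ undefined
(0/0); the package raises an error rather than reporting 0, and the paired
OSN/PN comparison simply excludes such glomeruli and lists them. Tuning
curves are displayed center-out (strongest odor centered, weaker responses
alternating right then left outward, ties broken by odor id); the layout is
fully specified here because only the visual convention is standard.

## Odor-space geometry

Odors are columns of the response matrix, i.e. vectors of class responses.
Three metrics are provided: cosine distance ($1 - \cos\theta$,
amplitude-insensitive), Euclidean distance (amplitude-sensitive) and
correlation distance ($1 - r$). Zero-norm or zero-variance vectors make
cosine/correlation undefined; these distances are set to 1 with a warning so
a silent neuron does not abort a population analysis.

Hierarchical clustering uses Ward linkage on the supplied distance matrix
(`stats::hclust`, `ward.D2`, i.e. the Lance–Williams recurrence on the given
dissimilarities; two singletons merge at their distance). Applying Ward to
non-Euclidean cosine or correlation distances departs from Ward's
variance-based derivation but matches the common practice of the numerical
tools this analysis style originates from; the choice is deliberate and the
metric is always recorded on the distance object. Fixed cuts are supported
both as absolute linkage heights (default 0.6) and as a fraction of the
maximum height (default 0.7), with clusters defined as connected components
below the cut. Note that an absolute cut height is calibrated to a
particular data scale; for judging whether planted structure is recovered in
synthetic data the package's tests cut the tree into the planted number of
groups instead.

Cluster-signature glomeruli are the rows whose mean response across a
cluster's odors reaches a rate threshold (default 30 spikes/s).

PCA is column-mean-centered and unscaled (variance fractions are reported on
the raw response scale; standardization is available as a flag). Explained
fractions come from the singular values and are cross-checked in the test
suite against an independent covariance eigendecomposition.

ANOSIM (analysis of similarities) tests whether between-group rank distances
exceed within-group rank distances,
$R = (\bar r_B - \bar r_W)/(M/2)$, $M = n(n-1)/2$, with an add-one
permutation p-value. Given a raw matrix the dissimilarity is Bray–Curtis on
rectified intensities; a precomputed distance matrix is used as-is.
Computation is delegated to `vegan::anosim`; an independent rank-based
implementation of $R$ lives in the test suite as an oracle. With two groups
the complementary labeling reproduces the observed $R$, so the smallest
attainable p-value is about $2/(n_{perm}+1)$.

Matrix–matrix correlation (anatomy vs function, physicochemical vs neural
space, sequence vs response distances) is the Pearson correlation over
upper-triangle pairs with a parametric t-test p-value, plus an optional
label-shuffle control reporting the mean ± s.d. of shuffled correlations.
Anatomical distances between glomeruli are Euclidean distances between atlas
centroids — the simplest defensible reading, since no surface-based
definition is standard.

The OSN→PN pairing-shuffle control permutes the glomerulus pairing uniformly
(fixed points allowed: with ~29 glomeruli the expected single fixed point
changes the mean negligibly and keeping the permutation uniform is simpler
to reason about).

## Density maps and functional maps

Skeletons (SWC, 7 columns, one root) are resampled so that every parent–child
edge is split into $\lceil \mathrm{len}/0.5\,\mu m\rceil$ equal segments;
segment midpoints are binned into 1 µm³ voxels by floor binning with
half-open voxel intervals. The default template grid is 135 × 135 × 105
voxels; region grids for the calyx (55 × 46 × 32 µm) and LH (52 × 53 × 43 µm)
boxes add a margin so boxcar smoothing does not push mass off the grid.
Histograms are smoothed with a normalized 9 × 9 × 9 boxcar kernel — "9
voxels" is read as full width, and the kernel is three-dimensional because
the filtering is. Boundaries are zero-padded: interior mass is conserved to
numerical precision (asserted at 1e-9 in the tests), mass within 4 voxels of
an edge is attenuated; a renormalizing variant was considered and rejected
as it silently changes totals. When several sister skeletons exist their
unsmoothed histograms are averaged before smoothing (averaging and the
linear filter commute except at boundaries; a single-exemplar mode exists).

One floor-binning property worth knowing: a point lying exactly on a voxel
boundary can change bins by one ulp of floating-point noise when the same
translation is applied to points and grid origin. This is inherent to
half-open binning, not a defect; the translation-covariance test therefore
keeps its points off boundaries.

A functional map for odor $j$ is
$\sum_c \max(r_{cj}, 0) \cdot D_c$ voxelwise, where $D_c$ is class $c$'s
density map — no per-class normalization, since the construction is a plain
product-sum (a unit-mass normalization flag exists because published map
images are typically rescaled per image for display; numeric outputs here are
never rescaled). Classes with responses but no morphology are skipped and
reported, mirroring partial anatomical coverage of a recorded population.
Maps are compared by correlation distance on the full flattened 3-D voxel
arrays (2-D projections are available but 3-D is the default: projection
discards exactly the spatial structure the maps exist to capture), clustered
with Ward, and summarized as mass fractions over named region masks (e.g.
the dorsoventral split of the LH used for valence).

## Temporal analyses

PSTHs are trial- and neuron-averaged rates in fixed bins (default 100 ms,
matching trajectory displays; 50 ms available) over the recording span
[-1, 3] s. Population trajectories share one PCA basis fitted on the pooled
(time × odor) × class observations of raw binned rates — a per-bin basis
would make paths incomparable, and smoothing before fitting was rejected to
keep the tensor an unmodeled summary of the spikes. The inter-odor
separation timecourse is the mean pairwise Euclidean distance between class
rate vectors per bin, with the peak reported at the earliest tie.
Window-averaging the tensor over the response window and computing odor
distances reproduces the static odor-space distances exactly (asserted to
1e-9), which ties the temporal and static modules together.

Oscillatory synchrony is out of scope: it requires simultaneous local-field
recordings that the data model does not include.

# The synthetic-data generator

The generator exists so every downstream stage is testable end to end; it
emulates the statistical structure the analyses assume, at the study's
problem sizes.

* **Panel**: 17 odors, 8 attractive / 9 aversive, each dissolved in mineral
  oil or water (the solvent determines the matched control) at $10^{-3}$
  dilution.
* **Tuning**: each of 31 classes innervates one glomerulus; glomeruli and
  odors carry planted group labels. Baseline tuning is uniform on
  0–10 spikes/s, multiplied by a gain (default 10) for odors of the class's
  own group. Groups are valence-pure — the default 3 groups split into one
  attractive group (8 odors) and two aversive groups (5 and 4) — so the
  planted cluster structure carries a valence signal, the synthetic analog
  of attractive and aversive odors engaging different glomerular clusters.
* **Spike trains**: inhomogeneous Poisson by thinning (exact for the
  piecewise-smooth profile used), over [-1, 3] s with the stimulus at
  [0, 1] s. During the stimulus the rate is baseline (5 spikes/s) plus the
  class-odor amplitude times a normalized profile: 60% of its mass in an
  alpha-shaped transient peaking at 150 ms, 40% in a sustained plateau; the
  profile integrates to 1 so the amplitude is the expected above-baseline
  count per window. Sister neurons (default 3 per class, the typical sister
  count, exposed as a parameter because the real distribution is variable)
  share the class profile; each neuron × odor × trial draws independent
  additive amplitude noise (s.d. 3 spikes/s), negative draws clipped at zero
  with a warning.
* **Atlas**: glomerulus centroids in a 100 × 100 × 50 µm box; a
  `spatial_clustering` knob interpolates between uniform placement (0) and
  tight placement around group centers (1).
* **Arbors**: random-walk trees (one per region per class) whose steps are
  pulled toward a target locus with isotropic noise. LH loci are structured
  by group — attractive-group classes dorsal, aversive ventral — while calyx
  loci are drawn nearly uniformly, reproducing the contrast between
  stereotyped LH targeting and distributed calyx targeting.

What the generator does **not** emulate: lateral inhibition between
glomeruli and any systematic OSN→PN tuning broadening or sharpening (the
synthetic OSN population shares the PN tuning model, so its OSN–PN
correlations are higher and its pairing-shuffle chance level lower than
real data would give); realistic arbor branching statistics; inter-animal
registration error (data are born in template space); odor-concentration
effects. Passing tests therefore demonstrate that the *machinery* is
correct — oracles, conservation laws, planted-structure recovery — not that
real recordings would yield any particular statistic.

# Numerical choices and problem sizes

* Window `[0.05, 1.05)` s; half-open intervals everywhere (windows, voxels).
* Ward on given distances via `ward.D2`; hclust's deterministic scan order
  breaks merge ties (smallest index pair first).
* Permutation p-values use the add-one estimator, so p = 0 is impossible.
* Per-glomerulus Pearson p-values use the t-distribution with N − 2 = 15
  degrees of freedom.
* Stochastic stages derive per-stage sub-seeds from the single global seed
  by hashing the stage name, so stages are reproducible independently.
* The test suite and the acceptance script run the full-scale analyses at
  the study's sizes (31 classes × 17 odors, 3 sisters, 2 trials; 29 shared
  glomeruli) and the morphology/map analyses on region-local grids (1 µm
  voxels for the headline run; property tests use coarser 2 µm grids and
  smaller arbors, chosen as the smallest sizes at which the planted spatial
  structure is unambiguous).

# Known limitations

* The bundled `inst/extdata/*_synthetic.csv` tables are synthetic stand-ins
  generated by this package at a fixed seed — they exercise the
  supplementary-table reader and the full statistics chain at the real
  study's dimensions, but they are not measured data, and statistics
  computed from them (threshold fractions, PCA fractions, cluster counts)
  characterize the generator, not the fly.
* Absolute dendrogram cut heights do not transfer across data scales; use
  `fraction_of_max` mode or a k-cut when comparing datasets.
* Ward on non-Euclidean distances and centroid-based anatomical distances
  are documented interpretations, selectable but not sidestepped.
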