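---
title: "Mining meta-stable conformational patterns and predicting molecular properties with ensemble models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining meta-stable conformational patterns and predicting molecular properties with ensemble models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pemnet)
library(dplyr)
```

## The model

`pemnet` treats an ensemble of short molecular-dynamics trajectories as
draws from a small set of long-lived conformational basins. Three modelling
assumptions carry the whole pipeline:

1. **A few dihedrals suffice.** The conformational state of the molecule is
   summarized by p torsion angles **X** = (θ₁, …, θ_p), chosen by the user
   (typically the rotatable bonds of the flexible tail). Dihedrals are
   internal coordinates, so the descriptors are invariant under rigid-body
   motion and comparable across uncoupled trajectories.
2. **Basins are compact in descriptor space.** A meta-stable pattern is a
   cluster of frames whose dihedrals are tightly grouped; K-means over the
   descriptors identifies them. Within a pattern, structures (and therefore
   properties) vary little; between patterns they vary a lot.
3. **Properties are smooth in conformation.** The property of a new
   conformer can be interpolated from the properties of nearby reference
   conformers. This is what makes the ensemble-model predictor work without
   any training step.

### Dihedral descriptors

Torsions follow the IUPAC sign convention (clockwise positive looking down
the central bond), computed with the projection/atan2 formulation, which is
stable near 0° and 180°. All angles are wrapped to the half-open interval
[−180°, 180°), so cis is 0 and trans is −180 — one canonical representative
per angle. Angular *differences* (used in distances) are wrapped to
(−180°, 180°]: two dihedrals at +179° and −179° are 2° apart.

An energy series can be subsampled at its interior local minima before
statistics, mimicking the practice of retaining relaxed snapshots. Strict
comparison is the default; an optional plateau mode reports the first index
of an interior flat minimum, since "local minimum" is not operationally
unique on sampled data. Which energy to filter on (ground- or excited-state)
is deliberately a caller choice — the filter is property-agnostic.

### Clustering and the circular embedding

K-means runs on either the raw wrapped angles (`embedding = "raw"`) or, by
default, on the circular embedding θ → (cos θ, sin θ). The chord metric of
the circular embedding respects dihedral periodicity: two planted clusters
at +175° and −175° are one basin, and the circular embedding sees them as
one, while raw angles tear the seam. Raw mode is kept because plain internal
coordinates are what a minimal implementation would use, and the two modes
let users measure whether the seam matters for their descriptors.

Implementation: k-means++ seeding feeds `stats::kmeans` Lloyd iterations;
the best of `n_init = 10` seeded restarts (lowest within-cluster sum of
squares) is kept, so a fit is a pure function of (data, seed, parameters).
If a Lloyd run collapses a cluster to empty, that initialization is redrawn
from the seeded stream (bounded retries) rather than accepting fewer than k
clusters. Centroids are back-mapped to angles via atan2 of the (sin, cos)
components for reporting and for mirror-pair detection.

Choosing k: `select_k()` sweeps candidate counts and reports per-cluster
member counts and circular spreads (plus the within-cluster inertia, which
is non-increasing in k). The working criterion is geometric tightness — pick
the smallest k at which the widest cluster is still "one basin". On real
chromophore data a per-pattern heavy-atom deviation after superposition
(Kabsch, `superpose()`, with an optional atom mask so users can align heavy
atoms only) of ≲ 0.5 Å is the natural threshold; k = 12 is the package-wide
default for that use case, and on synthetic benchmarks the planted k shows
up as the point where the max spread collapses and then flattens.

Near-planar chromophores produce mirror twins: for every pattern with
dihedrals **c** there is a partner at −**c** (clockwise vs anti-clockwise
rotation). `merge_symmetric_pairs()` detects pairs whose centroids satisfy
**c**′ ≈ −**c** within a circular RMS tolerance (default 10°; self-mirrors —
centroids near 0 or ±180 — map to themselves), pairing greedily by nearest
mismatch, and relabels frames to the lower id of each pair. Twelve planted
mirror states reduce to exactly six merged patterns.

### The kinetic network

Transition counts are ordered label pairs (t, t + lag) accumulated per
trajectory, never across trajectory boundaries; lag defaults to 1 frame
(counting along the raw series), exposed for coarser sampling. Rows are
normalized to probabilities; all-zero rows are returned as zeros and
flagged, never imputed. Self-transitions stay in the counts (they carry the
dwell time and keep rows stochastic) but never create graph edges, because
the network of interest is inter-pattern connectivity.

The graph is undirected — edge (i, j) exists iff max(P_ij, P_ji) reaches the
edge threshold, default 0 so any observed transition connects the patterns;
whether one should threshold on counts or probabilities is ambiguous in
general, so the threshold is a parameter rather than a guess. Connected
components and articulation vertices (patterns whose removal disconnects the
network — obligatory intermediates) come from igraph and are checked in the
tests against a brute-force remove-and-test oracle.

Populations: at each time, the population of pattern i is the fraction of
trajectories defined at that time currently in i — a probability simplex per
time point. For an ensemble long enough relative to the chain's mixing time,
these approach the stationary distribution (leading left eigenvector of the
transition matrix), which is the oracle used in the tests.

No Markov-state-model validation machinery (implied timescales,
Chapman–Kolmogorov) is included: the package builds the counting network
only.

### Property statistics

`fit_gaussian()` defaults to moments with the population (1/n) standard
deviation. That choice is deliberate: with 1/n normalization the weighted
combination of per-pattern (μ, σ, n) reproduces the global moments *exactly*
(the pooled-consistency property tested in the suite); with the n−1
convention it would not. A histogram least-squares mode exists for parity
with fitting a curve to a plotted distribution; on 10⁵ draws both recover
planted (μ, σ) to ~1%.

Coverage intervals are μ ± z·σ with z = 2.58 by default, covering
Φ(2.58) − Φ(−2.58) = 0.9901 ≈ 99% of a Gaussian — the conventional error
bar for per-atom charge distributions.

Emission spectra are sums of unit-area Gaussians centred at the snapshot
energies: unit intensity per snapshot (no oscillator-strength weighting —
none is assumed available), so the spectrum integral equals the snapshot
count, which is the normalization contract the tests enforce. Broadening
FWHM defaults to 0.2 eV — a typical empirical width for room-temperature
vibronic envelopes — with the grid step at FWHM/20 and the grid extended 3
broadening widths beyond the extreme energies; both are parameters.

### The PEM predictor

The property estimate at query **X** is

$$V(\mathbf{X}) = \sum_{i=1}^{M}\sum_{j=1}^{n} \omega_{ij}(\mathbf{X})\, T_{ij},$$

a weighted sum over n reference conformers from each of M patterns. The
weights are inverse-distance kernels of the general distance

$$u_{ij} = \left\| \mathbf{X} - \mathbf{X}'_{ij} \right\|,$$

computed by default on wrapped angular differences (periodicity again; a
raw mode exists). Two kernel modes are provided:

* **shepard** (default): ω_ij = u_ij^(−p) / Σ u^(−p) with exponent p = 4.
  The weights are a partition of unity, continuous in **X**, and decaying
  with distance, so remote patterns contribute little; predictions are
  convex combinations of reference properties and interpolate exactly at
  every reference. This is classic Shepard inverse-distance interpolation.
* **as-printed**: ω_ij = (1/u_ij) / Σ (1/u)^4 — an unnormalized literal
  variant kept for comparison. Its weights do not sum to one and carry units
  of (distance)³, so predictions are not convex combinations; it exists so
  users can measure the difference rather than have it silently corrected.
  The denominator sum runs over all (i, j) reference entries in both modes,
  consistent with the double sum of the estimator.

If the query coincides with one or more references (u = 0), the weight
collapses to the zero-distance reference(s), split equally among exact
ties — the continuous limit of the kernel, which guarantees interpolation
consistency. As p → ∞ the prediction approaches the nearest-neighbour value
(monotone locality). One prediction costs O(M·n) distance evaluations.

Reference selection: *batch* (all members per pattern), *stochastic* (one
seeded draw per pattern), or *mini-batch* (default, min(n, cluster size)
seeded draws without replacement, n = 10) — the trade-off between cost and
prediction variance. Defaults M = all patterns and n = 10 follow the
validation protocol used throughout. Patterns with no property-bearing
members are dropped with a warning.

Per-atom charges are predicted componentwise with a single shared weight
vector; optional renormalization spreads the residual between the configured
net charge and the summed prediction uniformly over atoms, so the output
sums to the net charge exactly (uniform spreading is the choice that
perturbs every atom equally and preserves all pairwise charge differences).

Validation follows the ratio protocol: the distribution of predicted /
reference values is summarized by a Gaussian fit (a faithful predictor gives
μ ≈ 1 with small σ), alongside deviation mode (predicted − reference) for
charges.

## The synthetic-data generator

Real surface-hopping ensembles cannot be regenerated at desk scale, so the
generator plants exactly the structure the pipeline assumes and nothing
more:

* a Markov chain over k latent conformational states (initial state from the
  stationary distribution, evolution by the configured row-stochastic
  matrix) — the ground-truth kinetic network;
* von Mises emissions of each dihedral around the current state's center.
  Von Mises (not wrapped Gaussian) because it is the canonical circular
  exponential family and admits exact sampling (Best–Fisher rejection, which
  the tests check against circular-moment identities). Concentration κ = 50
  (≈ 8° spread) for the "easy" presets, κ = 8 (≈ 21°) for `noisy_overlap`;
* properties from a truncated Fourier surface
  T\*(X) = a₀ + Σ_m (b_m cos θ_m + c_m sin θ_m) plus Gaussian noise —
  smooth, periodic, and cheaply differentiable, encoding "similar
  conformations have similar properties" while providing an exact oracle and
  an analytic Lipschitz constant for error bounds;
* per-atom charges from independent Fourier surfaces shifted per frame so
  the net charge is exactly the configured total, enabling exact
  renormalization tests.

Presets: `two_state_easy` (2 states, 20 × 200 frames), `twelve_state_mirror`
(6 mirror pairs with componentwise-negated centers at least ~30° apart,
60 × 300 frames), `noisy_overlap` (3 broad states). Self-transition
probabilities of 0.9–0.95 give dwell times of 10–20 frames — metastability
without freezing the chain. Each benchmark returns machine-readable
expectations (planted k, labels, transition matrix, stationary vector,
property oracle).

What passing on synthetic data does *not* show: real dihedral distributions
are not von Mises, real property surfaces are not low-order Fourier (conical
intersections produce cusps), descriptor sets may miss slow degrees of
freedom, and trajectory ensembles carry correlated initial conditions. The
synthetic results certify the machinery — recovery of planted structure,
exactness and convexity of the interpolation, normalization contracts — not
chemical accuracy on any particular molecule.

## Numerical choices

* Tie-breaks: nearest-centroid assignment resolves exact ties toward the
  lowest pattern id; merged mirror pairs take the lower id.
* The exact-match collapse in the kernel triggers at u ≤ 10⁻⁹ (degrees) —
  far below any physically meaningful angular difference, and the shepard
  kernel's own limit, so the predictor remains continuous to floating
  tolerance.
* Shepard weights are computed in log space to avoid overflow at very small
  distances.
* Degenerate torsions (coincident points, parallel bonds) raise errors and
  are never silently 0; the trajectory frame index is attached.
* Empty transition-matrix rows are flagged, not imputed; population time
  points with no defined trajectory are omitted with a warning.
* Pipeline stages always re-load their persisted text artifact before
  downstream stages consume it, so a fresh run and a `resume = TRUE` run are
  bit-identical and every artifact is reproducible from the manifest's seed
  and config hash.

## Problem sizes

The shipped analyses use 4,000-frame (two-state) and 18,000-frame
(twelve-state) clustering benchmarks, a 100-trajectory × 2,000-frame
ensemble for kinetic recovery, 1,000 held-out frames for PEM validation,
and 1,000 random reference sets for the kernel-correctness check — sizes at
which the planted structure is recovered with comfortable statistical margin
while a full run of the test suite and the acceptance script stays within a
couple of minutes on one core.

## Known limitations

* Descriptors are user-specified dihedrals; no automatic discovery, no
  non-torsional coordinates.
* K-means assumes roughly isotropic basins in the embedded space; strongly
  anisotropic or curved basins would need a different clusterer.
* The PEM kernel interpolates — it does not extrapolate gradients, and it
  cannot repair a descriptor set that fails to separate property-relevant
  conformations (two geometries with equal dihedrals but different
  properties are indistinguishable by construction).
* The network is a counting summary, not a validated Markov state model.
* XYZ is the only trajectory format; property tables are joined by
  (trajectory id, frame index), and frames without properties are excluded
  from statistics with a logged count.

## A complete run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  preset = "two_state_easy", k = 2L, seed = 1L,
  selection_mode = "mini-batch", n_refs = 10L,
  out_dir = tempfile("pemnet_run_")
)
manifest <- run_pipeline(cfg)
names(manifest$stages)
#> "descriptors" "cluster" "network" "stats" "references" "predict" "validate"
```
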