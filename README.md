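# pemnet

Meta-stable pattern networks and ensemble-model property prediction for
molecular dynamics trajectories.

## The problem

Excited-state ab initio molecular dynamics produces ensembles of short,
chaotic trajectories — hundreds of runs, hundreds of thousands of snapshots —
from which the chemistry (which conformational basins exist, how they
interconvert, how properties like the S1 excitation energy depend on
geometry) is hard to read by eye. At the same time, recomputing an electronic
property with TDDFT for every new geometry is expensive, even though
conformers within one basin have nearly identical properties.

`pemnet` addresses both halves for molecules whose conformational motion is
captured by a handful of dihedral angles (the motivating case is a
photoactive chromophore with a rotatable tail, e.g. sinapic acid on S1):

1. **Pattern mining.** Each frame is reduced to a descriptor vector
   **X** = (θ₁, …, θ_p) of dihedrals. K-means over these descriptors (with a
   periodicity-respecting (cos θ, sin θ) embedding by default) partitions the
   ensemble into k *meta-stable patterns* — basins of structurally similar
   conformers. Clockwise/anti-clockwise mirror pairs (centroids related by
   **c**′ ≈ −**c**) can be merged, halving k where the symmetry is real.
2. **Kinetic network.** Counting lag-1 label transitions along each
   trajectory (never across trajectory boundaries) gives a transition count
   matrix, row-normalized transition probabilities, the undirected pattern
   graph with its connected components and articulation (cut) vertices — the
   obligatory intermediates — and the time-dependent pattern populations of
   the ensemble.
3. **Statistics.** Property distributions (excitation energies, per-atom ESP
   charges) are characterized by Gaussian fits per pattern, with μ ± z·σ
   coverage intervals (z = 2.58 covers 99%), and Gaussian-broadened emission
   spectra are estimated from snapshot energies.
4. **PEM prediction.** The *Prediction-with-Ensemble-Models* interpolator
   estimates a property at any new geometry as a kernel-weighted sum over
   n reference conformers drawn from each of the M patterns:

   V(**X**) = Σᵢ₌₁^M Σⱼ₌₁^n ω_ij(**X**) · T_ij,

   with Shepard inverse-distance weights
   ω_ij = u_ij^(−p) / Σ u^(−p) (default exponent 4; the unnormalized literal
   kernel variant is also available) over the general distance
   u_ij = ‖**X** − **X**′_ij‖ computed on wrapped angular differences. No
   training beyond the clustering is involved, one prediction costs O(M·n)
   distance evaluations, and mini-batch selection (n = 10 seeded references
   per pattern) trades the cost of "batch" against the variance of
   "stochastic".

Because the method is purely geometric/statistical, every stage is testable
on synthetic data: the package ships a generator that plants a Markov chain
over latent conformational states with von Mises dihedral emissions and a
smooth Fourier property surface, so planted labels, transition matrices, and
property oracles are known exactly.

## Worked example

```r
library(pemnet)
library(dplyr)

# synthetic benchmark: 2 metastable states, 20 trajectories x 200 frames
bench <- make_benchmark("two_state_easy", seed = 1)
desc  <- select(bench$dataset$descriptors, -state)

model <- fit_patterns(desc, k = 2, seed = 1)
tidy(model)
#> # A tibble: 2 × 5
#>   pattern     n dih_1  dih_2 dih_3
#>     <int> <int> <dbl>  <dbl> <dbl>
#> 1       0  2226 -60.1   39.8 150.
#> 2       1  1774  69.6 -120.  -30.1

tm <- count_transitions(model$labels, k = 2)
round(tm$probabilities, 3)
#>       [,1]  [,2]
#> [1,] 0.955 0.045
#> [2,] 0.058 0.942

per_pattern_stats(model$labels, bench$dataset$properties,
                  property_cols = "excitation_energy")
#> # A tibble: 2 × 5
#>   pattern property             mu  sigma     n
#>     <int> <chr>             <dbl>  <dbl> <int>
#> 1       0 excitation_energy  3.41 0.0634  2226
#> 2       1 excitation_energy  1.50 0.0806  1774

dataset <- pem_dataset(model, desc, bench$dataset$properties)
refs <- select_references(dataset, dihedrals = paste0("dih_", 1:3),
                          mode = "mini-batch", n = 10, seed = 1)
pem_predict(c(-60, 40, 150), refs, "excitation_energy")
#> [1] 3.369077
property_oracle(bench$dataset$spec, c(-60, 40, 150))  # planted ground truth
#> [1] 3.424499
```

Reading the output: the two fitted centroids sit on the planted state centers
(−60, 40, 150) and (70, −120, −30); the recovered lag-1 transition matrix
matches the planted (0.95/0.05, 0.05/0.95) chain to counting noise; the two
patterns have cleanly separated excitation-energy distributions (3.41 vs
1.50 eV, σ below 0.1 eV — low bias within a pattern, high variance between
patterns); and a mini-batch PEM prediction at a state center lands within a
few hundredths of an eV of the noiseless planted surface.

The same steps run from the shell via the thin CLI
(`Rscript inst/cli/pemnet.R simulate|descriptors|cluster|network|stats|references|predict|validate|spectrum|run`),
and `run_pipeline()` executes all stages end-to-end with persisted artifacts
and a seed/hash manifest.

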