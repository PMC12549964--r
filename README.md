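# ionFootprint

Partial relative-orientation retrieval of proteins from the ion
footprints of X-ray-laser-induced Coulomb explosions — a desk-scale R
implementation.

## The problem

In single-particle imaging (SPI) at X-ray free-electron lasers, each
protein arrives at the beam in an unknown random orientation, and
recovering orientation is a central bottleneck of reconstruction. The
same pulse that scatters photons also ionizes the molecule and blows it
apart; the ions land on position-sensitive detectors as a 2D count
histogram (the *explosion footprint*) with no momentum, mass or
coincidence information. This package is for researchers who want to
study, with fast and fully reproducible simulations, how much relative
orientation information those footprints carry.

## The method

1. **Explode.** Atoms of a cloud (read from PDB or synthesized) draw
   Poisson charges with mean ∝ Z scaled to a target mean ionization
   (default 1.2 e/atom); charged atoms then repel via a softened Coulomb
   potential k·qᵢqⱼ/√(r² + ε²), integrated with velocity Verlet from rest
   until the potential energy is spent.
2. **Detect.** Asymptotic ion directions are ray-cast onto two 120 mm
   square panels at ±30 mm, each binned 18×18 and stacked into a 36×18
   count image; detector efficiency is binomial thinning per count.
3. **Compare.** For N oriented footprints, all N(N−1)/2 pairs get a
   pixel-space Euclidean distance d (optionally after a per-panel
   Gaussian blur, σ = 0.5 px) and a ground-truth relative angle
   θ = 2 arccos |Re(RᵢRⱼ⁻¹)| ∈ [0, π].
4. **Cut.** The upper envelope f(x) = max{θ : pair in distance bin x} is
   computed over 100 bins; the distance cutoff is the arg max of the
   forward-difference slope of f. Pairs with d ≤ cutoff are the retrieved
   similar-orientation pairs; their count and mean angle measure
   retrieval quality against the saturation level of random rotations,
   E[θ] = π/2 + 2/π ≈ 2.2074 rad (density p(θ) = (2/π) sin²(θ/2)).

## Worked example

```r
library(ionFootprint)

cloud <- synthesizeCloud(800, seed = 1, label = "demo")   # 800-atom globule
sim   <- simulateFootprints(cloud, nSimulations = 10,
                            patternsPerSimulation = 10, seed = 2)
cutoffAnalysis(sim$footprints)
#> CutoffReport 'demo': cutoff 11.88, 3/4950 pairs under, mean angle 0.367 rad
angleDistributionStats()$mean
#> [1] 2.207416
```

The 3 pairs selected by the data-driven cutoff average 0.37 rad of
relative orientation — well below the 2.21 rad a random pair would give,
i.e. the footprints really do sort similarly oriented explosions
together. Larger ensembles (the test battery runs 50 × 20 patterns of a
3000-atom cloud) push the under-cutoff mean to ~0.15 rad.

A thin CLI mirroring the library lives at `inst/cli/explode-orient`
(subcommands `simulate`, `retrieve`, `variance`, `fluence-check`,
`pipeline`).

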