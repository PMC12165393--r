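# gridtorus

Quantifying how close a neural population's activity manifold is to a
torus.

Grid cells in the medial entorhinal cortex fire on hexagonal lattices of
spatial fields, and persistent homology applied to their joint activity
reveals a toroidal manifold: barcodes with two long loops (`H1`) and one
long cavity (`H2`). Instead of a binary torus/no-torus call, this package
scores barcodes with a continuous **degree of toroidality**

Γ_d(τ_d, τ_d^ref) = 1 − d̂_B(τ_d, τ_d^ref),  d ∈ {1, 2},

where d̂_B is the bottleneck distance between barcodes after each is
rescaled by its internal scale u(τ) = max over bar pairs of the sup-norm
distance, and τ_d^ref is the barcode of an idealized torus built from the
data (keep the two longest `H1` bars and the longest `H2` bar; floor every
other bar to the minimum bar length of its dimension). Both components lie
in [0, 1]; barcodes consistent with toroidal topology have both above
about 0.6.

The package is a complete toolchain for asking *which temporal features of
spiking produce this topology*:

* **Barcodes and the measure** — exact bottleneck distance (binary search +
  Hopcroft–Karp, with a strict-bijection variant), normalized bottleneck,
  data/self reference construction, the toroidality score, and the
  `H1`-death/`H2`-birth gap statistic.
* **Rips persistence engine** — built-in Vietoris–Rips persistent
  cohomology in C++ (union-find `H0`, clearing, emergent and apparent pair
  accelerations), exact up to the enclosing radius; no external TDA
  backend required.
* **Toy manifolds** — 3D and 6D torus samplers with Gaussian corruption
  and noise sweeps, for validating the measure.
* **Grid-cell simulator** — rate-modulated Poisson populations on
  hexagonal or square lattices with truncated-Gaussian fields, an
  oscillator bank with dominant eta (4 Hz) and theta (8 Hz) lines on a
  1/f-like background, amplitude-to-rate calibration, field displacement,
  and a synthetic open-field foraging trajectory generator.
* **Pipeline** — Gaussian smoothing, 10 ms binning, population-vector
  selection (top-activity or random), PCA to 6D, density-aware maxmin
  downsampling to 1200 points, spike-time jittering, UMAP visualization.
* **Analyses** — sigmoid fits of Γ against jitter magnitude and the
  critical timescale Δt_C, behavioral timescales, occupancy-normalized
  ratemaps and grid scores, spike-train power spectra with eta/theta band
  powers, and displacement / frequency / gain / subsampling sweep runners.

## Worked example

Score a clean 1200-point torus sample against its own data-mode reference:

```r
library(gridtorus)
x  <- sampleTorus3D(1200, a = 5, c = 10, seed = 1)
bs <- ripsPersistence(x, maxdim = 2)
toroidality(bs, referenceMode = "data")
#> ToroidalityScore (reference: data)
#>   Gamma1 = 0.8297, Gamma2 = 0.9752
h1h2Gap(bs)
#> [1] 4.216228
```

The two essential loops dominate `H1` (bars `[1.3, 8.7)` and
`[1.53, 8.68)`) and a single cavity dominates `H2` (`[4.49, 9)`), so both
components are high and the gap is large and positive: the cavity coexists
with the loops, the torus signature. Γ1 sits near 0.83 rather than 1
because the Rips filtration of a finite torus sample genuinely contains
transient third loops (persistence ≈ 2.8 here) that any reference floors.

Simulate an oscillation-modulated grid module and push it through the
pipeline (a 10-minute session for illustration; analyses default to 30
minutes):

```r
bank <- buildOscillatorBank("methods_default", calibrationT = 600)
pop  <- gridPopulation(N = 75, spacing = 0.85, sigma = 0.12, seed = 2)
traj <- synthTrajectory(600, seed = 3)
sp   <- simulateGridModule(pop, traj, bank, seed = 4)
sp
#> SpikeTrains: 75 neurons, 108287 spikes, span [0.0, 600.0] s

bsm <- runTDA(sp, tdaConfig(k = 8000), seed = 5)
toroidality(bsm, referenceMode = "self")
#> ToroidalityScore (reference: self)
#>   Gamma1 = 0.7607, Gamma2 = 0.8853
etaThetaRatio(spikePSD(sp, duration = 600))
#> [1] 0.938
```

Both Γ components exceed the 0.6 torus threshold, and the spike spectra
carry the planted eta/theta peaks with comparable band power. Removing the
oscillations (`buildOscillatorBank("none")`) collapses the
`h1h2Gap()` statistic to zero: the cavity then appears only at radii where
the loops have already died. The methods vignette
(`vignettes/gridtorus-methods.Rmd`) documents the model, the measure, all
defaults and their rationale, and known limitations.

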