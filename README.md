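# nucfit

Classical nucleation analysis of protein-aggregate size distributions.

Misfolded-protein aggregation in mammalian cells begins with sub-diffractive
precursor clusters that conventional imaging cannot see. When such clusters
are measured — by single-molecule localization microscopy in fixed cells, or
by light-sheet intensity imaging in live cells — their size distribution can
be tested against the prediction of classical nucleation theory for a
super-saturated system undergoing a first-order phase transition. `nucfit`
implements that quantitative framework for researchers working on protein
aggregation and biomolecular condensates.

## The model

The free energy of a cluster of `n` monomer-equivalents, in units of
k<sub>B</sub>T, is

    ΔG(n) = a·n^(2/3) ± b·n

with `a > 0` a surface-energy coefficient and `b` a bulk (super-saturation)
coefficient; the minus sign (super-saturated case) creates a free-energy
maximum at the critical size **n<sub>c</sub> = (2a/3b)³** with barrier
**ΔG(n<sub>c</sub>) = 4a³/27b²**. Sub-critical clusters are
Boltzmann-distributed, `P(n) = A·exp(−ΔG(n))`, so a histogram of measured
cluster sizes yields an empirical free-energy curve `−ln P(n)` that can be
fitted for `a` and `b`. Both the critical radius and the barrier are
invariant under the unknown multiplicative factor relating the measured size
statistic to the true molecule count.

The package provides:

* a synthetic-data generator emulating the statistical structure of the
  microscopy data (truncated Boltzmann cluster sizes, cube-law cluster
  rendering, fluorophore blinking, 20 nm localization error, live-cell
  intensities and bleaching traces);
* DBSCAN clustering of localization maps (C++ core) with convex-hull
  cluster metrics, `n = (R/1 nm)³`, and the 50 nm diameter filter;
* normalized size histograms, empirical free energies, and the A = 1
  normalization offset;
* fits of the nucleation form with a self-consistent fitting range (up to
  80% of the fitted critical size), surface-asymptote (γ₁ = 2/3) and
  surface-subtraction (γ₂ = 1) diagnostics, and a Poisson count-likelihood
  engine that keeps the fitted critical radius insensitive to bin width;
* derived thermodynamics: critical size/radius, nucleation barrier,
  delta-method uncertainties, and surface-tension / density / label-spacing
  bounds;
* a kinetic Monte Carlo implementation of the Szilard
  production–condensation–clearance steady state, with a dense
  master-equation oracle and washout-schedule experiments;
* live-cell analysis: exponential bleach correction, intensity-to-count
  conversion, distribution fitting in N, growth/shrink trace
  classification, linear growth-law fits, and merger-additivity checks.

## Worked example

Draw 25,000 cluster sizes from the fixed-cell free-energy model, build the
size distribution, run the self-consistent fit, and derive the
thermodynamics:

```r
library(nucfit)

cfg   <- generator_config(seed = 1)          # a = 1.07e-3, b = 4.3e-6
sizes <- sample_cluster_sizes(cfg, n_draws = 25000)
dist  <- histogram_sizes(sizes, delta_n = 3e4)
fit   <- self_consistent_fit(dist)
fit
#> Nucleation free-energy fit (super-saturated)
#>   a = 0.001077 +/- 1.1e-05, b = 4.347e-06 +/- 9.8e-08 (kBT units)
#>   fit range n in [30000, 3.62529e+06], 120 bins, 2 iteration(s)
#>   n_c = 4.509e+06, R_c = 165.2 nm, barrier = 9.8 kBT

nucleation_parameters(fit)
#> n_c = 4.509e+06, R_c = 165.2 (+/- 2.1) nm, barrier = 9.8 (+/- 0.16) kBT
```

The fit recovers the generating parameters within one standard error; the
critical radius (165 nm, well below the diffraction limit) and the ~10
k<sub>B</sub>T barrier are read off directly. Surface-tension bounds from the reference fixed- and live-cell
coefficients:

```r
surface_tension_bounds(a_fixed = 0.001, a_live = 0.166,
                       N_c = 1400, R_c = 162)
#> Surface-tension bounds (condensate-cytoplasm interface)
#>   minimum density: 0.000329 molecules/nm^3
#>   sigma lower bound: 4.3e-06 N/m
#>   sigma upper bounds: 0.00071 (live), 0.0009 (fixed) N/m
#>   label spacing 14.5 nm, volume fraction 0.0011
```

i.e. the interface tension lies between ~4×10⁻⁶ and ~10⁻³ N/m — the range
reported for in-vivo liquid condensates — and the labelled tracer occupies
about a thousandth of the cluster volume.

A full synthetic pipeline (simulate maps → DBSCAN → filter → histogram →
fit → thermodynamics) runs via `run_pipeline(pipeline_config(...))`, or
from the shell through `inst/cli/nucfit.R` with subcommands `simulate`,
`cluster`, `fit`, `thermo`, `szilard`, `pipeline`.

## Notes

The methods vignette (`vignettes/nucfit-methods.Rmd`) documents the model,
the kinetic closure of the Szilard simulator, the Poisson fitting engine,
the synthetic world's stated parameters, and — importantly — which
properties the measurement layer does *not* preserve: hull-based radii
carry the localization error additively, so map-level parameter recovery
is biased even though distribution-level recovery is clean. One acceptance
check is intentionally left failing with that analysis.
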