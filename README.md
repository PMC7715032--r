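# ca3net

Configurable-scale simulation and analysis of the rat
entorhinal–dentate–CA3 circuit, built to study how topographically
organized excitatory connectivity shapes the spatial and temporal
structure of pairwise spike correlations across the CA3 sheet.

The package is for computational neuroscientists who want to (1)
generate anatomically constrained stochastic connectomes on an unfolded
two-dimensional hippocampal coordinate frame, (2) simulate
conductance-based reduced-compartment CA3 networks with EPSP-calibrated
AMPA/NMDA synapses, and (3) characterize the resulting population
activity with three-dimensional space–time correlation maps.

## The model in brief

**Connectivity.** Three excitatory afferent systems are generated
stochastically from anatomical constraints:

* *Perforant path* (lateral/medial entorhinal → distal/proximal
  stratum lacunosum-moleculare): Gaussian axon terminal fields along
  the longitudinal axis (span 1–1.5 mm, read as ±2 sd) centered by a
  monotone topographic map; per-cell input budgets are synaptic
  density × dendritic length per layer (0.63 syn/µm lacunosum; up to
  1,658 lateral and 1,105 medial inputs distally, none proximally).
* *Mossy fibers* (dentate granule cells → stratum lucidum, plus the
  proximal oriens for infrapyramidal-origin fibers in CA3c): one fiber
  per granule cell crossing CA3 transversely and bending toward the
  temporal pole in CA3a (cubic-spline trajectories with control-point
  noise); synapses placed by a Poisson process along arc length with
  region-dependent inter-synapse means (162/223/345 µm in CA3c/b/a)
  and assigned to a CA3 cell within 30 µm, or dropped.
* *Associational system* (CA3 → CA3 radiatum and oriens, 3.61 and
  3.15 syn/µm): per-cell axon fields as 2D skew-Gaussian densities,
  f(z) = 2φ(z)Φ(αz) per axis, with parameters interpolated over a 3×3
  injection grid; 18k–29k recurrent inputs per cell at full scale.

Axons are conduction delays: path length / velocity (0.32, 0.27 and
0.39 m/s for perforant, mossy and associational axons).

**Neurons and synapses.** CA3 pyramidal cells are 8-compartment
conductance-based models (one compartment per afferent layer) with
Hodgkin–Huxley style channels and three presets expressing the CA3
firing-type taxonomy (bursting, strongly adapting, weakly adapting).
Synaptic conductances are peak-normalized double-exponential (AMPA)
and triple-exponential (NMDA, with sigmoidal magnesium block)
waveforms, calibrated by bisection so somatic unitary EPSPs match
published targets — 0.30 mV for perforant/associational synapses and
3.2 mV (135 ms half-height width) for the large mossy "detonator"
synapses. Entorhinal input is a 5 Hz renewal process (Poisson with an
exponentially decaying 35 ms refractory period); the random dentate
surrogate realizes 0.62 Hz.

**Correlation maps.** For binary 1-ms-binned trains the
overlap-normalized cross-correlation is

    (x ⋆ y)[n] = 1/(σx σy) · 1/L(n) · Σm (x[m] − μx)(y[m+n] − μy),

summed over the overlap of length L(n) = N − |n| (the autocorrelation
is exactly 1 at lag 0). Pairs are averaged by their signed
(longitudinal, transverse) displacement at 0.1 mm / 1 ms resolution
into a 3D map; *global* maps use every pair, *local* maps use pairs
with at least one member in one of nine longitudinal × transverse CA3
sections. Cross-sections, 30%-of-maximum thresholding, peak
extraction, an analytic null noise bound, and spatial-profile width
estimation are provided.

## Worked example

Weakly correlated dentate input propagated to a 2%-scale CA3
population through mossy fibers at five times reference strength:

```r
library(ca3net)
s <- 0.02
lay <- build_layout(0, round(120000 * mf_fiber_fraction(s)),
                    round(25000 * s), seed = 1)
conn <- build_connectome(lay,
  connectome_config(pathways = "MF",
                    weight_scale = c(LPP = 1, MPP = 1, MF = 5, ASSOC = 1)),
  seed = 2)
conn
#> <ca3net_connectome> 22301 edges, seed 2
#>   MF: 22301 edges
#>   (311285 MF synapses dropped: no cell in range)

spec <- cluster_spec(n_clusters = 4, events_per_cluster = 9,
                     spatial_sd = 0.5, jitter_sd = 2,
                     participation = 0.4, background_rate = 0.22,
                     duration = 3000)
dg <- make_cluster_raster(spec, lay, population = "DG", seed = 3)$raster
dg
#> <spike_raster> 34141 DG neurons, 3000 ms, 62466 spikes (mean rate 0.6099 Hz)

ras <- simulate_network(conn, list(DG = dg), lay,
                        sim_config(duration = 3000))
m <- accumulate_map(ras, lay, max_lag_ms = 100)
round(peak_correlation(m, min_count = 30), 3)
#> [1] 0.025
population_lag(dg, ras, lay)$lag_ms
#> [1] 7
```

The dentate raster realizes the 0.62 Hz rate with planted 0.5-mm
spatial clusters; the dropped synapses are fibers contacting CA3 cells
outside the modelled 2% sample (the fiber subsampling keeps the
expected mossy in-degree at its full-scale value). The global map's
robust peak (~0.025 over bins holding ≥30 pairs) reflects the cluster
structure inherited from the dentate input, and the population lag —
the time shift at which the CA3 spatio-temporal pattern best matches
the dentate pattern — is a few milliseconds of conduction plus
synaptic integration.

A thin command-line front end over the same functions is in
`inst/cli/ca3net.R` (`make-renewal`, `make-clusters`,
`build-connectome`, `run-experiment`).

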