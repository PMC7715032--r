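---
title: "Modelling topographic correlation structure in the entorhinal-dentate-CA3 circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling topographic correlation structure in the entorhinal-dentate-CA3 circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ca3net` is a configurable-scale simulator and analysis toolkit for the
rat entorhinal-dentate-CA3 circuit. It asks how topographically
organized excitatory connectivity — the perforant path, the dentate
mossy fibers, and the recurrent CA3 associational system — shapes the
spatial and temporal structure of pairwise spike correlations across
the CA3 sheet. This vignette documents the model, its assumptions, the
tunable parameters, and the design decisions a user should understand
before interpreting results.

## Coordinate frame and populations

All positions live on unfolded two-dimensional sheets: a longitudinal
(septotemporal) axis, 0 mm at the temporal pole, and a transverse
(proximodistal) axis, 0 at the proximal border. CA3 is divided into
CA3c, CA3b and CA3a (proximal to distal, equal thirds by default) and
covered by three overlapping 5-mm longitudinal windows centered at
7.5 mm (septal), 5.0 mm (middle) and 2.5 mm (temporal). Window
membership uses half-open intervals with the lower edge inclusive, so
boundary ties go to the distal side and to the window above.

Sheet dimensions are not published for this circuit as a flattened
frame, so the defaults are documented assumptions chosen once on
anatomical grounds: 10 mm longitudinal extent for all three subfields,
2 mm transverse extent for CA3, 1.5 mm for the dentate sheet and 4 mm
for the entorhinal band. The reference full-scale populations are
112,000 entorhinal cells, 120,000 granule cells and 25,000 CA3
pyramidal cells, placed uniformly at random (a density-profile hook
exists; the literature does not constrain the in-sheet density, so
uniform is the default). Granule cells are labelled suprapyramidal or
infrapyramidal with probability 0.5 each — the blade split is likewise
not published.

```{r}
library(ca3net)
lay <- build_layout(2240, 2400, 500, seed = 1)
section_membership(lay)[1:3, ]
```

## Spike sources

Entorhinal activity is a renewal process: a homogeneous Poisson
process whose hazard recovers exponentially after each spike,
$\lambda(t) = \lambda_0\,(1 - e^{-\Delta t/\tau})$ with $\tau = 35$ ms.
The published description states the refractory form and the realized
rates (5 Hz entorhinal; 0.62 Hz for the random dentate surrogate) but
not the hazard equation; the chosen form is the minimal hazard with
exponential recovery. The base rate $\lambda_0$ is calibrated by
root-finding on the semi-analytic mean-ISI map so the *realized* rate
matches the target — we read the published "mean firing rate" as the
realized rate, since that is what a raster exhibits. Sampling uses
exact thinning against the dominating rate $\lambda_0$, and every
neuron draws from an independent substream derived from
`(seed, neuron id)`, which makes rasters reproducible under any
generation order.

Spike trains are binned at 1 ms into binary (clipped, not counted)
vectors, matching the binary-train convention of the correlation
statistic.

## Connectivity

**Perforant path.** Lateral and medial entorhinal cells (a configurable
0.5/0.5 split) project to the distal and proximal stratum
lacunosum-moleculare respectively. Each axon's terminal field is a
Gaussian along the longitudinal axis of the target, centered at the
image of the cell's position under a monotone topographic map
(identity on normalized position by default; the quantitative
entorhinal-dentate map lives in prior literature and is consumed as
configuration). The published field span of 1-1.5 mm is read as the
±2 sd mass of the Gaussian, so sd = span/4 with a default span of
1.25 mm. Fields are truncated and renormalized at the sheet edges. The
transverse profile is uniform: the published topography is
longitudinal, and the distal-greater-than-proximal budget gradient
carries the transverse trend.

**Budgets.** Input counts per CA3 cell are synaptic density times
dendritic length per layer: densities 0.63 (lacunosum, both divisions),
3.61 (radiatum) and 3.15 (oriens) synapses/µm, with layer lengths
interpolating linearly between the proximal and distal values implied
by the published proximal/distal counts (0/1,658 LEC, 0/1,105 MEC,
11,241/11,281 radiatum, 7,147/17,893 oriens). Sampling is
postsynaptic: presynaptic candidates are drawn with probability
proportional to their field density at the cell, with replacement,
until the budget is met; repeats are multi-synapse contacts. In-degree
therefore equals the budget exactly, by construction.

**Mossy fibers.** Each granule cell sends one fiber that enters CA3c
at its longitudinal level, runs transversely through CA3c and CA3b,
and bends toward the temporal pole within CA3a. The deviation-vs-
transverse-position profile is a natural cubic spline through package
control points with Gaussian control-point jitter (sd 0.05 mm), so the
expected path equals the noiseless spline. Neither the control points
nor the bend amplitude are published numerically; the default bend of
0.5 mm is chosen so that the arc-length stretch of the bend does not
cancel the published inter-synapse spacing gradient (162 µm CA3c,
223 µm CA3b, 345 µm CA3a) — at 1 mm the stretched CA3a arc would pack
as many synapses per unit area as CA3b, contradicting the decreasing
density that the source anatomy reports. Synapses follow an
inhomogeneous Poisson process along arc length at rate 1/mean(region);
each synapse is assigned to one CA3 cell drawn uniformly among cells
within 30 µm, or dropped (and counted) if none is in range. Fibers are
not clamped at the sheet edge: a path that leaves the sheet simply
places synapses where no cell can capture them, which avoids an
artificial pile-up of fibers along the temporal border.
Infrapyramidal-origin fibers target the proximal stratum oriens while
inside CA3c and the stratum lucidum beyond; suprapyramidal fibers
target the lucidum throughout.

**Associational system.** Every CA3 cell's axon field is a
two-dimensional skew-Gaussian — a product of two one-dimensional
skew-normal densities $f(z) = 2\phi(z)\Phi(\alpha z)$ — whose
parameters are interpolated bilinearly (extrapolated linearly) from a
3×3 grid of parameter sets indexed by injection position
(septal/middle/temporal × CA3c/b/a). The fitted grid values are not
published; the shipped grid is a qualitative placeholder (fields
elongated longitudinally, skewed away from the injection site) and is
plain configuration. Associational edges split between radiatum and
oriens according to the two layer budgets.

**Delays.** Axons are represented as conduction delays: path length
divided by 0.32 m/s (perforant path), 0.27 m/s (mossy fibers) or
0.39 m/s (associational). Path length is Euclidean sheet distance for
perforant-path and associational edges (for the perforant path,
measured from the field's mapped entry point at the proximal border)
and arc length along the fiber for mossy-fiber edges.

```{r}
conn <- build_connectome(lay, connectome_config(budget_fraction = 0.02),
                         seed = 2)
conn
```

## Neuron and synapse models

CA3 pyramidal cells are reduced to 8 compartments in a chain — distal
and proximal oriens, soma, lucidum, proximal and distal radiatum,
proximal and distal lacunosum-moleculare — one per afferent layer,
each pathway targeting exactly one compartment. The channel-level
parameters of the original reduced models live in supplementary
material that is not available, so the package uses standard
Hodgkin-Huxley formalisms for the listed channel families (transient
Na, delayed-rectifier K, A-type K, M-type K, high-threshold Ca, fast
Ca-and-voltage-dependent K, slow Ca-dependent AHP K, HCN, leak;
Pinsky-Rinzel/Traub-derived kinetics with tabulated rates) and ships
three presets hand-tuned so a standard somatic step (0.3 nA, 1 s)
expresses the three CA3 firing types: bursting, strongly adapting and
weakly adapting. Classification is rule-based: bursting if the
response opens with ≥3 spikes at ISIs under 10 ms, otherwise by the
adaptation index $(ISI_{last}-ISI_{first})/(ISI_{last}+ISI_{first})$
with threshold 0.3. No quantitative trace match to the original
models is claimed — only the firing-type taxonomy.

Voltage integrates with a fixed-step backward-Euler scheme (tridiagonal
solve per cell per step) at dt = 0.025 ms; gates use exponential Euler
with voltage-tabulated rates. Spikes are upward somatic crossings of
−10 mV with a 2 ms lockout (the threshold and integration scheme are
not published; these are package choices). Determinism: identical
connectome, sources and configuration reproduce output rasters
bit-for-bit.

Synaptic conductances are peak-normalized waveforms: AMPA a double
exponential (analytic peak), NMDA a triple exponential with the peak
found by bracketed root-finding and a sigmoidal magnesium block
$1/(1+e^{-0.062 v}[\mathrm{Mg}^{2+}]/3.57)$. Synapses are
deterministic (no release stochasticity or plasticity). NMDA time
constants (4/40/150 ms, mixing weight 0.6) are documented assumptions:
the unitary-EPSP data cannot constrain them because the magnesium
block suppresses most NMDA current at rest.

### EPSP calibration

Weights and AMPA decay constants are constrained so the somatic
unitary EPSP on the reference cell matches published targets: 0.30 mV
peak for perforant-path and associational synapses (HHW 46.1 ms
lacunosum, 40.9 ms radiatum, 38.0 ms oriens) and 3.2 mV / 135 ms for
the two mossy-fiber targets. Calibration is a two-stage bisection —
decay constant against the half-height width, then weight against the
peak, iterated twice because cable filtering couples them weakly. Two
design choices matter here:

* The AMPA rise constant is held fixed at 1 ms and only the decay
  constant is searched. A fixed rise:decay *ratio* would force the
  135-ms mossy target into a rise time of tens of milliseconds, which
  contradicts both the fast rise of experimental unitary mossy EPSPs
  and the ~9 ms dentate-to-CA3 propagation lag; a fixed small rise
  keeps the search one-dimensional without that distortion.
* The NMDA:AMPA peak-conductance ratio defaults to 0.3. At a ratio of
  1 the residual (~6%) unblocked NMDA current at rest, decaying over
  150 ms, dominates the somatic half-width and makes the 38-46 ms
  targets unreachable on any sensibly fast membrane.

The reference cell for calibration is the weakly adapting preset: its
subthreshold response is linear and drift-free, whereas the adapting
presets' Ca/AHP pools settle over seconds and corrupt small-EPSP
measurement. Network simulations default to the strongly adapting
preset, whose spike-frequency adaptation keeps population rates in the
most plausible regime under the large, slow mossy EPSP (see
Limitations).

```{r}
kin <- default_kinetics()
kin$lucidum$achieved
```

## The space-time correlation map

For binary trains $x, y$ the overlap-normalized cross-correlation at
lag $n$ is
$$(x \star y)[n] = \frac{1}{\sigma_x \sigma_y}\,\frac{1}{L(n)}
  \sum_{m} (x[m]-\mu_x)(y[m+n]-\mu_y),$$
with means and population standard deviations over the full trains and
the sum over the overlap of the shifted trains. The normalization is
read as division by the overlap length $L(n) = N - |n|$ at shift $n$:
that is the only reading under which the autocorrelation equals 1 at
lag 0, which anchors the scale of the statistic. Values are defined
where the overlap holds at least 2 bins.

Maps accumulate pairs by relative position: the signed post-minus-
reference displacement (0.1 mm bins, floor convention) indexes the
spatial bin and the pair's correlation enters every time-lag bin
(1 ms). Every unordered pair contributes both orders — the reverse
order at the negated displacement with the lag axis reversed — so the
point symmetry map$[d,t]$ = map$[-d,-t]$ holds by construction.
Self-pairs are excluded; silent (σ = 0) neurons are dropped with a
logged count; empty bins are `NA`, never zero-filled. Local maps
restrict to pairs with at least one member inside one of the nine
longitudinal × transverse sections, so a pair spanning two sections
contributes to both. Pair enumeration is exhaustive below 2,000 active
neurons and a seeded uniform subsample above. The default maximum lag
is ±500 ms (the published analyses do not state theirs; every analysis
here passes an explicit `max_lag_ms`).

Three derived statistics:

* `peak_correlation()` — maximum over populated bins; at reduced scale
  single-pair bins dominate the raw maximum, so analyses here restrict
  to bins averaging ≥30 pairs (`min_count`).
* `map_noise_bound()` — an analytic null bound: the coincidence count
  feeding a cell is approximately Poisson, and the bound converts its
  upper quantile (Bonferroni-corrected over populated cells, default
  family-wise α = 0.01) into correlation units. Independent-train maps
  stay below it with probability ≥ 1−α.
* `map_spatial_halfwidth()` — a Gaussian fit to the longitudinal
  profile near zero transverse/time lag. By default it fits the
  *covariance* twin of the map: with spatially inhomogeneous rates the
  σ-normalization of the correlation statistic widens the apparent
  profile (in the cluster-dominated limit by a factor of √2), while
  the covariance profile recovers the planted spatial scale
  unbiasedly. For Gaussian clusters of sd $s$, pair co-activation
  decays with sd $\sqrt 2 s$, so the implied cluster sd is the fitted
  profile sd divided by $\sqrt 2$.

## Fixtures and the scale-down policy

The fixture generator plants known structure: background renewal
spiking plus cluster events at Gaussian spatial profiles
(participation probability, temporal jitter), with a ground-truth
event table. Roaming clusters (a fresh center per event) emulate
upstream activity organized by topographic wiring, whose dense regions
appear at varying positions; fixed centers are a harsher test with
persistent rate hot-spots. Fixtures exercise the identical layout and
section machinery as simulations, so the correlation pipeline is
validated end-to-end without any network integration.

Experiments run at a configurable population fraction $s$:

* postsynaptically budgeted pathways scale their in-degree budgets by
  $s$, optionally compensating weights by $1/s$;
* the mossy-fiber pathway instead keeps the 30 µm capture radius and
  subsamples the dentate fiber population by an analytically derived
  fraction (`mf_fiber_fraction()`) that holds the expected MF
  in-degree at its full-scale value. Enlarging the radius would smear
  the ±30 µm longitudinal origin window a CA3 cell samples — exactly
  the topographic structure the correlation analyses probe.

Desk-scale analyses in the tests and the acceptance script use
$s = 0.02$ (500 CA3 cells), 3-5 s of activity, and the cluster
fixture at the 0.62 Hz dentate rate. These sizes were chosen so each
experiment completes in tens of seconds while leaving the measured
directions well clear of their counting noise.

## Known limitations

* **Full-scale quantitative correlation values are out of reach at
  desk scale.** Published peak correlations (order 0.003-0.03) come
  from 25,000-cell maps with ~3×10⁸ pairs; 500-cell maps measure the
  same directions with far fewer pairs per bin. The package reports
  directions and reduced-scale magnitudes, not the full-scale numbers.
* **The wcMF transverse gradient does not reproduce with the shipped
  presets.** With the published mossy EPSP (3.2 mV, 135 ms) and
  in-degree (~50) at 0.62 Hz, the mossy pathway delivers a
  depolarizing integral that mean-drives the reduced cells at any
  weight factor tested (×1-×5); CA3c, with the largest in-degree,
  saturates at its adaptation-limited rate and its normalized pairwise
  correlation falls below CA3b's — the opposite of the published
  CA3c ≥ CA3b ≥ CA3a ordering, whose stated mechanism is the
  decreasing synapse density. The original models' full channel
  repertoire (unavailable supplementary material) evidently kept them
  out of this regime. The corresponding acceptance check is expected
  to fail and is left failing; the perforant-path direction
  (CA3a ≥ CA3c) and the associational-extent direction both reproduce.
* The associational-extent comparison runs with uncompensated
  perforant-path weights: with full $1/s$ compensation at $s = 0.02$
  every unitary EPSP is suprathreshold and the baseline saturates near
  100 Hz, which lands the model in the published *high*-strength
  regime (shrinking extent) for any added recurrence.
* No inhibition (true of the modelled circuit as published), no
  synaptic stochasticity or plasticity, no explicit 3D geometry, no
  local field potentials.
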