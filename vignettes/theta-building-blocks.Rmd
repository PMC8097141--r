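---
title: "Building-block features, theta rhythms and PRCs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building-block features, theta rhythms and PRCs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the neuron and
network models, the quantification protocols, the synthetic model-database
generator, and every place where the design was genuinely open and a
choice had to be made. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The cell model and its integration

All cells are two-regime Izhikevich neurons: a quadratic membrane equation
with capacitance $C_m$ and piecewise scaling factor $k$ ($k_{low}$ at or
below the instantaneous threshold $v_t$, $k_{high}$ above), a linear
recovery variable $u$ with rate $a$ and voltage sensitivity $b$, and a
hybrid reset ($V \ge v_{peak} \Rightarrow V \leftarrow c$,
$u \leftarrow u + d$). The default parameter set is a strongly adapting
CA1 pyramidal-cell fit; a fast-firing PV+ interneuron preset
(`pv_default_params()`) ships for the network model, taken from the
published fitting lineage the network presets build on.

**Integration scheme.** Forward Euler with `dt = 0.04` ms. Euler is the
standard choice for hybrid (discontinuous-reset) systems of this type,
where high-order schemes lose their advantage at the reset. Two guards
back the choice: a convergence test (spike counts identical at `dt` and
`dt/2` over a 1 s, 20 pA step for all parameter sets used in the tests)
and a first-spike-latency test against the same scheme at `dt/16`
(agreement within 1 ms over 2 s). The spike timestamp is the time of the
step at which $V$ first reaches $v_{peak}$, with no sub-step
interpolation: PRC shifts are normalized by periods two to four orders of
magnitude larger than `dt`, so interpolation would change nothing at the
reported precision. The reset is applied at most once per step.

**Initial state.** Every protocol starts "from rest", which the package
takes literally: $(V, u) = (v_r, 0)$ is the exact fixed point of the model
at zero input (at $V = v_r$ both the quadratic term and the $u$-nullcline
vanish), and the resting-equilibrium test verifies that the integrator
holds it to $10^{-6}$ mV over a second. State is re-initialized to
$(v_r, 0)$ for every step of every sweep, so quantification is
bit-reproducible with no carry-over between sweep steps.

## 2. Feature quantification protocols

The three protocols map a parameter set to its quantified
`[SFA, Rheo, PIR]` triplet.

* **Rheobase**: constant currents from −25 to 25 pA in 0.5 pA increments,
  ascending; the first current producing a spike within the first 500 ms
  is the quantified value. The detection window is exposed
  (`window_ms`).
* **PIR**: 1 s hyperpolarizing steps from 0 to −25 pA in 0.5 pA
  increments, released to zero current; the first step at which a spike
  follows the release while none did at the previous step is the
  quantified value. The protocol text does not bound how long after
  release a spike may occur; the package counts spikes within 500 ms of
  step offset (config-exposed). Rebound here is driven by the recovery
  variable: hyperpolarization drives $u$ negative through the $b(V - v_r)$
  term, and the unrecovered negative $u$ acts as an inward current on
  release. Setting $b = 0$ abolishes the effect, which the test suite
  verifies by exhaustive simulation of all 51 steps.
* **SFA**: 1 s steps from 0 to 98 pA inclusive in 2 pA increments. Per
  step, the initial frequency is the inverse of the first interspike
  interval and the final frequency the inverse of the last; one
  least-squares line is fitted to each frequency-vs-current series and
  SFA is the slope difference (initial − final, Hz/pA). Only steps with
  **at least 3 spikes** qualify: with exactly two spikes the initial and
  final intervals coincide and carry no adaptation contrast. Both series
  use the same qualifying set so the slopes are comparable. With fewer
  than two qualifying steps SFA is undefined, with the reason recorded.

For the default cell this yields `[0.4626, 3.5, −5.0]`. The SFA and PIR
values match the published base values for this parameter set (0.46 Hz/pA
and −5.0 pA). The rheobase deserves a note: the published base value for
this cell is 4.0 pA, but under the protocol exactly as stated the model's
first spiking sweep current is 3.5 pA, with the spike at ≈263 ms — well
inside the 500 ms window, converged across `dt` from 0.1 to 0.0025 ms and
confirmed by an independent adaptive-step integration with event
detection. A 4.0 pA outcome would require a detection window of roughly
250 ms or less. The package follows the stated protocol and reports
3.5 pA; `run_base_validation()` checks against the values the stated
protocol actually produces.

## 3. The model database (synthetic-data generator)

The heterogeneity study needs a large population of phenotyped models.
`build_database()` sweeps the Cartesian product of value lists for
$(a, b, d, k_{low})$ — the four parameters that shape the triplet — with
all other parameters fixed, and phenotypes every combination. Rows whose
three features are all undefined are retained but flagged.

**Reference grid.** `default_grid_spec()` uses $a \in [0.0006, 0.0016]$
and $k_{low} \in [0.04, 0.12]$ geometrically spaced, $b \in [1.5, 4]$ and
$d \in [2, 11]$ arithmetically spaced, with the value nearest the default
replaced by the default so the base cell is always a grid member; 10
values per parameter give 10,000 models. The ranges were chosen once,
from per-parameter sensitivity scans, so that the resulting feature
distributions have the qualitative structure the downstream workflows
assume: the base triplet falls in the [High SFA, Medium Rheo, Low PIR]
bands, and the three study populations (MMH, HML, LML) are all
non-empty. Wider ranges (e.g. $a$ up to 0.004, $d$ up to 20) produce so
many strongly adapting, strongly rebounding models that the base cell is
pushed into the middle bands and the HML cell empties out. The grid is a
reference fixture; any `grid_spec()` can be swept.

**Bands.** Low/Medium/High are a tertile split (type-7 quantiles at 1/3
and 2/3) of each feature's defined values — the natural parameter-free
reading of a three-way partition. Narrow/Broad are symmetric intervals
about the base value spanning 20% and 60% of the observed range
(config-exposed fractions), so Narrow ⊂ Broad always holds.

**Selection.** `select_population()` samples qualifying rows uniformly
*with replacement*: a handful of distinct models (the HML cell of the
reference test grid has 4 at $4^4$ resolution) can populate networks of
thousands of cells, mirroring the study design where e.g. 25 distinct
models fill 10,000 network positions. Band membership of every draw is an
invariant checked in the tests. Seeds are mandatory.

What the generator does and does not emulate: it reproduces the
*structure* of the study's supplementary database — regular parameter
variation around a strongly adapting base, feature distributions
partitionable into bands containing the base at HML — but not its exact
histograms or band edges, which depend on an unpublished grid. Passing
tests therefore demonstrate correct mechanics and qualitative structure,
not numeric agreement with the original database.

## 4. The E–I network model

The reference network is 10,000 PYR + 500 PV+ cells. Connectivity is
independent Bernoulli per ordered pair, no self-connections:
PYR→PYR 0.008 (sparse, < 1%), PYR→PV 0.05, PV→PYR 0.3, PV→PV 0.12.
Config validation enforces the sparseness bound at reference scale and
the asymmetry p(PV→PYR) > p(PYR→PV) required by the EPSC/IPSC
amplitude-ratio constraint of the design lineage.

**Synapses** are conductance-based with instantaneous rise and
single-exponential decay; each presynaptic spike increments the target
conductance by the projection weight, and current is
$g\,(E_{rev} - V)$. Reversal potentials are −15 mV (excitatory onto
Izhikevich cells) and −85 mV (inhibitory), per the modelling lineage;
spikes are delivered with a one-integration-step delay. Weights and decay
constants are **presets, not fitted quantities**: the study's own values
live in cited prior work and supplementary material. The shipped presets
(PYR→PYR 0.1 nS/6 ms, PYR→PV 0.1 nS/3 ms, PV→PYR 0.01 nS/8 ms,
PV→PV 0.55 nS/3 ms at reference scale) were tuned once so that the
reduced-scale networks exhibit the study's qualitative regimes — see the
test suite — and are all config-overridable.

**Scaling.** `scale_network()` multiplies cell counts by a factor and
compensates each projection's weight so the product
(presynaptic count × probability × weight) — the expected synaptic load
per target cell — is preserved, probabilities held fixed. The default
working scale in tests is 0.1 (1,000 + 50 cells).

**Drive.** Each cell receives a mean current plus zero-mean noise whose
amplitude is interpreted peak-to-peak (Gaussian SD = amplitude/4). The
default noise process is Ornstein–Uhlenbeck with a 10 ms correlation
time. This is a deliberate choice: the PYR membrane time constant near
rest is $C_m / (k_{low}(v_t - v_r)) \approx 240$ ms, so noise refreshed
every integration step is averaged away almost completely — at the
plausible 10–30 pA amplitudes a white per-step process moves the membrane
by well under a millivolt and the network stays silent. Correlated noise
concentrates the same amplitude at frequencies the membrane can follow.
Piecewise-constant white noise (resampled every `noise_dt` ms) remains
available. PYR cells default to mean 0, amplitude 30 pA (the upper end of
the 10–30 pA fluctuation range in which population bursts occur); PV+
cells to mean 120 pA, amplitude 20 pA, placing them near their ≈130 pA
rheobase so that PYR volleys recruit them.

**Mechanism.** In the E-only configuration, noise-initiated spikes are
amplified by recurrent excitation into near-synchronous population
bursts; each spike increments the slow adaptation variable
($d = 10$ pA per spike, decay $\tau = 1/a \approx 833$ ms), which
terminates the burst and sets the inter-burst interval — the population
rhythm runs at theta (3–4 Hz at the shipped presets) even though single
cells fire slower. Adding the PV+ population preserves the rhythm while
inhibition silences most PYR cells each cycle: participation per cycle
drops (≈0.34 vs ≈0.5 E-only at matched seeds in the acceptance test) and
the mean PYR rate stays below the burst frequency — sparse firing, the
hallmark the E–I design exists to reproduce.

## 5. Rhythm metrics

The population rate (1 ms bins, Hz per cell) is analysed with a Welch
averaged periodogram: 2048 ms Hann windows, 50% overlap, per-segment mean
subtraction. The first 500 ms of every simulation are discarded as
transient. No installed package provides a Welch estimator, so
`welch_psd()` implements it directly (and is itself tested against known
sinusoids and modulated-Poisson ground truth). The spectral peak inside
the search band (default 3–12 Hz) gives the rhythm frequency and power;
"rhythmic" means the peak exceeds 5× the band's median density — a
scale-free criterion, since the study's power units are arbitrary. The
recording must cover at least 10 cycles of the band minimum.

Ground truth for validation comes from
`simulate_modulated_poisson_raster()`: independent Poisson trains with
rate $r(t) = r_0 (1 + m \sin 2\pi f t)$. The acceptance tests recover
$f \in \{4, 7, 10, 15\}$ Hz within spectral resolution, classify
depth-0 (white) rasters as non-rhythmic, and verify that detected power
grows monotonically with modulation depth.

## 6. Phase response curves

`compute_prc()` implements the direct method with an inhibitory pulse
(1 ms, −500 pA by default — an "inhibitory bolus" approximation). The
unperturbed period $\lambda$ is the 9th-to-10th spike interval under
tonic drive; for each phase $i/100$ a *fresh, re-initialized* simulation
delivers the pulse $i\lambda/100$ ms after the 10th spike and measures
the perturbed period $\lambda_p$ as the 10th-to-11th interval. Negative
shifts are phase delays. Because each phase is an independent run,
permuting the evaluation order cannot change anything — the tests verify
that the shared phases of 5- and 10-point grids agree bitwise.

**Reference-period choice.** The shift is normalized as
$(\lambda_u - \lambda_p)/\lambda_u$ with $\lambda_u$ the *unperturbed
10th-to-11th interval*, not $\lambda$ itself. With slow adaptation
($\tau_u \approx 833$ ms) consecutive intervals still drift ≈0.03% per
period around the 10th spike, so normalizing against the 9th-to-10th
interval would give a zero-amplitude pulse a spurious constant shift of
≈$3\times10^{-4}$. Measuring reference and perturbed periods on the same
interval makes the null-perturbation PRC exactly zero; $\lambda$ and
$\lambda_u$ differ by under 0.1%, and $\lambda$ (as stated in the
protocol) still defines the phase spacing and the reported intrinsic
frequency. A transient check warns when the 8th–9th and 9th–10th
intervals differ by more than 1% (strongly adapting corners of the
database trip this; their PRCs remain well-defined but carry the
warning). If a pulse suppresses the next spike entirely within the
simulated window (extended up to 64 periods), the shift is recorded as
`NA` with a warning and excluded from population means.

**Population means.** `mean_prc()` weights each distinct model equally —
the population unit of the study's PRC figures is the distinct model, not
its abundance in the network; abundance weighting is achieved by
repeating entries. The two scalar features are the mean shift at phase
0.3 and the variance of the 99 difference quotients of the 100-point mean
curve (sample variance, as in MATLAB's `var`). Both are checked against
brute-force recomputation. Open question resolved: whether study means
average over distinct models or all network cells is unstated; the
package defaults to distinct models and documents the alternative.

For the default cell at 20 pA the PRC is delay-dominated from phase ≈0.4
onward with a small early-phase advance region — expected, since this
rebound-capable cell can convert early-cycle hyperpolarization into an
advanced rebound spike, matching the study's description of a
phase-advance region for its medium (base-containing) population.

## 7. Workflows, problem sizes and determinism

`run_base_validation()` phenotypes the default cell and fails on
tolerance breach (SFA ±0.02 Hz/pA; Rheo/PIR exact on the 0.5 pA grid);
a deliberately coarse `dt` makes it fail, guarding misconfiguration.
`run_triangle_sweep()` visits feature-band triplets, simulating one
reduced-scale E–I network per feasible vertex and recording empty
vertices as infeasible rows. `run_prc_study()` selects the slow/medium/
fast populations (MMH, HML, LML) and tabulates PRC features against mean
intrinsic frequency over 20:2:30 pA.

The test suite runs at deliberately reduced sizes chosen as a sensible
desk-scale compromise: a $4^4$ = 256-model database (the smallest
reference-grid resolution at which the base cell classifies HML and all
study triplets are populated), 1,000 + 50-cell networks for 6 s, and
20–100-phase PRCs. Every stage consumes randomness only through explicit
seeds: identical config + seed gives bit-identical databases, rasters and
PRCs. There is no command-line binary: the exported functions,
`scripts/acceptance.R` and this vignette are the interface.

## 8. Known limitations

* Model output is spikes; no field-potential (LFP) synthesis.
* Two cell classes only; no gap junctions or other interneuron types.
* Feature bands and network regimes depend on the swept grid; the
  reference grid reproduces the study's qualitative band structure, not
  its exact supplementary histograms or the full-scale frequency/power
  values.
* The rheobase of the default cell quantifies to 3.5 pA under the stated
  protocol, one 0.5 pA grid step below the published 4.0 pA base value
  (section 2); all downstream defaults use the computed value.
* Drive noise is an explicit model choice (OU, 10 ms correlation); white
  per-step noise at realistic amplitudes cannot excite these
  high-capacitance cells.
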