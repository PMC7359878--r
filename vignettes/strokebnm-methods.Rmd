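---
title: "Methods: brain-network models of stroke, rewiring and peri-infarct slow oscillations"
author: "strokebnm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-network models of stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strokebnm` models how a focal cortical stroke reorganises brain activity
at two scales. At the whole-cortex scale, a Kuramoto phase-oscillator
network on a structural connectome generates region-wise oscillatory
activity whose phase-locking-value (PLV) functional connectivity can be
compared, before and after simulated structural damage and rewiring,
with FC changes observed in wide-field calcium imaging. At the local
scale, a spiking network of adaptive exponential integrate-and-fire
(adex) neurons reproduces the slow oscillation of peri-infarct (and
anesthetised) cortex, and a biophysical forward model turns its spikes
into the GCaMP6f fluorescence a two-photon microscope would record.
This vignette documents the models, the parameters that matter, the
numerical choices, and the limits of what the synthetic experiments
demonstrate.

## 1. The Kuramoto brain-network model

Each region `i` of an `N`-region connectome carries a phase
`theta_i(t)`:

    dtheta_i = [ 2*pi*f + (1/N) * sum_j K * w_ij * sin(theta_j - theta_i) ] dt
               + sqrt(2 D dt) * xi_i

with a common natural frequency `f` (Hz), global coupling `K` scaling
the connectome weights `w_ij` (coupling from region `j` onto `i`), and
independent Gaussian white noise of strength `D` (autocorrelation
`2 D delta(t)`). Couplings are instantaneous: at the low frequencies of
calcium imaging, axonal delays are short relative to the oscillation
period, and tract-length information is not generally available for
mesoscale connectomes. The working point used throughout the
stroke-fitting pipeline is `f = 2` Hz, `K = 4.3`, `D = 1`.

Numerics: Euler–Maruyama at `dt = 1` ms (`f*dt = 0.002`, far inside the
stable regime), initial phases uniform on `(-pi, pi]`, a 10 s transient
discarded, and phases recorded at 100 Hz — phases evolve on the `1/f`
timescale, so the 10-fold decimation loses nothing while shrinking PLV
computation by the same factor. The `1/N` prefactor is kept explicit
rather than absorbed into `K`. Runs are bit-reproducible given the seed.

## 2. Structural lesion and rebound operators

A lesion is two numbers. The survival fraction `s` in [0, 1] scales
every afferent and efferent weight of the stroke region homogeneously
(`s = 0` disconnects it; `s = 0.9` removes 10% of each link). Both link
directions are damaged because calcium FC is undirected and the infarct
destroys the tissue, not a fibre direction; afferent-only and
efferent-only modes exist for sensitivity analyses. Damage composes
multiplicatively: lesioning with `s1` then `s2` equals lesioning with
`s1*s2`.

The rebound factor `r` in [0, 5] models post-stroke structural rewiring:
a budget `B = r * (total lost weight)` is added back to the network.
In the default `redistribute` mode the budget goes to the nodes that had
links to the infarct in the healthy connectome, proportionally to that
healthy link strength, and within each node it is spread over its
remaining links proportionally to their current weights — no new links
are created, and the budget is conserved exactly (`sum(out) -
sum(lesioned) = B`, checked to 1e-9 relative). `r > 1` expresses
over-compensation. A `restore` mode instead rebuilds the stroke links
themselves; it is kept because "restored toward the infarct" and
"redistributed along the other links" are both physiologically
defensible readings of post-stroke sprouting, and the choice is
consequential only for the stroke region's own connectivity.

## 3. PLV functional connectivity

The FC pipeline mirrors the analysis of wide-field calcium recordings
(25 Hz sampling): a zero-phase 4th-order Butterworth band-pass to the
upper delta band (2.5–5 Hz, where such recordings carry their
resting-state peak), per-channel instantaneous phases from the analytic
signal (FFT Hilbert transform), and

    PLV_ij = | (1/M) * sum_m exp( 1i * (theta_i(m) - theta_j(m)) ) |

PLV is 1 for any constant phase offset and concentrates around
`sqrt(pi/4)/sqrt(M)` for independent phases. Significance comes from
surrogate ensembles: each channel's Fourier phases are randomised
independently (preserving its power spectrum, destroying cross-channel
phase relations), the PLV matrix is recomputed `n` times (default 100),
and the per-pair 0.95 quantile is the significance floor. Model phases
from the Kuramoto simulation are used directly for model PLV; the
sin → band-pass → Hilbert route exists and is tested to agree within
0.05 RMS when `f` lies inside the band (pipeline-parity check).

FC change versus the healthy condition defaults to the bounded
`difference` mode (`PLV_cond - PLV_ref`); `relative` is available since
small reference PLVs make ratios unstable.

## 4. Fitting lesion parameters to observed FC changes

`model_change_grid()` simulates, for every `(s, r)` cell of an 11 × 11
grid (`s` in 0–1 by 0.1, `r` in 0–5 by 0.5), the healthy and the
lesioned/rewired network with *shared* noise seeds — the paired design
cancels most of the Monte-Carlo error of the difference — and stores the
seed-averaged FC change on the analysis subset (12 regions outside the
stroke core, mirroring the exclusion of tissue-displaced regions in the
imaging analysis). `fit_parameter_grid()` then correlates (Pearson, on
strictly-upper-triangle vectors) an observed FC change with each cell's
model change; the argmax is the fitted lesion, ties breaking toward
smaller damage, then smaller rebound. One model grid serves every
condition fitted against it (stroke and rehabilitation), which is also
why the library is a first-class object. Changes are averaged across
seeds *before* correlating: averaging per-seed correlations instead
would attenuate noisy cells unequally and bias the argmax toward
strong-lesion cells.

**What the fit can and cannot identify.** To first order the model FC
change decomposes as `(1 - s) * [damage_direction + r *
rebound_direction]`: the survival fraction `s` sets mostly the
*magnitude* of the pattern, the rebound factor `r` its *direction*.
Pearson correlation is scale-invariant, so the fit localises `r` sharply
(in the packaged recovery experiment, within one grid cell in 10/10
replicates) while `s` is constrained only by weak second-order
curvature — the fit surface shows a ridge over `s`, matching the broad
"recovery path" plateaus such grids exhibit. Parameter-recovery claims
in this package are therefore stated for `r`; recovering `s` from a
single condition's normalized FC change is not possible at realistic
noise levels, and the test suite reports the empirical bias of both.

## 5. The synthetic connectome and ground-truth experiments

No atlas download is required: `generate_synthetic_connectome()` draws a
directed Erdős–Rényi graph (density 0.3) with log-normal weights (the
heavy-tailed form of tract-tracing connectomes) and builds the stroke
region as a hub connected to every other region at 2.5× the median link
weight — a lesion must have a measurable network-wide FC footprint to be
worth fitting. `generate_ground_truth_experiment()` scales weights by 2
so that `K = 4.3` sits in the partially synchronised regime where FC is
sensitive to structure, simulates "stroke" and "rehab" conditions at
known `(s, r)`, restricts to the 12-region analysis subset, adds
truncated-Gaussian observation noise (σ configurable; the recovery
study uses 0.02), and records every parameter and seed in a manifest
for bit-identical regeneration. Three simulation seeds per condition
(healthy/lesioned pairs sharing seeds) give the "empirical" matrices a
stable pattern at desk-scale cost.

What the generator does *not* emulate: the spatial block structure of
real cortical FC (somatosensory/visual modules), hemodynamic or optical
artefacts, and any geometry — "nearest neighbours of the core" is
defined by connection strength, not distance.

## 6. The adex slow-oscillation network

Both cell classes follow the adaptive exponential integrate-and-fire
equations (mV, ms, nS, pF, pA):

    Cm dV/dt   = Gl(El - V) + Gl*Delta_V*exp((V - V_thre)/Delta_V)
                 + ge(Ee - V) + gi(Ei - V) - w + I_ext + sigma*xi(t)
    tau_w dw/dt = a(V - El) - w ,   w <- w + b at each spike

with printed physiology: `Gl = 10` nS, `Cm = 150` pF, `V_thre = -50`,
`V_reset = -65`, `T_refrac = 5` ms; RS (excitatory): `El = -60`,
`Delta_V = 2.0`, `a = 4` nS, `tau_w = 500` ms; FS (inhibitory):
`El = -65`, `Delta_V = 0.5`, `a = b = 0`. The spike-triggered adaptation
increment `b` is the anesthesia knob: 60 pA for deep, 20 pA for light
anesthesia. The adaptation equation uses the stated `tau_w = 500` ms;
an alternative form in which `w` decays with the membrane constant
`Cm/Gl` is available behind `literal_adaptation = TRUE` for comparison
(15 ms adaptation cannot support a ~2 Hz rhythm).

The network architecture is not dictated by the neuron equations and was
chosen from the standard RS/FS slow-oscillation literature, then
calibrated once and frozen: 1600 RS + 400 FS neurons, connection
probability 0.02, conductance-based exponential synapses
(`tau_syn = 5` ms, `Ee = 0`, `Ei = -80` mV) with quantal conductances
`Q_exc = 2` nS, `Q_inh = 10` nS, membrane current noise `sigma = 280`
pA·sqrt(ms), and a constant RS drive `I_ext = 40` pA. The calibration
targets were a ~2.1 Hz fluorescence spectral peak at `b = 60` pA and the
correct ordering versus `b = 20` pA. The drive matters mechanically:
with purely noise-ignited Down-to-Up transitions the cycle time is an
exponential waiting time — irregular, and paradoxically *slower* at low
`b` because weakly adapted Up states last longer and accumulate more
total adaptation. A modest depolarizing drive moves ignition to the
moment the adaptation current has decayed sufficiently, so the Down
duration is set by `tau_w` and by how much `w` each Up state accrues —
which restores the physiological ordering (less adaptation → faster
rhythm). With the frozen defaults, 10 seeds of 30 s runs give median
spectral peaks of 2.10 Hz (`b = 60`) and 2.32 Hz (`b = 20`), ordered
correctly in every seed.

Numerics: forward Euler at `dt = 0.1` ms with the exponential term
capped (any capped step fires a spike the same step anyway, so the guard
is inert in practice); spikes are detected at the upward `V >= V_thre`
crossing before reset; `V` is clamped during the refractory period while
`w` and the synapses keep evolving. The membrane noise stream comes from
an internal xoshiro256++ generator with Box–Muller normals, seeded
deterministically from the run seed — the simulation draws hundreds of
millions of normals per run, and this keeps the generator out of the
inner-loop bottleneck while preserving exact reproducibility.

## 7. From spikes to GCaMP6f fluorescence

The forward model is a chain of four closed-form stages, all in
mV/ms/nM units at the recorded trace resolution (0.5 ms):

1. *Spike reconstruction*: the integrate-and-fire trace replaces action
   potentials by a reset, so a stereotyped rectangular spike
   (`+30` mV, 1 ms) is painted over the recorded membrane potential at
   each spike time. The Boltzmann activation saturates above ~0 mV, so
   the exact waveform shape is immaterial to the calcium integral.
2. *L-type calcium current*: `I_Ca = g_Ca * s(V) * (V - E_Ca)` with
   `s(V) = 1/(1 + exp(-(V - V_half)/rho))`, `g_Ca = 5` mS/cm²,
   `E_Ca = 120` mV, `V_half = -25` mV, `rho = 5` mV.
3. *Calcium pool*: `d[Ca]/dt = -k_Ca * I_Ca - ([Ca] - Ca_basal)/tau_Ca`
   with `k_Ca = 0.002` (nM/ms)/(µA/cm²), `tau_Ca = 760` ms, basal 0 nM;
   integrated as an exact first-order recursion (`tau_Ca >> dt`).
4. *Indicator*: Hill saturation
   `F = dF + K_F * Ca^n_H / (Ca^n_H + k_d^n_H)` with `K_F = 10`,
   `k_d = 375` nM (GCaMP6f), `n_H = 2.3`. The dissociation constant is
   raised to the Hill exponent so that `F(k_d)` is exactly
   half-saturation and the denominator is dimensionally homogeneous; the
   unexponentiated variant is available behind `literal_kd = TRUE`.

Population fluorescence averages the per-neuron traces of a recorded
subset (100 RS / 25 FS neurons by default); with 2000 statistically
exchangeable neurons, a 100-neuron average is spectrally
indistinguishable from the full-population mean while keeping memory
flat. Subthreshold fluctuations do contribute to `I_Ca` between spikes
(the current is applied to the full trace), but at `-60` mV the channel
is ~3 orders of magnitude below saturation, so spikes dominate.

The slow-oscillation frequency is read as the maximum of a Welch power
spectrum (Hann window, 50% overlap, 4× zero-padding, per-segment mean
removal) within 0.5–10 Hz; a peak below twice the band's median power is
reported as `NA` rather than a number (flat-spectrum guard). Because
`tau_Ca` acts as a ~0.2 Hz low-pass, the fluorescence spectrum is
reddened relative to the firing-rate spectrum; with the frozen network
the peak survives and coincides with the rate peak, which is itself a
useful cross-check (`population_rate()` pathway).

## 8. Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is a pure function
of its arguments; manifests make fixtures bit-regenerable. The packaged
experiments use desk-scale sizes chosen for statistical stability: 18
regions and 120 s of simulated activity per Kuramoto run (about 0.25 s
of compute each), 6 shared seeds per model-grid cell, 10 replicate
datasets for the recovery study, and ten 30 s runs of the 2000-neuron
adex network per anesthesia regime. The acceptance script
(`scripts/acceptance.R`) reruns the adex/fluorescence pipeline from
scratch at exactly these sizes.

## 9. Known limitations

* The Kuramoto model is phenomenological: identical natural frequencies,
  no delays, no amplitude dynamics. It addresses phase coherence only.
* The fit objective (normalized pattern correlation of FC changes)
  identifies the rebound factor but leaves the damage magnitude on a
  ridge (section 4); treat fitted `s` from a single condition as weakly
  constrained.
* The adex architecture beyond the printed neuron physiology is a
  calibrated model choice; the slow-oscillation frequencies are robust
  to the seed but not claimed to be robust to, e.g., halving the network
  size.
* The synthetic connectome reproduces heavy-tailed weights and a hub
  stroke region, not the modular geometry of a real cortical atlas, so
  passing recovery tests demonstrate the pipeline's statistical
  machinery, not fidelity to mouse anatomy.
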