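# strokebnm

Brain-network models of stroke, structural rewiring and peri-infarct
slow oscillations.

After a focal cortical stroke — experimentally, a photothrombotic lesion
of the right primary motor cortex (rM1) in mice — brain activity
reorganises at two scales: long-range functional connectivity (FC)
between cortical regions changes as the structural connectome is damaged
and rewired during recovery, and the local network around the infarct
switches to a slow, anesthesia-like oscillation. `strokebnm` provides
simulation and inference tools for both phenomena, for computational
neuroscientists who want to relate imaging observations to candidate
structural and cellular mechanisms without any external data downloads:

* **Connectome operators** — a weighted directed region-by-region
  coupling matrix with a designated stroke region; a lesion operator
  that scales the infarct's links by a survival fraction `s ∈ [0, 1]`,
  and a rebound operator that redistributes `r ∈ [0, 5]` times the lost
  weight over the links of the formerly infarct-connected nodes
  (conserving the budget exactly).
* **Kuramoto brain-network model** — stochastic phase oscillators
  `dθ_i = [2πf + (1/N) Σ_j K w_ij sin(θ_j − θ_i)] dt + √(2D dt) ξ_i`
  on the connectome (compiled core; bit-reproducible given the seed).
* **Phase-locking-value FC** — band-pass (2.5–5 Hz upper delta for
  calcium signals), Hilbert phases,
  `PLV_ij = |(1/M) Σ_m e^{i(θ_i(m)−θ_j(m))}|`, surrogate significance
  thresholds, FC-change matrices, and a grid fit of `(s, r)` to an
  observed FC change by Pearson correlation of upper-triangle vectors.
* **Adex spiking network** — 1600 regular-spiking + 400 fast-spiking
  adaptive exponential integrate-and-fire neurons whose spike-triggered
  adaptation increment `b` models anesthesia depth (60 pA deep, 20 pA
  light).
* **Calcium/GCaMP6f forward model** — reconstructed spike waveforms →
  L-type calcium current (Boltzmann activation) → first-order calcium
  pool (τ = 760 ms) → Hill-saturating fluorescence (k_d = 375 nM,
  n_H = 2.3), per neuron and population-averaged.
* **Synthetic-data generators** — hub-structured synthetic connectomes,
  ground-truth lesion experiments with manifests, calcium-like region
  signals, Poisson spike trains.

## Worked example

```r
library(strokebnm)

## a synthetic 18-region connectome with a hub stroke region
conn <- generate_synthetic_connectome(18, seed = 42)
#> <connectome> 18 regions, 114 directed links, total weight 215.7
#>   stroke region: rM1

## 70% damage to rM1's links, rebound = 1 (full redistribution)
spec     <- lesion_spec(retain = 0.3, rebound = 1.0)
lesioned <- apply_stroke(conn, spec)
rewired  <- apply_rebound(conn, spec)
sum(conn$weights) - sum(lesioned$weights)   # weight lost: 64.97
sum(rewired$weights) - sum(lesioned$weights) # weight restored: 64.97

## simulate both conditions and compare phase-locking FC
kp   <- kuramoto_params(duration = 60, transient = 10, seed = 7)
ph_h <- simulate_phases(conn, kp)
ph_l <- simulate_phases(rewired, kp)
mean(order_parameter(ph_h))                  # global synchrony 0.666
chg  <- fc_change(plv_matrix(ph_l), plv_matrix(ph_h))
mean(abs(chg$delta[upper.tri(chg$delta)]))   # mean |PLV change| 0.075

## peri-infarct slow oscillation under deep anesthesia (b = 60 pA)
run <- simulate_network(network_architecture(), adex_params("RS", b = 60),
                        adex_params("FS"), duration = 30, seed = 1)
#> <adex_run> 2000 neurons (1600 RS / 400 FS), 30 s, 393191 spikes (6.55 Hz mean)
fl  <- population_fluorescence_from_run(run, population = "exc")
oscillation_frequency(fl, band = c(0.5, 10)) # spectral peak 2.17 Hz
```

The numbers shown are the actual output of this script. Lowering the
adaptation increment to `b = 20` pA (light anesthesia) speeds the rhythm
up to ≈ 2.3 Hz — the anesthesia-depth dependence the local model exists
to reproduce.

For lesion-parameter inference, build a model library once with
`model_change_grid()` and fit any number of observed FC-change matrices
against it with `fit_parameter_grid()`; see the methods vignette
(`vignettes/strokebnm-methods.Rmd`) for the model equations, calibration
choices, and a frank account of which lesion parameter the fit can
identify (the rebound factor) and which it cannot (the damage
magnitude, which normalized pattern correlation leaves on a ridge).

A command-line front end covering the main operations (`lesion`,
`simulate-bnm`, `fc`, `fit-grid`, `simulate-adex`, `forward-calcium`,
`make-fixtures`) is installed at `inst/cli/strokebnm`.

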