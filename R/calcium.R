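#' Calcium and GCaMP6f fluorescence parameters
#'
#' Constants of the spikes-to-fluorescence forward model: an L-type
#' high-voltage-activated calcium current with Boltzmann activation, a
#' first-order intracellular calcium pool, and a Hill-saturating
#' fluorescent indicator (GCaMP6f).
#'
#' @param E_Ca calcium reversal potential (mV).
#' @param g_Ca maximal calcium conductance (mS/cm^2).
#' @param V_half Boltzmann half-activation voltage (mV).
#' @param rho Boltzmann slope factor (mV).
#' @param k_Ca current-to-concentration coupling ((nM/ms)/(uA/cm^2)).
#' @param tau_Ca calcium decay time constant (ms).
#' @param Ca_basal basal calcium concentration (nM).
#' @param dF fluorescence offset. @param K_F fluorescence scale.
#' @param k_d indicator dissociation constant (nM).
#' @param n_H Hill coefficient.
#' @param spike_peak amplitude of the reconstructed spike waveform (mV).
#' @param spike_width duration of the reconstructed spike (ms).
#' @param literal_kd if `TRUE`, the Hill denominator uses `k_d` without
#'   the Hill exponent (an alternative printed form; the default applies
#'   the exponent, which gives exact half-saturation at `Ca = k_d` and is
#'   dimensionally consistent).
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(E_Ca = 120, g_Ca = 5, V_half = -25, rho = 5,
                           k_Ca = 0.002, tau_Ca = 760, Ca_basal = 0,
                           dF = 0, K_F = 10, k_d = 375, n_H = 2.3,
                           spike_peak = 30, spike_width = 1,
                           literal_kd = FALSE) {
  if (tau_Ca <= 0 || k_d <= 0 || n_H <= 0 || rho <= 0)
    stop("tau_Ca, k_d, n_H and rho must be positive", call. = FALSE)
  structure(list(E_Ca = E_Ca, g_Ca = g_Ca, V_half = V_half, rho = rho,
                 k_Ca = k_Ca, tau_Ca = tau_Ca, Ca_basal = Ca_basal,
                 dF = dF, K_F = K_F, k_d = k_d, n_H = n_H,
                 spike_peak = spike_peak, spike_width = spike_width,
                 literal_kd = literal_kd),
            class = "calcium_params")
}

#' Overwrite clamped spikes with a stereotyped waveform
#'
#' Integrate-and-fire membrane traces replace the action potential by a
#' reset/clamp, so the suprathreshold excursion that drives the calcium
#' channel is missing. This paints a stereotyped spike (rectangular
#' pulse of amplitude `spike_peak` lasting `spike_width`) over the trace
#' at each spike time; all other samples are unchanged. The exact shape
#' is immaterial because the Boltzmann activation saturates above ~0 mV.
#'
#' @param vm membrane trace (mV), sampled at `dt`.
#' @param spike_times spike times (s) within the trace span.
#' @param dt sampling interval of `vm` (ms).
#' @param params a [calcium_params()].
#' @return The membrane trace with reconstructed spikes.
#' @export
reconstruct_spike_waveforms <- function(vm, spike_times, dt,
                                        params = calcium_params()) {
  if (length(spike_times) == 0L) return(vm)
  t_ms <- sort(spike_times) * 1000
  if (any(t_ms < 0) || any(t_ms / dt > length(vm) + 0.5))
    stop("spike time outside the trace span", call. = FALSE)
  if (any(diff(t_ms) < params$spike_width))
    stop("reconstructed spikes overlap: inter-spike interval below spike_width ",
         "(violates the refractory contract upstream)", call. = FALSE)
  width_samp <- max(1L, round(params$spike_width / dt))
  out <- vm
  n <- length(vm)
  for (tm in t_ms) {
    i0 <- min(n, max(1L, round(tm / dt)))
    i1 <- min(n, i0 + width_samp - 1L)
    out[i0:i1] <- params$spike_peak
  }
  out
}

#' L-type calcium current from a membrane trace
#'
#' `I_Ca = g_Ca * s(V) * (V - E_Ca)` with the Boltzmann activation
#' `s(V) = 1 / (1 + exp(-(V - V_half)/rho))`. The current is inward
#' (negative) for all `V < E_Ca`.
#'
#' @param vm membrane trace (mV).
#' @param params a [calcium_params()].
#' @return Current trace (uA/cm^2), same length as `vm`.
#' @export
calcium_current <- function(vm, params = calcium_params()) {
  if (any(!is.finite(vm))) stop("non-finite membrane potential", call. = FALSE)
  params$g_Ca * boltzmann_s(vm, params) * (vm - params$E_Ca)
}

# steady-state channel activation
boltzmann_s <- function(vm, params) {
  1 / (1 + exp(-(vm - params$V_half) / params$rho))
}

#' Integrate the intracellular calcium pool
#'
#' Forward Euler integration of
#' `d[Ca]/dt = -k_Ca * I_Ca - ([Ca] - Ca_basal) / tau_Ca`
#' from `[Ca](0) = Ca_basal`. Inward (negative) current raises the
#' concentration, which then relaxes back with `tau_Ca`.
#'
#' @param i_ca current trace (uA/cm^2) sampled at `dt`.
#' @param dt sampling interval (ms).
#' @param params a [calcium_params()].
#' @return A `calcium_trace`: list with `ca` (nM) and `dt` (ms).
#' @export
integrate_calcium <- function(i_ca, dt, params = calcium_params()) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  # Ca[t+1] = Ca[t] * (1 - dt/tau) + dt * (-k*I[t] + basal/tau):
  # a first-order linear recursion, evaluated by a recursive filter
  decay <- 1 - dt / params$tau_Ca
  drive <- dt * (-params$k_Ca * i_ca + params$Ca_basal / params$tau_Ca)
  ca <- as.numeric(stats::filter(drive, decay, method = "recursive",
                                 init = params$Ca_basal))
  if (any(ca < 0)) {
    warning("negative calcium concentration clamped to 0 ",
            "(outward calcium current exceeded the pool)")
    ca <- pmax(ca, 0)
  }
  structure(list(ca = ca, dt = dt), class = "calcium_trace")
}

#' GCaMP6f fluorescence from calcium
#'
#' Hill saturation of the indicator:
#' `F = dF + K_F * Ca^n_H / (Ca^n_H + k_d^n_H)`, half-saturating at
#' `Ca = k_d` and approaching `dF + K_F` for large calcium.
#'
#' @param ca a `calcium_trace` or numeric concentration vector (nM).
#' @param params a [calcium_params()].
#' @return A `fluorescence_trace`: list with `f` (a.u.) and `dt` (ms; `NA`
#'   when the input was a bare vector).
#' @export
fluorescence <- function(ca, params = calcium_params()) {
  if (inherits(ca, "calcium_trace")) {
    x <- ca$ca
    dt <- ca$dt
  } else {
    x <- as.numeric(ca)
    dt <- NA_real_
  }
  if (any(x < 0)) stop("calcium concentration must be nonnegative", call. = FALSE)
  kden <- if (params$literal_kd) params$k_d else params$k_d^params$n_H
  f <- params$dF + params$K_F * x^params$n_H / (x^params$n_H + kden)
  structure(list(f = f, dt = dt), class = "fluorescence_trace")
}

#' Population-averaged fluorescence
#'
#' Arithmetic mean per time point across the traces of each population,
#' emulating the spatially averaged two-photon signal of a cell class.
#'
#' @param traces list of `fluorescence_trace` objects (equal lengths).
#' @param populations character vector of population labels, one per
#'   trace (default: a single population `"all"`).
#' @return Named list of [signal_timeseries()], one per population.
#' @export
population_fluorescence <- function(traces, populations = NULL) {
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  if (is.null(populations)) populations <- rep("all", length(traces))
  if (length(populations) != length(traces))
    stop("one population label per trace required", call. = FALSE)
  lens <- vapply(traces, function(tr) length(tr$f), integer(1L))
  if (length(unique(lens)) != 1L)
    stop("traces must have equal length", call. = FALSE)
  dt <- traces[[1L]]$dt
  out <- list()
  for (pop in unique(populations)) {
    idx <- which(populations == pop)
    m <- do.call(rbind, lapply(traces[idx], function(tr) tr$f))
    out[[pop]] <- signal_timeseries(matrix(colMeans(m), nrow = 1L),
                                    fs = 1000 / dt, labels = pop)
  }
  out
}

#' Full spikes-to-fluorescence chain for a recorded adex population
#'
#' For each recorded neuron of the requested population: paints the
#' stereotyped spikes over the recorded membrane trace
#' ([reconstruct_spike_waveforms()]), computes the calcium current
#' ([calcium_current()]), integrates the calcium pool
#' ([integrate_calcium()]) and applies the indicator Hill curve
#' ([fluorescence()]); then averages across neurons.
#'
#' @param run an `adex_run` from [simulate_network()].
#' @param params a [calcium_params()].
#' @param population `"exc"` or `"inh"`.
#' @return A one-channel [signal_timeseries()] of the population-mean
#'   fluorescence at the run's recorded sampling rate.
#' @export
population_fluorescence_from_run <- function(run, params = calcium_params(),
                                             population = c("exc", "inh")) {
  population <- match.arg(population)
  stopifnot(inherits(run, "adex_run"))
  pop_of_rec <- run$population[run$recorded]
  rows <- which(pop_of_rec == population)
  if (length(rows) == 0L)
    stop("no recorded neurons in population '", population, "'", call. = FALSE)
  dt <- run$record_dt
  traces <- lapply(rows, function(rw) {
    neuron <- run$recorded[rw]
    st <- run$spikes$time_s[run$spikes$neuron == neuron]
    vm <- reconstruct_spike_waveforms(run$vm[rw, ], st, dt, params)
    fluorescence(integrate_calcium(calcium_current(vm, params), dt, params),
                 params)
  })
  population_fluorescence(traces)[["all"]]
}
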