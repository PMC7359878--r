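#' Adex neuron parameters
#'
#' Parameters of the adaptive exponential integrate-and-fire neuron in
#' mV/ms/nS/pF/pA units. The two presets correspond to the cortical cell
#' classes used in the slow-oscillation network: regular-spiking (RS,
#' excitatory, adapting) and fast-spiking (FS, inhibitory, non-adapting,
#' `a = b = 0`).
#'
#' The spike-triggered adaptation increment `b` is the anesthesia knob:
#' `b = 60` pA models deep anesthesia, `b = 20` pA light anesthesia.
#'
#' @param type `"RS"` or `"FS"` preset.
#' @param Gl leak conductance (nS). @param Cm membrane capacitance (pF).
#' @param El resting potential (mV; -60 RS, -65 FS).
#' @param Delta_V spike-initiation steepness (mV; 2.0 RS, 0.5 FS).
#' @param V_thre spike threshold (mV). @param V_reset reset potential (mV).
#' @param T_refrac refractory period (ms).
#' @param tau_w adaptation time constant (ms).
#' @param a subthreshold adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @param tau_syn synaptic decay time constant (ms).
#' @param E_syn_exc,E_syn_inh excitatory/inhibitory reversal potentials (mV).
#' @param sigma membrane current-noise amplitude (pA sqrt(ms); white-noise
#'   current of standard deviation `sigma/sqrt(dt)` at step `dt`).
#' @param I_ext constant external depolarizing drive (pA; 40 for RS, 0
#'   for FS). Together with `sigma` it sets the Down-to-Up ignition rate
#'   of the slow oscillation.
#' @param literal_adaptation if `TRUE`, the adaptation variable decays
#'   with the membrane time constant `Cm/Gl` instead of `tau_w` (an
#'   alternative printed form of the model, kept for comparison).
#' @return An object of class `adex_params`.
#' @export
adex_params <- function(type = c("RS", "FS"),
                        Gl = 10, Cm = 150,
                        El = if (type == "RS") -60 else -65,
                        Delta_V = if (type == "RS") 2.0 else 0.5,
                        V_thre = -50, V_reset = -65, T_refrac = 5,
                        tau_w = 500,
                        a = if (type == "RS") 4 else 0,
                        b = if (type == "RS") 60 else 0,
                        tau_syn = 5, E_syn_exc = 0, E_syn_inh = -80,
                        sigma = 280, I_ext = if (type == "RS") 40 else 0,
                        literal_adaptation = FALSE) {
  type <- match.arg(type)
  force(El); force(Delta_V); force(a); force(b); force(I_ext)
  if (Gl <= 0 || Cm <= 0) stop("conductances and capacitance must be positive",
                               call. = FALSE)
  if (V_reset > V_thre) stop("V_reset must not exceed V_thre", call. = FALSE)
  if (b < 0) stop("b must be nonnegative", call. = FALSE)
  if (tau_w <= 0 || tau_syn <= 0) stop("time constants must be positive",
                                       call. = FALSE)
  structure(list(type = type, Gl = Gl, Cm = Cm, El = El, Delta_V = Delta_V,
                 V_thre = V_thre, V_reset = V_reset, T_refrac = T_refrac,
                 tau_w = tau_w, a = a, b = b, tau_syn = tau_syn,
                 E_syn_exc = E_syn_exc, E_syn_inh = E_syn_inh,
                 sigma = sigma, I_ext = I_ext,
                 literal_adaptation = literal_adaptation),
            class = "adex_params")
}

#' Network architecture for the RS/FS adex network
#'
#' Population sizes, random-connectivity probability, and synaptic quantal
#' conductances. These are model choices (they are not uniquely determined
#' by the neuron equations); the defaults, together with the membrane
#' noise `sigma` in [adex_params()], were calibrated once so that the
#' deep-anesthesia network (`b = 60` pA) oscillates near 2.1 Hz, and are
#' frozen here.
#'
#' @param N_exc,N_inh excitatory/inhibitory population sizes.
#' @param p_connect connection probability per ordered neuron pair.
#' @param Q_exc,Q_inh excitatory/inhibitory quantal conductances (nS).
#' @param seed integer seed for the random connectivity.
#' @return An object of class `network_architecture`.
#' @export
network_architecture <- function(N_exc = 1600L, N_inh = 400L,
                                 p_connect = 0.02,
                                 Q_exc = 2, Q_inh = 10, seed = 1L) {
  if (N_exc < 1L || N_inh < 1L) stop("populations must be nonempty", call. = FALSE)
  if (p_connect <= 0 || p_connect > 1)
    stop("p_connect must be in (0, 1]", call. = FALSE)
  structure(list(N_exc = as.integer(N_exc), N_inh = as.integer(N_inh),
                 p_connect = p_connect, Q_exc = Q_exc, Q_inh = Q_inh,
                 seed = as.integer(seed)),
            class = "network_architecture")
}

# CSR out-adjacency (0-based) for a directed Erdos-Renyi graph without
# self-connections, seed-deterministic.
build_adjacency <- function(arch) {
  set.seed(arch$seed)
  n <- arch$N_exc + arch$N_inh
  tgt <- vector("list", n)
  for (j in seq_len(n)) {
    hit <- which(stats::runif(n) < arch$p_connect)
    hit <- hit[hit != j]
    tgt[[j]] <- hit - 1L
  }
  counts <- lengths(tgt)
  list(targets = as.integer(unlist(tgt)),
       ptr = as.integer(c(0L, cumsum(counts))))
}

#' Simulate the RS/FS adex network
#'
#' Integrates the conductance-based two-population adex network by
#' forward Euler with an overflow-guarded exponential term. A spike is
#' registered at the step where V crosses `V_thre` upward; V is reset and
#' clamped for `T_refrac`, and the adapting (RS) neurons increment their
#' adaptation current by `b`. Membrane noise is a white-noise current of
#' amplitude `sigma` in each population. The run is a deterministic
#' function of `(arch, params, duration, seed)`.
#'
#' @param arch a [network_architecture()].
#' @param params_exc,params_inh [adex_params()] for the two populations.
#' @param duration simulated time (s), at least 1 s.
#' @param seed integer seed for initial conditions and membrane noise
#'   (connectivity has its own seed in `arch`).
#' @param dt integration step (ms), at most 0.5 ms.
#' @param n_record_exc,n_record_inh how many neurons of each population
#'   record membrane and adaptation traces (the first so many of each).
#' @param record_dt sampling interval (ms) of recorded traces.
#' @return An `adex_run`: list with `spikes` (data.frame `neuron`,
#'   `time_s`), `population` (per-neuron `"exc"`/`"inh"`), `vm` and `w`
#'   (recorded subset x time, mV and pA), `recorded` (neuron indices),
#'   `record_dt` (ms), `dt`, `duration`, `arch`, `params_exc`,
#'   `params_inh`.
#' @export
simulate_network <- function(arch, params_exc = adex_params("RS"),
                             params_inh = adex_params("FS"),
                             duration = 30, seed = 1L, dt = 0.1,
                             n_record_exc = 100L, n_record_inh = 25L,
                             record_dt = 0.5) {
  stopifnot(inherits(arch, "network_architecture"),
            inherits(params_exc, "adex_params"),
            inherits(params_inh, "adex_params"))
  if (duration < 1) stop("duration must be at least 1 s", call. = FALSE)
  adj <- build_adjacency(arch)
  n <- arch$N_exc + arch$N_inh
  set.seed(as.integer(seed))
  V0 <- c(stats::runif(arch$N_exc, params_exc$V_reset, params_exc$V_thre),
          stats::runif(arch$N_inh, params_inh$V_reset, params_inh$V_thre))
  record_every <- max(1L, round(record_dt / dt))
  rec_idx <- c(seq_len(min(n_record_exc, arch$N_exc)) - 1L,
               arch$N_exc + seq_len(min(n_record_inh, arch$N_inh)) - 1L)
  n_steps <- round(duration * 1000 / dt)
  res <- adex_core(arch$N_exc, arch$N_inh, adj$targets, adj$ptr,
                   unclass(params_exc), unclass(params_inh),
                   arch$Q_exc, arch$Q_inh, dt, n_steps, V0,
                   rec_idx, record_every,
                   isTRUE(params_exc$literal_adaptation), as.integer(seed))
  spikes <- data.frame(neuron = res$spike_neuron + 1L,
                       time_s = res$spike_step * dt / 1000)
  population <- rep(c("exc", "inh"), c(arch$N_exc, arch$N_inh))
  structure(list(spikes = spikes, population = population,
                 vm = res$vm, w = res$w, recorded = rec_idx + 1L,
                 record_dt = record_every * dt, dt = dt,
                 duration = duration, arch = arch,
                 params_exc = params_exc, params_inh = params_inh),
            class = "adex_run")
}

#' @export
print.adex_run <- function(x, ...) {
  n <- x$arch$N_exc + x$arch$N_inh
  cat(sprintf("<adex_run> %d neurons (%d RS / %d FS), %.3g s, %d spikes (%.2f Hz mean)\n",
              n, x$arch$N_exc, x$arch$N_inh, x$duration, nrow(x$spikes),
              nrow(x$spikes) / n / x$duration))
  invisible(x)
}

#' Population firing rate
#'
#' Spike counts per time bin divided by `bin * population size`, in Hz.
#'
#' @param run an `adex_run`.
#' @param bin bin width (ms).
#' @param population `"exc"`, `"inh"` or `"all"`.
#' @return A [signal_timeseries()] with one channel.
#' @export
population_rate <- function(run, bin = 10, population = c("exc", "inh", "all")) {
  population <- match.arg(population)
  stopifnot(inherits(run, "adex_run"))
  n_exc <- run$arch$N_exc
  keep <- switch(population,
                 exc = run$spikes$neuron <= n_exc,
                 inh = run$spikes$neuron > n_exc,
                 all = rep(TRUE, nrow(run$spikes)))
  n_pop <- switch(population, exc = n_exc, inh = run$arch$N_inh,
                  all = n_exc + run$arch$N_inh)
  if (n_pop == 0L) stop("empty population", call. = FALSE)
  if (bin <= 0) stop("bin must be positive", call. = FALSE)
  edges <- seq(0, run$duration, by = bin / 1000)
  if (edges[length(edges)] < run$duration) edges <- c(edges, run$duration)
  counts <- graphics::hist(run$spikes$time_s[keep], breaks = edges,
                           plot = FALSE)$counts
  rate <- counts / (bin / 1000) / n_pop
  signal_timeseries(matrix(rate, nrow = 1L), fs = 1000 / bin,
                    labels = population)
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram with a Hann window, 50% overlap and
#' per-segment mean removal.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nperseg segment length in samples (default: up to 1/4 of the
#'   signal, at least 256).
#' @param nfft FFT length (zero-padded; default 4 x `nperseg` for a
#'   finer frequency grid).
#' @return List with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, nperseg = NULL, nfft = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, max(256L, floor(n / 4)))
  nperseg <- min(nperseg, n)
  if (is.null(nfft)) nfft <- 4L * nperseg
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  norm <- sum(win^2)
  acc <- numeric(nfft)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(c(seg, numeric(nfft - nperseg))))^2
  }
  acc <- acc / length(starts) / (fs * norm)
  half <- floor(nfft / 2)
  list(freq = (seq_len(half) - 1L) * fs / nfft,
       power = acc[seq_len(half)])
}

#' Dominant oscillation frequency
#'
#' Frequency of the maximum of the Welch power spectrum within `band`.
#' Returns `NA` (with a warning) when the spectrum is flat in the band,
#' i.e. the peak does not stand above the band's median power by the
#' required factor -- the signature of a signal with no rhythmic
#' component.
#'
#' @param sig a [signal_timeseries()] (first channel used) or numeric
#'   vector with attribute-free sampling given via `fs`.
#' @param band `(f_lo, f_hi)` search band in Hz, default `c(0.5, 10)`.
#' @param fs sampling rate, required when `sig` is a bare vector.
#' @param peak_factor required ratio of peak to median band power.
#' @return Peak frequency (Hz), or `NA_real_` if no clear peak.
#' @export
oscillation_frequency <- function(sig, band = c(0.5, 10), fs = NULL,
                                  peak_factor = 2) {
  if (inherits(sig, "signal_timeseries")) {
    x <- sig$x[1L, ]
    fs <- sig$fs
  } else {
    x <- as.numeric(sig)
    if (is.null(fs)) stop("fs required for a bare vector", call. = FALSE)
  }
  min_len <- 10 / band[1L] * fs
  if (length(x) < min_len)
    stop("signal shorter than 10 cycles of the band's lower edge", call. = FALSE)
  ps <- welch_psd(x, fs)
  inb <- ps$freq >= band[1L] & ps$freq <= band[2L]
  if (!any(inb)) stop("band outside the resolvable spectrum", call. = FALSE)
  pw <- ps$power[inb]
  fq <- ps$freq[inb]
  if (max(pw) < peak_factor * stats::median(pw)) {
    warning("no spectral peak above the band's median power; returning NA")
    return(NA_real_)
  }
  fq[which.max(pw)]
}
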