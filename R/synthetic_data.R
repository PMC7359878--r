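#' Generate a ground-truth lesion experiment
#'
#' Builds a synthetic connectome, simulates the healthy network and the
#' lesioned/rewired network at known parameters `(s_true, r_true)` (and a
#' milder "rehab" condition), and returns the FC-change matrices on a
#' 12-region analysis subset that excludes the stroke core and its most
#' strongly connected neighbours -- the synthetic counterpart of
#' analysing only ipsilesional regions outside the infarct. The result is
#' the input expected by [fit_parameter_grid()], with known truth for
#' parameter-recovery studies.
#'
#' Observation noise models measurement error on the "empirical" PLV
#' change: truncated additive Gaussian, applied symmetrically.
#'
#' @param n_regions connectome size (at least 14, so that a 12-region
#'   subset outside the stroke core exists).
#' @param s_true,r_true lesion parameters of the "stroke" condition.
#' @param s_rehab,r_rehab lesion parameters of the "rehab" condition
#'   (defaults: milder damage, same rebound).
#' @param kp a [kuramoto_params()].
#' @param seeds integer vector of simulation seeds; healthy and lesioned
#'   runs share each seed and the PLVs are seed-averaged.
#' @param sigma_obs standard deviation of the observation noise added to
#'   the FC-change entries (0 = noiseless).
#' @param conn_seed seed of the synthetic connectome.
#' @param mode FC-change mode (see [fc_change()]).
#' @param noise_seed seed of the observation noise.
#' @return A `ground_truth_experiment`: list with `healthy_conn`,
#'   `s_true`, `r_true`, `s_rehab`, `r_rehab`, `kp`, `seeds`,
#'   `data_change_stroke`, `data_change_rehab`, `region_subset`, and a
#'   `manifest` recording every parameter needed for bit-identical
#'   regeneration.
#' @export
generate_ground_truth_experiment <- function(n_regions = 18L,
                                             s_true = 0.3, r_true = 1.0,
                                             s_rehab = min(1, s_true + 0.3),
                                             r_rehab = r_true,
                                             kp = kuramoto_params(),
                                             seeds = 1:3,
                                             sigma_obs = 0,
                                             conn_seed = 42L,
                                             mode = "difference",
                                             noise_seed = 7L) {
  if (n_regions < 14L)
    stop("n_regions must be at least 14 for a 12-region subset outside the core",
         call. = FALSE)
  if (s_true < 0 || s_true > 1 || r_true < 0 || r_true > 5)
    stop("lesion parameters out of range", call. = FALSE)
  # weight_scale = 2 places the reference coupling K = 4.3 in the
  # partially synchronised regime where FC is sensitive to structure
  conn <- generate_synthetic_connectome(n_regions, seed = conn_seed,
                                        weight_scale = 2)
  k <- conn$stroke_region
  # exclude the stroke core plus its strongest neighbours, keeping 12
  strength <- conn$weights[, k] + conn$weights[k, ]
  strength[k] <- Inf
  excluded <- order(strength, decreasing = TRUE)[seq_len(n_regions - 12L)]
  subset <- conn$labels[sort(setdiff(seq_len(n_regions), excluded))]

  change_for <- function(s, r) {
    spec <- lesion_spec(retain = s, rebound = r)
    conn_l <- apply_rebound(conn, spec)
    acc_h <- 0
    acc_l <- 0
    for (sd in seeds) {
      kp_s <- kp
      kp_s$seed <- as.integer(sd)
      acc_h <- acc_h + plv_matrix(simulate_phases(conn, kp_s))$plv
      acc_l <- acc_l + plv_matrix(simulate_phases(conn_l, kp_s))$plv
    }
    fc_h <- structure(list(plv = acc_h / length(seeds), labels = conn$labels,
                           band = NULL, condition = "healthy"),
                      class = "fc_matrix")
    fc_l <- structure(list(plv = acc_l / length(seeds), labels = conn$labels,
                           band = NULL, condition = "lesion"),
                      class = "fc_matrix")
    subset_fc_change(fc_change(fc_l, fc_h, mode = mode), subset)
  }
  chg_stroke <- change_for(s_true, r_true)
  chg_rehab <- change_for(s_rehab, r_rehab)
  if (sigma_obs > 0) {
    set.seed(as.integer(noise_seed))
    chg_stroke$delta <- add_observation_noise(chg_stroke$delta, sigma_obs)
    chg_rehab$delta <- add_observation_noise(chg_rehab$delta, sigma_obs)
  }
  manifest <- list(n_regions = n_regions, s_true = s_true, r_true = r_true,
                   s_rehab = s_rehab, r_rehab = r_rehab,
                   kp = unclass(kp), seeds = as.integer(seeds),
                   sigma_obs = sigma_obs, conn_seed = as.integer(conn_seed),
                   mode = mode, noise_seed = as.integer(noise_seed),
                   region_subset = subset)
  structure(list(healthy_conn = conn, s_true = s_true, r_true = r_true,
                 s_rehab = s_rehab, r_rehab = r_rehab, kp = kp,
                 seeds = as.integer(seeds),
                 data_change_stroke = chg_stroke,
                 data_change_rehab = chg_rehab,
                 region_subset = subset, manifest = manifest),
            class = "ground_truth_experiment")
}

# symmetric truncated-Gaussian perturbation of an FC-change matrix;
# truncation keeps difference-mode entries inside [-1, 1]
add_observation_noise <- function(delta, sigma) {
  n <- nrow(delta)
  noise <- matrix(0, n, n)
  up <- upper.tri(noise)
  noise[up] <- pmin(pmax(stats::rnorm(sum(up), 0, sigma), -3 * sigma), 3 * sigma)
  noise <- noise + t(noise)
  pmin(pmax(delta + noise, -1), 1)
}

#' Generate calcium-like region signals
#'
#' Emulates region-wise wide-field calcium recordings: the sine of
#' simulated Kuramoto phases, decimated to the recording rate (25 Hz in
#' the emulated setup, i.e. a 12.5 Hz Nyquist), plus white observation
#' noise at a given SNR and an additive slow (< 0.5 Hz) confound that the
#' band-pass stage must remove.
#'
#' @param conn a [connectome()].
#' @param kp a [kuramoto_params()]; `kp$f` must lie in
#'   `(0.5, fs_out / 2)`.
#' @param fs_out output sampling rate (Hz).
#' @param snr signal-to-noise variance ratio; `Inf` for noiseless, `0`
#'   for pure noise (no oscillatory component).
#' @param slow_amp amplitude of the slow confound (0 disables it).
#' @param slow_freq frequency of the slow confound (Hz, below 0.5).
#' @param noise_seed seed of the observation noise and confound phases.
#' @return A [signal_timeseries()] at `fs_out`.
#' @export
generate_calcium_like_signals <- function(conn, kp = kuramoto_params(),
                                          fs_out = 25, snr = 10,
                                          slow_amp = 1, slow_freq = 0.2,
                                          noise_seed = 1L) {
  if (fs_out < 2 * kp$f)
    stop("fs_out below twice the oscillation frequency (aliasing)", call. = FALSE)
  if (kp$f <= 0.5 || kp$f >= fs_out / 2)
    stop("kp$f must lie inside (0.5, fs_out/2)", call. = FALSE)
  kp_rec <- kp
  kp_rec$record_dt <- 1 / fs_out
  re <- kp_rec$record_dt / kp$dt
  if (abs(re - round(re)) > 1e-8)
    stop("1/fs_out must be an integer multiple of kp$dt", call. = FALSE)
  ph <- simulate_phases(conn, kp_rec)
  x <- sin(ph$phases)
  n <- nrow(x)
  m <- ncol(x)
  tt <- seq_len(m) / fs_out
  set.seed(as.integer(noise_seed))
  if (snr == 0) {
    x <- matrix(stats::rnorm(n * m), n, m)
  } else if (is.finite(snr)) {
    sd_noise <- sqrt(stats::var(as.numeric(x)) / snr)
    x <- x + matrix(stats::rnorm(n * m, 0, sd_noise), n, m)
  }
  if (slow_amp > 0) {
    phase0 <- stats::runif(n, 0, 2 * pi)
    conf <- slow_amp * sin(outer(phase0, 2 * pi * slow_freq * tt, `+`))
    x <- x + conf
  }
  signal_timeseries(x, fs_out, conn$labels)
}

#' Generate homogeneous Poisson spike trains
#'
#' @param rate firing rate (Hz, nonnegative).
#' @param n_neurons number of independent trains.
#' @param duration train length (s).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return List of numeric vectors of spike times (s), one per neuron.
#' @export
generate_poisson_spikes <- function(rate, n_neurons = 1L, duration = 10,
                                    seed = 1L) {
  if (rate < 0) stop("rate must be nonnegative", call. = FALSE)
  set.seed(as.integer(seed))
  lapply(seq_len(n_neurons), function(i) {
    if (rate == 0) return(numeric(0))
    n_exp <- stats::qpois(1 - 1e-12, rate * duration) + 10L
    t <- cumsum(stats::rexp(n_exp, rate))
    t[t <= duration]
  })
}
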