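#' Kuramoto simulation parameters
#'
#' Bundles the parameters of the stochastic Kuramoto brain-network model
#' in which each region is a phase oscillator with the common natural
#' frequency `f`, coupled through the connectome weights scaled by the
#' global coupling `K`, and perturbed by Gaussian white noise of strength
#' `D` (autocorrelation `2 D delta(t)`).
#'
#' The defaults mirror the working point used for the stroke-recovery
#' fits: `f = 2` Hz, `K = 4.3`, `D = 1`.
#'
#' @param f common natural frequency (Hz).
#' @param K global coupling (dimensionless, scales all connectome weights).
#' @param D noise strength (rad^2/s).
#' @param dt Euler--Maruyama step (s).
#' @param duration total simulated time (s).
#' @param transient initial stretch (s) discarded before analysis.
#' @param record_dt sampling interval (s) of the returned phases; must be
#'   a multiple of `dt`. Phases vary on the 1/f timescale so they can be
#'   recorded far more coarsely than they are integrated.
#' @param seed integer seed for initial phases and noise.
#' @return An object of class `kuramoto_params`.
#' @export
kuramoto_params <- function(f = 2, K = 4.3, D = 1, dt = 1e-3,
                            duration = 120, transient = 10,
                            record_dt = 1e-2, seed = 1L) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration <= transient || transient < 0)
    stop("need duration > transient >= 0", call. = FALSE)
  if (D < 0 || K < 0) stop("K and D must be nonnegative", call. = FALSE)
  re <- record_dt / dt
  if (abs(re - round(re)) > 1e-8)
    stop("record_dt must be an integer multiple of dt", call. = FALSE)
  structure(list(f = f, K = K, D = D, dt = dt, duration = duration,
                 transient = transient, record_dt = record_dt,
                 seed = as.integer(seed)),
            class = "kuramoto_params")
}

#' Simulate Kuramoto phases on a connectome
#'
#' Integrates `dtheta_i = [2 pi f + (1/N) sum_j K w_ij sin(theta_j -
#' theta_i)] dt + sqrt(2 D dt) xi_i` by Euler--Maruyama, with `xi_i`
#' independent standard normal increments. Initial phases are uniform on
#' `(-pi, pi]` from the seeded generator; the transient is discarded and
#' phases are returned wrapped to `(-pi, pi]` at the recorded sampling
#' rate. Identical `(conn, params)` produce bit-identical output.
#'
#' @param conn a [connectome()].
#' @param params a [kuramoto_params()].
#' @return A `phase_timeseries`: list with `phases` (regions x time, rad),
#'   `fs` (Hz), `labels`.
#' @export
simulate_phases <- function(conn, params) {
  stopifnot(inherits(conn, "connectome"), inherits(params, "kuramoto_params"))
  n <- nrow(conn$weights)
  set.seed(params$seed)
  theta0 <- stats::runif(n, -pi, pi)
  n_steps <- round(params$duration / params$dt)
  transient_steps <- round(params$transient / params$dt)
  record_every <- round(params$record_dt / params$dt)
  ph <- kuramoto_core(conn$weights, params$K, params$f, params$D,
                      params$dt, n_steps, transient_steps, record_every,
                      theta0)
  phase_timeseries(ph, fs = 1 / params$record_dt, labels = conn$labels)
}

#' Phase time series container
#'
#' @param phases regions x time matrix of phases wrapped to `(-pi, pi]`.
#' @param fs sampling rate (Hz).
#' @param labels region names.
#' @return An object of class `phase_timeseries`.
#' @export
phase_timeseries <- function(phases, fs, labels = NULL) {
  phases <- as.matrix(phases)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(phases)))
  if (ncol(phases) < 1L) stop("need at least one sample", call. = FALSE)
  structure(list(phases = unname(phases), fs = fs,
                 labels = as.character(labels)),
            class = "phase_timeseries")
}

#' @export
print.phase_timeseries <- function(x, ...) {
  cat(sprintf("<phase_timeseries> %d regions x %d samples @ %.4g Hz\n",
              nrow(x$phases), ncol(x$phases), x$fs))
  invisible(x)
}

#' Kuramoto order parameter
#'
#' `R(t) = |mean_i exp(1i * theta_i(t))|`, the global synchrony index:
#' 1 for identical phases, near 0 for incoherent ones.
#'
#' @param phases a `phase_timeseries` or a regions x time phase matrix.
#' @return Numeric vector `R(t)` in \[0, 1\], one value per sample.
#' @export
order_parameter <- function(phases) {
  ph <- if (inherits(phases, "phase_timeseries")) phases$phases else as.matrix(phases)
  re <- colMeans(cos(ph))
  im <- colMeans(sin(ph))
  sqrt(re^2 + im^2)
}
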