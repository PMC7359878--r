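#' Signal time series container
#'
#' Real-valued, uniformly sampled multichannel traces (channels x time),
#' e.g. region-wise calcium-like signals.
#'
#' @param x channels x time numeric matrix.
#' @param fs sampling rate (Hz).
#' @param labels channel names.
#' @return An object of class `signal_timeseries`.
#' @export
signal_timeseries <- function(x, fs, labels = NULL) {
  x <- as.matrix(x)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(x)))
  structure(list(x = unname(x), fs = fs, labels = as.character(labels)),
            class = "signal_timeseries")
}

#' @export
print.signal_timeseries <- function(x, ...) {
  cat(sprintf("<signal_timeseries> %d channels x %d samples @ %.4g Hz\n",
              nrow(x$x), ncol(x$x), x$fs))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Forward--backward (zero-phase) 4th-order Butterworth band-pass applied
#' per channel; signal length is preserved. The analysis band for
#' calcium functional connectivity is the upper delta band, 2.5--5 Hz.
#'
#' @param ts a [signal_timeseries()].
#' @param f_lo,f_hi band edges (Hz), `0 < f_lo < f_hi < fs/2`.
#' @param order filter order (default 4).
#' @return A filtered [signal_timeseries()].
#' @export
bandpass_filter <- function(ts, f_lo, f_hi, order = 4L) {
  stopifnot(inherits(ts, "signal_timeseries"))
  nyq <- ts$fs / 2
  if (!(f_lo > 0 && f_lo < f_hi))
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi >= nyq)
    stop(sprintf("f_hi = %g Hz is at or above the Nyquist frequency %g Hz",
                 f_hi, nyq), call. = FALSE)
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  y <- t(apply(ts$x, 1L, function(row) signal::filtfilt(bf, row)))
  signal_timeseries(y, ts$fs, ts$labels)
}

#' Analytic instantaneous phase
#'
#' Per-channel instantaneous phase of the analytic signal
#' `x + i H\{x\}` (Hilbert transform via FFT), wrapped to `(-pi, pi]`.
#' The input should be band-limited (band-pass filtered) for the phase to
#' be physically meaningful; that is the caller's responsibility.
#'
#' @param ts a [signal_timeseries()] with at least 64 samples.
#' @return A `phase_timeseries`.
#' @export
analytic_phase <- function(ts) {
  stopifnot(inherits(ts, "signal_timeseries"))
  if (ncol(ts$x) < 64L)
    stop("need at least 64 samples for a stable analytic phase", call. = FALSE)
  rng <- apply(ts$x, 1L, function(r) diff(range(r)))
  if (any(rng == 0))
    stop("constant channel: instantaneous phase is undefined", call. = FALSE)
  ph <- t(apply(ts$x, 1L, function(row) Arg(analytic_signal(row))))
  phase_timeseries(ph, ts$fs, ts$labels)
}

# analytic signal x + i*H{x} via the frequency-domain construction:
# double the positive frequencies, zero the negative ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-locking-value matrix
#'
#' `PLV_ij = |(1/M) sum_m exp(1i (theta_i(m) - theta_j(m)))|` over the `M`
#' samples: 1 for perfectly locked phases (any constant offset), near 0
#' for independent ones. The matrix is symmetric with unit diagonal by
#' construction.
#'
#' @param phases a `phase_timeseries` (or regions x time phase matrix)
#'   with at least 2 channels.
#' @param band optional `(f_lo, f_hi)` tag recording the analysis band.
#' @param condition optional condition tag (e.g. `"healthy"`, `"stroke"`).
#' @return An `fc_matrix`: list with `plv` (N x N), `labels`, `band`,
#'   `condition`.
#' @export
plv_matrix <- function(phases, band = NULL, condition = "model") {
  if (inherits(phases, "phase_timeseries")) {
    ph <- phases$phases
    labels <- phases$labels
  } else {
    ph <- as.matrix(phases)
    labels <- sprintf("R%02d", seq_len(nrow(ph)))
  }
  if (nrow(ph) < 2L) stop("need at least 2 channels", call. = FALSE)
  if (anyNA(ph)) stop("NaN/NA in phases", call. = FALSE)
  m <- ncol(ph)
  C <- cos(ph)
  S <- sin(ph)
  # mean_m cos(ti - tj) and mean_m sin(ti - tj) via real matrix products
  re <- (C %*% t(C) + S %*% t(S)) / m
  im <- (S %*% t(C) - C %*% t(S)) / m
  plv <- sqrt(pmin(re^2 + im^2, 1))
  plv <- (plv + t(plv)) / 2
  diag(plv) <- 1
  structure(list(plv = plv, labels = labels, band = band,
                 condition = condition),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d regions, condition '%s', mean off-diagonal PLV %.3f\n",
              nrow(x$plv), x$condition, mean(x$plv[upper.tri(x$plv)])))
  invisible(x)
}

#' Surrogate significance threshold for PLV
#'
#' Builds an ensemble of surrogate signals that preserve each channel's
#' power spectrum but destroy cross-channel phase relations (independent
#' Fourier phase randomisation per channel), recomputes the PLV matrix on
#' each, and returns the per-pair quantile as the significance floor:
#' observed PLVs below it are compatible with spectrally matched but
#' unrelated signals.
#'
#' @param ts a [signal_timeseries()], already band-pass filtered to the
#'   analysis band.
#' @param n_surrogates ensemble size (at least 19).
#' @param quantile significance quantile in (0, 1), default 0.95.
#' @param seed integer seed for the surrogate phases.
#' @return An `fc_matrix` whose `plv` entries are the per-pair thresholds
#'   (`condition = "surrogate"`).
#' @export
surrogate_significance <- function(ts, n_surrogates = 100L, quantile = 0.95,
                                   seed = 1L) {
  stopifnot(inherits(ts, "signal_timeseries"))
  if (n_surrogates < 19L)
    stop("need at least 19 surrogates for a 95% threshold", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must be inside (0, 1)", call. = FALSE)
  n <- nrow(ts$x)
  m <- ncol(ts$x)
  set.seed(as.integer(seed))
  vals <- array(NA_real_, c(n, n, n_surrogates))
  for (b in seq_len(n_surrogates)) {
    surr <- t(apply(ts$x, 1L, phase_randomize))
    ph <- t(apply(surr, 1L, function(row) Arg(analytic_signal(row))))
    vals[, , b] <- plv_matrix(phase_timeseries(ph, ts$fs, ts$labels))$plv
  }
  thr <- apply(vals, c(1L, 2L), stats::quantile, probs = quantile, names = FALSE)
  thr <- (thr + t(thr)) / 2
  diag(thr) <- 1
  structure(list(plv = thr, labels = ts$labels, band = NULL,
                 condition = "surrogate"),
            class = "fc_matrix")
}

# Fourier-transform surrogate: randomise phases, keep the amplitude
# spectrum, enforce conjugate symmetry so the result is real.
phase_randomize <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor((n - 1) / 2)
  phi <- stats::runif(half, 0, 2 * pi)
  rot <- complex(modulus = 1, argument = phi)
  Xs <- X
  Xs[2:(half + 1)] <- X[2:(half + 1)] * rot
  Xs[n:(n - half + 1)] <- Conj(Xs[2:(half + 1)])
  Re(stats::fft(Xs, inverse = TRUE) / n)
}

#' Functional-connectivity change versus a reference condition
#'
#' @param fc_cond,fc_ref `fc_matrix` objects with matching labels, e.g.
#'   stroke (or rehab) versus healthy.
#' @param mode `"difference"` (`PLV_cond - PLV_ref`, bounded in
#'   \[-1, 1\]) or `"relative"` (`(PLV_cond - PLV_ref) / PLV_ref`).
#' @return An `fc_change`: list with `delta` (N x N, zero diagonal),
#'   `labels`, `mode`.
#' @export
fc_change <- function(fc_cond, fc_ref, mode = c("difference", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fc_cond, "fc_matrix"), inherits(fc_ref, "fc_matrix"))
  if (!identical(fc_cond$labels, fc_ref$labels))
    stop("condition and reference FC label sets differ", call. = FALSE)
  d <- fc_cond$plv - fc_ref$plv
  if (mode == "relative") {
    off <- row(d) != col(d)
    if (any(fc_ref$plv[off] == 0))
      stop("relative change undefined: zero entry in the reference PLV",
           call. = FALSE)
    d[off] <- d[off] / fc_ref$plv[off]
  }
  diag(d) <- 0
  structure(list(delta = d, labels = fc_cond$labels, mode = mode),
            class = "fc_change")
}

subset_fc_change <- function(chg, labels) {
  idx <- match(labels, chg$labels)
  if (anyNA(idx)) stop("unknown region labels in subset", call. = FALSE)
  structure(list(delta = chg$delta[idx, idx, drop = FALSE], labels = labels,
                 mode = chg$mode),
            class = "fc_change")
}

upper_vec <- function(m) m[upper.tri(m)]

#' Simulate the model FC-change library over a lesion-parameter grid
#'
#' For every `(s, r)` cell of the grid the healthy connectome is lesioned
#' and rewired ([apply_rebound()]), healthy and lesioned Kuramoto
#' simulations are run with shared seeds (the same noise realisation for
#' both conditions, which cancels a large part of the Monte-Carlo error
#' of the difference), and the seed-averaged FC change on the analysis
#' subset is stored. The resulting library is independent of any observed
#' data, so a single grid serves every condition fitted against it (e.g.
#' a stroke and a rehabilitation dataset).
#'
#' @param healthy_conn the pre-stroke [connectome()].
#' @param kp a [kuramoto_params()]; seeds `kp$seed, kp$seed + 1, ...` are
#'   used.
#' @param s_grid,r_grid nonempty grids of survival fractions in \[0, 1\]
#'   and rebound factors in \[0, 5\].
#' @param region_subset labels of the analysis regions (at least 3);
#'   default: all non-stroke regions.
#' @param n_seeds number of simulation seeds averaged per cell.
#' @param mode FC-change mode (see [fc_change()]).
#' @param rebound_mode passed to [apply_rebound()].
#' @return A `model_fc_grid`: list with `deltas` (cells x region-pairs
#'   matrix of upper-triangle FC-change vectors), `s_grid`, `r_grid`,
#'   `labels`, `n_seeds`, `mode`.
#' @export
model_change_grid <- function(healthy_conn, kp,
                              s_grid = seq(0, 1, 0.1),
                              r_grid = seq(0, 5, 0.5),
                              region_subset = NULL,
                              n_seeds = 8L,
                              mode = c("difference", "relative"),
                              rebound_mode = "redistribute") {
  mode <- match.arg(mode)
  stopifnot(inherits(healthy_conn, "connectome"),
            inherits(kp, "kuramoto_params"))
  if (length(s_grid) == 0L || length(r_grid) == 0L)
    stop("parameter grids must be nonempty", call. = FALSE)
  if (is.null(region_subset))
    region_subset <- setdiff(healthy_conn$labels,
                             healthy_conn$labels[healthy_conn$stroke_region])
  if (length(region_subset) < 3L)
    stop("analysis subset has fewer than 3 regions; correlation is meaningless",
         call. = FALSE)
  n_pairs <- choose(length(region_subset), 2)
  n_cells <- length(s_grid) * length(r_grid)
  deltas <- matrix(0, n_cells, n_pairs)
  for (k in seq_len(n_seeds)) {
    kp_k <- kp
    kp_k$seed <- kp$seed + k - 1L
    fc_healthy <- plv_matrix(simulate_phases(healthy_conn, kp_k),
                             condition = "healthy")
    cell <- 0L
    for (ri in seq_along(r_grid)) {
      for (si in seq_along(s_grid)) {
        cell <- cell + 1L
        spec <- lesion_spec(retain = s_grid[si], rebound = r_grid[ri])
        conn_l <- apply_rebound(healthy_conn, spec, mode = rebound_mode)
        fc_les <- plv_matrix(simulate_phases(conn_l, kp_k),
                             condition = "lesion")
        chg <- fc_change(fc_les, fc_healthy, mode = mode)
        deltas[cell, ] <- deltas[cell, ] +
          upper_vec(subset_fc_change(chg, region_subset)$delta)
      }
    }
  }
  structure(list(deltas = deltas / n_seeds, s_grid = s_grid, r_grid = r_grid,
                 labels = region_subset, n_seeds = n_seeds, mode = mode,
                 base_seed = kp$seed),
            class = "model_fc_grid")
}

#' @export
print.model_fc_grid <- function(x, ...) {
  cat(sprintf("<model_fc_grid> %d x %d cells, %d regions, %d seeds per cell\n",
              length(x$s_grid), length(x$r_grid), length(x$labels),
              x$n_seeds))
  invisible(x)
}

#' Fit lesion parameters to an observed FC change
#'
#' Correlates the observed FC change with the seed-averaged model FC
#' change of every `(s, r)` cell (Pearson, on the strictly-upper-triangle
#' vectors over the analysis subset, diagonal excluded) and returns the
#' grid together with its argmax. Ties break toward smaller damage
#' (larger `s`), then smaller `r`.
#'
#' The model library can be passed precomputed (a [model_change_grid()]),
#' which is the economical way to fit several conditions -- e.g. stroke
#' and rehabilitation -- against the same grid; alternatively a healthy
#' [connectome()] plus `kp` builds the library on the fly.
#'
#' @param data_change an `fc_change` observed in data (or synthesised by
#'   [generate_ground_truth_experiment()]); its labels must equal the
#'   grid's analysis subset.
#' @param model either a `model_fc_grid` or a healthy [connectome()].
#' @param kp a [kuramoto_params()] (required when `model` is a
#'   connectome; `kp$seed` is the base seed).
#' @param s_grid,r_grid,n_seeds,rebound_mode grid-construction settings,
#'   used only when `model` is a connectome.
#' @param mode FC-change mode, must match how `data_change` was computed.
#' @return A `fit_result`: list with `values` (length(s_grid) x
#'   length(r_grid) correlation grid), `s_grid`, `r_grid`, `best_s`,
#'   `best_r`, `best_value`. Cells whose model change is constant (e.g.
#'   `s = 1, r = 0`: no lesion, hence no change) are `NA`.
#' @export
fit_parameter_grid <- function(data_change, model, kp = NULL,
                               s_grid = seq(0, 1, 0.1),
                               r_grid = seq(0, 5, 0.5),
                               n_seeds = 8L,
                               mode = c("difference", "relative"),
                               rebound_mode = "redistribute") {
  mode <- match.arg(mode)
  stopifnot(inherits(data_change, "fc_change"))
  if (inherits(model, "connectome")) {
    if (is.null(kp))
      stop("kp is required when fitting from a connectome", call. = FALSE)
    model <- model_change_grid(model, kp, s_grid = s_grid, r_grid = r_grid,
                               region_subset = data_change$labels,
                               n_seeds = n_seeds, mode = mode,
                               rebound_mode = rebound_mode)
  }
  stopifnot(inherits(model, "model_fc_grid"))
  if (!identical(data_change$labels, model$labels))
    stop("data labels do not match the model grid's analysis subset",
         call. = FALSE)
  if (!identical(data_change$mode, model$mode))
    stop("FC-change mode of data and model grid differ", call. = FALSE)
  dvec <- upper_vec(data_change$delta)
  if (stats::sd(dvec) == 0)
    stop("observed FC change is constant; correlation undefined", call. = FALSE)
  vals <- apply(model$deltas, 1L, function(mvec) {
    if (stats::sd(mvec) == 0) NA_real_ else stats::cor(mvec, dvec)
  })
  values <- matrix(vals, length(model$s_grid), length(model$r_grid),
                   dimnames = list(s = signif(model$s_grid, 4),
                                   r = signif(model$r_grid, 4)))
  if (all(is.na(values)))
    stop("no grid cell produced a non-constant model FC change", call. = FALSE)
  # argmax; ties toward larger s (less damage), then smaller r
  best <- which(values == max(values, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(-best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  structure(list(values = values, s_grid = model$s_grid,
                 r_grid = model$r_grid,
                 best_s = model$s_grid[best[1L]],
                 best_r = model$r_grid[best[2L]],
                 best_value = values[best[1L], best[2L]],
                 n_seeds = model$n_seeds, mode = mode),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d x %d grid; best: s = %.3g, r = %.3g (cor = %.4f)\n",
              length(x$s_grid), length(x$r_grid), x$best_s, x$best_r,
              x$best_value))
  invisible(x)
}
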