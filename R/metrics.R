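#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlapped segment-averaged periodogram of a
#' DC-removed signal.  Scaled as a one-sided density so that
#' \code{sum(power) * df} equals the signal variance (Parseval).
#'
#' @param x a \code{lanmm_ts} (use \code{channel}) or a numeric vector
#'   (supply \code{fs}).
#' @param channel \code{"vP1"} or \code{"vP2"} when \code{x} is a
#'   recorded time series.
#' @param fs sampling rate, 1/s.
#' @param seg_seconds segment length in seconds (sets the frequency
#'   resolution, 1/seg_seconds Hz).
#' @return an object of class \code{lanmm_spectrum}: data frame with
#'   columns \code{freq} (Hz, increasing) and \code{power} (mV^2/Hz).
#' @export
psd_welch <- function(x, channel = "vP1", fs = NULL, seg_seconds = 10) {
  if (inherits(x, "lanmm_ts")) {
    fs <- attr(x, "sample_rate")
    x <- x[[channel]]
  }
  stopifnot(is.numeric(x), !is.null(fs))
  nseg <- round(seg_seconds * fs)
  if (length(x) < 2 * nseg)
    stop("signal shorter than two Welch segments (",
         2 * seg_seconds, " s needed)")
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))
  wnorm <- sum(w^2)
  hop <- floor(nseg / 2)
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  acc <- acc / length(starts) / (fs * wnorm)
  nh <- floor(nseg / 2) + 1
  power <- acc[seq_len(nh)]
  power[2:(nh - 1)] <- 2 * power[2:(nh - 1)]   # one-sided
  df <- data.frame(freq = (seq_len(nh) - 1) * fs / nseg, power = power)
  structure(df, class = c("lanmm_spectrum", "data.frame"), fs = fs)
}

#' @export
plot.lanmm_spectrum <- function(x, fmax = 100, log = "y", ...) {
  i <- x$freq <= fmax & x$power > 0
  graphics::plot(x$freq[i], x$power[i], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "power (mV²/Hz)", ...)
  invisible(x)
}

#' Dominant spectral frequency
#'
#' Frequency of maximum power above \code{fmin}, optionally excluding a
#' band (the 12-30 Hz beta band is excluded in the frequency maps, as
#' the model produces no significant power there).  Ties break toward
#' the lower frequency.  If the spectral peak carries less than
#' \code{floor_frac} of the total power the signal is considered steady
#' and \code{NA} is returned.
#'
#' @param s a [psd_welch()] result.
#' @param exclude_band optional \code{c(lo, hi)} Hz to omit.
#' @param fmin lowest admissible frequency, Hz.
#' @param floor_frac peak-power floor as a fraction of total power.
#' @return frequency in Hz, or \code{NA} for a flat (steady) spectrum.
#' @export
dominant_frequency <- function(s, exclude_band = NULL, fmin = 0.5,
                               floor_frac = 1e-6) {
  stopifnot(nrow(s) > 0)
  if (all(s$power == 0)) stop("all-zero spectrum")
  keep <- s$freq >= fmin
  if (!is.null(exclude_band))
    keep <- keep & !(s$freq >= exclude_band[1] & s$freq <= exclude_band[2])
  f <- s$freq[keep]; p <- s$power[keep]
  if (!length(p) || max(p) < floor_frac * sum(s$power)) return(NA_real_)
  f[which.max(p)]
}

#' Map dominant frequencies over the input plane
#'
#' Integrates the model on a rectangular grid of input rates and records
#' the dominant frequency of each observable.  Cells where the two
#' channels fall in different canonical bands (delta/theta/alpha vs
#' gamma) are flagged multifrequency; failed integrations are flagged
#' invalid rather than dropped.
#'
#' @param params base parameter set.
#' @param phi1_grid,phi2_grid input-rate grids, 1/s.
#' @param settings [solver_settings()] used per cell.
#' @param exclude_band spectral band omitted from the dominant-frequency
#'   search (default 12-30 Hz).
#' @return data frame of class \code{lanmm_freq_map} with columns
#'   \code{phi_e1}, \code{phi_e2}, \code{f_vP1}, \code{f_vP2},
#'   \code{multifrequency}, \code{valid}.
#' @export
frequency_map <- function(params, phi1_grid, phi2_grid,
                          settings = solver_settings(t_transient = 10,
                                                     t_record = 20),
                          exclude_band = c(12, 30)) {
  grid <- expand.grid(phi_e1 = phi1_grid, phi_e2 = phi2_grid)
  f1 <- f2 <- rep(NA_real_, nrow(grid))
  valid <- rep(TRUE, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$inputs$phi_e1 <- grid$phi_e1[i]
    p$inputs$phi_e2 <- grid$phi_e2[i]
    ts <- tryCatch(simulate_lanmm(p, settings), error = function(e) NULL)
    if (is.null(ts)) { valid[i] <- FALSE; next }
    seg <- min(10, settings$t_record / 2)
    domf <- function(ch) tryCatch(
      dominant_frequency(psd_welch(ts, ch, seg_seconds = seg),
                         exclude_band),
      error = function(e) NA_real_)   # flat spectrum at a fixed point
    f1[i] <- domf("vP1")
    f2[i] <- domf("vP2")
  }
  band_of <- function(f) {
    ifelse(is.na(f), "steady",
           ifelse(f < 12, "slow", ifelse(f > 30, "gamma", "beta")))
  }
  out <- cbind(grid, f_vP1 = f1, f_vP2 = f2,
               multifrequency = band_of(f1) != band_of(f2) &
                 !is.na(f1) & !is.na(f2),
               valid = valid)
  structure(out, class = c("lanmm_freq_map", "data.frame"))
}

#' Zero-phase band-pass filtering with phase or envelope extraction
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero phase lag), followed by the analytic signal: either its
#' instantaneous phase or its envelope amplitude.
#'
#' @param x numeric signal or \code{lanmm_ts} (with \code{channel}).
#' @param band \code{c(lo, hi)} Hz, inside (0, Nyquist).
#' @param extract \code{"phase"} or \code{"amplitude"}.
#' @param fs sampling rate, 1/s (taken from the time series if given).
#' @param channel channel name for \code{lanmm_ts} input.
#' @param order Butterworth order.
#' @return numeric vector: phase in radians (-pi, pi] or envelope in mV.
#' @export
bandpass_phase_amp <- function(x, band, extract = c("phase", "amplitude"),
                               fs = NULL, channel = "vP1", order = 4) {
  extract <- match.arg(extract)
  if (inherits(x, "lanmm_ts")) {
    fs <- attr(x, "sample_rate")
    x <- x[[channel]]
  }
  stopifnot(!is.null(fs))
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("band must lie strictly inside (0, Nyquist)")
  x <- x - mean(x)
  n0 <- length(x)
  ## narrow low bands are numerically fragile for transfer-function
  ## Butterworth filtering at high sampling rates: decimate first so
  ## the band edge sits at a healthy fraction of Nyquist, filter there,
  ## and interpolate the analytic-signal quantities back
  dec <- max(1L, floor(fs / (25 * band[2])))
  if (dec > 1L) {
    xd <- signal::decimate(x, dec)
    fsd <- fs / dec
  } else {
    xd <- x
    fsd <- fs
  }
  bf <- signal::butter(order, band / (fsd / 2), type = "pass")
  xf <- signal::filtfilt(bf, xd)
  z <- analytic_signal(xf)
  if (dec == 1L) {
    if (extract == "phase") return(Arg(z))
    return(Mod(z))
  }
  td <- seq(0, by = dec / fs, length.out = length(z))
  t0 <- seq(0, by = 1 / fs, length.out = n0)
  if (extract == "phase") {
    uw <- unwrap_phase(Arg(z))
    ph <- stats::approx(td, uw, t0, rule = 2)$y
    (ph + pi) %% (2 * pi) - pi
  } else {
    stats::approx(td, Mod(z), t0, rule = 2)$y
  }
}

## cumulative unwrapping of wrapped phase angles
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

## analytic signal via the frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Tort modulation index for phase-amplitude coupling
#'
#' Bins the phase series into \code{n_bins} equal bins, averages the
#' amplitude series per bin, normalizes the bin means to a distribution
#' P, and returns the Kullback-Leibler divergence of P from uniform,
#' normalized by \code{log(n_bins)} so that MI lies in [0, 1].  MI is 0
#' iff the binned amplitude is uniform over phase and approaches 1 when
#' all amplitude concentrates in a single phase bin.  MI is invariant
#' under positive rescaling of the amplitude.
#'
#' @param phase phase series, radians.
#' @param amplitude envelope series, same length, nonnegative.
#' @param n_bins number of phase bins (default 18, i.e. 20 degrees).
#' @return an object of class \code{lanmm_pac}: list with \code{mi},
#'   \code{bin_centers}, \code{bin_mean_amplitudes}, \code{n_bins}.
#' @export
tort_mi <- function(phase, amplitude, n_bins = 18) {
  stopifnot(length(phase) == length(amplitude), n_bins >= 2)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- findInterval(phase, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, n_bins)
  if (any(counts == 0))
    stop("empty phase bins: insufficient or degenerate data")
  means <- vapply(seq_len(n_bins),
                  function(b) mean(amplitude[idx == b]), numeric(1))
  P <- means / sum(means)
  kl <- sum(ifelse(P > 0, P * log(P * n_bins), 0))
  structure(list(mi = kl / log(n_bins),
                 bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 bin_mean_amplitudes = means, n_bins = n_bins),
            class = "lanmm_pac")
}

#' @export
print.lanmm_pac <- function(x, ...) {
  cat(sprintf("Tort modulation index: %.4f (%d phase bins)\n",
              x$mi, x$n_bins))
  invisible(x)
}

#' Phase-amplitude coupling of a recorded simulation
#'
#' Convenience pipeline: band-pass the phase channel in
#' \code{phase_band}, the amplitude channel in \code{amp_band}
#' (zero-phase Butterworth), extract phase and envelope, and compute the
#' Tort modulation index.
#'
#' @param ts a \code{lanmm_ts}.
#' @param phase_band,amp_band frequency bands, Hz (defaults: theta
#'   phase, gamma amplitude).
#' @param phase_channel,amp_channel observable channels.
#' @param n_bins phase bins.
#' @return a \code{lanmm_pac} (see [tort_mi()]).
#' @export
pac_mi <- function(ts, phase_band = c(4, 8), amp_band = c(30, 100),
                   phase_channel = "vP1", amp_channel = "vP2",
                   n_bins = 18) {
  ph <- bandpass_phase_amp(ts, phase_band, "phase", channel = phase_channel)
  am <- bandpass_phase_amp(ts, amp_band, "amplitude", channel = amp_channel)
  res <- tort_mi(ph, am, n_bins)
  res$phase_band <- phase_band
  res$amp_band <- amp_band
  res
}

#' Two largest Lyapunov exponents (Benettin algorithm)
#'
#' Integrates the flow together with two tangent vectors under the
#' variational equations, re-orthonormalizing by Gram-Schmidt at fixed
#' intervals and accumulating the log stretch factors.  For the laminar
#' model a compiled fixed-step RK4 path is used; arbitrary systems
#' (see [reference_le_system()]) run through an adaptive R path with
#' identical renormalization bookkeeping.
#'
#' @param sys a [lanmm_params()] object, or a list with elements
#'   \code{f(y)} (vector field), \code{n} (dimension) and optionally
#'   \code{jac(y)}.
#' @param y0 initial state (default: zero state for the laminar model).
#' @param t_transient discarded initial stretch, s.
#' @param t_accum accumulation time, s.
#' @param renorm_interval Gram-Schmidt interval, s.
#' @param dt RK4 step of the compiled path, s.
#' @param n_blocks number of blocks for the convergence error (standard
#'   deviation of per-block exponent estimates).
#' @param t_warmup tangent-frame alignment stretch (renormalized but not
#'   accumulated) between the transient and the accumulation window, s.
#' @return an object of class \code{lanmm_les}: list with
#'   \code{lambda1 >= lambda2} (1/s) and \code{convergence_error}.
#' @export
benettin_les <- function(sys, y0 = NULL, t_transient = 20, t_accum = 200,
                         renorm_interval = 0.1, dt = 2e-4, n_blocks = 10,
                         t_warmup = 10) {
  if (inherits(sys, "lanmm_params")) {
    if (is.null(y0)) y0 <- rep(0, 10)
    r <- .Call(lanmm_benettin_c, as.numeric(y0), as_parm_vector(sys),
               as.numeric(dt), as.numeric(t_transient),
               as.numeric(t_accum), as.numeric(renorm_interval),
               as.integer(n_blocks), as.numeric(t_warmup))
    l <- sort(r[1:2], decreasing = TRUE)
    nb <- (length(r) - 2) / 2
    blocks1 <- r[2 + seq_len(nb)]
    err <- stats::sd(blocks1)
    return(structure(list(lambda1 = l[1], lambda2 = l[2],
                          convergence_error = err,
                          block_estimates = blocks1),
                     class = "lanmm_les"))
  }
  benettin_generic(sys, y0, t_transient, t_accum, renorm_interval,
                   n_blocks, t_warmup)
}

## adaptive-integrator Benettin for arbitrary vector fields
benettin_generic <- function(sys, y0, t_transient, t_accum,
                             renorm_interval, n_blocks, t_warmup = 0) {
  n <- sys$n
  stopifnot(!is.null(y0), length(y0) == n)
  jacf <- if (!is.null(sys$jac)) sys$jac else function(y)
    numeric_jacobian(sys$f, y)
  fvar <- function(t, y, p) {
    yy <- y[seq_len(n)]
    V <- matrix(y[-seq_len(n)], n, 2)
    list(c(sys$f(yy), as.vector(jacf(yy) %*% V)))
  }
  ## transient
  if (t_transient > 0) {
    o <- deSolve::ode(y0, c(0, t_transient),
                      function(t, y, p) list(sys$f(y)), NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-11)
    y0 <- o[nrow(o), -1]
  }
  V <- diag(n)[, 1:2]
  state <- c(y0, as.vector(V))
  nwarm <- ceiling(t_warmup / renorm_interval)
  nseg <- nwarm + ceiling(t_accum / renorm_interval)
  sums <- c(0, 0)
  block_l1 <- numeric(0)
  bsum <- 0; bt <- 0
  seg_per_block <- max(1, floor((nseg - nwarm) / n_blocks))
  for (s in seq_len(nseg)) {
    o <- deSolve::ode(state, c(0, renorm_interval), fvar, NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-11)
    state <- o[nrow(o), -1]
    if (!all(is.finite(state))) stop("trajectory blow-up")
    V <- matrix(state[-seq_len(n)], n, 2)
    n1 <- sqrt(sum(V[, 1]^2)); V[, 1] <- V[, 1] / n1
    V[, 2] <- V[, 2] - sum(V[, 1] * V[, 2]) * V[, 1]
    n2 <- sqrt(sum(V[, 2]^2)); V[, 2] <- V[, 2] / n2
    state[-seq_len(n)] <- as.vector(V)
    if (s <= nwarm) next
    sums <- sums + log(c(n1, n2))
    bsum <- bsum + log(n1); bt <- bt + renorm_interval
    if ((s - nwarm) %% seg_per_block == 0) {
      block_l1 <- c(block_l1, bsum / bt)
      bsum <- 0; bt <- 0
    }
  }
  l <- sort(sums / ((nseg - nwarm) * renorm_interval), decreasing = TRUE)
  structure(list(lambda1 = l[1], lambda2 = l[2],
                 convergence_error = stats::sd(block_l1),
                 block_estimates = block_l1),
            class = "lanmm_les")
}

numeric_jacobian <- function(f, y, eps = 1e-6) {
  n <- length(y)
  f0 <- f(y)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    dy <- y; dy[j] <- dy[j] + eps
    dm <- y; dm[j] <- dm[j] - eps
    J[, j] <- (f(dy) - f(dm)) / (2 * eps)
  }
  J
}

#' @export
print.lanmm_les <- function(x, ...) {
  cat(sprintf("Lyapunov exponents: lambda1 = %.4f, lambda2 = %.4f 1/s (conv. err %.3g)\n",
              x$lambda1, x$lambda2, x$convergence_error))
  invisible(x)
}

#' Classify a dynamical regime from the two largest Lyapunov exponents
#'
#' chaotic if \eqn{\lambda_1 >} tol; steady if \eqn{\lambda_1 < -}tol;
#' periodic if \eqn{|\lambda_1| \le} tol and \eqn{\lambda_2 < -}tol;
#' quasiperiodic (2-torus) if both are within tol of zero.
#'
#' @param le a [benettin_les()] result or numeric \code{c(l1, l2)}.
#' @param tol zero-exponent tolerance, 1/s.
#' @return one of \code{"steady"}, \code{"periodic"},
#'   \code{"quasiperiodic"}, \code{"chaotic"}.
#' @export
classify_regime <- function(le, tol = 0.05) {
  if (inherits(le, "lanmm_les")) le <- c(le$lambda1, le$lambda2)
  l1 <- le[1]; l2 <- le[2]
  if (l1 > tol) "chaotic"
  else if (l1 < -tol) "steady"
  else if (l2 < -tol) "periodic"
  else "quasiperiodic"
}

#' Lyapunov regime map over the input plane
#'
#' Runs [benettin_les()] and [classify_regime()] on a rectangular grid
#' of the two input rates.  Deterministic for fixed settings.
#'
#' @param params base parameter set.
#' @param phi1_grid,phi2_grid input-rate grids, 1/s.
#' @param t_transient,t_accum,dt,t_warmup per-cell Benettin settings (see
#'   [benettin_les()]); map defaults are shorter than the single-point
#'   defaults to keep large grids tractable.
#' @param tol zero-exponent tolerance for classification, 1/s.
#' @return data frame of class \code{lanmm_regime_map} with columns
#'   \code{phi_e1}, \code{phi_e2}, \code{lambda1}, \code{lambda2},
#'   \code{regime}, \code{valid}.
#' @export
regime_map <- function(params, phi1_grid, phi2_grid, t_transient = 10,
                       t_accum = 30, dt = 2e-4, tol = 0.05,
                       t_warmup = 15) {
  grid <- expand.grid(phi_e1 = phi1_grid, phi_e2 = phi2_grid)
  l1 <- l2 <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$inputs$phi_e1 <- grid$phi_e1[i]
    p$inputs$phi_e2 <- grid$phi_e2[i]
    le <- tryCatch(
      benettin_les(p, t_transient = t_transient, t_accum = t_accum,
                   dt = dt, t_warmup = t_warmup),
      error = function(e) NULL)
    if (!is.null(le)) { l1[i] <- le$lambda1; l2[i] <- le$lambda2 }
  }
  regime <- rep(NA_character_, nrow(grid))
  ok <- !is.na(l1)
  regime[ok] <- vapply(which(ok), function(i)
    classify_regime(c(l1[i], l2[i]), tol), character(1))
  structure(cbind(grid, lambda1 = l1, lambda2 = l2, regime = regime,
                  valid = ok),
            class = c("lanmm_regime_map", "data.frame"))
}

#' @export
plot.lanmm_regime_map <- function(x, ...) {
  cols <- c(steady = "grey85", periodic = "steelblue",
            quasiperiodic = "orange", chaotic = "red3")
  graphics::plot(x$phi_e1, x$phi_e2, pch = 15, cex = 0.8,
                 col = cols[x$regime], xlab = "phi_e1 (1/s)",
                 ylab = "phi_e2 (1/s)", ...)
  graphics::legend("topleft", legend = names(cols), col = cols,
                   pch = 15, cex = 0.8, bg = "white")
  invisible(x)
}
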