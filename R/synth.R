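#' Synthetic phase-amplitude-coupled signal
#'
#' Amplitude-modulation family with a closed-form modulation profile:
#' \deqn{x(t) = \sin(2\pi f_s t) + [1 - d + d (1 + \sin(2\pi f_s t))/2]
#'   \sin(2\pi f_f t) + \epsilon(t)}
#' where \eqn{d \in [0,1]} is the coupling depth (\eqn{d = 0}: fast
#' amplitude independent of slow phase; \eqn{d = 1}: fully modulated)
#' and \eqn{\epsilon} is seeded Gaussian noise.  Used as ground truth
#' for validating the modulation-index estimator.
#'
#' @param slow_freq,fast_freq component frequencies, Hz
#'   (\code{fast_freq > slow_freq}).
#' @param coupling_depth modulation depth in [0, 1].
#' @param noise_sd noise standard deviation, mV.
#' @param duration signal length, s.
#' @param sample_rate sampling rate, 1/s (> 2 fast_freq).
#' @param seed RNG seed; identical seeds give identical signals.
#' @return a \code{lanmm_ts}-like data frame with columns \code{t},
#'   \code{vP1} (the composite signal) and \code{vP2} (copy), carrying
#'   \code{sample_rate} and the generator spec as attributes.
#' @export
synthetic_pac_signal <- function(slow_freq = 6, fast_freq = 40,
                                 coupling_depth = 1, noise_sd = 0,
                                 duration = 20, sample_rate = 1000,
                                 seed = 12345) {
  stopifnot(fast_freq > slow_freq, sample_rate > 2 * fast_freq,
            coupling_depth >= 0, coupling_depth <= 1)
  t <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  slow <- sin(2 * pi * slow_freq * t)
  env <- 1 - coupling_depth + coupling_depth * (1 + slow) / 2
  x <- slow + env * sin(2 * pi * fast_freq * t)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    x <- x + stats::rnorm(length(t), sd = noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  ts <- data.frame(t = t, vP1 = x, vP2 = x)
  structure(ts, class = c("lanmm_ts", "data.frame"),
            sample_rate = sample_rate,
            spec = list(slow_freq = slow_freq, fast_freq = fast_freq,
                        coupling_depth = coupling_depth,
                        noise_sd = noise_sd, seed = seed))
}

#' Reference dynamical systems with known Lyapunov spectra
#'
#' Small systems whose two largest Lyapunov exponents are known in
#' closed form, for validating the Benettin estimator:
#' \describe{
#'   \item{linear_stable}{a diagonal linear flow with eigenvalues
#'     (-1, -3): \eqn{\lambda_1 = -1}.}
#'   \item{harmonic_pair}{the planar limit-cycle normal form
#'     \eqn{\dot r = \kappa r (1 - r^2)}, \eqn{\dot \theta = \omega},
#'     with \eqn{\kappa = 1}: \eqn{\lambda_1 = 0},
#'     \eqn{\lambda_2 = -2\kappa}.}
#'   \item{quasiperiodic_torus_flow}{two uncoupled phase oscillators
#'     with incommensurate frequencies embedded in the plane pair
#'     (an isometric flow on the 2-torus): \eqn{\lambda_1 = \lambda_2
#'     = 0}.}
#' }
#'
#' @param label one of the three system names.
#' @return a list with \code{f}, \code{jac}, \code{n}, \code{y0},
#'   \code{known} (named exponents), suitable for [benettin_les()].
#' @export
reference_le_system <- function(label = c("linear_stable", "harmonic_pair",
                                          "quasiperiodic_torus_flow")) {
  label <- match.arg(label)
  switch(label,
    linear_stable = list(
      label = label, n = 2,
      f = function(y) c(-1, -3) * y,
      jac = function(y) diag(c(-1, -3)),
      y0 = c(1, 1),
      known = c(lambda1 = -1, lambda2 = -3)
    ),
    harmonic_pair = {
      kappa <- 1; omega <- 2 * pi
      list(
        label = label, n = 2,
        f = function(y) {
          r2 <- sum(y^2)
          c(kappa * y[1] * (1 - r2) - omega * y[2],
            kappa * y[2] * (1 - r2) + omega * y[1])
        },
        jac = function(y) {
          r2 <- sum(y^2)
          matrix(c(kappa * (1 - r2) - 2 * kappa * y[1]^2,
                   -2 * kappa * y[1] * y[2] - omega,
                   -2 * kappa * y[1] * y[2] + omega,
                   kappa * (1 - r2) - 2 * kappa * y[2]^2),
                 2, 2, byrow = TRUE)
        },
        y0 = c(0.5, 0),
        known = c(lambda1 = 0, lambda2 = -2 * kappa)
      )
    },
    quasiperiodic_torus_flow = {
      w1 <- 2 * pi; w2 <- 2 * pi * sqrt(2)
      list(
        label = label, n = 4,
        f = function(y) c(-w1 * y[2], w1 * y[1], -w2 * y[4], w2 * y[3]),
        jac = function(y) {
          J <- matrix(0, 4, 4)
          J[1, 2] <- -w1; J[2, 1] <- w1
          J[3, 4] <- -w2; J[4, 3] <- w2
          J
        },
        y0 = c(1, 0, 1, 0),
        known = c(lambda1 = 0, lambda2 = 0)
      )
    })
}

#' Discrete convolution oracle for the synaptic kernel
#'
#' Convolves a uniformly sampled input rate signal with the sampled
#' kernel impulse response (rectangle rule).  This is the linear-systems
#' definition of the synapse and serves as an independent check that
#' the second-order ODE block used in the vector field implements the
#' same operator.
#'
#' @param rate_signal input firing rate samples, 1/s.
#' @param kernel a synaptic kernel (see [psp_kernel()]).
#' @param dt sampling interval, s.
#' @return postsynaptic potential samples, mV (same length).
#' @export
convolution_oracle <- function(rate_signal, kernel, dt) {
  n <- length(rate_signal)
  tk <- seq(0, (n - 1) * dt, by = dt)
  h <- psp_kernel(tk, kernel) * dt
  out <- stats::convolve(rate_signal, rev(h), type = "open")[seq_len(n)]
  out
}

#' Integrate one synaptic block driven by a prescribed rate signal
#'
#' Solves \eqn{\ddot y + 2 a \dot y + a^2 y = A a r(t)} for a sampled
#' input rate \eqn{r(t)} (linear interpolation between samples).  Used
#' together with [convolution_oracle()] as a dual-route consistency
#' check of the synapse model.
#'
#' @inheritParams convolution_oracle
#' @return potential samples, mV.
#' @export
synapse_ode_response <- function(rate_signal, kernel, dt) {
  n <- length(rate_signal)
  tgrid <- seq(0, (n - 1) * dt, by = dt)
  rfun <- stats::approxfun(tgrid, rate_signal, rule = 2)
  f <- function(t, y, p)
    list(c(y[2], kernel$A * kernel$a * rfun(t) - 2 * kernel$a * y[2] -
             kernel$a^2 * y[1]))
  out <- deSolve::ode(c(0, 0), tgrid, f, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  out[, 2]
}
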