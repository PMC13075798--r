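#' Second-order synaptic kernel
#'
#' The impulse response of a synapse: an incoming spike-rate impulse
#' produces the postsynaptic potential \eqn{h(t) = A a t e^{-a t}} for
#' \eqn{t \ge 0} and 0 for \eqn{t < 0}.  \eqn{A} (mV) sets the gain and
#' sign (negative for GABAergic synapses), \eqn{a} (1/s) the time scale;
#' the peak \eqn{A/e} occurs at \eqn{t = 1/a} and the integrated area is
#' \eqn{A/a}.
#'
#' @param t time in seconds (vectorized).
#' @param kernel a kernel element of [lanmm_params()] (list with
#'   \code{A}, \code{a}), e.g. \code{lanmm_params()$kernels$AMPA}.
#' @return potential in mV.
#' @export
psp_kernel <- function(t, kernel) {
  ifelse(t >= 0, kernel$A * kernel$a * t * exp(-kernel$a * t), 0)
}

#' Frequency response of a synaptic kernel
#'
#' Fourier transform of the kernel impulse response,
#' \eqn{H(j\omega) = A a / (a + j\omega)^2}.  The magnitude decreases
#' monotonically with \eqn{|\omega|}; faster kernels (larger \eqn{a})
#' retain relatively more gain at high frequencies.
#'
#' @param omega angular frequency in rad/s (vectorized).
#' @inheritParams psp_kernel
#' @return complex gain (mV per unit rate).
#' @export
frequency_response <- function(omega, kernel) {
  kernel$A * kernel$a / (kernel$a + 1i * omega)^2
}

#' Population sigmoid: membrane potential to firing rate
#'
#' \eqn{\sigma(v) = 2\varphi_0 / (1 + e^{r (v_0 - v)})}: strictly
#' increasing from 0 to \eqn{2\varphi_0}, with \eqn{\sigma(v_0) =
#' \varphi_0}.  Overflow-safe for arbitrarily large \eqn{|v|}.
#'
#' @param v membrane potential, mV (vectorized).
#' @param v0 threshold potential at half-maximal rate, mV.
#' @param phi0 half-maximal firing rate, 1/s.
#' @param r sigmoid steepness, 1/mV.
#' @return firing rate, 1/s.
#' @export
sigmoid <- function(v, v0 = 6, phi0 = 2.5, r = 0.56) {
  x <- r * (v0 - v)
  x <- pmin(x, 700)          # exp() would overflow to Inf; rate is then 0
  2 * phi0 / (1 + exp(x))
}

## d sigma / d v, used by the analytic Jacobian
sigmoid_deriv <- function(v, v0 = 6, phi0 = 2.5, r = 0.56) {
  s <- sigmoid(v, v0, phi0, r)
  r * s * (1 - s / (2 * phi0))
}

#' Convert a presynaptic firing rate to a steady postsynaptic potential
#'
#' A constant input rate driving the synaptic kernel settles at the
#' potential \eqn{(A/a) \cdot rate} (the kernel area times the rate).
#' External inputs \code{phi_e1}, \code{phi_e2} enter the model in these
#' units: a rate of 200 1/s through the AMPA kernel equals 6.5 mV at the
#' sigmoid argument.
#'
#' @param rate firing rate, 1/s (nonnegative, vectorized).
#' @inheritParams psp_kernel
#' @return potential, mV.
#' @export
input_rate_to_potential <- function(rate, kernel) {
  stopifnot(all(rate >= 0))
  kernel$A / kernel$a * rate
}

## sigmoid arguments of the five populations, in model order
## P1, SS, SST, P2, PV
population_inputs <- function(state, p) {
  C <- unname(p$connectivity)
  kin <- p$kernels$AMPA$A / p$kernels$AMPA$a
  y <- state
  c(C[1] * y[2] + C[2] * y[3] + C[3] * kin * p$inputs$phi_e1 + C[11] * y[4],
    C[4] * y[1],
    C[5] * y[1],
    C[6] * y[4] + C[7] * y[5] + C[8] * kin * p$inputs$phi_e2 + C[12] * y[1],
    C[9] * y[4] + C[10] * y[5] + C[13] * y[1])
}

#' Vector field of the laminar model
#'
#' The ten coupled first-order equations: five synaptic potential blocks
#' in second-order form, \eqn{\dot y_i = y_{i+5}},
#' \eqn{\dot y_{i+5} = a A \sigma(v_i) - 2 a y_{i+5} - a^2 y_i}, with the
#' population-specific kernel and sigmoid argument.  This is the
#' reference R implementation; simulation routines use the identical
#' compiled version.
#'
#' @param state numeric length-10 state vector (y1..y5 PSPs in mV,
#'   y6..y10 derivatives in mV/s).
#' @param params a [lanmm_params()] object.
#' @return the length-10 time derivative.
#' @export
lanmm_rhs <- function(state, params) {
  if (!all(is.finite(state))) stop("non-finite state")
  p <- params
  v <- population_inputs(state, p)
  sg <- p$sigmoid
  s <- c(sigmoid(v[1], sg$v0, sg$phi0, sg$r),
         sigmoid(v[2], sg$v0, sg$phi0, sg$r),
         sigmoid(v[3], sg$v0, sg$phi0, sg$r),
         sigmoid(v[4], sg$v0_P2, sg$phi0, sg$r),
         sigmoid(v[5], sg$v0, sg$phi0, sg$r))
  ka <- c(p$kernels$AMPA$a, p$kernels$AMPA$a, p$kernels$GABA_slow$a,
          p$kernels$AMPA$a, p$kernels$GABA_fast$a)
  kA <- c(p$kernels$AMPA$A, p$kernels$AMPA$A, p$kernels$GABA_slow$A,
          p$kernels$AMPA$A, p$kernels$GABA_fast$A)
  c(state[6:10],
    ka * kA * s - 2 * ka * state[6:10] - ka^2 * state[1:5])
}

#' Analytic Jacobian of the vector field
#'
#' Dense 10x10 Jacobian.  Rows 1-5 are the selector \code{[0 I]} onto
#' the derivative states; rows 6-10 differentiate each second-order
#' block through the sigmoid chain rule
#' \eqn{\sigma'(v) = r \sigma (1 - \sigma / 2\varphi_0)}.
#'
#' @inheritParams lanmm_rhs
#' @return a 10x10 numeric matrix.
#' @export
lanmm_jacobian <- function(state, params) {
  p <- params
  C <- unname(p$connectivity)
  sg <- p$sigmoid
  v <- population_inputs(state, p)
  aA <- p$kernels$AMPA$a;  AA <- p$kernels$AMPA$A
  aGs <- p$kernels$GABA_slow$a; AGs <- p$kernels$GABA_slow$A
  aGf <- p$kernels$GABA_fast$a; AGf <- p$kernels$GABA_fast$A
  g1 <- aA * AA * sigmoid_deriv(v[1], sg$v0, sg$phi0, sg$r)
  g2 <- aA * AA * sigmoid_deriv(v[2], sg$v0, sg$phi0, sg$r)
  g3 <- aGs * AGs * sigmoid_deriv(v[3], sg$v0, sg$phi0, sg$r)
  g4 <- aA * AA * sigmoid_deriv(v[4], sg$v0_P2, sg$phi0, sg$r)
  g5 <- aGf * AGf * sigmoid_deriv(v[5], sg$v0, sg$phi0, sg$r)
  J <- matrix(0, 10, 10)
  J[1:5, 6:10] <- diag(5)
  J[6, 2] <- g1 * C[1]; J[6, 3] <- g1 * C[2]; J[6, 4] <- g1 * C[11]
  J[6, 1] <- -aA^2;     J[6, 6] <- -2 * aA
  J[7, 1] <- g2 * C[4]; J[7, 2] <- -aA^2;     J[7, 7] <- -2 * aA
  J[8, 1] <- g3 * C[5]; J[8, 3] <- -aGs^2;    J[8, 8] <- -2 * aGs
  J[9, 4] <- g4 * C[6] - aA^2; J[9, 5] <- g4 * C[7]
  J[9, 1] <- g4 * C[12];       J[9, 9] <- -2 * aA
  J[10, 4] <- g5 * C[9]; J[10, 5] <- g5 * C[10] - aGf^2
  J[10, 1] <- g5 * C[13]; J[10, 10] <- -2 * aGf
  J
}

## derivative of the vector field w.r.t. one of the input rates
lanmm_dfdp <- function(state, params, vary = c("phi_e1", "phi_e2")) {
  vary <- match.arg(vary)
  p <- params
  C <- unname(p$connectivity)
  sg <- p$sigmoid
  kin <- p$kernels$AMPA$A / p$kernels$AMPA$a
  v <- population_inputs(state, p)
  aA <- p$kernels$AMPA$a; AA <- p$kernels$AMPA$A
  d <- numeric(10)
  if (vary == "phi_e1") {
    d[6] <- aA * AA * sigmoid_deriv(v[1], sg$v0, sg$phi0, sg$r) * C[3] * kin
  } else {
    d[9] <- aA * AA * sigmoid_deriv(v[4], sg$v0_P2, sg$phi0, sg$r) * C[8] * kin
  }
  d
}

#' Pyramidal observables
#'
#' The two measured membrane potentials: the deep pyramidal potential
#' \eqn{v_{P1} = C_1 y_2 + C_2 y_3 + C_{11} y_4} and the superficial
#' pyramidal potential \eqn{v_{P2} = C_6 y_4 + C_7 y_5 + C_{12} y_1},
#' i.e. the sums of postsynaptic potentials impinging on each pyramidal
#' population (excluding external input).
#'
#' @inheritParams lanmm_rhs
#' @return named numeric \code{c(vP1, vP2)} in mV.
#' @export
lanmm_observables <- function(state, params) {
  C <- unname(params$connectivity)
  y <- state
  c(vP1 = C[1] * y[2] + C[2] * y[3] + C[11] * y[4],
    vP2 = C[6] * y[4] + C[7] * y[5] + C[12] * y[1])
}
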