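test_that("synaptic kernel has the analytic peak, boundary and area", {
  p <- lanmm_params()
  for (k in p$kernels) {
    expect_identical(psp_kernel(0, k), 0)
    expect_identical(psp_kernel(-0.01, k), 0)
    ## analytic maximum A/e at t = 1/a
    expect_equal(psp_kernel(1 / k$a, k), k$A / exp(1), tolerance = 1e-12)
    ## quadrature area equals closed-form A/a
    area <- stats::integrate(psp_kernel, 0, Inf, kernel = k,
                             rel.tol = 1e-10)$value
    expect_equal(area, k$A / k$a, tolerance = 1e-6)
  }
  expect_equal(psp_kernel(1 / 100, p$kernels$AMPA), 3.25 / exp(1),
               tolerance = 1e-12)
})

test_that("kernel frequency response: DC gain, half-power, relative bandwidth", {
  p <- lanmm_params()
  ampa <- p$kernels$AMPA
  gf <- p$kernels$GABA_fast
  expect_equal(frequency_response(0, ampa), complex(real = 0.0325),
               tolerance = 1e-12)
  ## |a + ja|^2 = 2 a^2 halves the DC magnitude
  expect_equal(Mod(frequency_response(ampa$a, ampa)),
               Mod(frequency_response(0, ampa)) / 2, tolerance = 1e-12)
  ## magnitude monotone decreasing in |omega|
  m <- Mod(frequency_response(seq(0, 2000, by = 10), ampa))
  expect_true(all(diff(m) < 0))
  ## fast GABA retains relatively more gain at gamma frequencies
  w <- 2 * pi * 40
  rel <- function(k) Mod(frequency_response(w, k) / frequency_response(0, k))
  expect_gt(rel(gf), rel(ampa))
})

test_that("sigmoid hits half-max at threshold, saturates, stays monotone and finite", {
  expect_identical(sigmoid(6, v0 = 6), 2.5)
  expect_equal(sigmoid(1e4), 5, tolerance = 1e-12)
  expect_equal(sigmoid(-1e4), 0, tolerance = 1e-12)
  expect_true(all(is.finite(sigmoid(c(-1e9, 1e9)))))
  v <- seq(-50, 50, length.out = 1000)
  expect_true(all(diff(sigmoid(v)) > 0))
})

test_that("input rate converts to potential by the kernel area", {
  ampa <- lanmm_params()$kernels$AMPA
  expect_equal(input_rate_to_potential(200, ampa), 6.5, tolerance = 1e-12)
  expect_identical(input_rate_to_potential(0, ampa), 0)
  expect_equal(input_rate_to_potential(90, ampa), 2.925, tolerance = 1e-12)
  expect_error(input_rate_to_potential(-1, ampa))
})

test_that("vector field matches a direct substitution of the block equations", {
  p <- lanmm_params(phi_e1 = 200, phi_e2 = 90)
  d <- lanmm_rhs(rep(0, 10), p)
  expect_identical(d[1:5], rep(0, 5))
  ## at the zero state each acceleration is a*A*sigma(input contribution)
  kin <- 3.25 / 100
  expect_equal(d[6], 100 * 3.25 * sigmoid(1 * kin * 200, v0 = 6),
               tolerance = 1e-12)
  expect_equal(d[7], 100 * 3.25 * sigmoid(0, v0 = 6), tolerance = 1e-12)
  expect_equal(d[8], 50 * (-22) * sigmoid(0, v0 = 6), tolerance = 1e-12)
  expect_equal(d[9], 100 * 3.25 * sigmoid(1 * kin * 90, v0 = 1),
               tolerance = 1e-12)
  expect_equal(d[10], 220 * (-30) * sigmoid(0, v0 = 6), tolerance = 1e-12)
  expect_error(lanmm_rhs(c(rep(0, 9), NaN), p))
})

test_that("vector field vanishes at a solved equilibrium", {
  eq <- find_equilibrium(lanmm_params())
  expect_lt(max(abs(lanmm_rhs(eq$state, lanmm_params()))), 1e-10)
  expect_identical(eq$state[6:10], rep(0, 5))
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(42)
  p <- lanmm_params(phi_e1 = 150, phi_e2 = 80)
  worst <- 0
  for (i in 1:100) {
    y <- rnorm(10, sd = c(rep(2, 5), rep(50, 5)))
    J <- lanmm_jacobian(y, p)
    Jfd <- lanmm:::numeric_jacobian(function(z) lanmm_rhs(z, p), y)
    worst <- max(worst, max(abs(J - Jfd)) / max(1, max(abs(J))))
  }
  expect_lt(worst, 1e-6)
})

test_that("Jacobian rows for the potential states are the [0 I] selector", {
  J <- lanmm_jacobian(rnorm(10), lanmm_params(phi_e1 = 50))
  expect_identical(J[1:5, 1:5], matrix(0, 5, 5))
  expect_identical(J[1:5, 6:10], diag(5))
})

test_that("resting equilibrium is stable with oscillatory and real modes", {
  eq <- find_equilibrium(lanmm_params())
  expect_true(eq$stable)
  ev <- eq$eigenvalues
  n_complex_pairs <- sum(Im(ev) > 1e-6)
  n_real <- sum(abs(Im(ev)) < 1e-6)
  expect_gte(n_complex_pairs, 3)
  expect_gte(n_real, 2)
  expect_true(all(Re(ev) < 0))
})

test_that("observables are the stated linear combinations", {
  p <- lanmm_params()
  expect_identical(unname(lanmm_observables(rep(0, 10), p)), c(0, 0))
  e2 <- replace(rep(0, 10), 2, 1)
  expect_equal(unname(lanmm_observables(e2, p)), c(108, 0))
  e1 <- replace(rep(0, 10), 1, 1)
  expect_equal(unname(lanmm_observables(e1, p)), c(0, 200))
})

test_that("compiled vector field matches the R reference along a trajectory", {
  p <- lanmm_params(phi_e1 = 250)
  st <- solver_settings(t_transient = 0, t_record = 0.5)
  ts_c <- simulate_lanmm(p, st)
  f <- function(t, y, parms) list(lanmm_rhs(y, p))
  out <- deSolve::ode(rep(0, 10), ts_c$t, f, NULL, method = "lsoda",
                      rtol = st$rel_tol, atol = st$abs_tol)
  C <- unname(p$connectivity)
  vp1_r <- C[1] * out[, 3] + C[2] * out[, 4] + C[11] * out[, 5]
  expect_lt(sqrt(mean((ts_c$vP1 - vp1_r)^2)), 1e-5)
})
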