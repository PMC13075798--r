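test_that("synthetic coupled signals are seed-deterministic", {
  a <- synthetic_pac_signal(coupling_depth = 0.5, noise_sd = 0.3, seed = 99)
  b <- synthetic_pac_signal(coupling_depth = 0.5, noise_sd = 0.3, seed = 99)
  expect_identical(a$vP1, b$vP1)
  c <- synthetic_pac_signal(coupling_depth = 0.5, noise_sd = 0.3, seed = 100)
  expect_false(identical(a$vP1, c$vP1))
  expect_error(synthetic_pac_signal(slow_freq = 50, fast_freq = 40))
})

test_that("modulation index tracks the generated coupling depth", {
  mi_at <- function(d) {
    sg <- synthetic_pac_signal(slow_freq = 6, fast_freq = 40,
                               coupling_depth = d, duration = 20)
    ph <- bandpass_phase_amp(sg, c(4, 8), "phase")
    am <- bandpass_phase_amp(sg, c(30, 100), "amplitude")
    tort_mi(ph, am)$mi
  }
  mis <- vapply(c(0, 0.25, 0.5, 0.75, 1), mi_at, numeric(1))
  expect_lt(mis[1], 0.01)
  expect_true(all(diff(mis) > 0))
  expect_gt(mis[5], 0.05)
})

test_that("reference systems reproduce their known Lyapunov spectra", {
  lin <- reference_le_system("linear_stable")
  le <- benettin_les(lin, y0 = lin$y0, t_transient = 2, t_accum = 30,
                     t_warmup = 2)
  expect_within(le$lambda1, -1, 0.05)

  nf <- reference_le_system("harmonic_pair")
  le2 <- benettin_les(nf, y0 = nf$y0, t_transient = 20, t_accum = 60,
                      t_warmup = 10)
  expect_within(le2$lambda1, 0, 0.05)
  expect_within(le2$lambda2, -2, 0.1)   # -2*kappa, 5%

  tor <- reference_le_system("quasiperiodic_torus_flow")
  le3 <- benettin_les(tor, y0 = tor$y0, t_transient = 2, t_accum = 30,
                      t_warmup = 2)
  expect_lt(abs(le3$lambda1), 0.05)
  expect_lt(abs(le3$lambda2), 0.05)

  expect_error(reference_le_system("lorenz"))
})

test_that("the synaptic ODE block reproduces the convolution operator", {
  k <- lanmm_params()$kernels$AMPA
  dt <- 1e-4
  n <- 20000
  ## constant rate settles at (A/a) * rate
  y_const <- convolution_oracle(rep(120, n), k, dt)
  expect_within(y_const[n], k$A / k$a * 120, 1e-3)
  ## discrete impulse reproduces the sampled kernel
  imp <- c(1 / dt, rep(0, 999))
  y_imp <- convolution_oracle(imp, k, dt)
  expect_lt(max(abs(y_imp - psp_kernel(seq(0, by = dt,
                                           length.out = 1000), k))),
            1e-3)
  ## band-limited random rate: ODE route vs convolution route
  set.seed(2024)
  tgrid <- seq(0, (n - 1) * dt, by = dt)
  freqs <- runif(8, 0.5, 15)
  amps <- rnorm(8, sd = 20)
  rate <- 150 + Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * tgrid),
                                freqs, amps))
  rate <- pmax(rate, 0)
  y_ode <- synapse_ode_response(rate, k, dt)
  y_conv <- convolution_oracle(rate, k, dt)
  i <- tgrid > 0.2            # discard the convolution edge
  expect_lt(sqrt(mean((y_ode[i] - y_conv[i])^2)), 1e-4)
})
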