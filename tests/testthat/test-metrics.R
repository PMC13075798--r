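test_that("Welch spectrum localizes a pure tone and conserves variance", {
  fs <- 1000
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  s <- psd_welch(x, fs = fs, seg_seconds = 10)
  expect_within(s$freq[which.max(s$power)], 10, 0.1)
  set.seed(7)
  w <- rnorm(length(t))
  sw <- psd_welch(w, fs = fs, seg_seconds = 10)
  df <- diff(sw$freq[1:2])
  expect_within(sum(sw$power) * df / stats::var(w), 1, 0.05)
  expect_error(psd_welch(w[1:100], fs = fs, seg_seconds = 10), "short")
})

test_that("dominant frequency respects the exclusion band and noise floor", {
  f <- seq(0, 500, by = 0.1)
  p <- rep(1e-9, length(f))
  p[f == 20] <- 5          # inside the excluded beta band
  p[f == 40] <- 3
  s <- structure(data.frame(freq = f, power = p),
                 class = c("lanmm_spectrum", "data.frame"))
  expect_equal(dominant_frequency(s, exclude_band = c(12, 30)), 40)
  expect_equal(dominant_frequency(s), 20)
  flat <- structure(data.frame(freq = f, power = rep(1e-12, length(f))),
                    class = c("lanmm_spectrum", "data.frame"))
  expect_true(is.na(dominant_frequency(flat, floor_frac = 1e-2)))
  zero <- structure(data.frame(freq = f, power = rep(0, length(f))),
                    class = c("lanmm_spectrum", "data.frame"))
  expect_error(dominant_frequency(zero))
})

test_that("band-pass phase advances linearly and envelopes stay flat", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 6 * t)
  ph <- bandpass_phase_amp(x, c(4, 8), "phase", fs = fs)
  uw <- lanmm:::unwrap_phase(ph)
  i <- seq(2000, 8000)
  slope <- stats::coef(stats::lm(uw[i] ~ t[i]))[2]
  expect_within(slope / (2 * pi), 6, 0.06)
  am <- bandpass_phase_amp(x, c(4, 8), "amplitude", fs = fs)
  core <- am[i]
  expect_lt(diff(range(core)) / mean(core), 0.02)
  expect_error(bandpass_phase_amp(x, c(0, 8), fs = fs))
  expect_error(bandpass_phase_amp(x, c(600, 700), fs = fs))
})

test_that("zero-phase filtering preserves the center of mass of a pulse", {
  fs <- 1000
  n <- 4000
  x <- exp(-((seq_len(n) - 2000) / 40)^2)      # symmetric pulse at 2000
  bf <- signal::butter(4, c(5, 50) / (fs / 2), "pass")
  y <- signal::filtfilt(bf, x)
  com <- function(v) sum(seq_along(v) * abs(v)) / sum(abs(v))
  expect_lt(abs(com(y) - com(x)), 1)
})

test_that("modulation index hits its theoretical limits and invariances", {
  set.seed(11)
  ph <- runif(20000, -pi, pi)
  am <- abs(rnorm(20000, mean = 5))
  expect_lt(tort_mi(ph, am)$mi, 0.01)
  ## all amplitude in a single phase bin: MI = 1 exactly
  am1 <- ifelse(ph > -pi & ph < -pi + 2 * pi / 18, 1, 0)
  expect_equal(tort_mi(ph, am1)$mi, 1, tolerance = 1e-12)
  ## exact invariance under positive amplitude rescaling
  r1 <- tort_mi(ph, am)$mi
  r2 <- tort_mi(ph, 37.5 * am)$mi
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_gte(r1, 0)
  expect_error(tort_mi(ph[1:10], am[1:10], n_bins = 18), "bins")
})

test_that("regime labels follow the exponent sign pattern", {
  expect_identical(classify_regime(c(-2, -5)), "steady")
  expect_identical(classify_regime(c(0.001, -1.2)), "periodic")
  expect_identical(classify_regime(c(0.002, -0.003)), "quasiperiodic")
  expect_identical(classify_regime(c(0.2, 0.01)), "chaotic")
})

test_that("compiled and generic Benettin paths agree on the laminar model", {
  p <- lanmm_params(phi_e1 = 250)
  le_c <- benettin_les(p, t_transient = 10, t_accum = 40, t_warmup = 10)
  sys <- list(n = 10, f = function(y) lanmm_rhs(y, p),
              jac = function(y) lanmm_jacobian(y, p))
  ts <- simulate_lanmm(p, solver_settings(t_transient = 10, t_record = 1))
  le_r <- benettin_les(sys, y0 = attr(ts, "final_state"),
                       t_transient = 0, t_accum = 40, t_warmup = 10)
  expect_lt(abs(le_c$lambda1 - le_r$lambda1), 0.05)
  expect_lt(abs(le_c$lambda2 - le_r$lambda2), 0.3)
  expect_identical(classify_regime(le_c), "periodic")
})

test_that("frequency map flags multifrequency cells and steady cells", {
  mp <- frequency_map(lanmm_params(), 125, 307,
                      solver_settings(t_transient = 10, t_record = 20))
  expect_identical(nrow(mp), 1L)
  expect_lt(mp$f_vP1, 12)
  expect_gt(mp$f_vP2, 30)
  expect_true(mp$multifrequency)
  mp2 <- frequency_map(lanmm_params(), 50, 0,
                       solver_settings(t_transient = 10, t_record = 20))
  expect_true(is.na(mp2$f_vP1) || mp2$f_vP1 < 1)
  expect_false(isTRUE(mp2$multifrequency))
})

test_that("steady-regime exponent matches the equilibrium spectrum", {
  p <- lanmm_params(phi_e1 = 50)
  le <- benettin_les(p, t_transient = 20, t_accum = 40, t_warmup = 10)
  eq <- find_equilibrium(p)
  expect_within(le$lambda1, max(Re(eq$eigenvalues)), 0.5)
  expect_lt(le$lambda1, 0)
})
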