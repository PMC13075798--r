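test_that("integration is deterministic and tolerance-converged", {
  p <- lanmm_params(phi_e1 = 250)
  st <- solver_settings(t_transient = 2, t_record = 5)
  a <- simulate_lanmm(p, st)
  b <- simulate_lanmm(p, st)
  expect_identical(a$vP1, b$vP1)
  expect_identical(a$vP2, b$vP2)
  st2 <- solver_settings(rel_tol = st$rel_tol / 2, abs_tol = st$abs_tol,
                         t_transient = 2, t_record = 5)
  c <- simulate_lanmm(p, st2)
  expect_lt(sqrt(mean((a$vP1 - c$vP1)^2)), 1e-4)
})

test_that("zero input relaxes to the stable fixed point", {
  p <- lanmm_params()
  ts <- simulate_lanmm(p, solver_settings(t_transient = 5, t_record = 1),
                       init = rep(0.05, 10), keep_states = TRUE)
  yT <- attr(ts, "final_state")
  expect_lt(sqrt(sum(lanmm_rhs(yT, p)^2)), 1e-6)
})

test_that("the alpha operating point sustains a finite oscillation", {
  ts <- sim_at(250, 0, t_record = 20)
  expect_gt(diff(range(ts$vP1)), 1)
  expect_lt(max(abs(ts$vP1)), 500)
  expect_lt(max(abs(ts$vP2)), 500)
})

test_that("DC removal centers channels without changing their widths", {
  ts <- sim_at(250, 0, t_record = 20)
  r1 <- diff(range(ts$vP1))
  out <- remove_dc(ts)
  expect_lt(abs(mean(out$vP1)), 1e-12 * max(1, sd(ts$vP1)))
  expect_lt(abs(mean(out$vP2)), 1e-12 * max(1, sd(ts$vP2)))
  expect_equal(diff(range(out$vP1)), r1, tolerance = 1e-12)
  ## a constant channel becomes identically zero
  flat <- ts
  flat$vP1 <- rep(3.2, nrow(flat))
  expect_true(all(remove_dc(flat)$vP1 == 0))
})

test_that("pulse response: superficial layer responds harder, both relax", {
  ts <- pulse_response(lanmm_params(), pulse_width = 1e-3,
                       pulse_rate = 200, t_record = 2)
  base <- attr(ts, "baseline")
  dev1 <- max(abs(ts$vP1 - base[["vP1"]]))
  dev2 <- max(abs(ts$vP2 - base[["vP2"]]))
  expect_gt(dev2, dev1)
  ## damped return to rest: final deviations under 1% of the peaks
  tail_idx <- ts$t > 1.5
  expect_lt(max(abs(ts$vP1[tail_idx] - base[["vP1"]])), 0.01 * dev1)
  expect_lt(max(abs(ts$vP2[tail_idx] - base[["vP2"]])), 0.01 * dev2)
})

test_that("a zero-width pulse leaves the system at the fixed point", {
  ts <- pulse_response(lanmm_params(), pulse_width = 0, t_record = 0.5)
  expect_lt(diff(range(ts$vP1)), 1e-9)
  expect_lt(diff(range(ts$vP2)), 1e-9)
})
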