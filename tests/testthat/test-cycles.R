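test_that("shooting converges on the alpha orbit with unit trivial multiplier", {
  cyc <- cached("cyc250", cycle_from_simulation(lanmm_params(phi_e1 = 250)))
  expect_within(1 / cyc$period, 10.4, 1)
  expect_lt(abs(cyc$trivial_multiplier - 1), 1e-3)
  expect_true(cyc$stable)
  expect_gt(cyc$amplitude[["amp1"]], 1)
})

test_that("the fast orbit past the second Hopf runs at gamma frequency", {
  cyc <- cached("cyc500", cycle_from_simulation(lanmm_params(phi_e1 = 500)))
  expect_within(1 / cyc$period, 40.5, 2)
  expect_lt(abs(cyc$trivial_multiplier - 1), 1e-3)
  expect_true(cyc$stable)
})

test_that("monodromy determinant obeys the Liouville trace identity", {
  cyc <- cached("cyc250", cycle_from_simulation(lanmm_params(phi_e1 = 250)))
  model <- lanmm:::cmodel_single_fast(cyc$params)
  fm <- lanmm:::flow_mono(model, cyc$anchor_state, cyc$param, cyc$period)
  ## integral of trace(J) along the orbit, trapezoid rule
  ns <- 2000
  orb <- lanmm:::flow_only(model, cyc$anchor_state, cyc$param,
                           seq(0, cyc$period, length.out = ns))
  trs <- apply(orb[, -1], 1, function(y)
    sum(diag(model$jac(y, cyc$param))))
  dt <- cyc$period / (ns - 1)
  itr <- sum((trs[-1] + trs[-ns]) / 2) * dt
  expect_equal(abs(det(fm$M)), exp(itr), tolerance = 0.01)
})

test_that("stable cycles attract nearby trajectories", {
  cyc <- cached("cyc250", cycle_from_simulation(lanmm_params(phi_e1 = 250)))
  model <- lanmm:::cmodel_single_fast(cyc$params)
  ## the period map contracts toward the orbit: for a point on the
  ## cycle it is the identity, so successive period-map differences of
  ## a perturbed point shrink geometrically as it is attracted
  step_T <- function(y) unname(
    lanmm:::flow_only(model, y, cyc$param, c(0, cyc$period))[2, -1])
  y <- cyc$anchor_state + 1e-3
  diffs <- numeric(8)
  for (k in 1:8) {
    y2 <- step_T(y)
    diffs[k] <- sqrt(sum((y2 - y)^2))
    y <- y2
  }
  expect_lt(diffs[8], diffs[1] / 4)
})

test_that("the slow-cycle branch folds, losing amplitude and gaining frequency", {
  br <- cycle_branch_flc()
  bif <- detect_cycle_bifurcations(br)
  flc <- bif[bif$kind == "FLC", ]
  expect_gte(nrow(flc), 1)
  ## amplitude decreases and frequency increases across the fold region
  lo <- which.min(abs(br$param - 125))
  hi <- max(which(br$param > 175))
  expect_lt(br$amp_vP1[hi], br$amp_vP1[lo])
  expect_gt(br$freq[hi], br$freq[lo])
})

test_that("the alpha branch shrinks onto the supercritical Hopf point", {
  br <- cached("cycbr_hopf", {
    cyc <- cycle_from_simulation(lanmm_params(phi_e1 = 345))
    continue_cycles(cyc, range = c(340, 375), step = 1, max_step = 3)
  })
  ## amplitude falls monotonically toward zero approaching the Hopf
  top <- br[br$param > 350, ]
  expect_lt(min(top$amp_vP1), 0.5)
  expect_lt(stats::cor(top$param, top$amp_vP1), -0.9)
  ## a small Hopf-born cycle is stable: nontrivial multipliers inside
  ## the unit circle, so no bifurcations flagged past the fold region
  expect_true(all(top$stable))
})

test_that("a torus bifurcation destabilizes the alpha cycle under superficial drive", {
  res <- cached("tr90", {
    cyc <- cycle_from_simulation(lanmm_params(phi_e1 = 250, phi_e2 = 90))
    br <- continue_cycles(cyc, range = c(260, 150), step = 1, max_step = 4)
    list(br = br, bif = detect_cycle_bifurcations(br))
  })
  tr <- res$bif[res$bif$kind == "torus", ]
  expect_gte(nrow(tr), 1)
  expect_within(tr$param[1], 190, 15)
  ## the branch is unstable on the high side of the crossing and the
  ## multiplier test brackets the unit circle
  mods <- res$br$max_nontrivial_mod
  expect_gt(max(mods), 1.1)
  expect_lt(min(mods), 0.99)
  ## past the torus bifurcation the attractor is quasiperiodic:
  ## two near-zero Lyapunov exponents (cross-module consistency)
  le <- cached("le200_90", benettin_les(
    lanmm_params(phi_e1 = 200, phi_e2 = 90),
    t_transient = 10, t_accum = 60, t_warmup = 20))
  expect_lt(abs(le$lambda1), 0.05)
  expect_lt(abs(le$lambda2), 0.05)
})
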