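test_that("branch points satisfy the equilibrium condition everywhere", {
  br <- branch_phi2_0()
  expect_true(all(br$residual < 1e-10))
  expect_gt(nrow(br), 50)
  ## both stable and unstable segments are present
  expect_true(any(br$stable) && any(!br$stable))
  ## derivative states vanish on the whole branch
  states <- attr(br, "states")
  expect_lt(max(abs(states[, 6:10])), 1e-9)
})

test_that("forward and backward traversal recover the same curve", {
  br_f <- branch_phi2_0()
  br_b <- cached("branch0_rev",
                 continue_equilibria(lanmm_params(), range = c(0, 600),
                                     start = 600, direction = -1,
                                     guess = attr(br_f, "states")[nrow(br_f), ]))
  ## polish each branch onto a common parameter grid and compare the
  ## solved states: both traversals must describe the same curve
  grid <- seq(5, 80, by = 15)
  solve_from <- function(br, lam) {
    ## among nearby branch points take the lowest-potential equilibrium
    ## (the resting branch), then polish at exactly lam
    near <- which(abs(br$param - lam) < 5)
    i <- near[which.min(attr(br, "states")[near, 1])]
    p <- lanmm_params(phi_e1 = lam)
    find_equilibrium(p, guess = attr(br, "states")[i, ])$state
  }
  for (lam in grid) {
    sf <- solve_from(br_f, lam)
    sb <- solve_from(br_b, lam)
    expect_lt(max(abs(sf - sb)), 1e-6)
  }
})

test_that("codimension-one scan finds the fold and both Hopf points", {
  bif <- bifurcations_phi2_0()
  folds <- bif$param[bif$kind == "fold" & bif$param > 0]
  hopfs <- bif[grepl("hopf", bif$kind), ]
  expect_length(folds, 1)
  expect_equal(nrow(hopfs), 2)
  ## every detection is refined onto its defining condition
  expect_lt(max(abs(hopfs$diagnostic)), 1e-6)
  ## Hopf frequencies sit in the alpha and gamma ranges
  expect_within(sort(hopfs$frequency)[1], 10.8, 1)
  expect_within(sort(hopfs$frequency)[2], 40.3, 2)
  ## both probe as supercritical
  expect_true(all(hopfs$kind == "hopf_super"))
})

test_that("a linear stable system yields no detections", {
  m <- linear_cmodel()
  br <- continue_equilibria(NULL, range = c(0, 10), model = m,
                            guess = c(0, 0), step = 0.5)
  expect_true(all(br$stable))
  bif <- detect_codim1(br, classify_hopf = FALSE)
  expect_identical(nrow(bif), 0L)
})

test_that("the oscillation-creating fold classifies as SNIC with diverging period", {
  bif <- bifurcations_phi2_0()
  i <- which(bif$kind == "fold" & bif$param > 0)[1]
  res <- cached("snic0", classify_snic(bif[i, ], lanmm_params(),
                                       state = attr(bif, "states")[i, ]))
  expect_identical(res$kind, "SNIC")
  expect_gt(res$period_near, res$period_far)
})

test_that("a saddle-node without an invariant circle stays a fold", {
  ## 1-D normal form x' = mu - x^2: past the fold trajectories escape,
  ## no periodic orbit exists on either side
  probe <- function(offset) {
    mu <- offset
    if (mu >= 0) return(list(period = NA_real_, amp = 0))
    list(period = NA_real_, amp = 0)
  }
  res <- classify_snic(list(param = 0), probe_fn = probe)
  expect_identical(res$kind, "fold")
})

test_that("Hopf loci move left with rising superficial drive, the fold barely", {
  loci <- cached("locus_fast_hopf", {
    fast <- trace_locus_2param(lanmm_params(), "hopf",
                               grid_phi2 = c(0, 40, 80),
                               range_phi1 = c(0, 600),
                               freq_range = c(20, 60))
    fold <- trace_locus_2param(lanmm_params(), "fold",
                               grid_phi2 = c(0, 40, 80),
                               range_phi1 = c(0, 600))
    list(fast = fast, fold = fold)
  })
  ## gamma-onset Hopf shifts to much smaller phi_e1
  expect_true(all(diff(loci$fast$phi_e1) < -50))
  ## SNIC locus nearly vertical: total drift a few rate units
  expect_lt(max(loci$fold$phi_e1) - min(loci$fold$phi_e1), 15)
  expect_identical(nrow(trace_locus_2param(lanmm_params(), "fold",
                                           grid_phi2 = numeric(0))), 0L)
})
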