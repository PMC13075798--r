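test_that("zero coupling gains decouple the columns exactly", {
  set.seed(5)
  tp0 <- two_column_params(phi = 100, g_ff = 0, g_fb_p11 = 0,
                           g_fb_p12 = 0, g_fb_sst = 0)
  y <- rnorm(20, sd = 0.3)
  d2 <- two_column_rhs(y, tp0)
  p1 <- lanmm_params(phi_e1 = 100, phi_e2 = 100)
  expect_identical(d2, c(lanmm_rhs(y[1:10], p1), lanmm_rhs(y[11:20], p1)))
})

test_that("two-column Jacobian matches finite differences with coupling on", {
  set.seed(6)
  tp <- two_column_params(phi = 120)
  worst <- 0
  for (i in 1:20) {
    y <- rnorm(20, sd = c(rep(1, 5), rep(30, 5)))
    J <- two_column_jacobian(y, tp)
    Jfd <- lanmm:::numeric_jacobian(function(z) two_column_rhs(z, tp), y)
    worst <- max(worst, max(abs(J - Jfd)) / max(1, max(abs(J))))
  }
  expect_lt(worst, 1e-6)
})

test_that("decoupled two-column bifurcations duplicate the single-column ones", {
  tp0 <- two_column_params(phi = 0, g_ff = 0, g_fb_p11 = 0,
                           g_fb_p12 = 0, g_fb_sst = 0)
  res <- cached("twocol_dec", two_column_branch(tp0, range = c(0, 600)))
  ## oracle: one column receiving the same rate on both inputs
  oracle <- cached("diag_oracle", {
    m <- lanmm:::cmodel_single_diag(lanmm_params())
    br <- continue_equilibria(NULL, range = c(0, 600), model = m,
                              guess = rep(0, 10))
    detect_codim1(br, classify_hopf = FALSE)
  })
  fold_2c <- res$bifurcations$param[res$bifurcations$kind == "fold" &
                                      res$bifurcations$param > 0]
  fold_1c <- oracle$param[oracle$kind == "fold" & oracle$param > 0]
  expect_gte(length(fold_2c), 1)
  expect_within(fold_2c[1], fold_1c[1], 0.05)
})

test_that("coupled columns oscillate with multifrequency content", {
  tp <- two_column_params(phi = 125)
  ts <- cached("twocol125",
               simulate_two_column(tp, solver_settings(t_transient = 10,
                                                       t_record = 30)))
  f <- function(ch) dominant_frequency(
    psd_welch(ts[[ch]], fs = attr(ts, "sample_rate"), seg_seconds = 10),
    exclude_band = c(12, 30))
  ## deep-layer populations below the alpha band in both columns
  expect_lt(f("vP11"), 12)
  expect_lt(f("vP21"), 12)
  ## superficial layers carry a gamma component on top
  gpow <- function(ch) {
    s <- psd_welch(ts[[ch]], fs = attr(ts, "sample_rate"),
                   seg_seconds = 10)
    sum(s$power[s$freq >= 30 & s$freq <= 100]) / sum(s$power)
  }
  expect_gt(gpow("vP12"), 10 * gpow("vP11"))
  expect_gt(gpow("vP22"), 10 * gpow("vP21"))
})

test_that("coupling reshapes the equilibrium diagram but keeps its skeleton", {
  tp <- two_column_params(phi = 0)
  res <- cached("twocol_cpl", two_column_branch(tp, range = c(0, 600)))
  expect_gte(nrow(res$bifurcations), 1)
  ## the coupled fold differs from the decoupled one, but modestly
  dec <- cached("twocol_dec", two_column_branch(
    two_column_params(phi = 0, g_ff = 0, g_fb_p11 = 0, g_fb_p12 = 0,
                      g_fb_sst = 0), range = c(0, 600)))
  f_c <- res$bifurcations$param[res$bifurcations$kind == "fold" &
                                  res$bifurcations$param > 0][1]
  f_d <- dec$bifurcations$param[dec$bifurcations$kind == "fold" &
                                  dec$bifurcations$param > 0][1]
  expect_false(isTRUE(all.equal(f_c, f_d, tolerance = 1e-6)))
  expect_lt(abs(f_c - f_d), 50)
})

test_that("weakening the PV synapse shifts loci left and then kills gamma", {
  sc <- cached("pvscan", pv_scan(
    c7_values = c(550, 300, 100), phi2_grid = seq(0, 300, by = 100),
    phi1_range = c(0, 600)))
  l <- sc$loci
  base <- l[l$C7 == 550 & l$phi_e2 == 0, ]
  mid <- l[l$C7 == 300 & l$phi_e2 == 0, ]
  ## all three loci move to smaller inputs (hyperexcitability)
  expect_lt(mid$fold, base$fold)
  expect_lt(mid$hopf1, base$hopf1)
  expect_lt(mid$hopf2, base$hopf2)
  ## the coexistence region grows
  a <- sc$coexistence
  expect_gt(a$area_fraction[a$C7 == 300], a$area_fraction[a$C7 == 550])
  ## strong reduction: no gamma-generating Hopf anywhere in the window
  expect_true(all(is.na(l$hopf2[l$C7 == 100])))
  expect_equal(a$area_fraction[a$C7 == 100], 0)
})
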