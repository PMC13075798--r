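test_that("default construction reproduces the standard parameter table", {
  p <- lanmm_params()
  expect_equal(p$kernels$AMPA$A, 3.25)
  expect_equal(p$kernels$GABA_slow$A, -22)
  expect_equal(p$kernels$GABA_fast$A, -30)
  expect_equal(unname(p$connectivity),
               c(108, 33.7, 1, 135, 33.75, 70, 550, 1, 200, 100, 80, 200, 30))
  expect_equal(p$sigmoid$v0, 6)
  expect_equal(p$sigmoid$v0_P2, 1)
  expect_equal(p$sigmoid$phi0, 2.5)
  expect_equal(p$sigmoid$r, 0.56)
})

test_that("named overrides land on the right fields and bad ones fail", {
  p <- lanmm_params(phi_e1 = 200, C7 = 300, r = 0.6, a_GABA_fast = 200)
  expect_equal(p$connectivity[["C7"]], 300)
  expect_equal(p$sigmoid$r, 0.6)
  expect_equal(p$kernels$GABA_fast$a, 200)
  expect_equal(p$inputs$phi_e1, 200)
  expect_error(lanmm_params(C99 = 1), "unknown")
  expect_error(lanmm_params(phi_e1 = -5))
  expect_error(lanmm_params(A_AMPA = -1))   # AMPA gain must stay positive
})

test_that("parameter sets round-trip through JSON bit-exactly", {
  p <- lanmm_params(phi_e1 = 200, phi_e2 = 90, C7 = 412.5)
  f <- withr::local_tempfile(fileext = ".json")
  write_lanmm_params(p, f)
  expect_identical(unclass(read_lanmm_params(f)), unclass(p))
})

test_that("the canonical standard parameter file ships and round-trips", {
  f <- system.file("extdata", "table1.json", package = "lanmm")
  expect_true(nzchar(f))
  expect_identical(unclass(read_lanmm_params(f)), unclass(lanmm_params()))
})
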