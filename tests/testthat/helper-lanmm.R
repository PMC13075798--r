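# Shared fixtures.  Expensive objects (branches, long simulations) are
# computed lazily once per test run and reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## equilibrium branch at phi_e2 = 0 over the standard window
branch_phi2_0 <- function() {
  cached("branch0", continue_equilibria(lanmm_params(), range = c(0, 600)))
}

bifurcations_phi2_0 <- function() {
  cached("bif0", detect_codim1(branch_phi2_0()))
}

## standard 60 s simulation at an operating point (10 s transient)
sim_at <- function(phi1, phi2, t_record = 50) {
  key <- sprintf("sim_%g_%g_%g", phi1, phi2, t_record)
  cached(key, simulate_lanmm(
    lanmm_params(phi_e1 = phi1, phi_e2 = phi2),
    solver_settings(t_transient = 10, t_record = t_record)))
}

## theta-cycle branch through the fold-of-cycles region at phi_e2 = 0
cycle_branch_flc <- function() {
  cached("cycbr_flc", {
    cyc <- cycle_from_simulation(lanmm_params(phi_e1 = 125))
    continue_cycles(cyc, range = c(115, 185))
  })
}

## a generic linear stable system exposed through the continuation
## interface (no bifurcations anywhere)
linear_cmodel <- function() {
  A <- matrix(c(-2, 1, 0, -3), 2, 2)
  list(
    n = 2,
    f = function(y, lam) as.vector(A %*% y) + c(lam, 0),
    jac = function(y, lam) A,
    dfdp = function(y, lam) c(1, 0),
    observe = function(y, lam) c(y[1], y[2]),
    vary = "mu"
  )
}

expect_within <- function(value, target, tol) {
  expect_true(is.finite(value) && abs(value - target) <= tol,
              label = sprintf("%.6g within %g of %.6g", value, tol, target))
}
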