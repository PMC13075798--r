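#' Parvalbumin-dysfunction scan: bifurcation loci under reduced C7
#'
#' Reducing the PV to superficial-pyramidal coupling \code{C7} models
#' the synaptic damage attributed to amyloid-beta oligomers.  For each
#' \code{C7} value the three loci bounding the multifrequency region
#' (SNIC-labelled fold, the Hopf terminating the slow rhythm, and the
#' Hopf creating the fast cycle) are recomputed over a window of the
#' input plane, together with the fraction of the window where the slow
#' and fast limit cycles coexist (the slow cycle lives between the fold
#' and the first Hopf locus; the fast one past the second Hopf locus).
#'
#' @param params base parameter set (its \code{C7} is overridden).
#' @param c7_values C7 values to scan (include the baseline 550).
#' @param phi2_grid \code{phi_e2} values at which the 1-D loci are
#'   recomputed.
#' @param phi1_range continuation range in \code{phi_e1}; also the
#'   window over which the coexistence fraction is measured.
#' @param area_resolution grid resolution (per axis) of the coexistence
#'   fraction.
#' @return an object of class \code{lanmm_pv_scan}: list with
#'   \code{loci} (data frame: \code{C7}, \code{phi_e2}, \code{fold},
#'   \code{hopf1}, \code{hopf2} in \code{phi_e1} units, NA where a
#'   locus has left the window) and \code{coexistence} (data frame:
#'   \code{C7}, \code{area_fraction}).
#' @export
pv_scan <- function(params = lanmm_params(),
                    c7_values = c(550, 300, 150, 75),
                    phi2_grid = seq(0, 300, by = 50),
                    phi1_range = c(0, 600), area_resolution = 48) {
  loci <- list()
  coex <- list()
  for (c7 in c7_values) {
    p <- params
    p$connectivity[["C7"]] <- c7
    rows <- lapply(phi2_grid, function(p2) {
      pp <- p
      pp$inputs$phi_e2 <- p2
      bif <- equilibrium_bifurcations(pp, vary = "phi_e1",
                                      range = phi1_range)
      ## keep loci that have drifted below the window: a gamma Hopf at
      ## negative phi_e1 means the fast cycle exists across the whole
      ## row, which still bounds the coexistence region correctly
      folds <- bif$param[bif$kind == "fold" & bif$param > -300 &
                           bif$param <= phi1_range[2]]
      ## the slow-rhythm Hopf terminates the large cycle (~10 Hz);
      ## the fast one creates the gamma cycle (~40 Hz)
      hs <- bif[grepl("hopf", bif$kind) & bif$param <= phi1_range[2], ,
                drop = FALSE]
      slow <- hs$param[hs$frequency < 20]
      fast <- hs$param[hs$frequency >= 20]
      data.frame(
        C7 = c7, phi_e2 = p2,
        fold = if (length(folds)) max(folds) else NA_real_,
        hopf1 = if (length(slow)) max(slow) else NA_real_,
        hopf2 = if (length(fast)) min(fast) else NA_real_)
    })
    ldf <- do.call(rbind, rows)
    loci[[length(loci) + 1]] <- ldf
    coex[[length(coex) + 1]] <- data.frame(
      C7 = c7,
      area_fraction = coexistence_fraction(ldf, phi1_range,
                                           range(phi2_grid),
                                           area_resolution))
  }
  structure(list(loci = do.call(rbind, loci),
                 coexistence = do.call(rbind, coex),
                 phi1_range = phi1_range, phi2_grid = phi2_grid),
            class = "lanmm_pv_scan")
}

## fraction of the window where the slow cycle (between fold and first
## Hopf locus) and the fast cycle (past the second Hopf locus) coexist,
## from the interpolated loci geometry
coexistence_fraction <- function(ldf, phi1_range, phi2_range, res) {
  ok <- stats::complete.cases(ldf[, c("fold", "hopf1", "hopf2")])
  if (sum(ok) < 2) return(0)
  li <- function(col) stats::approxfun(ldf$phi_e2[ok], ldf[[col]][ok],
                                       rule = 2)
  f_fold <- li("fold"); f_h1 <- li("hopf1"); f_h2 <- li("hopf2")
  g1 <- seq(phi1_range[1], phi1_range[2], length.out = res)
  g2 <- seq(phi2_range[1], phi2_range[2], length.out = res)
  cnt <- 0
  for (p2 in g2) {
    slow_lo <- f_fold(p2); slow_hi <- f_h1(p2); fast_lo <- f_h2(p2)
    cnt <- cnt + sum(g1 > pmax(slow_lo, fast_lo) & g1 < slow_hi)
  }
  cnt / (res * res)
}

#' @export
print.lanmm_pv_scan <- function(x, ...) {
  cat("PV-dysfunction scan (C7 reduction)\n")
  print(x$coexistence, row.names = FALSE)
  invisible(x)
}

## ------------------------------------------------------------------
## Two-column model: two laminar columns coupled by feedforward
## (P12 -> P22, superficial to superficial) and feedback
## (P21 -> {P11, P12, SST11}) long-range projections.  Long-range
## firing rates enter the target sigmoid arguments scaled by the steady
## AMPA gain A/a, exactly as the external inputs do.

#' Two-column parameter set
#'
#' Column i, layer j indexing: \code{P11}/\code{P21} deep pyramidal,
#' \code{P12}/\code{P22} superficial pyramidal.  All four pyramidal
#' populations receive the same external rate \code{phi}.  The default
#' coupling gains are a documented placeholder set of magnitude
#' comparable to the intra-column constants C11-C13 (the canonical
#' long-range constants are not part of the single-column standard
#' set); with all gains zero the columns evolve independently.
#'
#' @param base single-column [lanmm_params()] shared by both columns.
#' @param phi shared external input rate, 1/s.
#' @param g_ff feedforward gain P12 to P22.
#' @param g_fb_p11,g_fb_p12,g_fb_sst feedback gains from P21 onto P11,
#'   P12 and SST of column 1.
#' @return an object of class \code{lanmm_twocol_params}.
#' @export
two_column_params <- function(base = lanmm_params(), phi = 0,
                              g_ff = 50, g_fb_p11 = 30, g_fb_p12 = 30,
                              g_fb_sst = 30) {
  structure(list(base = base, phi = phi,
                 gains = c(g_ff = g_ff, g_fb_p11 = g_fb_p11,
                           g_fb_p12 = g_fb_p12, g_fb_sst = g_fb_sst)),
            class = "lanmm_twocol_params")
}

as_parm_vector_twocol <- function(tp) {
  pv <- as_parm_vector(tp$base)        # 25 values; slots 24,25 are inputs
  c(pv[1:23], tp$phi, unname(tp$gains))
}

## per-population sigmoid arguments of the 20-dimensional system;
## returns list(args = 10 values (P11,SS1,SST1,P12,PV1,P21,SS2,SST2,P22,PV2),
##              rates of P21 and P12)
twocol_args <- function(state, tp) {
  b <- tp$base
  C <- unname(b$connectivity)
  sg <- b$sigmoid
  kin <- b$kernels$AMPA$A / b$kernels$AMPA$a
  g <- tp$gains
  y1 <- state[1:10]; y2 <- state[11:20]
  a_p21 <- C[1] * y2[2] + C[2] * y2[3] + C[3] * kin * tp$phi + C[11] * y2[4]
  r_p21 <- sigmoid(a_p21, sg$v0, sg$phi0, sg$r)
  a_p11 <- C[1] * y1[2] + C[2] * y1[3] + C[3] * kin * tp$phi +
    C[11] * y1[4] + g[["g_fb_p11"]] * kin * r_p21
  a_p12 <- C[6] * y1[4] + C[7] * y1[5] + C[8] * kin * tp$phi +
    C[12] * y1[1] + g[["g_fb_p12"]] * kin * r_p21
  r_p12 <- sigmoid(a_p12, sg$v0_P2, sg$phi0, sg$r)
  a_p22 <- C[6] * y2[4] + C[7] * y2[5] + C[8] * kin * tp$phi +
    C[12] * y2[1] + g[["g_ff"]] * kin * r_p12
  list(
    args = c(a_p11, C[4] * y1[1],
             C[5] * y1[1] + g[["g_fb_sst"]] * kin * r_p21,
             a_p12, C[9] * y1[4] + C[10] * y1[5] + C[13] * y1[1],
             a_p21, C[4] * y2[1], C[5] * y2[1],
             a_p22, C[9] * y2[4] + C[10] * y2[5] + C[13] * y2[1]),
    r_p21 = r_p21, r_p12 = r_p12, a_p21 = a_p21, a_p12 = a_p12)
}

#' Vector field of the two-column model
#'
#' Reference R implementation; simulation uses the identical compiled
#' version.  With all coupling gains zero the derivative equals two
#' independent single-column evaluations exactly.
#'
#' @param state length-20 state (column 1 then column 2).
#' @param tp a [two_column_params()] object.
#' @return the length-20 time derivative.
#' @export
two_column_rhs <- function(state, tp) {
  if (!all(is.finite(state))) stop("non-finite state")
  b <- tp$base
  sg <- b$sigmoid
  aa <- twocol_args(state, tp)
  v0s <- c(sg$v0, sg$v0, sg$v0, sg$v0_P2, sg$v0)
  s <- sigmoid(aa$args, rep(v0s, 2), sg$phi0, sg$r)
  ka <- rep(c(b$kernels$AMPA$a, b$kernels$AMPA$a, b$kernels$GABA_slow$a,
              b$kernels$AMPA$a, b$kernels$GABA_fast$a), 2)
  kA <- rep(c(b$kernels$AMPA$A, b$kernels$AMPA$A, b$kernels$GABA_slow$A,
              b$kernels$AMPA$A, b$kernels$GABA_fast$A), 2)
  pos <- c(1:5, 11:15)
  der <- c(6:10, 16:20)
  dy <- numeric(20)
  dy[pos] <- state[der]
  dy[der] <- ka * kA * s - 2 * ka * state[der] - ka^2 * state[pos]
  dy
}

#' Analytic Jacobian of the two-column model
#'
#' Includes the long-range chain terms: the feedback rate of P21
#' depends on column-2 states, and the feedforward drive onto P22
#' depends on column-1 states through the P12 rate (which itself
#' carries the feedback dependence).
#'
#' @inheritParams two_column_rhs
#' @return a 20x20 numeric matrix.
#' @export
two_column_jacobian <- function(state, tp) {
  b <- tp$base
  C <- unname(b$connectivity)
  sg <- b$sigmoid
  kin <- b$kernels$AMPA$A / b$kernels$AMPA$a
  g <- tp$gains
  aa <- twocol_args(state, tp)
  aA <- b$kernels$AMPA$a; AA <- b$kernels$AMPA$A
  aGs <- b$kernels$GABA_slow$a; AGs <- b$kernels$GABA_slow$A
  aGf <- b$kernels$GABA_fast$a; AGf <- b$kernels$GABA_fast$A

  ## d a_p21 / d state: C1 y2[2] + C2 y2[3] + C11 y2[4]
  da_p21 <- numeric(20)
  da_p21[12] <- C[1]; da_p21[13] <- C[2]; da_p21[14] <- C[11]
  ds_p21 <- sigmoid_deriv(aa$a_p21, sg$v0, sg$phi0, sg$r) * da_p21

  da_p11 <- numeric(20)
  da_p11[2] <- C[1]; da_p11[3] <- C[2]; da_p11[4] <- C[11]
  da_p11 <- da_p11 + g[["g_fb_p11"]] * kin * ds_p21

  da_p12 <- numeric(20)
  da_p12[4] <- C[6]; da_p12[5] <- C[7]; da_p12[1] <- C[12]
  da_p12 <- da_p12 + g[["g_fb_p12"]] * kin * ds_p21
  ds_p12 <- sigmoid_deriv(aa$a_p12, sg$v0_P2, sg$phi0, sg$r) * da_p12

  da_p22 <- numeric(20)
  da_p22[14] <- C[6]; da_p22[15] <- C[7]; da_p22[11] <- C[12]
  da_p22 <- da_p22 + g[["g_ff"]] * kin * ds_p12

  ## argument gradients for all ten second-order blocks, in state order
  dargs <- list(
    da_p11,
    {d <- numeric(20); d[1] <- C[4]; d},
    {d <- numeric(20); d[1] <- C[5]; d + g[["g_fb_sst"]] * kin * ds_p21},
    da_p12,
    {d <- numeric(20); d[4] <- C[9]; d[5] <- C[10]; d[1] <- C[13]; d},
    da_p21,
    {d <- numeric(20); d[11] <- C[4]; d},
    {d <- numeric(20); d[11] <- C[5]; d},
    da_p22,
    {d <- numeric(20); d[14] <- C[9]; d[15] <- C[10]; d[11] <- C[13]; d})

  v0s <- rep(c(sg$v0, sg$v0, sg$v0, sg$v0_P2, sg$v0), 2)
  ka <- rep(c(aA, aA, aGs, aA, aGf), 2)
  kA <- rep(c(AA, AA, AGs, AA, AGf), 2)
  pos <- c(1:5, 11:15)
  der <- c(6:10, 16:20)
  J <- matrix(0, 20, 20)
  for (k in seq_len(10)) {
    J[pos[k], der[k]] <- 1
    gk <- ka[k] * kA[k] *
      sigmoid_deriv(aa$args[k], v0s[k], sg$phi0, sg$r)
    J[der[k], ] <- gk * dargs[[k]]
    J[der[k], pos[k]] <- J[der[k], pos[k]] - ka[k]^2
    J[der[k], der[k]] <- J[der[k], der[k]] - 2 * ka[k]
  }
  J
}

## derivative of the two-column field w.r.t. the shared input phi
two_column_dfdp <- function(state, tp, eps = 1e-6) {
  tp2 <- tp; tp2$phi <- tp$phi + eps
  tp3 <- tp; tp3$phi <- tp$phi - eps
  (two_column_rhs(state, tp2) - two_column_rhs(state, tp3)) / (2 * eps)
}

#' Observables of the two-column model
#'
#' @inheritParams two_column_rhs
#' @return named numeric \code{c(vP11, vP12, vP21, vP22)} in mV.
#' @export
two_column_observables <- function(state, tp) {
  C <- unname(tp$base$connectivity)
  y1 <- state[1:10]; y2 <- state[11:20]
  c(vP11 = C[1] * y1[2] + C[2] * y1[3] + C[11] * y1[4],
    vP12 = C[6] * y1[4] + C[7] * y1[5] + C[12] * y1[1],
    vP21 = C[1] * y2[2] + C[2] * y2[3] + C[11] * y2[4],
    vP22 = C[6] * y2[4] + C[7] * y2[5] + C[12] * y2[1])
}

## single column driven by the same rate on both inputs (the decoupled
## limit of the two-column model); used as the decoupling oracle
cmodel_single_diag <- function(params) {
  force(params)
  setp <- function(lam) {
    params$inputs$phi_e1 <- lam
    params$inputs$phi_e2 <- lam
    params
  }
  list(
    n = 10,
    f    = function(y, lam) lanmm_rhs(y, setp(lam)),
    jac  = function(y, lam) lanmm_jacobian(y, setp(lam)),
    dfdp = function(y, lam) lanmm_dfdp(y, setp(lam), "phi_e1") +
      lanmm_dfdp(y, setp(lam), "phi_e2"),
    observe = function(y, lam) lanmm_observables(y, setp(lam)),
    setp = setp, vary = "phi"
  )
}

## generic-system interface for the continuation machinery, varying phi
cmodel_twocol <- function(tp) {
  force(tp)
  setp <- function(lam) { tp$phi <- lam; tp }
  list(
    n = 20,
    f    = function(y, lam) two_column_rhs(y, setp(lam)),
    jac  = function(y, lam) two_column_jacobian(y, setp(lam)),
    dfdp = function(y, lam) two_column_dfdp(y, setp(lam)),
    observe = function(y, lam) {
      o <- two_column_observables(y, setp(lam))
      c(o[["vP11"]], o[["vP12"]])
    },
    cparms = function(lam) as_parm_vector_twocol(setp(lam)),
    c_derivs = "lanmm_derivs_twocol",
    c_init = "lanmm_initmod_twocol",
    compiled_var = FALSE,
    setp = setp, vary = "phi"
  )
}

#' Simulate the two-column model
#'
#' Compiled integration of the 20-dimensional coupled system; the four
#' pyramidal observables are sampled after the transient.
#'
#' @param tp a [two_column_params()] object.
#' @param settings a [solver_settings()].
#' @param init initial state (length 20), default zero.
#' @return a data frame of class \code{lanmm_twocol_ts} with columns
#'   \code{t}, \code{vP11}, \code{vP12}, \code{vP21}, \code{vP22}.
#' @export
simulate_two_column <- function(tp, settings = solver_settings(),
                                init = rep(0, 20)) {
  stopifnot(inherits(tp, "lanmm_twocol_params"), length(init) == 20)
  dt <- 1 / settings$sample_rate
  times <- seq(0, settings$t_transient + settings$t_record, by = dt)
  out <- deSolve::ode(init, times, func = "lanmm_derivs_twocol",
                      parms = as_parm_vector_twocol(tp),
                      dllname = "lanmm",
                      initfunc = "lanmm_initmod_twocol",
                      method = "lsoda", rtol = settings$rel_tol,
                      atol = settings$abs_tol, maxsteps = 50000)
  if (!all(is.finite(out[nrow(out), -1]))) stop("integration blew up")
  keep <- out[, 1] >= settings$t_transient - 1e-12
  y <- out[keep, -1, drop = FALSE]
  obs <- t(apply(y, 1, two_column_observables, tp = tp))
  colnames(obs) <- c("vP11", "vP12", "vP21", "vP22")
  ts <- data.frame(t = out[keep, 1] - settings$t_transient, obs)
  structure(ts, class = c("lanmm_twocol_ts", "data.frame"),
            params = tp, sample_rate = settings$sample_rate,
            final_state = unname(y[nrow(y), ]))
}

#' Equilibrium branch and bifurcations of the two-column model
#'
#' Reuses the pseudo-arclength continuation machinery on the
#' 20-dimensional system, varying the shared input \code{phi}.  With
#' zero coupling gains the detected bifurcation values reproduce the
#' single-column ones (duplicated across the two columns).
#'
#' @param tp a [two_column_params()] object.
#' @param range \code{phi} interval.
#' @param both_ends additionally continue a second branch downward from
#'   \code{range[2]} (the equilibrium curve of the coupled system can
#'   be disconnected over the window).
#' @param ... passed to [continue_equilibria()].
#' @return a list with \code{branches} (list of \code{lanmm_eq_branch};
#'   their \code{vP1}/\code{vP2} columns hold \code{vP11}/\code{vP12})
#'   and \code{bifurcations} (a combined [detect_codim1()] data frame).
#' @export
two_column_branch <- function(tp, range = c(0, 600), both_ends = TRUE,
                              ...) {
  model <- cmodel_twocol(tp)
  br1 <- continue_equilibria(NULL, range = range, model = model,
                             guess = rep(0, 20), ...)
  branches <- list(br1)
  bif <- detect_codim1(br1, classify_hopf = FALSE)
  if (both_ends) {
    br2 <- tryCatch(
      continue_equilibria(NULL, range = range, model = model,
                          guess = rep(0, 20), start = range[2],
                          direction = -1, ...),
      error = function(e) NULL)
    if (!is.null(br2)) {
      branches <- c(branches, list(br2))
      b2 <- detect_codim1(br2, classify_hopf = FALSE)
      ## merge, dropping duplicates picked up by both runs
      for (i in seq_len(nrow(b2))) {
        dup <- any(bif$kind == b2$kind[i] &
                     abs(bif$param - b2$param[i]) < 0.5)
        if (!dup) bif <- rbind(bif, b2[i, ])
      }
    }
  }
  if (nrow(bif)) bif <- bif[order(bif$param), ]
  list(branches = branches, bifurcations = bif)
}

#' Periodic-orbit branch of the two-column model
#'
#' Seeds a cycle from simulation at \code{phi_seed} and continues it
#' over \code{range}, detecting FLC/torus/period-doubling events via
#' the Floquet multipliers of the 20-dimensional monodromy matrix.
#'
#' @param tp a [two_column_params()] object.
#' @param phi_seed operating point used to seed the orbit.
#' @param range continuation interval in \code{phi}.
#' @param ... passed to [continue_cycles()].
#' @return list with \code{branch} and \code{bifurcations}.
#' @export
two_column_cycles <- function(tp, phi_seed, range, ...) {
  model <- cmodel_twocol(tp)
  tp$phi <- phi_seed
  ts <- simulate_two_column(tp, solver_settings(t_transient = 15,
                                                t_record = 10))
  per <- estimate_period(ts$vP11, attr(ts, "sample_rate"))
  if (is.na(per)) stop("no oscillation at the seed point")
  sol <- shoot_newton(model, attr(ts, "final_state"), per, phi_seed)
  if (!sol$ok) stop("shooting failed for the two-column orbit")
  cyc <- make_cycle(model, sol, phi_seed)
  br <- continue_cycles(cyc, range, model = model, ...)
  list(branch = br, bifurcations = detect_cycle_bifurcations(br))
}
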